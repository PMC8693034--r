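#' Backbone structures
#'
#' A `backbone` object stores, per residue, the coordinates of the
#' heavy backbone atoms N, CA, C and (when present) CB.  CA is required
#' for every modelled residue; CB may be absent (glycine).
#'
#' @param residue_index Integer vector of residue numbers (1-based at
#'   file boundaries).
#' @param aa Character vector of one-letter residue codes.
#' @param n,ca,c,cb Numeric L x 3 coordinate matrices; rows of `cb` may
#'   be `NA` where no CB exists.
#' @return An object of class `backbone`.
#' @export
new_backbone <- function(residue_index, aa, n, ca, c, cb) {
  L <- length(residue_index)
  for (m in list(n, ca, c, cb)) {
    stopifnot(is.matrix(m), nrow(m) == L, ncol(m) == 3)
  }
  if (anyNA(ca) || !all(is.finite(ca))) {
    stop_protgeom("CA coordinates must be present and finite for every residue")
  }
  structure(
    list(residue_index = as.integer(residue_index), aa = aa,
         n = n, ca = ca, c = c, cb = cb),
    class = "backbone"
  )
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf(
    "<backbone> %d residues, %d with CB\n",
    length(x$residue_index), sum(stats::complete.cases(x$cb))
  ))
  invisible(x)
}

#' @export
length.backbone <- function(x) length(x$residue_index)

#' Read backbone atoms from a PDB file
#'
#' Keeps the N/CA/C/CB atoms of one chain from the `ATOM` records.
#' Alternate locations are resolved by first occurrence; residues
#' lacking a CA are dropped with a warning.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier; default takes the first chain present.
#' @return A [new_backbone()] object.
#' @export
read_backbone <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop_protgeom("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop_protgeom("no ATOM records for chain ", chain)
  at <- at[at$elety %in% c("N", "CA", "C", "CB"), , drop = FALSE]
  # altloc: first occurrence wins
  key <- paste(at$resno, at$elety)
  first <- !duplicated(key)
  dup <- at[!first, , drop = FALSE]
  if (nrow(dup) > 0L) {
    kept <- at[first, , drop = FALSE]
    for (r in seq_len(nrow(dup))) {
      k <- paste(dup$resno[r], dup$elety[r])
      i <- match(k, paste(kept$resno, kept$elety))
      same_alt <- identical(dup$alt[r], kept$alt[i]) ||
        (is.na(dup$alt[r]) && is.na(kept$alt[i]))
      differs <- any(abs(
        c(dup$x[r], dup$y[r], dup$z[r]) -
          c(kept$x[i], kept$y[i], kept$z[i])
      ) > 1e-6)
      if (same_alt && differs) {
        stop_protgeom(sprintf(
          "duplicate atom %s in residue %d with conflicting coordinates",
          dup$elety[r], dup$resno[r]
        ))
      }
    }
  }
  at <- at[first, , drop = FALSE]
  resno <- sort(unique(at$resno))
  grab <- function(ety) {
    i <- match(paste(resno, ety), paste(at$resno, at$elety))
    cbind(at$x[i], at$y[i], at$z[i])
  }
  n <- grab("N"); ca <- grab("CA"); cc <- grab("C"); cb <- grab("CB")
  has_ca <- stats::complete.cases(ca)
  if (!all(has_ca)) {
    warning(sprintf(
      "dropping %d residue(s) lacking CA", sum(!has_ca)
    ), call. = FALSE)
    n <- n[has_ca, , drop = FALSE]; ca <- ca[has_ca, , drop = FALSE]
    cc <- cc[has_ca, , drop = FALSE]; cb <- cb[has_ca, , drop = FALSE]
    resno <- resno[has_ca]
  }
  aa3 <- at$resid[match(paste(resno, "CA"), paste(at$resno, at$elety))]
  aa <- suppressWarnings(bio3d::aa321(aa3))
  aa[is.na(aa)] <- "X"
  new_backbone(resno, aa, n, ca, cc, cb)
}

aa123_safe <- function(aa) {
  out <- suppressWarnings(bio3d::aa123(aa))
  out[is.na(out) | out == "UNK"] <- "ALA"
  out
}

#' Write a backbone (or CB trace) as PDB
#'
#' @param struct A [new_backbone()] object.
#' @param path Output path.
#' @param chain Chain identifier to write.
#' @return `path`, invisibly.
#' @export
write_backbone <- function(struct, path, chain = "A") {
  L <- length(struct)
  xyz <- c(); elety <- c(); resno <- c(); resid <- c()
  aa3 <- aa123_safe(struct$aa)
  for (i in seq_len(L)) {
    for (ety in c("N", "CA", "C", "CB")) {
      m <- struct[[tolower(ety)]]
      if (anyNA(m[i, ])) next
      xyz <- c(xyz, m[i, ])
      elety <- c(elety, ety)
      resno <- c(resno, struct$residue_index[i])
      resid <- c(resid, aa3[i])
    }
  }
  bio3d::write.pdb(
    file = path, xyz = xyz, elety = elety, resno = resno,
    resid = resid, chain = rep(chain, length(elety))
  )
  invisible(path)
}

#' Write a CB-only coordinate trace as PDB
#'
#' Used to export coarse-grained models from the distance-geometry
#' realiser.
#'
#' @param xyz L x 3 coordinate matrix.
#' @param path Output path.
#' @param aa Optional one-letter sequence (defaults to alanine).
#' @return `path`, invisibly.
#' @export
write_cb_trace <- function(xyz, path, aa = NULL) {
  L <- nrow(xyz)
  aa <- aa %||% rep("A", L)
  bio3d::write.pdb(
    file = path, xyz = as.vector(t(xyz)),
    elety = rep("CB", L), resno = seq_len(L),
    resid = aa123_safe(aa), chain = rep("A", L)
  )
  invisible(path)
}
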