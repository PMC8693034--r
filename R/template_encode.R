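#' One-hot template geometry encoding
#'
#' Encodes a template's binned geometry into the query frame as an
#' L x L x 100 one-hot feature map (37 distance + 25 omega + 25 theta
#' + 13 phi channels).  A query pair (i, j) carries the one-hot of the
#' template labels at the aligned template pair; pairs with either
#' endpoint unaligned are all-zero, so each pair's channel sum is 0 or
#' 4.  The per-pair alignment confidence is
#' `s(i, j) = (s(i) + s(j)) / 2` with `s = 0` at unaligned positions.
#'
#' @param labels [bin_geometries()] labels computed on the template's
#'   own coordinates.
#' @param hit A one-row hits tibble (see [new_template_hit()]) mapping
#'   query to template positions.
#' @param l_query Query length L.
#' @return A list with `feat` (L x L x 100 array) and `s` (L x L
#'   confidence map).
#' @export
encode_template <- function(labels, hit, l_query) {
  al <- hit$alignment[[1]]
  lt <- nrow(labels$dist)
  if (any(al$query_pos < 1L | al$query_pos > l_query)) {
    stop_protgeom("alignment references query positions outside 1..L")
  }
  if (any(al$template_pos < 1L | al$template_pos > lt)) {
    stop_protgeom("alignment references template positions outside 1..L_template")
  }
  na <- nrow(al)
  feat <- array(0, c(l_query, l_query, 100L))
  ai <- rep(seq_len(na), times = na)
  bi <- rep(seq_len(na), each = na)
  qi <- al$query_pos[ai]; qj <- al$query_pos[bi]
  ti <- al$template_pos[ai]; tj <- al$template_pos[bi]
  tt <- cbind(ti, tj)
  offs <- c(dist = 0L, omega = 37L, theta = 62L, phi = 87L)
  for (h in names(offs)) {
    feat[cbind(qi, qj, offs[[h]] + labels[[h]][tt] + 1L)] <- 1
  }
  s_pos <- rep(0, l_query)
  s_pos[al$query_pos] <- al$confidence
  list(feat = feat, s = outer(s_pos, s_pos, `+`) / 2)
}

#' Build the multi-template feature stack
#'
#' Computes and bins each template's geometry, encodes it into the
#' query frame, and collects the per-template confidence maps.  At most
#' 10 templates are accepted (run [filter_and_rank_templates()] first).
#'
#' @param hits A hits tibble (already filtered to good templates).
#' @param template_structs List of [new_backbone()] template
#'   structures, parallel to the rows of `hits`.
#' @param l_query Query length L.
#' @return An object of class `template_stack`: list with `feats`
#'   (list of L x L x 100 arrays), `s` (list of L x L confidence
#'   maps), `ids` and `n`.
#' @export
build_template_stack <- function(hits, template_structs, l_query) {
  n <- nrow(hits)
  if (n != length(template_structs)) {
    stop_protgeom("hits and template_structs lengths differ")
  }
  if (n > 10L) {
    stop_protgeom("at most 10 templates enter the stack; filter first")
  }
  enc <- purrr::map(seq_len(n), function(k) {
    labels <- bin_geometries(compute_geometries(template_structs[[k]]))
    encode_template(labels, hits[k, ], l_query)
  })
  structure(
    list(
      feats = purrr::map(enc, "feat"),
      s = purrr::map(enc, "s"),
      ids = hits$template_id,
      n = n
    ),
    class = "template_stack"
  )
}

#' @export
print.template_stack <- function(x, ...) {
  cat(sprintf(
    "<template_stack> %d template(s), L = %d, 100 channels each\n",
    x$n, if (x$n > 0) dim(x$feats[[1]])[1] else NA_integer_
  ))
  invisible(x)
}

#' Argmax-decode an encoded template back to label maps
#'
#' Inverse of [encode_template()] on fully aligned pairs; unaligned
#' (all-zero) pairs decode to label 0.  Used for encode/decode
#' consistency checks.
#'
#' @param feat An L x L x 100 template feature array.
#' @return A `geometry_labels` list.
#' @export
decode_template <- function(feat) {
  L <- dim(feat)[1]
  slices <- list(
    dist = 1:37, omega = 38:62, theta = 63:87, phi = 88:100
  )
  out <- purrr::map(slices, function(ix) {
    sub <- feat[, , ix, drop = FALSE]
    lab <- apply(sub, c(1, 2), which.max) - 1L
    covered <- apply(sub, c(1, 2), max) > 0
    matrix(as.integer(ifelse(covered, lab, 0L)), L, L)
  })
  out$mask <- apply(feat[, , 1:37, drop = FALSE], c(1, 2), max) > 0 &
    out$dist > 0
  structure(out, class = "geometry_labels")
}
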