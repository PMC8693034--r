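# Synthetic benchmark data: toy compact backbones, covariation-bearing
# MSAs and noisy partially-covering templates, so that featurisation,
# both networks, fusion, training and realization can run end to end
# without any external database.

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# 8 physicochemical residue classes used for class-preserving joint
# substitutions at covarying contact pairs.
AA_CLASSES <- c("AVLIM", "FWY", "KR", "DE", "ST", "NQ", "CG", "HP")

#' Generate a compact toy backbone
#'
#' Builds a self-avoiding CA walk with 3.8 A steps confined to a
#' sphere sized at ~135 cubic Angstrom per residue (protein-like
#' packing), mixing turns and extended stretches; enforces a minimum
#' non-local CA-CA distance of 3.5 A (|i-j| >= 3).  N and C are placed
#' on ideal local geometry around each CA and CB by [virtual_cbeta()];
#' glycines carry no CB.  Chains are regenerated until they are folded
#' rather than extended: at least `2 L` pairs with CB-CB distance
#' < 8 A at separation >= 12.
#'
#' @param L Chain length (>= 8).
#' @param seed Optional RNG seed.
#' @param min_long_contacts Compactness requirement; defaults to
#'   `2 * L` for chains of 36 residues or more and is waived for
#'   shorter toys, where separation-12 pairs are too scarce.
#' @param max_tries Chain regeneration budget.
#' @return A [new_backbone()] object.
#' @export
gen_backbone <- function(L, seed = NULL, min_long_contacts = NULL,
                         max_tries = 200L) {
  if (L < 8L) stop_protgeom("L must be >= 8")
  if (!is.null(seed)) set.seed(seed)
  min_long_contacts <- min_long_contacts %||% if (L >= 36L) 2L * L else 0L
  radius <- (3 * L * 135 / (4 * pi))^(1 / 3)
  for (try in seq_len(max_tries)) {
    ca <- gen_ca_walk(L, radius)
    if (is.null(ca)) next
    struct <- backbone_from_ca(ca)
    gm <- compute_geometries(struct)
    sep <- abs(row(gm$d) - col(gm$d))
    n_long <- sum(gm$d < 8 & sep >= 12 & upper.tri(gm$d))
    if (n_long >= min_long_contacts) return(struct)
  }
  stop_protgeom("backbone placement failed; try a smaller L")
}

gen_ca_walk <- function(L, radius, step = 3.8) {
  ca <- matrix(0, L, 3)
  dir <- rand_unit()
  for (i in 2:L) {
    placed <- FALSE
    for (att in 1:120) {
      prop <- 0.55 * dir + 0.9 * rand_unit()
      r <- sqrt(sum(ca[i - 1, ]^2))
      if (r > 0.75 * radius) {
        prop <- prop - 1.2 * (r / radius - 0.75) * ca[i - 1, ] / r
      }
      prop <- prop / sqrt(sum(prop^2))
      cand <- ca[i - 1, ] + step * prop
      ok <- TRUE
      if (i >= 3 && sqrt(sum((cand - ca[i - 2, ])^2)) < 4.6) ok <- FALSE
      if (ok && i >= 4) {
        dd <- sqrt(rowSums((ca[seq_len(i - 3), , drop = FALSE] -
                              matrix(cand, i - 3, 3, byrow = TRUE))^2))
        if (min(dd) < 3.5) ok <- FALSE
      }
      if (ok) {
        ca[i, ] <- cand
        dir <- prop
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  ca
}

# Ideal-geometry N, C and CB around a CA trace; ~7% glycines lack CB.
backbone_from_ca <- function(ca) {
  L <- nrow(ca)
  aa <- sample(strsplit("ARNDCQEGHILKMFPSTWYVG", "")[[1]], L, replace = TRUE)
  n <- cc <- matrix(0, L, 3)
  beta <- 34.5 * pi / 180
  for (i in seq_len(L)) {
    prev <- if (i > 1) ca[i - 1, ] else 2 * ca[1, ] - ca[2, ]
    nxt <- if (i < L) ca[i + 1, ] else 2 * ca[L, ] - ca[L - 1, ]
    t1 <- (ca[i, ] - prev); t1 <- t1 / sqrt(sum(t1^2))
    t2 <- (nxt - ca[i, ]); t2 <- t2 / sqrt(sum(t2^2))
    axis <- t1 + t2
    if (sqrt(sum(axis^2)) < 1e-6) axis <- t1
    axis <- axis / sqrt(sum(axis^2))
    nrm <- vcross(matrix(t1, 1), matrix(t2, 1))[1, ]
    if (sqrt(sum(nrm^2)) < 1e-6) {
      nrm <- vcross(matrix(axis, 1), matrix(rand_unit(), 1))[1, ]
    }
    nrm <- nrm / sqrt(sum(nrm^2))
    u <- -cos(beta) * axis + sin(beta) * nrm
    v <- cos(beta) * axis + sin(beta) * nrm
    n[i, ] <- ca[i, ] + 1.458 * u / sqrt(sum(u^2))
    cc[i, ] <- ca[i, ] + 1.525 * v / sqrt(sum(v^2))
  }
  cb <- virtual_cbeta(n, ca, cc)
  cb[aa == "G", ] <- NA_real_
  new_backbone(seq_len(L), aa, n, ca, cc, cb)
}

#' Generate a covariation-bearing synthetic MSA
#'
#' Row 0 is the target sequence.  Contacting position pairs (CB-CB
#' distance < 8 A, separation >= 6; reduced to a greedy matching so
#' each column joins at most one pair) mutate jointly: with probability
#' `coupling_strength` the pair is resampled through a fixed per-pair
#' bijection between eight physicochemical residue classes, which is
#' the covariation signal the coupling features are meant to detect.
#' All other columns mutate independently; gaps are inserted at
#' `gap_rate` in non-query rows.
#'
#' @param structure A [new_backbone()] target.
#' @param n_rows Number of alignment rows (>= 2).
#' @param coupling_strength Joint-mutation probability at coupled
#'   pairs.
#' @param gap_rate Per-cell gap probability.
#' @param mut_rate Independent mutation probability per column.
#' @param seed Optional RNG seed.
#' @return An [new_msa()] object.
#' @export
gen_msa <- function(structure, n_rows = 100, coupling_strength = 0.9,
                    gap_rate = 0.02, mut_rate = 0.35, seed = NULL) {
  if (n_rows < 2L) stop_protgeom("n_rows must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  L <- length(structure)
  query <- structure$aa
  query[!query %in% strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]] <- "A"
  gm <- compute_geometries(structure)
  sep <- abs(row(gm$d) - col(gm$d))
  cand <- which(gm$d < 8 & sep >= 6 & upper.tri(gm$d) & gm$mask,
                arr.ind = TRUE)
  if (nrow(cand) > 0) cand <- cand[order(gm$d[cand]), , drop = FALSE]
  used <- rep(FALSE, L)
  pairs <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!used[i] && !used[j]) {
      used[i] <- used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  cls <- strsplit(AA_CLASSES, "")
  sigma <- lapply(pairs, function(p) sample.int(length(cls)))
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  indep <- setdiff(seq_len(L), unlist(pairs))
  rows <- character(n_rows)
  rows[1] <- paste(query, collapse = "")
  for (r in 2:n_rows) {
    s <- query
    mut <- indep[runif(length(indep)) < mut_rate]
    s[mut] <- sample(aa20, length(mut), replace = TRUE)
    for (pi in seq_along(pairs)) {
      p <- pairs[[pi]]
      if (runif(1) < coupling_strength) {
        c1 <- sample.int(length(cls), 1)
        c2 <- sigma[[pi]][c1]
        s[p[1]] <- sample(cls[[c1]], 1)
        s[p[2]] <- sample(cls[[c2]], 1)
      } else {
        for (q in p) {
          if (runif(1) < mut_rate) s[q] <- sample(aa20, 1)
        }
      }
    }
    gp <- runif(L) < gap_rate
    s[gp] <- "-"
    rows[r] <- paste(s, collapse = "")
  }
  new_msa(c("query", sprintf("syn%03d", seq_len(n_rows - 1L))), rows)
}

#' Generate noisy partially-covering synthetic templates
#'
#' Each template copies the target coordinates on a contiguous covered
#' segment, perturbed by isotropic Gaussian noise of standard
#' deviation `noise_sd`; the alignment is the identity on covered
#' positions, the per-position confidence is `exp(-noise_sd)`
#' uniformly, and probability/E-value are set to pass (or fail) the
#' good-template filter according to `good`.
#'
#' @param structure A [new_backbone()] target.
#' @param noise_sd Coordinate noise (Angstrom).
#' @param coverage Fraction of the target covered, in (0, 1].
#' @param n_templates Number of templates.
#' @param good Logical (recycled): should each hit pass the
#'   good-template filter?
#' @param seed Optional RNG seed.
#' @return A list with `hits` (hits tibble) and `templates` (list of
#'   [new_backbone()]).
#' @export
gen_templates <- function(structure, noise_sd = 0.5, coverage = 1,
                          n_templates = 1, good = TRUE, seed = NULL) {
  if (coverage <= 0 || coverage > 1) stop_protgeom("coverage must be in (0, 1]")
  if (n_templates < 1L) stop_protgeom("n_templates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  L <- length(structure)
  good <- rep_len(good, n_templates)
  seg_len <- ceiling(coverage * L)
  hits <- list(); templates <- list()
  for (k in seq_len(n_templates)) {
    start <- if (seg_len == L) 1L else sample.int(L - seg_len + 1L, 1)
    idx <- start:(start + seg_len - 1L)
    noise <- function(m) {
      m + matrix(rnorm(length(m), sd = noise_sd), nrow(m), 3)
    }
    tmpl <- new_backbone(
      seq_len(seg_len), structure$aa[idx],
      noise(structure$n[idx, , drop = FALSE]),
      noise(structure$ca[idx, , drop = FALSE]),
      noise(structure$c[idx, , drop = FALSE]),
      structure$cb[idx, , drop = FALSE] +
        matrix(rnorm(seg_len * 3, sd = noise_sd), seg_len, 3)
    )
    hits[[k]] <- new_template_hit(
      template_id = sprintf("tpl%02d", k),
      probability = if (good[k]) 95 else 30,
      evalue = if (good[k]) 1e-10 else 0.5,
      query_pos = idx, template_pos = seq_len(seg_len),
      confidence = rep(exp(-noise_sd), seg_len)
    )
    templates[[k]] <- tmpl
  }
  list(hits = dplyr::bind_rows(hits), templates = templates)
}

#' Generate a full synthetic target
#'
#' Bundles a backbone, its true geometry labels, a covariation-bearing
#' MSA and (optionally) templates into one benchmark unit.
#'
#' @inheritParams gen_backbone
#' @inheritParams gen_msa
#' @param msa_depth Number of MSA rows (drawn uniformly from a range
#'   if length 2).
#' @param n_templates Number of synthetic templates (0 for none).
#' @param template_noise_sd,template_coverage Template parameters.
#' @return A list of class `synthetic_target` with `structure`,
#'   `msa`, `maps`, `labels`, and optionally `hits`/`templates`.
#' @export
gen_target <- function(L = 48, msa_depth = c(30, 200),
                       coupling_strength = 0.9, n_templates = 0,
                       template_noise_sd = 0.5, template_coverage = 1,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bb <- gen_backbone(L)
  depth <- if (length(msa_depth) == 2L) {
    sample(seq(msa_depth[1], msa_depth[2]), 1)
  } else {
    msa_depth
  }
  msa <- gen_msa(bb, n_rows = depth,
                 coupling_strength = coupling_strength)
  maps <- compute_geometries(bb)
  out <- list(
    structure = bb, msa = msa, maps = maps,
    labels = bin_geometries(maps)
  )
  if (n_templates > 0) {
    tp <- gen_templates(bb, noise_sd = template_noise_sd,
                        coverage = template_coverage,
                        n_templates = n_templates)
    out$hits <- tp$hits
    out$templates <- tp$templates
  }
  structure(out, class = "synthetic_target")
}

#' Generate a dataset of synthetic targets
#'
#' @inheritParams gen_target
#' @param n Number of targets.
#' @param seed RNG seed for reproducibility.
#' @return A list of `synthetic_target` objects.
#' @export
gen_dataset <- function(n, L = 48, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) gen_target(L = L, ...))
}
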