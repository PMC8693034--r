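#' Expected distances from the predicted distance head
#'
#' A simplified restraint extraction: pairs whose no-contact
#' probability is at most `tau` are restrained to the expectation of
#' the 36 contact-bin midpoints under the renormalised contact-bin
#' distribution; other pairs are unrestrained.
#'
#' @param p_d An L x L x 37 normalised distance head.
#' @param tau No-contact probability threshold.
#' @return A list of class `distance_restraints` with `d` (L x L
#'   expected distance, NA when unrestrained) and logical `mask`.
#' @export
expected_distance <- function(p_d, tau = 0.5) {
  if (dim(p_d)[3] != 37L) stop_protgeom("distance head must have 37 bins")
  L <- dim(p_d)[1]
  p0 <- p_d[, , 1]
  mask <- p0 <= tau
  diag(mask) <- FALSE
  mids <- distance_bin_midpoints()
  num <- array(0, c(L, L))
  for (b in seq_len(36)) num <- num + p_d[, , b + 1] * mids[b]
  den <- apply(p_d[, , 2:37, drop = FALSE], c(1, 2), sum)
  d <- ifelse(mask & den > 0, num / pmax(den, .Machine$double.eps), NA_real_)
  structure(list(d = d, mask = mask & !is.na(d)), class = "distance_restraints")
}

# Quadratic stress of coordinates against target distances on the
# restrained pairs (each unordered pair counted once).
restraint_stress <- function(xyz, restraints) {
  dm <- as.matrix(stats::dist(xyz))
  m <- restraints$mask & upper.tri(restraints$mask)
  sum((dm[m] - restraints$d[m])^2)
}

stress_grad <- function(xvec, L, target, mask_ut) {
  xyz <- matrix(xvec, L, 3)
  dm <- as.matrix(stats::dist(xyz))
  err <- matrix(0, L, L)
  err[mask_ut] <- dm[mask_ut] - target[mask_ut]
  err <- err + t(err)
  dm_safe <- dm + diag(L) + (dm == 0)
  coef <- 2 * err / dm_safe
  g <- matrix(0, L, 3)
  for (a in 1:3) {
    diffs <- outer(xyz[, a], xyz[, a], `-`)
    g[, a] <- rowSums(coef * diffs)
  }
  as.vector(g)
}

stress_fn <- function(xvec, L, target, mask_ut) {
  xyz <- matrix(xvec, L, 3)
  dm <- as.matrix(stats::dist(xyz))
  sum((dm[mask_ut] - target[mask_ut])^2)
}

#' Embed distance restraints into 3D coordinates
#'
#' Distance-geometry realisation: the partial distance matrix is
#' completed by shortest paths over the restraint graph, embedded by
#' classical multidimensional scaling, and polished by L-BFGS-B
#' minimisation of the masked quadratic stress with an analytic
#' gradient.  The final stress never exceeds the stress of the MDS
#' initialisation.
#'
#' @param restraints An [expected_distance()] result (or any list with
#'   `d` and `mask`).
#' @param jitter Standard deviation (Angstrom) of Gaussian noise added
#'   to the MDS initialisation (used by the decoy protocol).
#' @param maxit Maximum L-BFGS-B iterations.
#' @return A list of class `embedding` with `xyz` (L x 3), `stress`
#'   and `stress_init`.
#' @export
embed_restraints <- function(restraints, jitter = 0, maxit = 500) {
  L <- nrow(restraints$d)
  m <- restraints$mask
  ij <- which(m & upper.tri(m), arr.ind = TRUE)
  if (nrow(ij) == 0L) stop_protgeom("no restrained pairs to embed")
  g <- igraph::graph_from_data_frame(
    data.frame(from = ij[, 1], to = ij[, 2],
               weight = restraints$d[ij]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(L))
  )
  if (igraph::components(g)$no > 1L) {
    stop_protgeom("restraint graph is disconnected; cannot embed")
  }
  full <- igraph::distances(g)
  full <- full[order(as.integer(rownames(full))),
               order(as.integer(colnames(full)))]
  xyz <- cmdscale(stats::as.dist(full), k = 3)
  if (ncol(xyz) < 3) xyz <- cbind(xyz, matrix(0, L, 3 - ncol(xyz)))
  if (jitter > 0) xyz <- xyz + matrix(rnorm(L * 3, sd = jitter), L, 3)
  mask_ut <- m & upper.tri(m)
  s0 <- stress_fn(as.vector(xyz), L, restraints$d, mask_ut)
  opt <- optim(
    as.vector(xyz), fn = stress_fn, gr = stress_grad,
    L = L, target = restraints$d, mask_ut = mask_ut,
    method = "L-BFGS-B", control = list(maxit = maxit)
  )
  structure(
    list(xyz = matrix(opt$par, L, 3), stress = opt$value, stress_init = s0),
    class = "embedding"
  )
}

#' Decoy generation and selection protocol
#'
#' Generates `n_decoys` (default 120) randomised embeddings, keeps the
#' `n_keep` (default 5) with the lowest stress, refines those with
#' additional minimisation iterations, and returns the single
#' lowest-stress model.
#'
#' @inheritParams embed_restraints
#' @param n_decoys Number of coarse decoys generated.
#' @param n_keep Number of lowest-stress decoys refined.
#' @param jitter Initialisation noise (Angstrom) for decoy diversity.
#' @param decoy_maxit,refine_maxit Minimisation iteration budgets.
#' @return A list of class `decoy_result`: `model` (the best
#'   `embedding`), `decoy_stress` (length `n_decoys`), `kept` indices,
#'   `n_decoys`, `n_keep`.
#' @export
decoy_protocol <- function(restraints, n_decoys = 120, n_keep = 5,
                           jitter = 2, decoy_maxit = 60,
                           refine_maxit = 500) {
  if (n_decoys < 1) stop_protgeom("n_decoys must be >= 1")
  if (n_keep > n_decoys) stop_protgeom("n_keep cannot exceed n_decoys")
  decoys <- lapply(seq_len(n_decoys), function(i) {
    embed_restraints(restraints, jitter = if (i == 1) 0 else jitter,
                     maxit = decoy_maxit)
  })
  stress <- vapply(decoys, `[[`, numeric(1), "stress")
  kept <- order(stress)[seq_len(n_keep)]
  refined <- lapply(decoys[kept], function(d) {
    refine_embedding(d, restraints, maxit = refine_maxit)
  })
  rs <- vapply(refined, `[[`, numeric(1), "stress")
  structure(
    list(
      model = refined[[which.min(rs)]], decoy_stress = stress,
      kept = kept, n_decoys = n_decoys, n_keep = n_keep
    ),
    class = "decoy_result"
  )
}

refine_embedding <- function(emb, restraints, maxit = 500) {
  L <- nrow(emb$xyz)
  mask_ut <- restraints$mask & upper.tri(restraints$mask)
  opt <- optim(
    as.vector(emb$xyz), fn = stress_fn, gr = stress_grad,
    L = L, target = restraints$d, mask_ut = mask_ut,
    method = "L-BFGS-B", control = list(maxit = maxit)
  )
  structure(
    list(xyz = matrix(opt$par, L, 3), stress = opt$value,
         stress_init = emb$stress),
    class = "embedding"
  )
}

#' Optimal superposition RMSD (Kabsch)
#'
#' Coordinates from distance geometry are defined only up to rigid
#' motion (and reflection), so accuracy is measured after optimal
#' superposition, allowing reflection.
#'
#' @param a,b L x 3 coordinate matrices.
#' @return The root-mean-square deviation after superposition.
#' @export
kabsch_rmsd <- function(a, b) {
  ac <- scale(a, scale = FALSE); bc <- scale(b, scale = FALSE)
  best <- Inf
  for (flip in c(1, -1)) {
    bf <- bc %*% diag(c(1, 1, flip))
    s <- svd(crossprod(bf, ac))            # H = bf' ac = U D V'
    d <- sign(det(s$u %*% t(s$v)))
    rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    dev <- ac - bf %*% rot
    best <- min(best, sqrt(mean(rowSums(dev^2))))
  }
  best
}
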