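#' Per-pair fusion weights between the TBM and FM posteriors
#'
#' The TBM weight at pair (i, j) is the attention-weighted template
#' confidence `w_TBM(i, j) = sum_k w_k(i, j) s_k(i, j)` with
#' `s_k(i, j) = (s_k(i) + s_k(j)) / 2`; since the attention weights are
#' normalised and s_k lies in \[0,1\], w_TBM is automatically in
#' \[0,1\].  When no good templates are detected, w_TBM is identically
#' zero (FM-only mode), and `w_FM = 1 - w_TBM` everywhere.
#'
#' @param w An `attention_weights` array (N x L x L), or `NULL` when
#'   no good templates exist.
#' @param s List of per-template L x L confidence maps (e.g.
#'   `stack$s`), or `NULL`.
#' @param l_query Query length (required when `w` is `NULL`).
#' @return A list of class `fusion_weights` with `w_tbm` and `w_fm`
#'   (L x L, summing to one exactly).
#' @export
tbm_weight <- function(w, s, l_query = NULL) {
  if (is.null(w) || length(s) == 0L) {
    if (is.null(l_query)) {
      stop_protgeom("l_query needed to build FM-only fusion weights")
    }
    w_tbm <- matrix(0, l_query, l_query)
  } else {
    if (dim(w)[1] != length(s)) {
      stop_protgeom("attention weights and confidence maps disagree on N")
    }
    w_tbm <- matrix(0, dim(w)[2], dim(w)[3])
    for (k in seq_along(s)) {
      w_tbm <- w_tbm + w[k, , ] * s[[k]]
    }
    w_tbm <- pmax(pmin(w_tbm, 1), 0)
  }
  structure(list(w_tbm = w_tbm, w_fm = 1 - w_tbm),
            class = "fusion_weights")
}

#' Fuse the FM and TBM posteriors pixel-wise
#'
#' Per pair and per head the fused distribution is the convex
#' combination `w_FM p_FM + w_TBM p_TBM`; a single weight map is shared
#' across the four heads.  With w_TBM = 0 the output equals the FM
#' posterior bitwise, with w_TBM = 1 the TBM posterior.
#'
#' @param p_fm,p_tbm Normalised [new_geometry_posterior()] objects of
#'   equal L.
#' @param fw A [tbm_weight()] result.
#' @return The fused `geometry_posterior`.
#' @export
fuse_posteriors <- function(p_fm, p_tbm, fw) {
  if (!identical(dim(p_fm$dist)[1], dim(p_tbm$dist)[1]) ||
      !identical(dim(p_fm$dist)[1], nrow(fw$w_tbm))) {
    stop_protgeom("posterior/weight shapes do not match")
  }
  mix <- function(a, b) {
    a * as.numeric(fw$w_fm) + b * as.numeric(fw$w_tbm)
  }
  new_geometry_posterior(
    mix(p_fm$dist, p_tbm$dist), mix(p_fm$omega, p_tbm$omega),
    mix(p_fm$theta, p_tbm$theta), mix(p_fm$phi, p_tbm$phi)
  )
}

#' Mean-ensemble of geometry posteriors
#'
#' Per-pixel arithmetic mean of each head over an ensemble of
#' predictions (e.g. several trained models or MSA subsamples).
#'
#' @param posteriors Nonempty list of equal-shape
#'   [new_geometry_posterior()] objects.
#' @return The averaged posterior.
#' @export
ensemble_mean <- function(posteriors) {
  if (length(posteriors) == 0L) stop_protgeom("empty ensemble")
  avg <- function(h) {
    Reduce(`+`, lapply(posteriors, `[[`, h)) / length(posteriors)
  }
  new_geometry_posterior(avg("dist"), avg("omega"), avg("theta"), avg("phi"))
}

#' Select the best MSA by predicted top-contact probability
#'
#' Scores each candidate alignment by running the FM network and
#' averaging the contact probability over its top-scoring `2L` pairs
#' (i < j, sequence separation >= 6); the candidate with the highest
#' mean wins, ties resolved to the lowest index.
#'
#' @param candidates Nonempty list of [new_msa()] objects.
#' @param net A trained [res2net_fm()].
#' @param n_top Number of top pairs averaged; default `2 * L`.
#' @param min_separation Minimum |i - j| of scored pairs.
#' @return The index of the selected MSA.
#' @export
select_msa <- function(candidates, net, n_top = NULL, min_separation = 6) {
  if (length(candidates) == 0L) stop_protgeom("no candidate MSAs")
  scores <- vapply(candidates, function(m) {
    p <- forward_fm(net, msa_features(m))$posterior
    cp <- contact_probability(symmetrize(p)$dist)
    L <- nrow(cp)
    ii <- rep(seq_len(L), L); jj <- rep(seq_len(L), each = L)
    keep <- ii < jj & (jj - ii) >= min_separation
    v <- sort(cp[cbind(ii[keep], jj[keep])], decreasing = TRUE)
    mean(head(v, n_top %||% (2L * L)))
  }, numeric(1))
  which.max(scores)
}
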