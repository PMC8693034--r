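#' Template-based prediction for one target
#'
#' Runs the frozen FM front on the MSA features, computes the axial
#' attention weights against the template stack, combines the
#' templates, and runs the TBM trunk.
#'
#' @param net A [res2net_tbm()].
#' @param features An L x L x 526 feature tensor.
#' @param stack A [build_template_stack()] with at least one template.
#' @return A list with `posterior`, `attention` (N x L x L array) and
#'   `combined` (L x L x 100).
#' @export
predict_tbm <- function(net, features, stack) {
  emb <- fm_embedding(net, features)
  att <- attention_nodes(net, emb, stack)
  fwd <- forward_tbm(net, features, att$combined, embedding = emb)
  list(
    posterior = fwd$posterior,
    attention = structure(aperm(att$weights$value, c(3, 1, 2)),
                          class = "attention_weights"),
    combined = att$combined$value
  )
}

#' End-to-end geometry prediction
#'
#' The full pipeline for one target: featurise the MSA, predict with
#' the FM network, and, when good templates are available and a TBM
#' network is supplied, encode and attention-combine the templates,
#' predict with the TBM network, and fuse the two (symmetrised)
#' posteriors with the confidence-based per-pair weights.  Without
#' good templates the result is the FM posterior and w_TBM is
#' identically zero.
#'
#' @param msa An [new_msa()] object.
#' @param fm A trained [res2net_fm()].
#' @param tbm Optional trained [res2net_tbm()].
#' @param hits Optional hits tibble (unfiltered; the good-template
#'   rule is applied here).
#' @param templates Optional list of template [new_backbone()]s
#'   parallel to `hits`.
#' @return A list of class `geometry_prediction`: `posterior` (the
#'   fused, symmetrised [new_geometry_posterior()]), `posterior_fm`,
#'   `posterior_tbm` (or `NULL`), `fusion` ([tbm_weight()] result) and
#'   `n_templates` used.
#' @export
predict_geometry <- function(msa, fm, tbm = NULL, hits = NULL,
                             templates = NULL) {
  L <- msa_length(msa)
  features <- msa_features(msa)
  p_fm <- symmetrize(forward_fm(fm, features)$posterior)
  good <- if (is.null(hits)) empty_hits() else filter_and_rank_templates(hits)
  if (nrow(good) > 0L && !is.null(tbm)) {
    keep <- match(good$template_id, hits$template_id)
    stack <- build_template_stack(good, templates[keep], L)
    out <- predict_tbm(tbm, features, stack)
    p_tbm <- symmetrize(out$posterior)
    fw <- tbm_weight(out$attention, stack$s)
    fused <- fuse_posteriors(p_fm, p_tbm, fw)
    n_used <- stack$n
  } else {
    p_tbm <- NULL
    fw <- tbm_weight(NULL, NULL, l_query = L)
    fused <- p_fm
    n_used <- 0L
  }
  structure(
    list(
      posterior = fused, posterior_fm = p_fm, posterior_tbm = p_tbm,
      fusion = fw, n_templates = n_used
    ),
    class = "geometry_prediction"
  )
}

#' @export
print.geometry_prediction <- function(x, ...) {
  cat(sprintf(
    "<geometry_prediction> L = %d, %d template(s), mean w_TBM = %.3f\n",
    dim(x$posterior$dist)[1], x$n_templates, mean(x$fusion$w_tbm)
  ))
  invisible(x)
}
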