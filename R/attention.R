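# Attention-based multi-template combination.
#
# Reconstruction note: the module uses single-head axial attention
# between a 1x1 projection of the FM group-2 MSA embedding (query) and
# 1x1 projections of each template's 100-channel feature map (keys);
# scaled dot-product logits from the row-axis and column-axis passes
# are summed and softmaxed over the template (batch) axis, yielding
# per-template, per-pair weights.  Template confidences s_k do not
# enter the logits; they are used only downstream in the fusion weight
# w_TBM.

attention_nodes <- function(net, embedding, stack, tape = NULL,
                            params = NULL) {
  if (stack$n == 0L) {
    stop_protgeom("no templates in stack; route to FM-only mode")
  }
  params <- params %||% net$params
  q <- ad_conv2d(embedding, params[["att.q.W"]], params[["att.q.b"]],
                 k = 1L, tape = tape)
  logit_maps <- lapply(seq_len(stack$n), function(k) {
    key <- ad_conv2d(stack$feats[[k]], params[["att.k.W"]],
                     params[["att.k.b"]], k = 1L, tape = tape)
    ad_axial_logits(q, key, tape = tape)
  })
  lg <- ad_stack_maps(logit_maps, tape = tape)   # (L, L, N)
  w <- ad_softmax(lg, tape = tape)               # softmax over templates
  comb <- NULL
  for (k in seq_len(stack$n)) {
    wk <- ad_slice(w, k, k, tape = tape)
    wk <- ad_node(
      matrix(wk$value, dim(wk$value)[1], dim(wk$value)[2]),
      parents = list(wk), tape = tape,
      backfn = function(g) list(array(g, c(dim(g), 1L)))
    )
    term <- ad_scale_map(stack$feats[[k]], wk, tape = tape)
    comb <- if (is.null(comb)) term else ad_add(comb, term, tape = tape)
  }
  list(weights = w, combined = comb)
}

#' Per-template, per-pair attention weights
#'
#' Computes the axial-attention weights w_k(i, j) of each template,
#' normalised over the template axis by a softmax (so they sum to one
#' at every pair).  With a single template the weights are identically
#' one.
#'
#' @param embedding The FM group-2 MSA embedding (L x L x C array or
#'   node), e.g. `forward_fm(...)$group2`.
#' @param stack A [build_template_stack()].
#' @param net A [res2net_tbm()] holding the attention projections.
#' @return An N x L x L array of class `attention_weights`.
#' @export
attention_weights <- function(embedding, stack, net) {
  an <- attention_nodes(net, embedding, stack)
  w <- an$weights$value                      # (L, L, N)
  structure(aperm(w, c(3, 1, 2)), class = "attention_weights")
}

#' Combine template feature maps by attention weights
#'
#' `F(i, j, c) = sum_k w_k(i, j) F_k(i, j, c)`: the pair-wise weighted
#' summation of the per-template one-hot feature maps.
#'
#' @param stack A [build_template_stack()].
#' @param w An `attention_weights` array (N x L x L).
#' @return An L x L x 100 combined feature map.
#' @export
combine_templates <- function(stack, w) {
  if (dim(w)[1] != stack$n) {
    stop_protgeom("weight/template count mismatch")
  }
  L <- dim(w)[2]
  out <- array(0, c(L, L, dim(stack$feats[[1]])[3]))
  for (k in seq_len(stack$n)) {
    out <- out + stack$feats[[k]] * as.numeric(w[k, , ])
  }
  out
}
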