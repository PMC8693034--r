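#' Network configuration for the geometry predictors
#'
#' The de novo (FM) network has four groups of Res2Net blocks in the
#' `full` profile, with per-layer filter counts ranging from 64 to 512
#' and block counts chosen so the profile totals about 50 convolution
#' layers; the template-based (TBM) network reuses the FM stem and
#' first two groups (frozen) and adds four newly constructed groups, so
#' it contains six groups in total.  Every Res2Net block splits its
#' bottleneck into `scale = 4` channel subsets, and dilation cycles
#' through `dilation_cycle` across the blocks of a group.  The `tiny`
#' profile (two FM groups of two width-16 blocks) exists for desk-scale
#' work and continuous testing.
#'
#' @param profile `"tiny"` or `"full"`.
#' @param in_channels Input feature channels (526).
#' @param scale Number of channel subsets per block.
#' @param dilation_cycle Dilation rates cycled across blocks.
#' @param attention_dim Projection width of the template attention
#'   module.
#' @return A list of class `network_config`.
#' @export
network_config <- function(profile = c("tiny", "full"),
                           in_channels = 526L, scale = 4L,
                           dilation_cycle = c(1L, 2L, 4L),
                           attention_dim = 16L) {
  profile <- match.arg(profile)
  if (profile == "full") {
    fm_widths <- c(64L, 128L, 256L, 512L); fm_blocks <- c(3L, 3L, 2L, 2L)
    tbm_widths <- fm_widths; tbm_blocks <- fm_blocks
  } else {
    fm_widths <- c(16L, 16L); fm_blocks <- c(2L, 2L)
    tbm_widths <- rep(16L, 4L); tbm_blocks <- rep(1L, 4L)
  }
  structure(
    list(
      profile = profile, in_channels = as.integer(in_channels),
      scale = as.integer(scale), dilation_cycle = as.integer(dilation_cycle),
      fm_widths = fm_widths, fm_blocks = fm_blocks,
      tbm_widths = tbm_widths, tbm_blocks = tbm_blocks,
      template_channels = 100L, heads = HEAD_BINS,
      attention_dim = as.integer(attention_dim)
    ),
    class = "network_config"
  )
}

init_conv <- function(k, cin, cout) {
  list(
    W = matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
               k * k * cin, cout),
    b = rep(0, cout)
  )
}

init_inorm <- function(c) list(g = rep(1, c), b = rep(0, c))

put <- function(params, prefix, vals) {
  for (nm in names(vals)) params[[paste0(prefix, nm)]] <- vals[[nm]]
  params
}

#' Res2Net block configuration
#'
#' @param cin,cout Input/output channel counts.
#' @param bottleneck Bottleneck width (divisible by `scale`).
#' @param scale Number of channel subsets s.
#' @param dilation Dilation rate of the 3x3 convolutions.
#' @param normalize,activate Disable instance normalisation and/or the
#'   ELU activation (used by exact recursion checks).
#' @return A list of class `res2net_block_config`.
#' @export
res2net_block_config <- function(cin, cout, bottleneck = cout %/% 2L,
                                 scale = 4L, dilation = 1L,
                                 normalize = TRUE, activate = TRUE) {
  if (bottleneck %% scale != 0L) {
    stop_protgeom("bottleneck width must be divisible by the scale s")
  }
  if (dilation < 1L) stop_protgeom("dilation must be >= 1")
  structure(
    list(cin = cin, cout = cout, bottleneck = bottleneck, scale = scale,
         dilation = dilation, normalize = normalize, activate = activate),
    class = "res2net_block_config"
  )
}

init_block_params <- function(params, prefix, bc) {
  sw <- bc$bottleneck %/% bc$scale
  params <- put(params, paste0(prefix, "n0."), init_inorm(bc$cin))
  params <- put(params, paste0(prefix, "red."), init_conv(1L, bc$cin, bc$bottleneck))
  for (i in 2:bc$scale) {
    params <- put(params, paste0(prefix, "n", i, "."), init_inorm(sw))
    params <- put(params, paste0(prefix, "k", i, "."), init_conv(3L, sw, sw))
  }
  params <- put(params, paste0(prefix, "nm."), init_inorm(bc$bottleneck))
  params <- put(params, paste0(prefix, "exp."), init_conv(1L, bc$bottleneck, bc$cout))
  if (bc$cin != bc$cout) {
    params <- put(params, paste0(prefix, "proj."), init_conv(1L, bc$cin, bc$cout))
  }
  params
}

norm_act <- function(x, params, prefix, bc, tape) {
  if (bc$normalize) {
    x <- ad_instance_norm(
      x, params[[paste0(prefix, "g")]], params[[paste0(prefix, "b")]],
      tape = tape
    )
  }
  if (bc$activate) x <- ad_elu(x, tape = tape)
  x
}

#' Apply one Res2Net block
#'
#' Pre-activation bottleneck layout: 1x1 reduction, split into `scale`
#' equal channel subsets, hierarchical dilated 3x3 convolutions
#' (`y_1 = x_1`; `y_2 = K_2(x_2)`; `y_i = K_i(x_i + y_{i-1})` for
#' `i > 2`), concatenation, 1x1 expansion, and a residual connection
#' (identity, or a 1x1 projection when the channel count changes).
#' Each convolution is preceded by instance normalisation and ELU in
#' the pre-activation arrangement, so a zero-weight block is an exact
#' identity.  No down-sampling anywhere: output spatial shape equals
#' input spatial shape.
#'
#' @param x Input map (L x L x cin array or autodiff node).
#' @param params Flat named parameter list.
#' @param prefix Parameter name prefix of this block.
#' @param bc A [res2net_block_config()].
#' @param tape Autodiff tape or `NULL` for inference.
#' @return Output node (L x L x cout).
#' @export
res2net_block <- function(x, params, prefix, bc, tape = NULL) {
  x <- ad_wrap(x)
  if (dim(x$value)[3] != bc$cin) {
    stop_protgeom("input channels do not match block configuration")
  }
  sw <- bc$bottleneck %/% bc$scale
  h <- norm_act(x, params, paste0(prefix, "n0."), bc, tape)
  h <- ad_conv2d(h, params[[paste0(prefix, "red.W")]],
                 params[[paste0(prefix, "red.b")]], k = 1L, tape = tape)
  ys <- vector("list", bc$scale)
  prev <- NULL
  for (i in seq_len(bc$scale)) {
    xi <- ad_slice(h, (i - 1L) * sw + 1L, i * sw, tape = tape)
    if (i == 1L) {
      ys[[i]] <- xi
    } else {
      inp <- if (i == 2L) xi else ad_add(xi, prev, tape = tape)
      a <- norm_act(inp, params, paste0(prefix, "n", i, "."), bc, tape)
      ys[[i]] <- ad_conv2d(
        a, params[[paste0(prefix, "k", i, ".W")]],
        params[[paste0(prefix, "k", i, ".b")]],
        k = 3L, dilation = bc$dilation, tape = tape
      )
    }
    prev <- ys[[i]]
  }
  m <- ad_concat(ys, tape = tape)
  m <- norm_act(m, params, paste0(prefix, "nm."), bc, tape)
  out <- ad_conv2d(m, params[[paste0(prefix, "exp.W")]],
                   params[[paste0(prefix, "exp.b")]], k = 1L, tape = tape)
  res <- if (bc$cin != bc$cout) {
    ad_conv2d(x, params[[paste0(prefix, "proj.W")]],
              params[[paste0(prefix, "proj.b")]], k = 1L, tape = tape)
  } else {
    x
  }
  ad_add(res, out, tape = tape)
}

group_block_configs <- function(cfg, cin, width, n_blocks) {
  lapply(seq_len(n_blocks), function(b) {
    res2net_block_config(
      cin = if (b == 1L) cin else width, cout = width,
      # full profile: bottleneck stage as wide as the block, so every
      # whole-layer filter count sits in the 64-512 range
      bottleneck = if (cfg$profile == "full") width else
        max(cfg$scale, width %/% 2L),
      scale = cfg$scale,
      dilation = cfg$dilation_cycle[(b - 1L) %% length(cfg$dilation_cycle) + 1L]
    )
  })
}

init_groups <- function(params, prefix, cfg, cin, widths, blocks) {
  for (g in seq_along(widths)) {
    bcs <- group_block_configs(cfg, cin, widths[g], blocks[g])
    for (b in seq_along(bcs)) {
      params <- init_block_params(
        params, sprintf("%sg%d.b%d.", prefix, g, b), bcs[[b]]
      )
    }
    cin <- widths[g]
  }
  params
}

run_groups <- function(x, params, prefix, cfg, cin, widths, blocks,
                       tape = NULL, collect_after = NULL) {
  collected <- NULL
  for (g in seq_along(widths)) {
    bcs <- group_block_configs(cfg, cin, widths[g], blocks[g])
    for (b in seq_along(bcs)) {
      x <- res2net_block(
        x, params, sprintf("%sg%d.b%d.", prefix, g, b), bcs[[b]], tape
      )
    }
    cin <- widths[g]
    if (!is.null(collect_after) && g == collect_after) collected <- x
  }
  list(out = x, collected = collected)
}

#' Instantiate the de novo (FM) geometry network
#'
#' @param cfg A [network_config()].
#' @return An object of class `res2net_fm` holding the configuration
#'   and a flat named parameter list.
#' @export
res2net_fm <- function(cfg = network_config("tiny")) {
  params <- list()
  params <- put(params, "stem.", init_conv(1L, cfg$in_channels, cfg$fm_widths[1]))
  params <- init_groups(params, "", cfg, cfg$fm_widths[1],
                        cfg$fm_widths, cfg$fm_blocks)
  wlast <- tail(cfg$fm_widths, 1)
  params <- put(params, "nf.", init_inorm(wlast))
  for (h in names(cfg$heads)) {
    params <- put(params, paste0("head.", h, "."),
                  init_conv(1L, wlast, cfg$heads[[h]]))
  }
  structure(list(cfg = cfg, params = params), class = "res2net_fm")
}

#' @export
print.res2net_fm <- function(x, ...) {
  cat(sprintf(
    "<res2net_fm> profile '%s': %d groups, %d parameters tensors, %d scalars\n",
    x$cfg$profile, length(x$cfg$fm_widths), length(x$params),
    sum(vapply(x$params, length, numeric(1)))
  ))
  invisible(x)
}

head_forward <- function(x, params, cfg, tape, prefix = "") {
  a <- ad_instance_norm(
    x, params[[paste0(prefix, "nf.g")]], params[[paste0(prefix, "nf.b")]],
    tape = tape
  )
  a <- ad_elu(a, tape = tape)
  logits <- lapply(names(cfg$heads), function(h) {
    ad_conv2d(a, params[[paste0(prefix, "head.", h, ".W")]],
              params[[paste0(prefix, "head.", h, ".b")]], k = 1L, tape = tape)
  })
  names(logits) <- names(cfg$heads)
  logits
}

logits_to_posterior <- function(logits) {
  p <- lapply(logits, function(l) ad_softmax(l)$value)
  new_geometry_posterior(p$dist, p$omega, p$theta, p$phi)
}

#' Forward pass of the FM network
#'
#' Runs the stem, all FM Res2Net groups and the four 1x1 prediction
#' heads with per-pixel softmax.  Also exposes the output of the second
#' group, which the TBM network concatenates with template features.
#'
#' @param net A [res2net_fm()] object.
#' @param features An L x L x 526 [msa_features()] tensor.
#' @param tape Autodiff tape (training) or `NULL` (inference).
#' @param params Optional parameter list overriding `net$params`
#'   (used during optimisation, where parameters are autodiff leaves).
#' @return A list with `posterior` (a [new_geometry_posterior()]),
#'   `logits` (nodes), and `group2` (node after the second group).
#' @export
forward_fm <- function(net, features, tape = NULL, params = NULL) {
  cfg <- net$cfg
  fv <- ad_value(features)
  if (length(dim(fv)) != 3L || dim(fv)[3] != cfg$in_channels) {
    stop_protgeom(sprintf(
      "FM input must have %d channels, got %s",
      cfg$in_channels, paste(dim(fv), collapse = "x")
    ))
  }
  params <- params %||% net$params
  x <- ad_conv2d(features, params[["stem.W"]], params[["stem.b"]],
                 k = 1L, tape = tape)
  rg <- run_groups(x, params, "", cfg, cfg$fm_widths[1],
                   cfg$fm_widths, cfg$fm_blocks, tape = tape,
                   collect_after = min(2L, length(cfg$fm_widths)))
  logits <- head_forward(rg$out, params, cfg, tape)
  list(
    posterior = logits_to_posterior(logits),
    logits = logits,
    group2 = rg$collected
  )
}

#' Instantiate the template-based (TBM) geometry network
#'
#' Wraps a trained FM network whose stem and first two groups are
#' reused frozen; adds the attention projections, a 1x1 stem over the
#' concatenated (group-2 output + 100 template channels) map, four new
#' Res2Net groups and fresh prediction heads, for six groups in total.
#'
#' @param fm A (trained) [res2net_fm()] object.
#' @return An object of class `res2net_tbm`.
#' @export
res2net_tbm <- function(fm) {
  cfg <- fm$cfg
  params <- list()
  for (nm in names(fm$params)) params[[paste0("fm.", nm)]] <- fm$params[[nm]]
  g2w <- cfg$fm_widths[min(2L, length(cfg$fm_widths))]
  params <- put(params, "att.q.", init_conv(1L, g2w, cfg$attention_dim))
  params <- put(params, "att.k.",
                init_conv(1L, cfg$template_channels, cfg$attention_dim))
  params <- put(params, "stem2.",
                init_conv(1L, g2w + cfg$template_channels, cfg$tbm_widths[1]))
  params <- init_groups(params, "t.", cfg, cfg$tbm_widths[1],
                        cfg$tbm_widths, cfg$tbm_blocks)
  wlast <- tail(cfg$tbm_widths, 1)
  params <- put(params, "t.nf.", init_inorm(wlast))
  for (h in names(cfg$heads)) {
    params <- put(params, paste0("t.head.", h, "."),
                  init_conv(1L, wlast, cfg$heads[[h]]))
  }
  structure(list(cfg = cfg, params = params), class = "res2net_tbm")
}

#' @export
print.res2net_tbm <- function(x, ...) {
  cat(sprintf(
    "<res2net_tbm> profile '%s': %d groups (first 2 reused frozen from FM)\n",
    x$cfg$profile, n_tbm_groups(x)
  ))
  invisible(x)
}

#' Number of Res2Net groups in a network
#'
#' For the TBM network this counts the two reused FM groups plus the
#' newly constructed groups.
#'
#' @param net A `res2net_fm` or `res2net_tbm` object.
#' @return Integer group count.
#' @export
n_groups <- function(net) UseMethod("n_groups")

#' @export
n_groups.res2net_fm <- function(net) length(net$cfg$fm_widths)

#' @export
n_groups.res2net_tbm <- function(net) n_tbm_groups(net)

n_tbm_groups <- function(net) {
  min(2L, length(net$cfg$fm_widths)) + length(net$cfg$tbm_widths)
}

# Run the frozen FM front (stem + groups 1-2) as constants and return
# the group-2 embedding node.
fm_embedding <- function(tbm, features, tape = NULL, frozen = TRUE) {
  cfg <- tbm$cfg
  n_front <- min(2L, length(cfg$fm_widths))
  params <- tbm$params
  x <- ad_conv2d(features, params[["fm.stem.W"]], params[["fm.stem.b"]],
                 k = 1L, tape = tape)
  rg <- run_groups(
    x, params, "fm.", cfg, cfg$fm_widths[1],
    cfg$fm_widths[seq_len(n_front)], cfg$fm_blocks[seq_len(n_front)],
    tape = tape
  )
  rg$out
}

#' Forward pass of the TBM network
#'
#' Concatenates the frozen FM group-2 embedding of the MSA features
#' with the attention-combined 100-channel template map, then runs the
#' four new Res2Net groups and heads.  During training only parameters
#' outside the reused FM front receive gradients (the front is run as
#' constants, so the gradient with respect to every reused parameter
#' is identically zero).
#'
#' @param net A [res2net_tbm()] object.
#' @param features An L x L x 526 feature tensor.
#' @param combined_templates L x L x 100 attention-combined template
#'   map (array or node).
#' @param tape Autodiff tape or `NULL`.
#' @param params Optional parameter override (autodiff leaves during
#'   optimisation).
#' @param embedding Optional precomputed FM group-2 embedding node.
#' @return As [forward_fm()] (without `group2`).
#' @export
forward_tbm <- function(net, features, combined_templates, tape = NULL,
                        params = NULL, embedding = NULL) {
  cfg <- net$cfg
  params <- params %||% net$params
  fv <- ad_value(features); cv <- ad_value(combined_templates)
  if (dim(fv)[1] != dim(cv)[1]) {
    stop_protgeom("feature and template map lengths L differ")
  }
  if (dim(cv)[3] != cfg$template_channels) {
    stop_protgeom("combined template map must have 100 channels")
  }
  emb <- embedding %||% fm_embedding(net, features, tape = tape)
  x <- ad_concat(list(emb, ad_wrap(combined_templates)), tape = tape)
  x <- ad_conv2d(x, params[["stem2.W"]], params[["stem2.b"]],
                 k = 1L, tape = tape)
  rg <- run_groups(x, params, "t.", cfg, cfg$tbm_widths[1],
                   cfg$tbm_widths, cfg$tbm_blocks, tape = tape)
  logits <- head_forward(rg$out, params, cfg, tape, prefix = "t.")
  list(posterior = logits_to_posterior(logits), logits = logits)
}

#' Symmetrise a geometry posterior
#'
#' Distance and omega are symmetric by construction, so their heads are
#' averaged with their (i, j) <-> (j, i) transposes; theta and phi are
#' genuinely asymmetric and left untouched.  Convexity preserves
#' normalisation.
#'
#' @param posterior A [new_geometry_posterior()].
#' @return The symmetrised posterior.
#' @export
symmetrize <- function(posterior) {
  sym <- function(a) (a + aperm(a, c(2, 1, 3))) / 2
  new_geometry_posterior(
    sym(posterior$dist), sym(posterior$omega),
    posterior$theta, posterior$phi
  )
}

#' Save or load a network checkpoint
#'
#' Checkpoints are named-parameter archives with the embedded
#' configuration.
#'
#' @param net A `res2net_fm` or `res2net_tbm`.
#' @param path Checkpoint path.
#' @return `save_checkpoint()`: `path`, invisibly; `load_checkpoint()`:
#'   the network object.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(class = class(net), cfg = net$cfg, params = net$params),
          path, compress = "gzip")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  structure(list(cfg = x$cfg, params = x$params), class = x$class)
}
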