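#' Deterministic training/validation split
#'
#' Shuffles indices and assigns `floor(fraction * n)` items to the
#' validation set; with the 15,051-chain corpus and the default 5%
#' this yields 752 validation and 14,299 training items.
#'
#' @param n Number of items.
#' @param fraction Validation fraction.
#' @return A list with integer index vectors `train` and `validation`.
#' @export
split_train_validation <- function(n, fraction = 0.05) {
  n_val <- floor(n * fraction)
  perm <- sample.int(n)
  list(
    validation = sort(perm[seq_len(n_val)]),
    train = sort(perm[seq(n_val + 1L, n)])
  )
}

#' Crop-or-stitch length augmentation
#'
#' Samples shorter than `max_len` pass through unchanged.  Longer
#' samples are reduced either to a single random contiguous window or
#' (with probability `p_stitch`) to the concatenation of one window
#' from the first half and one from the second half of the sequence.
#' MSA columns and the label rows/columns are sliced by the same index
#' set, so inter-segment pair labels are the true original geometry.
#' Re-drawing every epoch makes the generated sequences distinct,
#' which is the data-augmentation point of the scheme.
#'
#' @param msa An [new_msa()] object.
#' @param labels Matching [bin_geometries()] labels.
#' @param max_len Longest accepted sample (exclusive); lengths beyond
#'   it arise from memory limits of 2D map networks.
#' @param p_stitch Probability of the two-window mode for long
#'   samples.
#' @param min_window Minimum window length.
#' @return A list of class `training_sample` with `msa`, `labels` and
#'   the original-coordinate `index` set.
#' @export
crop_or_stitch <- function(msa, labels, max_len = 260L, p_stitch = 0.5,
                           min_window = 64L) {
  if (max_len < 2L) stop_protgeom("max_len must be >= 2")
  L <- msa_length(msa)
  if (L < max_len) {
    return(structure(
      list(msa = msa, labels = labels, index = seq_len(L)),
      class = "training_sample"
    ))
  }
  half <- L %/% 2L
  if (runif(1) < p_stitch && half >= min_window) {
    len1 <- sample(min_window:min(max_len - min_window - 1L, half), 1)
    len2 <- sample(min_window:min(max_len - len1 - 1L, L - half), 1)
    s1 <- sample.int(half - len1 + 1L, 1)
    s2 <- half + sample.int(L - half - len2 + 1L, 1)
    idx <- c(seq(s1, length.out = len1), seq(s2, length.out = len2))
  } else {
    len <- sample(min_window:(max_len - 1L), 1)
    s <- sample.int(L - len + 1L, 1)
    idx <- seq(s, length.out = len)
  }
  structure(
    list(msa = slice_msa(msa, idx), labels = slice_labels(labels, idx),
         index = idx),
    class = "training_sample"
  )
}

slice_msa <- function(msa, idx) {
  rows <- vapply(strsplit(msa$rows, ""), function(ch) {
    paste(ch[idx], collapse = "")
  }, character(1))
  new_msa(msa$ids, rows)
}

slice_labels <- function(labels, idx) {
  out <- lapply(labels[c("dist", "omega", "theta", "phi")], function(m) {
    m[idx, idx, drop = FALSE]
  })
  out$mask <- labels$mask[idx, idx, drop = FALSE]
  structure(out, class = "geometry_labels")
}

#' Training loss: summed categorical cross-entropy of the four heads
#'
#' Mean over valid residue pairs of the sum of the four negative
#' log-likelihoods (equal head weights).  A one-hot posterior matching
#' the labels gives loss 0; a uniform posterior gives
#' `log 37 + log 25 + log 25 + log 13` per pair.
#'
#' @param posterior A [new_geometry_posterior()].
#' @param labels A [bin_geometries()] result.
#' @param mask Logical L x L validity mask (defaults to all
#'   off-diagonal pairs).
#' @return The scalar loss.
#' @export
geometry_loss <- function(posterior, labels, mask = NULL) {
  L <- dim(posterior$dist)[1]
  mask <- mask %||% (diag(L) == 0)
  if (!any(mask)) stop_protgeom("all pairs masked out of the loss")
  n <- sum(mask)
  total <- 0
  for (h in names(HEAD_BINS)) {
    a <- posterior[[h]]
    sel <- cbind(
      rep(seq_len(L), L), rep(seq_len(L), each = L),
      as.vector(labels[[h]]) + 1L
    )
    p <- matrix(a[sel], L, L)
    total <- total + sum(-log(pmax(p[mask], 1e-12))) / n
  }
  total
}

# Adam optimiser step over a flat named parameter list.  `frozen` is a
# prefix: parameters whose names start with it are never updated.
adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, frozen = NULL) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    if (!is.null(frozen) && startsWith(nm, frozen)) next
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- state$m[[nm]] %||% (g * 0)
    v <- state$v[[nm]] %||% (g * 0)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state$m[[nm]] <- m; state$v[[nm]] <- v
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  params
}

# One forward/backward/update on a single sample.  Returns the updated
# parameter list and the loss value.
fm_train_step <- function(net, features, labels, mask, state, lr) {
  tape <- ad_tape()
  leaves <- lapply(net$params, ad_leaf, track = TRUE)
  fwd <- forward_fm(net, features, tape = tape, params = leaves)
  losses <- lapply(names(HEAD_BINS), function(h) {
    ad_ce_loss(fwd$logits[[h]], labels[[h]], mask, tape = tape)
  })
  loss <- ad_sum_scalar(losses, tape = tape)
  ad_backward(tape, loss)
  grads <- lapply(leaves, `[[`, "grad")
  net$params <- adam_step(net$params, grads, state, lr = lr)
  list(net = net, loss = loss$value)
}

target_features <- function(target, augment) {
  msa <- target$msa
  labels <- target$labels
  if (augment) {
    msa <- subsample_msa(msa)
    cs <- crop_or_stitch(msa, labels)
    msa <- cs$msa; labels <- cs$labels
  }
  L <- msa_length(msa)
  list(
    features = msa_features(msa), labels = labels,
    mask = diag(L) == 0
  )
}

#' Train the FM network on synthetic targets
#'
#' Desk-scale training loop: Adam, batch size one (sample lengths
#' vary), equal-weight four-head cross-entropy.  With
#' `augment = TRUE` the MSA is re-subsampled and long samples are
#' re-cropped/stitched every epoch, and features are rebuilt from the
#' augmented MSA; with `augment = FALSE` the feature tensors are
#' computed once up front and reused, which is the sensible mode when
#' every sample is shorter than the crop threshold.
#'
#' @param targets List of [gen_target()]-like lists (`msa`, `labels`).
#' @param cfg A [network_config()].
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param validation_fraction Fraction held out per
#'   [split_train_validation()].
#' @param augment Re-draw MSA subsamples and crops each epoch.
#' @param seed RNG seed; fixes initialisation, splits and
#'   augmentation, making histories reproducible.
#' @param verbose Print per-epoch losses.
#' @return A list of class `geom_training`: `net` (trained
#'   [res2net_fm()]), `history` (tibble of per-epoch train/validation
#'   loss) and `split`.
#' @export
train_fm <- function(targets, cfg = network_config("tiny"), epochs = 10,
                     lr = 1e-3, validation_fraction = 0.05,
                     augment = TRUE, seed = NULL, verbose = FALSE) {
  if (length(targets) == 0L) stop_protgeom("empty training set")
  if (!is.null(seed)) set.seed(seed)
  split <- split_train_validation(length(targets), validation_fraction)
  net <- res2net_fm(cfg)
  state <- adam_state()
  cache <- NULL
  if (!augment) {
    cache <- lapply(targets, target_features, augment = FALSE)
  }
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    tr_loss <- c()
    for (i in sample(split$train)) {
      prep <- if (augment) target_features(targets[[i]], TRUE) else cache[[i]]
      st <- fm_train_step(net, prep$features, prep$labels, prep$mask,
                          state, lr)
      net <- st$net
      if (!is.finite(st$loss)) {
        stop_protgeom(sprintf(
          "training diverged (non-finite loss) at epoch %d, sample %d", ep, i
        ))
      }
      tr_loss <- c(tr_loss, st$loss)
    }
    val_loss <- NA_real_
    if (length(split$validation) > 0L) {
      vl <- vapply(split$validation, function(i) {
        prep <- if (augment) target_features(targets[[i]], FALSE) else cache[[i]]
        fwd <- forward_fm(net, prep$features)
        geometry_loss(fwd$posterior, prep$labels, prep$mask)
      }, numeric(1))
      val_loss <- mean(vl)
    }
    history[[ep]] <- tibble::tibble(
      epoch = ep, train_loss = mean(tr_loss), validation_loss = val_loss
    )
    if (verbose) {
      message(sprintf(
        "epoch %d: train %.4f, validation %.4f", ep, mean(tr_loss), val_loss
      ))
    }
  }
  structure(
    list(net = net, history = dplyr::bind_rows(history), split = split),
    class = "geom_training"
  )
}

#' Train the TBM network with the FM front frozen
#'
#' Builds a [res2net_tbm()] around the given (trained) FM network and
#' optimises only the newly constructed parameters: the frozen FM stem
#' and groups 1-2 are evaluated as constants, so their gradients are
#' identically zero and their values never change.
#'
#' @param targets List of targets that include `hits` and `templates`
#'   (see [gen_target()] with `n_templates > 0`).
#' @param fm A trained [res2net_fm()].
#' @inheritParams train_fm
#' @return A list of class `geom_training` with the trained
#'   `res2net_tbm` as `net`.
#' @export
train_tbm <- function(targets, fm, epochs = 5, lr = 1e-3,
                      validation_fraction = 0.05, seed = NULL,
                      verbose = FALSE) {
  if (length(targets) == 0L) stop_protgeom("empty training set")
  if (!is.null(seed)) set.seed(seed)
  split <- split_train_validation(length(targets), validation_fraction)
  net <- res2net_tbm(fm)
  state <- adam_state()
  prep_all <- lapply(targets, function(t) {
    L <- msa_length(t$msa)
    stack <- build_template_stack(
      filter_and_rank_templates(t$hits), t$templates, L
    )
    c(target_features(t, augment = FALSE), list(stack = stack))
  })
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    tr_loss <- c()
    for (i in sample(split$train)) {
      st <- tbm_train_step(net, prep_all[[i]], state, lr)
      net <- st$net
      tr_loss <- c(tr_loss, st$loss)
    }
    val_loss <- NA_real_
    if (length(split$validation) > 0L) {
      vl <- vapply(split$validation, function(i) {
        p <- prep_all[[i]]
        out <- predict_tbm(net, p$features, p$stack)
        geometry_loss(out$posterior, p$labels, p$mask)
      }, numeric(1))
      val_loss <- mean(vl)
    }
    history[[ep]] <- tibble::tibble(
      epoch = ep, train_loss = mean(tr_loss), validation_loss = val_loss
    )
    if (verbose) {
      message(sprintf(
        "epoch %d: train %.4f, validation %.4f", ep, mean(tr_loss), val_loss
      ))
    }
  }
  structure(
    list(net = net, history = dplyr::bind_rows(history), split = split),
    class = "geom_training"
  )
}

tbm_train_step <- function(net, prep, state, lr) {
  tape <- ad_tape()
  trainable <- !startsWith(names(net$params), "fm.")
  leaves <- net$params
  leaves[trainable] <- lapply(net$params[trainable], ad_leaf, track = TRUE)
  emb <- fm_embedding(net, prep$features, tape = tape)
  att <- attention_nodes(net, emb, prep$stack, tape = tape, params = leaves)
  fwd <- forward_tbm(net, prep$features, att$combined, tape = tape,
                     params = leaves, embedding = emb)
  losses <- lapply(names(HEAD_BINS), function(h) {
    ad_ce_loss(fwd$logits[[h]], prep$labels[[h]], prep$mask, tape = tape)
  })
  loss <- ad_sum_scalar(losses, tape = tape)
  ad_backward(tape, loss)
  grads <- lapply(leaves, function(l) if (is_ad_node(l)) l$grad else NULL)
  net$params <- adam_step(net$params, grads, state, lr = lr, frozen = "fm.")
  list(net = net, loss = loss$value)
}
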