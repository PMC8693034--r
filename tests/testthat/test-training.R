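test_that("the 95/5 split reproduces the corpus counts", {
  set.seed(101)
  sp <- split_train_validation(15051)
  expect_length(sp$validation, 752L)
  expect_length(sp$train, 14299L)
  expect_setequal(c(sp$train, sp$validation), seq_len(15051))
})

test_that("crop-or-stitch passes short samples and bounds long ones", {
  set.seed(102)
  L <- 200L
  msa <- toy_msa(replicate(3, paste(
    sample(strsplit("ARNDC", "")[[1]], L, replace = TRUE), collapse = ""
  )))
  labels <- structure(
    list(dist = matrix(0L, L, L), omega = matrix(0L, L, L),
         theta = matrix(0L, L, L), phi = matrix(0L, L, L),
         mask = matrix(FALSE, L, L)),
    class = "geometry_labels"
  )
  out <- crop_or_stitch(msa, labels)
  expect_identical(out$msa$rows, msa$rows)
  expect_identical(out$index, seq_len(L))
  expect_error(crop_or_stitch(msa, labels, max_len = 1L), "max_len")
})

make_long_target <- function(L, seed) {
  set.seed(seed)
  rows <- replicate(2, paste(
    sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], L, replace = TRUE),
    collapse = ""
  ))
  d <- matrix(runif(L * L, 2, 30), L, L); d <- (d + t(d)) / 2; diag(d) <- 0
  maps <- list(d = d, omega = matrix(runif(L * L, -180, 179), L, L),
               theta = matrix(runif(L * L, -180, 179), L, L),
               phi = matrix(runif(L * L, 0, 180), L, L),
               mask = diag(L) == 0)
  list(msa = toy_msa(rows), labels = bin_geometries(maps))
}

test_that("stitching samples disjoint windows from the two halves with true labels", {
  tgt <- make_long_target(300L, 103)
  for (draw in 1:20) {
    out <- crop_or_stitch(tgt$msa, tgt$labels, p_stitch = 1)
    expect_lt(length(out$index), 260L)
    idx <- out$index
    n1 <- sum(idx <= 150L)
    expect_gt(n1, 0L)
    expect_lt(n1, length(idx))
    # each half-window is contiguous and strictly within its half
    expect_identical(idx[seq_len(n1)], seq(idx[1], length.out = n1))
    expect_identical(idx[-seq_len(n1)],
                     seq(idx[n1 + 1L], length.out = length(idx) - n1))
    expect_true(all(idx[-seq_len(n1)] >= 151L))
    # label slicing contract on random pairs
    pick <- cbind(sample(length(idx), 50, replace = TRUE),
                  sample(length(idx), 50, replace = TRUE))
    expect_identical(
      out$labels$dist[pick],
      tgt$labels$dist[cbind(idx[pick[, 1]], idx[pick[, 2]])]
    )
  }
})

test_that("augmentation never emits samples at or above the cap and varies", {
  tgt <- make_long_target(320L, 104)
  lens <- integer(30); first_idx <- NULL; varied <- FALSE
  for (i in 1:30) {
    out <- crop_or_stitch(tgt$msa, tgt$labels)
    lens[i] <- length(out$index)
    if (is.null(first_idx)) first_idx <- out$index
    if (!identical(out$index, first_idx)) varied <- TRUE
  }
  expect_true(all(lens < 260L))
  expect_true(varied)
})

test_that("geometry loss has its analytic anchors", {
  bb <- toy_backbone(8, seed = 105)
  labels <- bin_geometries(compute_geometries(bb))
  exact <- posterior_from_labels(labels, smoothing = 0)
  expect_equal(geometry_loss(exact, labels), 0, tolerance = 1e-9)

  L <- 8L
  unif <- new_geometry_posterior(
    array(1 / 37, c(L, L, 37)), array(1 / 25, c(L, L, 25)),
    array(1 / 25, c(L, L, 25)), array(1 / 13, c(L, L, 13))
  )
  expect_equal(geometry_loss(unif, labels),
               log(37) + log(25) + log(25) + log(13), tolerance = 1e-12)
  p <- random_posterior(L, seed = 106)
  expect_gte(geometry_loss(p, labels), 0)
  expect_error(geometry_loss(p, labels, mask = matrix(FALSE, L, L)),
               "masked")
})

test_that("training is reproducible from the seed and the loss moves", {
  set.seed(107)
  targets <- lapply(1:6, function(i) {
    bb <- gen_backbone(16)
    list(msa = gen_msa(bb, 20),
         labels = bin_geometries(compute_geometries(bb)))
  })
  r1 <- train_fm(targets, epochs = 2, seed = 55, augment = TRUE)
  r2 <- train_fm(targets, epochs = 2, seed = 55, augment = TRUE)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$net$params, r2$net$params)
  expect_false(identical(r1$history$train_loss[1],
                         r1$history$train_loss[2]))

  td <- tidy(r1)
  expect_true(all(c("epoch", "split", "loss") %in% names(td)))
  g <- glance(r1)
  expect_equal(g$epochs, 2L)
  expect_s3_class(autoplot(r1), "ggplot")
})
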