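test_that("block forward reproduces the hierarchical split recursion", {
  # 4 subsets of one channel each, normalisation and activation
  # disabled, identity reduce/expand: the block output minus the
  # residual must equal the concatenated recursion
  # y1 = x1, y2 = K2(x2), y3 = K3(x3 + y2), y4 = K4(x4 + y3).
  set.seed(61)
  L <- 8L
  bc <- res2net_block_config(cin = 4L, cout = 4L, bottleneck = 4L,
                             scale = 4L, dilation = 2L,
                             normalize = FALSE, activate = FALSE)
  params <- list(
    red.W = diag(4), red.b = rep(0, 4),
    exp.W = diag(4), exp.b = rep(0, 4)
  )
  ks <- list()
  for (i in 2:4) {
    ks[[i]] <- matrix(rnorm(9, sd = 0.5), 9, 1)
    params[[sprintf("k%d.W", i)]] <- ks[[i]]
    params[[sprintf("k%d.b", i)]] <- 0
  }
  x <- array(rnorm(L * L * 4), c(L, L, 4))
  out <- res2net_block(x, params, "", bc)$value

  xs <- lapply(1:4, function(i) x[, , i, drop = FALSE])
  y1 <- xs[[1]]
  y2 <- naive_conv2d(xs[[2]], ks[[2]], 0, 3, 2)
  y3 <- naive_conv2d(xs[[3]] + y2, ks[[3]], 0, 3, 2)
  y4 <- naive_conv2d(xs[[4]] + y3, ks[[4]], 0, 3, 2)
  want <- x
  want[, , 1] <- x[, , 1] + y1[, , 1]
  want[, , 2] <- x[, , 2] + y2[, , 1]
  want[, , 3] <- x[, , 3] + y3[, , 1]
  want[, , 4] <- x[, , 4] + y4[, , 1]
  expect_equal(out, want, tolerance = 1e-6)
})

test_that("a zero-weight block is an exact identity and keeps spatial shape", {
  set.seed(62)
  bc <- res2net_block_config(cin = 8L, cout = 8L, bottleneck = 8L)
  params <- list()
  params <- protgeom:::init_block_params(params, "", bc)
  for (nm in grep("\\.(W|b)$", names(params), value = TRUE)) {
    params[[nm]] <- params[[nm]] * 0
  }
  x <- array(rnorm(6 * 6 * 8), c(6, 6, 8))
  out <- res2net_block(x, params, "", bc)$value
  expect_identical(dim(out), dim(x))
  expect_equal(out, x)

  expect_error(
    res2net_block_config(cin = 8L, cout = 8L, bottleneck = 6L, scale = 4L),
    "divisible"
  )
})

test_that("FM forward yields normalised heads of the right shapes, deterministically", {
  set.seed(63)
  net <- res2net_fm(network_config("tiny"))
  L <- 10L
  X <- array(rnorm(L * L * 526), c(L, L, 526))
  out1 <- forward_fm(net, X)$posterior
  out2 <- forward_fm(net, X)$posterior
  expect_identical(out1, out2)
  expect_equal(dim(out1$dist), c(L, L, 37L))
  expect_equal(dim(out1$omega), c(L, L, 25L))
  expect_equal(dim(out1$theta), c(L, L, 25L))
  expect_equal(dim(out1$phi), c(L, L, 13L))
  for (h in c("dist", "omega", "theta", "phi")) {
    sums <- apply(out1[[h]], c(1, 2), sum)
    expect_equal(sums, matrix(1, L, L), tolerance = 1e-6)
    expect_true(all(out1[[h]] > 0))
  }
  expect_error(forward_fm(net, X[, , 1:100]), "526")
})

test_that("profiles instantiate with the documented group structure and filter range", {
  tiny <- res2net_fm(network_config("tiny"))
  expect_equal(n_groups(tiny), 2L)
  expect_equal(tiny$cfg$scale, 4L)

  full_cfg <- network_config("full")
  full <- res2net_fm(full_cfg)
  expect_equal(n_groups(full), 4L)
  # whole-layer filter counts (stem, reduce, expand, projection, group
  # widths) all sit in [64, 512]
  expect_true(all(full_cfg$fm_widths >= 64 & full_cfg$fm_widths <= 512))
  for (g in seq_along(full_cfg$fm_widths)) {
    bcs <- protgeom:::group_block_configs(
      full_cfg, if (g == 1) full_cfg$fm_widths[1] else full_cfg$fm_widths[g - 1],
      full_cfg$fm_widths[g], full_cfg$fm_blocks[g]
    )
    for (bc in bcs) {
      expect_gte(bc$bottleneck, 64L)
      expect_lte(bc$cout, 512L)
    }
  }
  # ~50 convolution layers: 5 per block plus stem and heads
  n_blocks <- sum(full_cfg$fm_blocks)
  expect_equal(5L * n_blocks, 50L)

  tbm <- res2net_tbm(tiny)
  expect_equal(n_groups(tbm), 6L)
})

test_that("TBM forward and training freeze the reused FM front", {
  set.seed(64)
  L <- 12L
  bb <- toy_backbone(L, seed = 99)
  msa <- gen_msa(bb, 20, seed = 100)
  X <- msa_features(msa)
  labels <- bin_geometries(compute_geometries(bb))
  fm <- res2net_fm(network_config("tiny"))
  tbm <- res2net_tbm(fm)

  tp <- gen_templates(bb, noise_sd = 0.3, n_templates = 2, seed = 101)
  stack <- build_template_stack(tp$hits, tp$templates, L)

  before <- tbm$params[startsWith(names(tbm$params), "fm.")]
  prep <- list(features = X, labels = labels, mask = diag(L) == 0,
               stack = stack)
  st <- protgeom:::tbm_train_step(tbm, prep, protgeom:::adam_state(), 1e-3)
  after <- st$net$params[startsWith(names(st$net$params), "fm.")]
  expect_identical(before, after)
  # ... and the new parameters did move
  expect_false(identical(
    tbm$params[["stem2.W"]], st$net$params[["stem2.W"]]
  ))

  # zero template map: output is a deterministic function of the MSA
  zero <- array(0, c(L, L, 100L))
  o1 <- forward_tbm(tbm, X, zero)$posterior
  o2 <- forward_tbm(tbm, X, zero)$posterior
  expect_identical(o1, o2)
  sums <- apply(o1$dist, c(1, 2), sum)
  expect_equal(sums, matrix(1, L, L), tolerance = 1e-6)
  expect_error(forward_tbm(tbm, X, zero[1:6, 1:6, ]), "differ")
})

test_that("symmetrisation averages the symmetric heads and preserves normalisation", {
  p <- random_posterior(6, seed = 65)
  s <- symmetrize(p)
  expect_equal(s$dist, aperm(s$dist, c(2, 1, 3)))
  expect_equal(s$omega, aperm(s$omega, c(2, 1, 3)))
  expect_identical(s$theta, p$theta)
  expect_identical(s$phi, p$phi)
  expect_equal(apply(s$dist, c(1, 2), sum), matrix(1, 6, 6),
               tolerance = 1e-12)
  expect_identical(symmetrize(s)$dist, s$dist)
})

test_that("checkpoints round-trip through disk", {
  set.seed(66)
  net <- res2net_fm(network_config("tiny"))
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(net, f)
  rt <- load_checkpoint(f)
  expect_s3_class(rt, "res2net_fm")
  expect_identical(rt$params, net$params)
  expect_identical(rt$cfg, net$cfg)
})
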