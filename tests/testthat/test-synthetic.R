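test_that("generated backbones honour the walk constraints and are compact", {
  for (seed in c(201, 202)) {
    bb <- gen_backbone(48, seed = seed)
    steps <- sqrt(rowSums(diff(bb$ca)^2))
    expect_true(all(abs(steps - 3.8) < 0.01))
    dm <- as.matrix(dist(bb$ca))
    sep <- abs(row(dm) - col(dm))
    expect_gte(min(dm[sep >= 3]), 3.5)
    gm <- compute_geometries(bb)
    sepd <- abs(row(gm$d) - col(gm$d))
    expect_gte(sum(gm$d < 8 & sepd >= 12 & upper.tri(gm$d)), 2L * 48L)
  }
  expect_error(gen_backbone(4), "L must be")
})

test_that("synthetic MSAs carry the query and a detectable covariation signal", {
  bb <- toy_backbone(32, seed = 203)
  msa <- gen_msa(bb, 150, coupling_strength = 0.9, seed = 204)
  expect_identical(msa$rows[1], paste(
    ifelse(bb$aa %in% strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
           bb$aa, "A"), collapse = ""
  ))
  expect_equal(msa_depth(msa), 150L)

  f2d <- couplings(msa, sequence_weights(msa))
  apc <- f2d[, , 442]
  gm <- compute_geometries(bb)
  sep <- abs(row(apc) - col(apc))
  contact <- gm$d < 8 & sep >= 6 & upper.tri(apc)
  noncontact <- gm$d >= 8 & sep >= 6 & upper.tri(apc)
  expect_gt(mean(apc[contact]), mean(apc[noncontact]))
})

test_that("zero coupling strength leaves columns independent", {
  bb <- toy_backbone(24, seed = 205)
  msa <- gen_msa(bb, 200, coupling_strength = 0, gap_rate = 0, seed = 206)
  mi <- protgeom:::msa_to_int_matrix(msa)[-1, ]

  # mutual information of the strongest column pair vs a permutation
  # baseline where rows of one column are shuffled
  mutinf <- function(a, b) {
    tab <- table(a, b) / length(a)
    pa <- rowSums(tab); pb <- colSums(tab)
    keep <- tab > 0
    sum((tab * log(tab / outer(pa, pb)))[keep])
  }
  L <- ncol(mi)
  obs <- c()
  for (i in 1:(L - 1)) for (j in (i + 1):L) {
    obs <- c(obs, mutinf(mi[, i], mi[, j]))
  }
  set.seed(207)
  perm <- c()
  for (r in 1:200) {
    i <- sample(L, 2)
    perm <- c(perm, mutinf(mi[, i[1]], sample(mi[, i[2]])))
  }
  # the observed MI distribution should look like the permutation null
  expect_lt(max(obs), max(perm) * 1.5)
  expect_lt(abs(mean(obs) - mean(perm)), 0.05)
})

test_that("synthetic templates degrade gracefully with noise and cover as asked", {
  bb <- toy_backbone(32, seed = 208)
  lab_true <- bin_geometries(compute_geometries(bb))

  tp0 <- gen_templates(bb, noise_sd = 0, coverage = 1, seed = 209)
  lab_t <- bin_geometries(compute_geometries(tp0$templates[[1]]))
  expect_identical(lab_t$dist, lab_true$dist)
  expect_identical(lab_t$omega, lab_true$omega)
  expect_identical(lab_t$theta, lab_true$theta)
  expect_identical(lab_t$phi, lab_true$phi)
  expect_equal(tp0$hits$alignment[[1]]$confidence, rep(1, 32))

  # mean pairwise-distance deviation grows with the noise level
  devs <- vapply(c(0.2, 1, 3), function(s) {
    tp <- gen_templates(bb, noise_sd = s, coverage = 1, seed = 210)
    gm <- compute_geometries(tp$templates[[1]])
    mean(abs(gm$d - compute_geometries(bb)$d))
  }, numeric(1))
  expect_true(all(diff(devs) > 0))

  tph <- gen_templates(bb, coverage = 0.5, seed = 211)
  expect_equal(nrow(tph$hits$alignment[[1]]), ceiling(32 / 2))

  # good flag drives the template filter
  tpg <- gen_templates(bb, n_templates = 2, good = c(TRUE, FALSE), seed = 212)
  expect_equal(nrow(filter_and_rank_templates(tpg$hits)), 1L)
})

test_that("the end-to-end template oracle holds: encode then decode recovers truth", {
  bb <- toy_backbone(24, seed = 213)
  lab <- bin_geometries(compute_geometries(bb))
  tp <- gen_templates(bb, noise_sd = 0, coverage = 1, seed = 214)
  stack <- build_template_stack(tp$hits, tp$templates, 24)
  expect_equal(stack$n, 1L)
  # channel sums are 0 or 4 per pair
  sums <- apply(stack$feats[[1]], c(1, 2), sum)
  expect_true(all(sums %in% c(0, 4)))
  dec <- decode_template(stack$feats[[1]])
  expect_identical(dec$dist, lab$dist)
  expect_identical(dec$omega, lab$omega)
  expect_identical(dec$theta, lab$theta)
  expect_identical(dec$phi, lab$phi)
})

test_that("fixtures round-trip through the external file formats", {
  bb <- toy_backbone(16, seed = 215)
  msa <- gen_msa(bb, 10, seed = 216)
  tp <- gen_templates(bb, n_templates = 2, seed = 217)

  fa <- withr::local_tempfile(fileext = ".a3m")
  write_msa(msa, fa)
  expect_identical(read_a3m(fa)$rows, msa$rows)

  fh <- withr::local_tempfile(fileext = ".tsv")
  write_hits_table(tp$hits, fh)
  rt <- read_hits_table(fh)
  expect_equal(rt$template_id, tp$hits$template_id)
  expect_equal(rt$alignment[[2]]$query_pos, tp$hits$alignment[[2]]$query_pos)
})
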