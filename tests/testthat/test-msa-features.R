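test_that("sequence weights follow the neighbour-count rule", {
  # k identical rows -> every weight 1/k, Neff = 1
  m <- toy_msa(rep("ACDEF", 4))
  w <- sequence_weights(m)
  expect_equal(w$w, rep(1 / 4, 4))
  expect_equal(w$neff, 1)

  # all rows below the cutoff -> all weights 1
  m <- toy_msa(c("ACDEF", "GHIKL", "MNPQR"))
  w <- sequence_weights(m)
  expect_equal(w$w, rep(1, 3))
  expect_equal(w$neff, 3)

  # two copies + one row at 50% identity (below 0.8 cutoff)
  m <- toy_msa(c("ACDE", "ACDE", "ACKL"))
  w <- sequence_weights(m)
  expect_equal(w$w, c(1 / 2, 1 / 2, 1))

  expect_error(sequence_weights(m, identity_cutoff = 0), "cutoff")
  expect_error(sequence_weights(m, identity_cutoff = 1.2), "cutoff")
})

test_that("profile and entropy match closed forms", {
  # fully conserved column, zero pseudocount
  m <- toy_msa(rep("A", 5))
  w <- sequence_weights(m)
  f1d <- profile_and_entropy(m, w, pseudocount = 0)
  expect_equal(dim(f1d), c(1L, 42L))
  expect_equal(f1d[1, 21], 1)            # PSSM channel for A
  expect_equal(f1d[1, 42], 0)            # entropy

  # uniform over all 21 states -> entropy log(21)
  m <- toy_msa(c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "-"))
  w <- sequence_weights(m)
  f1d <- profile_and_entropy(m, w, pseudocount = 0)
  expect_equal(f1d[1, 42], log(21), tolerance = 1e-12)

  # single sequence with pseudocount c: f = (delta + c) / (1 + 21c)
  m <- toy_msa("C")
  w <- sequence_weights(m)
  pc <- 0.3
  f1d <- profile_and_entropy(m, w, pseudocount = pc)
  fexp <- rep(pc / (1 + 21 * pc), 21)
  fexp[match("C", strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])] <-
    (1 + pc) / (1 + 21 * pc)
  expect_equal(f1d[1, 21:41], fexp, ignore_attr = TRUE)
  expect_equal(f1d[1, 42], -sum(fexp * log(fexp)), tolerance = 1e-12)
})

test_that("entropy stays within [0, log 21] on random alignments", {
  set.seed(31)
  alpha <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "-")
  for (rep in 1:5) {
    rows <- replicate(12, paste(sample(alpha, 9, replace = TRUE),
                                collapse = ""))
    m <- toy_msa(rows)
    f1d <- profile_and_entropy(m, sequence_weights(m))
    expect_true(all(f1d[, 42] >= 0 & f1d[, 42] <= log(21) + 1e-12))
  }
})

test_that("couplings equal a brute-force dense inverse on a toy MSA", {
  m <- toy_msa(c("AC", "CA", "AA"))
  w <- sequence_weights(m)
  shr <- 1.0
  got <- couplings(m, w, shrinkage = shr)

  # independent oracle: explicit 42 x 42 weighted covariance + solve()
  alpha <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "-")
  enc <- function(s) {
    ch <- strsplit(s, "")[[1]]
    x <- numeric(42)
    for (l in 1:2) x[21 * (l - 1) + match(ch[l], alpha)] <- 1
    x
  }
  X <- t(sapply(m$rows, enc))
  ww <- w$w
  f <- colSums(ww * X) / w$neff
  C <- t(X * ww) %*% X / w$neff - outer(f, f)
  C <- C + diag(shr / sqrt(w$neff), 42)
  P <- solve(C)
  block12 <- -P[1:21, 22:42]
  expect_equal(got[1, 2, 1:441], as.vector(block12), tolerance = 1e-8,
               ignore_attr = TRUE)
  # layout antisymmetry: block at (2,1) is the transpose
  expect_equal(got[2, 1, 1:441], as.vector(t(block12)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("APC channel is small for independent columns and finds planted pairs", {
  set.seed(99)
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  L <- 12
  rows <- replicate(200, paste(sample(aa20, L, replace = TRUE),
                               collapse = ""))
  m <- toy_msa(rows)
  w <- sequence_weights(m)
  f2d <- couplings(m, w)
  apc <- f2d[, , 442]
  expect_lte(mean(abs(apc[upper.tri(apc)])), 0.05)

  # plant a perfectly covarying pair between columns 3 and 9
  rows2 <- vapply(rows, function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[9] <- ch[3]
    paste(ch, collapse = "")
  }, character(1))
  m2 <- toy_msa(unname(rows2))
  f2d2 <- couplings(m2, sequence_weights(m2))
  apc2 <- f2d2[, , 442]
  diag(apc2) <- -Inf
  best <- which(apc2 == max(apc2), arr.ind = TRUE)[1, ]
  expect_setequal(as.integer(best), c(3L, 9L))
})

test_that("coupling magnitude decreases monotonically with shrinkage", {
  set.seed(7)
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  rows <- replicate(40, paste(sample(aa20, 8, replace = TRUE), collapse = ""))
  m <- toy_msa(rows)
  w <- sequence_weights(m)
  mags <- vapply(c(1, 4, 16, 64), function(s) {
    mean(abs(couplings(m, w, shrinkage = s)[, , 1:441]))
  }, numeric(1))
  expect_true(all(diff(mags) < 0))
})

test_that("input tensor assembly has the documented 526-channel layout", {
  m <- toy_msa(c("ACDEF", "AC-EF", "GCDEF"))
  w <- sequence_weights(m)
  f1d <- profile_and_entropy(m, w)
  f2d <- couplings(m, w)
  X <- assemble_input_tensor(f1d, f2d)
  expect_equal(dim(X), c(5L, 5L, 526L))
  # channels 1:42 tile residue i, 43:84 residue j
  expect_equal(X[2, 4, 1:42], f1d[2, ], ignore_attr = TRUE)
  expect_equal(X[2, 4, 43:84], f1d[4, ], ignore_attr = TRUE)
  expect_equal(X[3, 1, 85:526], f2d[3, 1, ], ignore_attr = TRUE)
  # APC channel symmetric
  expect_equal(X[, , 526], t(X[, , 526]))
  expect_error(assemble_input_tensor(f1d[1:3, ], f2d), "matching L")
})

test_that("single-sequence MSAs give zero couplings", {
  m <- toy_msa("ACDEFG")
  f2d <- couplings(m, sequence_weights(m))
  expect_true(all(f2d == 0))
})

test_that("MSA subsampling keeps the query and spans the depth range", {
  m1 <- toy_msa("ACD")
  expect_identical(subsample_msa(m1), m1)

  set.seed(123)
  big <- toy_msa(c("QQQ", rep("AAA", 999)),
                 ids = c("query", sprintf("r%d", 1:999)))
  ks <- integer(1000)
  for (i in 1:1000) {
    s <- subsample_msa(big)
    expect_identical(s$rows[1], "QQQ")
    ks[i] <- msa_depth(s)
  }
  expect_lte(min(ks), 1L)
  expect_gte(max(ks), 500L)
})
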