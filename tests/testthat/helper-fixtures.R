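# Shared fixtures, built in code.  Heavier objects are created once
# per test run and memoised here.

fixture_env <- new.env(parent = emptyenv())

# A small compact backbone reused across test files.
toy_backbone <- function(L = 24, seed = 421) {
  key <- sprintf("bb_%d_%d", L, seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- gen_backbone(L, seed = seed)
  }
  fixture_env[[key]]
}

toy_msa <- function(rows, ids = NULL) {
  new_msa(ids %||% sprintf("s%d", seq_along(rows)), rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent naive dense convolution oracle (same padding, dilation),
# deliberately loop-based and separate from the package's im2col path.
naive_conv2d <- function(x, w, b, k, dil) {
  L <- dim(x)[1]; cin <- dim(x)[3]; cout <- ncol(w)
  # w rows are ordered channel-fastest within each (ki, kj) block
  warr <- array(0, c(k, k, cin, cout))
  idx <- 1
  for (kj in 1:k) for (ki in 1:k) for (cc in 1:cin) {
    warr[ki, kj, cc, ] <- w[idx, ]
    idx <- idx + 1
  }
  off <- (k - 1) / 2
  y <- array(0, c(L, L, cout))
  for (i in 1:L) for (j in 1:L) {
    acc <- b
    for (ki in 1:k) for (kj in 1:k) {
      ii <- i + (ki - 1 - off) * dil
      jj <- j + (kj - 1 - off) * dil
      if (ii >= 1 && ii <= L && jj >= 1 && jj <= L) {
        for (cc in 1:cin) {
          acc <- acc + x[ii, jj, cc] * warr[ki, kj, cc, ]
        }
      }
    }
    y[i, j, ] <- acc
  }
  y
}

# Independent dihedral formula (projection onto the plane normal to
# the central bond), distinct from the package's cross-product path.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  t <- b2 / sqrt(sum(b2^2))
  u <- -b1 + sum(b1 * t) * t     # -b1 projected off the bond axis
  v <- b3 - sum(b3 * t) * t
  cr <- c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
  ang <- atan2(sum(cr * t), sum(u * v)) * 180 / pi
  if (ang >= 180) ang <- -180
  ang
}

oracle_planar <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# Central-difference numerical gradient of f at x.
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

random_posterior <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mk <- function(nb) {
    a <- array(rexp(L * L * nb), c(L, L, nb))
    a / array(rep(apply(a, c(1, 2), sum), nb), c(L, L, nb))
  }
  new_geometry_posterior(mk(37), mk(25), mk(25), mk(13))
}
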