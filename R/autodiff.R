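# Minimal reverse-mode automatic differentiation over base-R arrays.
#
# A "tape" is an environment recording operation nodes in creation
# order; backpropagation walks it in reverse.  Nodes are environments
# holding $value, $grad, $parents and a $backfn closure mapping the
# output gradient to per-parent gradients.  Constants are untracked
# leaves; parameters are tracked leaves whose gradients are collected
# after the backward pass.  Running ops with `tape = NULL` gives plain
# (inference-mode) evaluation.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

is_ad_node <- function(x) is.environment(x) && isTRUE(x$is_node)

ad_node <- function(value, parents = list(), backfn = NULL, tape = NULL,
                    track = TRUE) {
  nd <- new.env(parent = emptyenv())
  nd$is_node <- TRUE
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$track <- track
  if (!is.null(tape) && !is.null(backfn)) {
    tape$n <- tape$n + 1L
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

ad_leaf <- function(value, track = FALSE) {
  ad_node(value, track = track)
}

ad_value <- function(x) if (is_ad_node(x)) x$value else x

ad_wrap <- function(x) if (is_ad_node(x)) x else ad_leaf(x)

# Backpropagate from a scalar loss node through every recorded op.
ad_backward <- function(tape, loss) {
  loss$grad <- 1
  if (tape$n == 0L) return(invisible(NULL))
  for (k in seq(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    if (is.null(nd$grad)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (m in seq_along(ps)) {
      p <- ps[[m]]
      if (!is_ad_node(p) || !p$track) next
      g <- gs[[m]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

# ---- array helpers ---------------------------------------------------

pad_array <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  xp
}

# (L*L) x (k*k*C) patch matrix for a same-padded dilated convolution.
im2col <- function(x, k, dil) {
  d <- dim(x)
  L <- d[1]; C <- d[3]
  if (k == 1L) return(matrix(x, L * L, C))
  p <- as.integer(dil * (k - 1) / 2)
  xp <- pad_array(x, p)
  cols <- matrix(0, L * L, k * k * C)
  blk <- 0L
  for (kj in 0:(k - 1L)) {
    for (ki in 0:(k - 1L)) {
      slab <- xp[ki * dil + seq_len(L), kj * dil + seq_len(L), , drop = FALSE]
      cols[, blk * C + seq_len(C)] <- matrix(slab, L * L, C)
      blk <- blk + 1L
    }
  }
  cols
}

col2im <- function(dcols, L, C, k, dil) {
  if (k == 1L) return(array(dcols, c(L, L, C)))
  p <- as.integer(dil * (k - 1) / 2)
  dxp <- array(0, c(L + 2 * p, L + 2 * p, C))
  blk <- 0L
  for (kj in 0:(k - 1L)) {
    for (ki in 0:(k - 1L)) {
      ri <- ki * dil + seq_len(L); rj <- kj * dil + seq_len(L)
      dxp[ri, rj, ] <- dxp[ri, rj, , drop = FALSE] +
        array(dcols[, blk * C + seq_len(C)], c(L, L, C))
      blk <- blk + 1L
    }
  }
  dxp[p + seq_len(L), p + seq_len(L), , drop = FALSE]
}

# ---- operations ------------------------------------------------------

# Same-padded 2D convolution; weights are a (k*k*Cin) x Cout matrix.
ad_conv2d <- function(x, w, b, k = 1L, dilation = 1L, tape = NULL) {
  x <- ad_wrap(x); w <- ad_wrap(w); b <- ad_wrap(b)
  xv <- x$value; Wv <- w$value; bv <- b$value
  d <- dim(xv); L <- d[1]; Cin <- d[3]; Cout <- ncol(Wv)
  if (nrow(Wv) != k * k * Cin) {
    stop_protgeom(sprintf(
      "conv weight rows (%d) do not match k^2 * Cin = %d",
      nrow(Wv), k * k * Cin
    ))
  }
  cols <- im2col(xv, k, dilation)
  ym <- cols %*% Wv
  ym <- ym + rep(bv, each = nrow(ym))
  yv <- array(ym, c(L, L, Cout))
  ad_node(yv, parents = list(x, w, b), tape = tape, backfn = function(g) {
    gm <- matrix(g, L * L, Cout)
    dx <- if (x$track) col2im(gm %*% t(Wv), L, Cin, k, dilation) else NULL
    dW <- if (w$track) crossprod(cols, gm) else NULL
    db <- if (b$track) colSums(gm) else NULL
    list(dx, dW, db)
  })
}

# Instance normalisation: per-channel standardisation over the spatial
# dimensions, with learnable per-channel gain and shift.
ad_instance_norm <- function(x, gamma, beta, eps = 1e-5, tape = NULL) {
  x <- ad_wrap(x); gamma <- ad_wrap(gamma); beta <- ad_wrap(beta)
  xv <- x$value
  d <- dim(xv); n <- d[1] * d[2]; C <- d[3]
  xm <- matrix(xv, n, C)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  istd <- 1 / sqrt(colMeans(xc^2) + eps)
  xhat <- xc * rep(istd, each = n)
  ym <- xhat * rep(gamma$value, each = n) + rep(beta$value, each = n)
  ad_node(array(ym, d), parents = list(x, gamma, beta), tape = tape,
          backfn = function(g) {
    gm <- matrix(g, n, C)
    dgamma <- if (gamma$track) colSums(gm * xhat) else NULL
    dbeta <- if (beta$track) colSums(gm) else NULL
    dx <- NULL
    if (x$track) {
      dxhat <- gm * rep(gamma$value, each = n)
      t1 <- dxhat - rep(colMeans(dxhat), each = n)
      t2 <- xhat * rep(colMeans(dxhat * xhat), each = n)
      dx <- array((t1 - t2) * rep(istd, each = n), d)
    }
    list(dx, dgamma, dbeta)
  })
}

ad_elu <- function(x, tape = NULL) {
  x <- ad_wrap(x)
  xv <- x$value
  neg <- xv <= 0
  yv <- xv
  yv[neg] <- expm1(xv[neg])
  ad_node(yv, parents = list(x), tape = tape, backfn = function(g) {
    dx <- g
    dx[neg] <- g[neg] * (yv[neg] + 1)
    list(dx)
  })
}

ad_add <- function(x, y, tape = NULL) {
  x <- ad_wrap(x); y <- ad_wrap(y)
  ad_node(x$value + y$value, parents = list(x, y), tape = tape,
          backfn = function(g) list(g, g))
}

# Concatenate along the channel axis.
ad_concat <- function(xs, tape = NULL) {
  xs <- lapply(xs, ad_wrap)
  vals <- lapply(xs, `[[`, "value")
  d1 <- dim(vals[[1]])
  Cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  L <- d1[1]
  yv <- array(0, c(L, d1[2], sum(Cs)))
  at <- 0L
  for (v in vals) {
    yv[, , at + seq_len(dim(v)[3])] <- v
    at <- at + dim(v)[3]
  }
  ad_node(yv, parents = xs, tape = tape, backfn = function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (m in seq_along(xs)) {
      out[[m]] <- g[, , at + seq_len(Cs[m]), drop = FALSE]
      at <- at + Cs[m]
    }
    out
  })
}

# Channel slice x[, , from:to].
ad_slice <- function(x, from, to, tape = NULL) {
  x <- ad_wrap(x)
  d <- dim(x$value)
  ad_node(x$value[, , from:to, drop = FALSE], parents = list(x),
          tape = tape, backfn = function(g) {
    dx <- array(0, d)
    dx[, , from:to] <- g
    list(dx)
  })
}

# Multiply an (L, L, C) map by a per-pair (L, L) weight, broadcast over
# channels (column-major recycling makes the broadcast exact).
ad_scale_map <- function(x, m, tape = NULL) {
  x <- ad_wrap(x); m <- ad_wrap(m)
  xv <- x$value; mv <- m$value
  d <- dim(xv)
  yv <- xv * as.numeric(mv)
  ad_node(yv, parents = list(x, m), tape = tape, backfn = function(g) {
    dx <- if (x$track) g * as.numeric(mv) else NULL
    dm <- if (m$track) {
      matrix(rowSums(matrix(g * xv, d[1] * d[2], d[3])), d[1], d[2])
    } else NULL
    list(dx, dm)
  })
}

# Softmax over the last (channel) axis.
ad_softmax <- function(x, tape = NULL) {
  x <- ad_wrap(x)
  d <- dim(x$value)
  xm <- matrix(x$value, prod(d[1:2]), d[3])
  e <- exp(xm - xm[cbind(seq_len(nrow(xm)), max.col(xm, "first"))])
  ym <- e / rowSums(e)
  ad_node(array(ym, d), parents = list(x), tape = tape, backfn = function(g) {
    gm <- matrix(g, prod(d[1:2]), d[3])
    list(array(ym * (gm - rowSums(ym * gm)), d))
  })
}

# Masked mean categorical cross-entropy of logits against integer
# labels in 0..(C-1) (label + 1 indexes the channel axis).
ad_ce_loss <- function(logits, labels, mask, tape = NULL) {
  logits <- ad_wrap(logits)
  d <- dim(logits$value)
  n <- d[1] * d[2]
  xm <- matrix(logits$value, n, d[3])
  mx <- xm[cbind(seq_len(n), max.col(xm, "first"))]
  lse <- mx + log(rowSums(exp(xm - mx)))
  sel <- cbind(seq_len(n), as.vector(labels) + 1L)
  nll <- lse - xm[sel]
  mv <- as.vector(mask)
  n_valid <- sum(mv)
  if (n_valid == 0L) stop_protgeom("all pairs masked out of the loss")
  val <- sum(nll[mv]) / n_valid
  ad_node(val, parents = list(logits), tape = tape, backfn = function(g) {
    sm <- exp(xm - lse)
    sm[sel] <- sm[sel] - 1
    sm[!mv, ] <- 0
    list(array(g * sm / n_valid, d))
  })
}

# Sum of scalar nodes.
ad_sum_scalar <- function(xs, tape = NULL) {
  xs <- lapply(xs, ad_wrap)
  val <- sum(vapply(xs, `[[`, numeric(1), "value"))
  ad_node(val, parents = xs, tape = tape, backfn = function(g) {
    rep(list(g), length(xs))
  })
}

# Axial attention logits between a query map Q and a key map K (both
# (L, L, C)): scaled dot products of row-axis means plus column-axis
# means, broadcast back to an (L, L) logit map
# M[i, j] = <Qrow_i, Krow_i> / sqrt(C) + <Qcol_j, Kcol_j> / sqrt(C).
ad_axial_logits <- function(q, k, tape = NULL) {
  q <- ad_wrap(q); k <- ad_wrap(k)
  qv <- q$value; kv <- k$value
  d <- dim(qv); L <- d[1]; C <- d[3]
  sc <- 1 / sqrt(C)
  # row-axis means: average over j -> per-i vectors
  qr <- apply(qv, c(1, 3), mean); kr <- apply(kv, c(1, 3), mean)
  qc <- apply(qv, c(2, 3), mean); kc <- apply(kv, c(2, 3), mean)
  r <- rowSums(qr * kr) * sc
  ccol <- rowSums(qc * kc) * sc
  val <- outer(r, rep(1, L)) + outer(rep(1, L), ccol)
  ad_node(val, parents = list(q, k), tape = tape, backfn = function(g) {
    dr <- rowSums(g); dc <- colSums(g)
    expand_row <- function(dvec, other) {
      # gradient of a per-i quantity built from row means
      out <- array(0, d)
      contrib <- (dvec * other) * sc / L     # (L, C)
      for (cdx in seq_len(C)) {
        out[, , cdx] <- matrix(contrib[, cdx], L, L)
      }
      out
    }
    expand_col <- function(dvec, other) {
      out <- array(0, d)
      contrib <- (dvec * other) * sc / L
      for (cdx in seq_len(C)) {
        out[, , cdx] <- matrix(contrib[, cdx], L, L, byrow = TRUE)
      }
      out
    }
    dq <- if (q$track) expand_row(dr, kr) + expand_col(dc, kc) else NULL
    dk <- if (k$track) expand_row(dr, qr) + expand_col(dc, qc) else NULL
    list(dq, dk)
  })
}

# Stack a list of (L, L) maps into (L, L, N).
ad_stack_maps <- function(xs, tape = NULL) {
  xs <- lapply(xs, ad_wrap)
  L <- nrow(xs[[1]]$value)
  N <- length(xs)
  yv <- array(0, c(L, L, N))
  for (m in seq_len(N)) yv[, , m] <- xs[[m]]$value
  ad_node(yv, parents = xs, tape = tape, backfn = function(g) {
    lapply(seq_len(N), function(m) g[, , m])
  })
}
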