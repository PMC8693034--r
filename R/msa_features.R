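#' Identity-based sequence weights
#'
#' Down-weights redundant alignment rows: each row's weight is the
#' reciprocal of the number of rows (itself included) with pairwise
#' identity at or above `identity_cutoff`.  The effective depth Neff is
#' the sum of the weights.  Pairwise identity is the fraction of
#' columns with identical 21-state symbols (gap counts as a state).
#'
#' @param msa An [new_msa()] object.
#' @param identity_cutoff Identity threshold in (0, 1].
#' @return A list of class `sequence_weights` with elements `w`
#'   (per-row weights in (0,1]) and `neff`.
#' @export
sequence_weights <- function(msa, identity_cutoff = 0.8) {
  if (identity_cutoff <= 0 || identity_cutoff > 1) {
    stop_protgeom("identity_cutoff must be in (0, 1]")
  }
  mi <- msa_to_int_matrix(msa)
  n <- nrow(mi); L <- ncol(mi)
  X <- one_hot_rows(mi)
  matches <- tcrossprod(X)          # shared identical columns per pair
  nbr <- rowSums(matches / L >= identity_cutoff)
  w <- 1 / nbr
  structure(list(w = w, neff = sum(w)), class = "sequence_weights")
}

# N x 21L binary one-hot expansion of an integer-coded MSA.
one_hot_rows <- function(mi) {
  n <- nrow(mi); L <- ncol(mi)
  X <- matrix(0, n, N_STATES * L)
  # column index for (row n, position l, state s) = 21*(l-1) + s
  cols <- sweep(mi, 2, N_STATES * (seq_len(L) - 1L), `+`)
  X[cbind(rep(seq_len(n), L), as.vector(cols))] <- 1
  X
}

#' Per-position profile features: one-hot, PSSM and entropy
#'
#' Produces the L x 42 one-dimensional feature block: 20 channels of
#' query one-hot (wildcards give all-zero), 21 channels of weighted
#' residue/gap frequencies with an additive pseudocount, and one
#' positional entropy channel `-sum f log f` over the 21 states.
#'
#' @param msa An [new_msa()] object.
#' @param weights Matching [sequence_weights()].
#' @param pseudocount Additive pseudocount; default `1 / N_seq`.
#' @return An L x 42 numeric matrix.
#' @export
profile_and_entropy <- function(msa, weights, pseudocount = NULL) {
  mi <- msa_to_int_matrix(msa)
  L <- ncol(mi)
  if (L == 0L) stop_protgeom("zero-length MSA")
  pc <- pseudocount %||% (1 / nrow(mi))
  w <- weights$w
  counts <- matrix(0, L, N_STATES)
  for (s in seq_len(N_STATES)) {
    counts[, s] <- colSums(w * (mi == s))
  }
  f <- (counts + pc) / (weights$neff + N_STATES * pc)
  ent <- -rowSums(ifelse(f > 0, f * log(f), 0))
  q <- mi[1, ]
  onehot <- matrix(0, L, 20)
  ok <- q <= 20
  onehot[cbind(which(ok), q[ok])] <- 1
  out <- cbind(onehot, f, ent)
  dimnames(out) <- NULL
  out
}

#' Inverse-covariance coupling features with APC
#'
#' The coevolution block of the input tensor.  Builds the weighted
#' covariance of the 21L-dimensional one-hot encoding, regularises the
#' diagonal with `shrinkage / sqrt(Neff)`, inverts it, and reads the
#' negated off-diagonal 21 x 21 blocks as 441 coupling channels per
#' residue pair.  Channel 442 is the average-product-corrected
#' Frobenius norm of the 20 x 20 non-gap sub-block (the contact-signal
#' channel): `APC_ij = S_ij - S_i. S_.j / S_..`, where the gap state is
#' excluded from the norm by the standard APC convention.
#'
#' @param msa An [new_msa()] object.
#' @param weights Matching [sequence_weights()].
#' @param shrinkage Diagonal shrinkage constant (scaled by
#'   `1/sqrt(Neff)`).
#' @return An L x L x 442 array; all coupling channels are zero for a
#'   single-sequence MSA.
#' @export
couplings <- function(msa, weights, shrinkage = 4.5) {
  mi <- msa_to_int_matrix(msa)
  n <- nrow(mi); L <- ncol(mi)
  if (n == 1L) return(array(0, c(L, L, N_STATES^2 + 1L)))
  X <- one_hot_rows(mi)
  w <- weights$w
  f <- colSums(w * X) / weights$neff
  C <- crossprod(sqrt(w) * X) / weights$neff - tcrossprod(f)
  diag(C) <- diag(C) + shrinkage / sqrt(weights$neff)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    stop_protgeom(
      "covariance not positive definite; increase the shrinkage constant"
    )
  }
  P <- chol2inv(ch)
  Parr <- array(P, c(N_STATES, L, N_STATES, L))
  cp <- aperm(Parr, c(2, 4, 1, 3))          # (i, j, state_i, state_j)
  blocks <- -array(cp, c(L, L, N_STATES^2))
  # residue-diagonal blocks are self terms, not couplings
  ii <- rep(seq_len(L), N_STATES^2)
  kk <- rep(seq_len(N_STATES^2), each = L)
  blocks[cbind(ii, ii, kk)] <- 0
  # Frobenius norm over the 20x20 non-gap sub-block
  sub <- array(cp[, , 1:20, 1:20], c(L, L, 400L))
  S <- sqrt(rowSums(matrix(sub^2, ncol = 400L)))
  S <- matrix(S, L, L)
  diag(S) <- 0
  rs <- rowSums(S) / (L - 1)
  sbar <- sum(S) / (L * (L - 1))
  apc <- S - outer(rs, rs) / sbar
  diag(apc) <- 0
  out <- array(0, c(L, L, N_STATES^2 + 1L))
  out[, , seq_len(N_STATES^2)] <- blocks
  out[, , N_STATES^2 + 1L] <- apc
  out
}

#' Assemble the 526-channel input tensor
#'
#' Channel layout: 1-42 the 1D features of residue i tiled along j,
#' 43-84 the 1D features of residue j tiled along i, 85-525 the 441
#' coupling channels, 526 the APC contact channel.
#'
#' @param f1d L x 42 matrix from [profile_and_entropy()].
#' @param f2d L x L x 442 array from [couplings()].
#' @return An L x L x 526 array of class `feature_tensor`.
#' @export
assemble_input_tensor <- function(f1d, f2d) {
  L <- nrow(f1d)
  if (ncol(f1d) != 42L) stop_protgeom("f1d must have 42 columns")
  if (!all(dim(f2d) == c(L, L, 442L))) {
    stop_protgeom("f2d must be L x L x 442 with matching L")
  }
  X <- array(0, c(L, L, 526L))
  for (k in 1:42) {
    X[, , k] <- matrix(f1d[, k], L, L)               # varies along i
    X[, , 42L + k] <- matrix(f1d[, k], L, L, byrow = TRUE)  # along j
  }
  X[, , 85:526] <- f2d
  structure(X, class = c("feature_tensor", "array"))
}

#' MSA to network input tensor
#'
#' Convenience wrapper running [sequence_weights()],
#' [profile_and_entropy()], [couplings()] and
#' [assemble_input_tensor()].
#'
#' @inheritParams sequence_weights
#' @inheritParams profile_and_entropy
#' @inheritParams couplings
#' @return An L x L x 526 `feature_tensor`.
#' @export
msa_features <- function(msa, identity_cutoff = 0.8, pseudocount = NULL,
                         shrinkage = 4.5) {
  w <- sequence_weights(msa, identity_cutoff)
  f1d <- profile_and_entropy(msa, w, pseudocount)
  f2d <- couplings(msa, w, shrinkage)
  assemble_input_tensor(f1d, f2d)
}
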