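#' Contact probability from the distance head
#'
#' Converts the predicted distance distribution into a binary-contact
#' probability by summing the distance bins with d <= 8 A (bins 1-12
#' of the 36 contact bins, covering \[2, 8) A).
#'
#' @param p_d An L x L x 37 distance head.
#' @return An L x L contact probability map in \[0, 1\].
#' @export
contact_probability <- function(p_d) {
  if (length(dim(p_d)) != 3L || dim(p_d)[3] != 37L) {
    stop_protgeom("distance head must have 37 bins")
  }
  apply(p_d[, , 2:13, drop = FALSE], c(1, 2), sum)
}

sep_bounds <- function(class) {
  switch(
    class,
    short = c(6, 11), medium = c(12, 23), long = c(24, Inf),
    "medium+long" = c(12, Inf),
    stop_protgeom("unknown separation class: ", class)
  )
}

#' Top-k contact precision within a separation class
#'
#' Ranks the pairs i < j whose sequence separation |i - j| falls in
#' the class (short \[6, 12), medium \[12, 24), long \[24, Inf), or
#' the medium+long union used for the headline top-L metric) by
#' predicted contact probability (ties broken by ascending (i, j)),
#' and reports the fraction of the top `min(k, available)` pairs whose
#' true CB-CB distance is <= 8 A.
#'
#' @param cp Symmetric L x L contact probability map.
#' @param true_d Symmetric L x L true distance map (Angstrom).
#' @param k Number of top pairs assessed (e.g. L, L/2, L/5).
#' @param class One of `"short"`, `"medium"`, `"long"`,
#'   `"medium+long"`.
#' @return The precision as a fraction in \[0, 1\].
#' @export
topk_precision <- function(cp, true_d, k, class = "medium+long") {
  if (k < 1) stop_protgeom("k must be >= 1")
  b <- sep_bounds(class)
  L <- nrow(cp)
  ii <- rep(seq_len(L), L); jj <- rep(seq_len(L), each = L)
  keep <- ii < jj & (jj - ii) >= b[1] & (jj - ii) <= b[2]
  if (!any(keep)) {
    stop_protgeom("no residue pairs in separation class ", class)
  }
  i <- ii[keep]; j <- jj[keep]
  p <- cp[cbind(i, j)]
  ord <- order(-p, i, j)
  kk <- min(as.integer(k), length(ord))
  top <- ord[seq_len(kk)]
  mean(true_d[cbind(i[top], j[top])] <= 8)
}

#' Tidy contact-precision report
#'
#' Evaluates top L, L/2 and L/5 precision in the medium, long and
#' medium+long separation classes.
#'
#' @inheritParams topk_precision
#' @return A tibble with columns `class`, `k_label`, `k`, `precision`.
#' @export
contact_precision_report <- function(cp, true_d) {
  L <- nrow(cp)
  grid <- tidyr::expand_grid(
    class = c("medium", "long", "medium+long"),
    k_label = c("L", "L/2", "L/5")
  )
  grid$k <- as.integer(ceiling(L / c(1, 2, 5)))[match(grid$k_label, c("L", "L/2", "L/5"))]
  grid$precision <- purrr::map2_dbl(
    grid$class, grid$k,
    function(cl, k) {
      tryCatch(topk_precision(cp, true_d, k, cl),
               error = function(e) NA_real_)  # class empty at this L
    }
  )
  grid
}

#' Resampling-based paired method comparison
#'
#' Implements the half-subsample significance protocol: `reps` times,
#' half of the targets are drawn at random and the mean score of each
#' method over that half is recorded, giving paired mean samples.  The
#' Anderson-Darling test checks the differences for normality; if
#' normal, a two-tailed paired t-test is applied, otherwise the
#' Wilcoxon signed-rank test.  Differences with zero variance are
#' declared non-significant directly (p = 1) when their mean is zero.
#'
#' @param scores_a,scores_b Equal-length paired per-target scores
#'   (e.g. TM-scores) of the two methods.
#' @param reps Number of half-subsample repetitions.
#' @param alpha Significance level.
#' @return A list of class `method_comparison`: `p_value`, `test`
#'   (`"t"`, `"wilcoxon"` or `"degenerate"`), `significant`,
#'   `mean_diff` and the `paired_means` tibble.
#' @export
method_comparison <- function(scores_a, scores_b, reps = 10, alpha = 0.05) {
  n <- length(scores_a)
  if (n != length(scores_b)) stop_protgeom("paired score lists differ in length")
  if (n < 4L) stop_protgeom("need at least 4 paired scores")
  half <- n %/% 2L
  ma <- mb <- numeric(reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(n, half)
    ma[r] <- mean(scores_a[idx])
    mb[r] <- mean(scores_b[idx])
  }
  d <- ma - mb
  if (stats::sd(d) < .Machine$double.eps^0.5) {
    p <- if (abs(mean(d)) < .Machine$double.eps^0.5) 1 else 0
    test <- "degenerate"
  } else if (nortest::ad.test(d)$p.value > alpha) {
    p <- t.test(ma, mb, paired = TRUE)$p.value
    test <- "t"
  } else {
    p <- suppressWarnings(wilcox.test(ma, mb, paired = TRUE)$p.value)
    test <- "wilcoxon"
  }
  structure(
    list(
      p_value = p, test = test, significant = p < alpha,
      mean_diff = mean(d),
      paired_means = tibble::tibble(rep = seq_len(reps), mean_a = ma, mean_b = mb)
    ),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf(
    "<method_comparison> %s test, p = %.4g (%ssignificant), mean diff %.4g\n",
    x$test, x$p_value, if (x$significant) "" else "not ", x$mean_diff
  ))
  invisible(x)
}
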