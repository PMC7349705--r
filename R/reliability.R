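#' Intraclass correlation of replicate measurements
#'
#' One-way random-effects, single-measure ICC(1,1) from the ANOVA
#' decomposition of a subjects-by-replicates table:
#' ICC = (MSB - MSW) / (MSB + (k-1) MSW), with a 95% confidence interval
#' from the F distribution (Shrout-Fleiss).  This is the appropriate form
#' for duplicate membranes with no fixed rater structure.
#'
#' @param pairs an n x k matrix or data.frame of replicate measurements
#'   (k >= 2), or for k = 2 a list/data.frame of (replicate1, replicate2)
#'   columns.  n >= 3 subjects required.
#' @param conf confidence level for the interval, default 0.95.
#' @return object of class `reliability_report`: `icc_single`, `k`,
#'   `extrapolated` (Spearman-Brown step-up to the mean of k replicates),
#'   `n_pairs`, `ci95`.
#' @examples
#' set.seed(1)
#' truth <- rnorm(50, 6.7, 0.84)
#' m <- cbind(truth + rnorm(50, 0, 0.084), truth + rnorm(50, 0, 0.084))
#' icc(m)$icc_single
#' @export
icc <- function(pairs, conf = 0.95) {
  x <- as.matrix(pairs)
  storage.mode(x) <- "double"
  stop_if(ncol(x) < 2, "need at least 2 replicates per subject")
  stop_if(nrow(x) < 3, "need at least 3 subjects")
  stop_if(anyNA(x), "missing replicate values are not supported")
  n <- nrow(x)
  k <- ncol(x)
  grand <- mean(x)
  row_means <- rowMeans(x)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((x - row_means)^2) / (n * (k - 1))
  stop_if(msb + msw == 0, "zero total variance: ICC undefined")
  est <- (msb - msw) / (msb + (k - 1) * msw)
  alpha <- 1 - conf
  if (msw > 0) {
    f <- msb / msw
    fl <- f / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- f * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    ci <- c(1, 1)
  }
  structure(list(icc_single = est, k = k,
                 extrapolated = spearman_brown(est, k),
                 n_pairs = n, ci95 = ci),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> ICC(1,1) = %.4f (95%% CI %.3f-%.3f), n = %d\n",
              x$icc_single, x$ci95[1], x$ci95[2], x$n_pairs))
  cat(sprintf("  extrapolated repeatability of the mean of %d replicates: %.4f\n",
              x$k, x$extrapolated))
  invisible(x)
}

#' Spearman-Brown extrapolated repeatability
#'
#' Reliability of the mean of k replicate measurements given the
#' single-measure ICC: k * ICC / (1 + (k - 1) * ICC).  With k = 1 the ICC
#' is returned unchanged.
#'
#' @param icc_single single-measure ICC in (-1, 1].
#' @param k number of replicates averaged, integer >= 1.
#' @return extrapolated reliability.
#' @examples
#' spearman_brown(0.99, 2)  # 0.995
#' @export
spearman_brown <- function(icc_single, k) {
  stop_if(!is_count(k) || k < 1, "k must be an integer >= 1")
  stop_if(any(icc_single <= -1) || any(icc_single > 1),
          "icc_single must be in (-1, 1]")
  k * icc_single / (1 + (k - 1) * icc_single)
}
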