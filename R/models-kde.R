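# Gaussian-KDE odds-ratio baseline: classifies an OCR from the mean
# normalized ATAC depth in its window alone, by comparing Gaussian
# kernel-density estimates fitted to the positive and negative training
# distributions.

.scott_bw <- function(x) stats::sd(x) * length(x)^(-1 / 5)

#' Fit the kernel-density odds-ratio baseline
#'
#' Stores the two training samples of per-window mean ATAC signal and their
#' Scott's-rule bandwidths (`sd * n^(-1/5)`) for Gaussian-kernel density
#' evaluation.
#'
#' @param pos_means mean window signals of positive OCRs (length >= 2,
#'   nonzero variance).
#' @param neg_means mean window signals of negative OCRs (same constraints).
#' @return an object of class `kde_baseline`.
#' @export
fit_kde_baseline <- function(pos_means, neg_means) {
  pos_means <- as.numeric(pos_means)
  neg_means <- as.numeric(neg_means)
  if (length(pos_means) < 2 || length(neg_means) < 2)
    stop("both samples need at least 2 observations")
  if (stats::sd(pos_means) == 0 || stats::sd(neg_means) == 0)
    stop("degenerate sample: zero variance")
  structure(list(positive_sample = pos_means,
                 negative_sample = neg_means,
                 bw_pos = .scott_bw(pos_means),
                 bw_neg = .scott_bw(neg_means),
                 bandwidth_rule = "scott"),
            class = "kde_baseline")
}

#' @export
print.kde_baseline <- function(x, ...) {
  cat("kde_baseline:", length(x$positive_sample), "positive /",
      length(x$negative_sample), "negative training means;",
      "Scott bandwidths", signif(x$bw_pos, 4), "/", signif(x$bw_neg, 4), "\n")
  invisible(x)
}

# Gaussian kernel mixture density of `sample` evaluated at `x`, chunked so
# the n_x * n_sample kernel matrix never exceeds ~1e7 entries.
.kde_density <- function(x, sample, bw) {
  n <- length(sample)
  out <- numeric(length(x))
  chunk <- max(1L, floor(1e7 / n))
  for (lo in seq(1, length(x), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(x))
    z <- outer(x[lo:hi], sample, function(a, b) stats::dnorm(a, b, bw))
    out[lo:hi] <- rowMeans(z)
  }
  out
}

#' Score OCRs with the kernel-density odds-ratio baseline
#'
#' The score is the ratio of the positive to the negative Gaussian-mixture
#' density at the observed mean signal, `(f_pos(x) + eps) / (f_neg(x) +
#' eps)` with `eps = 1e-12`; the predicted label is 1 when the score
#' exceeds 1 (ties go to the majority negative class).
#'
#' @param baseline a fitted [fit_kde_baseline()].
#' @param mean_signal numeric vector of per-window mean ATAC signals.
#' @return a data.frame with columns `score` and `label` (integer 0/1).
#' @export
predict_kde_baseline <- function(baseline, mean_signal) {
  stopifnot(inherits(baseline, "kde_baseline"))
  eps <- 1e-12
  f_pos <- .kde_density(mean_signal, baseline$positive_sample,
                        baseline$bw_pos)
  f_neg <- .kde_density(mean_signal, baseline$negative_sample,
                        baseline$bw_neg)
  score <- (f_pos + eps) / (f_neg + eps)
  data.frame(score = score, label = as.integer(score > 1))
}
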