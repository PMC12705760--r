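#' Two-way agreement intraclass correlation, ICC(A,1)
#'
#' Single-measure, absolute-agreement ICC from the two-way (items x
#' raters) mean-squares decomposition:
#' `(MSR - MSE) / (MSR + (k - 1) MSE + (k / n) (MSC - MSE))`
#' with `MSR` the item (row) mean square, `MSC` the rater (column)
#' mean square and `MSE` the residual mean square.  Used per feature
#' category with concepts as items and each rater's classification
#' frequency as the rating; can be negative when agreement is worse
#' than chance.
#'
#' @param rt numeric matrix or data frame, items x 2 raters, at least
#'   2 items.
#' @return the ICC value (scalar, at most 1).
#' @export
icc_agreement <- function(rt) {
  rt <- as.matrix(rt)
  if (ncol(rt) != 2) stop_arg("`rt` must have exactly 2 rater columns")
  n <- nrow(rt)
  if (n < 2) stop_arg("need at least 2 items")
  if (anyNA(rt)) stop_arg("missing ratings are not supported")
  k <- 2
  grand <- mean(rt)
  if (all(rt == rt[1])) {
    stop_arg("ICC undefined: ratings have zero total variance")
  }
  rm_ <- rowMeans(rt)
  cm_ <- colMeans(rt)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((rt - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom == 0) stop_arg("ICC undefined: zero denominator")
  (msr - mse) / denom
}

#' Frequency-weighted mean of per-category ICCs
#'
#' `sum(icc_i * w_i) / sum(w_i)` with weights the mean classification
#' frequencies of the two raters, summarizing inter-rater reliability
#' across feature categories while down-weighting rarely used ones.
#'
#' @param iccs per-category ICC values.
#' @param freqs per-category mean classification frequencies
#'   (non-negative, not all zero).
#' @return the weighted mean ICC.
#' @export
weighted_mean_icc <- function(iccs, freqs) {
  if (length(iccs) != length(freqs)) stop_arg("`iccs` and `freqs` lengths differ")
  if (any(freqs < 0)) stop_arg("`freqs` must be non-negative")
  if (sum(freqs) == 0) stop_arg("`freqs` must not be all zero")
  sum(iccs * freqs) / sum(freqs)
}

#' Per-category inter-rater reliability of property codings
#'
#' Convenience wrapper: given two raters' participant-summed category
#' count tables (concepts x 11), computes the per-category ICC(A,1)
#' with concepts as items, each category's mean classification
#' frequency, and the frequency-weighted mean ICC.
#'
#' @param counts_a,counts_b concepts x categories count matrices of the
#'   two raters (same dimnames).
#' @return list with `icc` (per category), `freq` (mean frequencies)
#'   and `weighted_mean`.
#' @export
category_reliability <- function(counts_a, counts_b) {
  counts_a <- as.matrix(counts_a)
  counts_b <- as.matrix(counts_b)
  if (!identical(dim(counts_a), dim(counts_b))) stop_arg("rater tables differ in shape")
  k <- ncol(counts_a)
  icc <- numeric(k)
  freq <- numeric(k)
  for (j in seq_len(k)) {
    icc[j] <- icc_agreement(cbind(counts_a[, j], counts_b[, j]))
    freq[j] <- mean(c(sum(counts_a[, j]), sum(counts_b[, j])))
  }
  names(icc) <- names(freq) <- colnames(counts_a)
  list(icc = icc, freq = freq, weighted_mean = weighted_mean_icc(icc, freq))
}

#' Simulate a second rater's category codings
#'
#' Emulates independent re-coding of listed properties: each property
#' assigned by the first rater to a category is kept there with
#' probability `agreement` and otherwise reassigned to a category drawn
#' from the overall category distribution.  The result is a second
#' count table of the kind compared by [category_reliability()].
#'
#' @param counts items x categories count matrix (first rater).
#' @param agreement probability a property keeps its category.
#' @param seed integer seed.
#' @return items x categories count matrix of the simulated rater.
#' @export
simulate_rater_codings <- function(counts, agreement = 0.8, seed = 1) {
  counts <- as.matrix(counts)
  if (agreement < 0 || agreement > 1) stop_arg("`agreement` must be in [0, 1]")
  k <- ncol(counts)
  marginal <- colSums(counts)
  marginal <- (marginal + 1) / sum(marginal + 1)
  with_seed(seed, {
    out <- matrix(0L, nrow(counts), k, dimnames = dimnames(counts))
    for (i in seq_len(nrow(counts))) {
      for (j in seq_len(k)) {
        n <- counts[i, j]
        if (n == 0) next
        keep <- stats::rbinom(1, n, agreement)
        out[i, j] <- out[i, j] + keep
        if (n > keep) {
          moved <- stats::rmultinom(1, n - keep, marginal)
          out[i, ] <- out[i, ] + as.integer(moved)
        }
      }
    }
    out
  })
}
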