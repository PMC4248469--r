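#' Subsampling fraction from average coverage
#'
#' The k-mer subsample is held at constant expected density by scaling the
#' subsampling fraction inversely with fold coverage: `alpha = 0.1 * (70 /
#' C) = 7 / C`, clamped at 1 for coverage below 7-fold. Holding `alpha * K`
#' constant (K = total k-mers sequenced) keeps filter occupancies, false
#' positive rates and correction accuracy nearly constant as depth grows.
#'
#' @param coverage Average fold coverage `C > 0`.
#' @return Subsampling fraction in `(0, 1]`.
#' @examples
#' alpha_from_coverage(c(20, 35, 70, 140))
#' @export
alpha_from_coverage <- function(coverage) {
  if (any(!is.finite(coverage)) || any(coverage <= 0))
    stop("coverage must be positive")
  pmin(1, 7 / coverage)
}

#' Assumed maximum multiplicity of a weak k-mer
#'
#' `f(alpha) = max(2, 0.2 / alpha)`: the number of occurrences an
#' error-derived k-mer is conservatively assumed to have when modelling its
#' chance of slipping into the subsample filter.
#'
#' @param alpha Subsampling fraction in `(0, 1]`.
#' @return `max(2, 0.2 / alpha)`.
#' @export
f_alpha <- function(alpha) {
  stopifnot(all(alpha > 0), all(alpha <= 1))
  pmax(2, 0.2 / alpha)
}

#' Probability a weak k-mer enters the subsample
#'
#' `P(alpha) = 1 - (1 - alpha)^f(alpha)`: the chance that at least one of
#' the (at most `f(alpha)`) occurrences of a weak k-mer survives Bernoulli
#' subsampling. For small `alpha` this is nearly scale-invariant in `alpha`
#' (`P(alpha/z) ~ P(alpha)`), which is what makes the inverse-coverage rule
#' of [alpha_from_coverage()] work.
#'
#' @inheritParams f_alpha
#' @return Probability in `(0, 1]`.
#' @examples
#' p_alpha(0.1)   # 1 - 0.9^2
#' @export
p_alpha <- function(alpha) {
  stopifnot(all(alpha > 0), all(alpha <= 1))
  1 - (1 - alpha)^f_alpha(alpha)
}

#' False-positive-adjusted subsample-hit probability
#'
#' `P*(alpha) = P(alpha) + beta - beta * P(alpha)`, i.e. the probability
#' that a weak k-mer is found in the subsample filter either genuinely
#' (probability `P(alpha)`) or through a Bloom false positive (rate `beta`,
#' estimated from the filter's occupancy via [estimate_fp()]).
#'
#' @inheritParams f_alpha
#' @param beta Bloom filter false-positive estimate in `[0, 1)`.
#' @return Probability; monotone nondecreasing in both arguments.
#' @export
p_star <- function(alpha, beta) {
  stopifnot(all(beta >= 0), all(beta < 1))
  p <- p_alpha(alpha)
  p + beta - beta * p
}

#' Binomial trust thresholds
#'
#' A read position overlapped by `x` k-mers is tested against the count of
#' those k-mers found in the subsample filter. Under the error model the
#' count at an erroneous position is `Binom(x, p_star)`; the threshold
#' `y_x` is the minimum integer such that `P(Binom(x, p_star) <= y_x - 1) >=
#' quantile`, so that erroneous positions pass only with probability
#' `1 - quantile`. Equivalently `y_x = 1 + Q` where `Q` is the smallest
#' integer with CDF at least `quantile`.
#'
#' The CDF is computed by exact summation of binomial pmf terms in log
#' space; no normal approximation is involved (`x <= 31` keeps this cheap).
#' `y_x` is nondecreasing in `x` and in `p_star`, and may exceed `x`, in
#' which case no position overlapped by `x` k-mers can be trusted — the
#' regime reached when `alpha` (hence `p_star`) is too large.
#'
#' @param k k-mer length; thresholds are produced for `x = 1..k`.
#' @param p_star Per-k-mer hit probability from [p_star()].
#' @param quantile Tail mass controlling the test (default 0.995).
#' @return A tibble of class `threshold_table` with columns `x` and `y`.
#' @examples
#' trust_thresholds(7, p_star(0.1, 0.01))
#' @export
trust_thresholds <- function(k, p_star, quantile = 0.995) {
  stopifnot(k >= 1, k <= 31, p_star >= 0, p_star <= 1,
            quantile > 0.5, quantile < 1)
  y <- integer(k)
  for (x in seq_len(k)) {
    if (p_star <= 0) {
      y[x] <- 1L
    } else if (p_star >= 1) {
      y[x] <- x + 1L  # CDF jumps to 1 only at x
    } else {
      q <- 0:x
      logpmf <- lchoose(x, q) + q * log(p_star) + (x - q) * log1p(-p_star)
      cdf <- cumsum(exp(logpmf))
      y[x] <- which(cdf >= quantile)[1]  # q = index - 1, y = q + 1
    }
  }
  out <- tibble::tibble(x = seq_len(k), y = y)
  class(out) <- c("threshold_table", class(out))
  out
}

#' Write a threshold table as TSV
#'
#' @param thresholds A [trust_thresholds()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thresholds_tsv <- function(thresholds, path) {
  readr::write_tsv(thresholds[c("x", "y")], path)
  invisible(path)
}

#' Poisson rates of the sequencing model
#'
#' Diagnostics linking the simulator to the sequencing model: a correct
#' k-mer's multiplicity in the full dataset is approximately
#' `Pois(K * (1 - epsilon) / G)`, and in the subsample `Pois(alpha * K *
#' (1 - epsilon) / G)`, where `K` is the total number of k-mers sequenced,
#' `epsilon` the fraction of k-mers altered by errors and `G` the number of
#' genomic k-mers. Used to validate simulated multiplicity distributions,
#' not in the correction path itself.
#'
#' @inheritParams f_alpha
#' @param K Total k-mers sequenced.
#' @param epsilon Fraction of k-mers containing at least one error.
#' @param G Genomic k-mer count.
#' @return One-row tibble: `K`, `epsilon`, `lambda_correct` (subsample
#'   rate), `lambda_correct_full` (full-dataset rate), with
#'   `lambda_correct = alpha * lambda_correct_full`.
#' @export
poisson_diagnostics <- function(alpha, K, epsilon, G) {
  stopifnot(K >= 0, epsilon >= 0, epsilon <= 1, G > 0)
  full <- K * (1 - epsilon) / G
  tibble::tibble(
    K = K, epsilon = epsilon,
    lambda_correct = alpha * full,
    lambda_correct_full = full
  )
}

#' @method autoplot threshold_table
#' @export
autoplot.threshold_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "overlapping k-mers (x)",
      y = expression(y[x]),
      title = "Binomial trust thresholds"
    ) +
    ggplot2::theme_minimal()
}
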