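#' Exact two-sided binomial test (doubled smaller tail)
#'
#' The exact two-sided p-value for observing \code{k} successes in \code{n}
#' Bernoulli trials under success probability \code{p0}, by the
#' doubled-smaller-tail rule:
#' \deqn{p = \min(1,\; 2 \min(P(X \le k),\, P(X \ge k))).}
#' Tail probabilities come from exact pmf summation. Used to test siring
#' asymmetry when every one of \code{n} F1 hybrids carries the same
#' species' mtDNA: k = n = 6 gives p = 2 * 0.5^6 = 0.03125.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param p0 null success probability in (0, 1); default 0.5.
#' @return the p-value.
#' @examples
#' exactBinomialTwoSided(6, 6)  # 0.03125
#' @export
exactBinomialTwoSided <- function(k, n, p0 = 0.5) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      k != round(k) || n != round(n) || n < 1 || k < 0 || k > n)
    stop("require integers 0 <= k <= n with n >= 1")
  if (!is.numeric(p0) || p0 <= 0 || p0 >= 1)
    stop("p0 must lie in (0, 1)")
  pmf <- stats::dbinom(0:n, n, p0)
  lower <- sum(pmf[seq_len(k + 1L)])
  upper <- sum(pmf[(k + 1L):(n + 1L)])
  min(1, 2 * min(lower, upper))
}

#' AIC ranking and Akaike weights for a set of model fits
#'
#' For each fit, \eqn{AIC = 2k - 2\log L}; \eqn{\Delta_i = AIC_i -
#' \min_j AIC_j}; Akaike weights \eqn{w_i = e^{-\Delta_i/2} / \sum_j
#' e^{-\Delta_j/2}}, renormalized over exactly the supplied model set.
#' Rows are stably sorted by ascending AIC, ties broken by label.
#'
#' @param fits a data.frame with columns \code{label} (character),
#'   \code{logL} (numeric) and \code{k} (positive integer count of
#'   estimated parameters); an optional \code{fixed_params} column is
#'   carried through.
#' @return a data.frame sorted by AIC with added columns \code{aic},
#'   \code{delta_aic} and \code{weight} (weights sum to 1).
#' @examples
#' aicRank(data.frame(label = c("m1", "m2"), logL = c(2.48, 3.39),
#'   k = c(3, 4)))
#' @export
aicRank <- function(fits) {
  stopifnot(is.data.frame(fits),
    all(c("label", "logL", "k") %in% names(fits)), nrow(fits) >= 1L)
  if (any(fits$k < 1))
    stop("parameter counts k must be >= 1")
  out <- fits
  out$aic <- 2 * out$k - 2 * out$logL
  out$delta_aic <- out$aic - min(out$aic)
  ew <- exp(-out$delta_aic / 2)
  out$weight <- ew / sum(ew)
  out <- out[order(out$aic, out$label), ]
  rownames(out) <- NULL
  out
}

#' Cumulative Akaike weight of the top-ranked models
#'
#' @param table output of [aicRank()].
#' @param topN how many of the best-supported models to sum over
#'   (1 <= topN <= number of models).
#' @return the summed weight of the \code{topN} largest weights.
#' @examples
#' tab <- aicRank(data.frame(label = c("m1", "m2", "m3"),
#'   logL = c(0, 0, 0), k = c(1, 1, 1)))
#' cumulativeWeight(tab, 2)  # 2/3
#' @export
cumulativeWeight <- function(table, topN) {
  stopifnot(is.data.frame(table), "weight" %in% names(table))
  if (length(topN) != 1L || topN != round(topN) ||
      topN < 1 || topN > nrow(table))
    stop("topN must be an integer in [1, number of models]")
  sum(sort(table$weight, decreasing = TRUE)[seq_len(topN)])
}

#' Shortest-interval (HPD-style) summary of a sample
#'
#' The shortest contiguous interval containing \code{ceiling(mass * n)} of
#' the sorted sample points; width ties are broken toward the smallest
#' lower endpoint.
#'
#' @param samples numeric vector with at least 20 values.
#' @param mass fraction of the sample to cover, in (0, 1); default 0.95.
#' @return numeric vector \code{c(low, high)}.
#' @examples
#' hpdInterval(1:100)  # c(1, 95)
#' @export
hpdInterval <- function(samples, mass = 0.95) {
  if (length(samples) < 20L)
    stop("at least 20 samples are required")
  if (!is.numeric(mass) || mass <= 0 || mass >= 1)
    stop("mass must lie in (0, 1)")
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- which.min(widths)  # which.min returns the first (smallest) minimizer
  c(x[i], x[i + m - 1L])
}

#' Rescale mutation-scaled IM parameters into demographic units
#'
#' Converts a mutation-scaled population size \eqn{\theta = 4 N u g} and a
#' mutation-scaled migration rate \eqn{m = M/u} into the effective
#' population size \eqn{N = \theta / (4 u_g g)} and the population
#' migration rate \eqn{2Nm = \theta m / 2}, where \eqn{u_g} is the
#' per-locus per-generation mutation rate (per-year rate times generation
#' time) and \eqn{g} the locus inheritance scalar (1.0 autosomal, 0.25
#' mtDNA).
#'
#' @param theta mutation-scaled size (>= 0).
#' @param m mutation-scaled migration rate (>= 0).
#' @param mutationRatePerYear per-locus per-year substitution rate (> 0).
#' @param generationTimeYears generation time in years (> 0).
#' @param inheritanceScalar locus inheritance scalar (> 0), default 1.0.
#' @return list with \code{N} (effective size, individuals) and
#'   \code{twoNm} (migrant gene copies per generation).
#' @examples
#' demographicRescale(0.24, 0, 3e-5, 25)$N  # 80
#' @export
demographicRescale <- function(theta, m, mutationRatePerYear,
                               generationTimeYears, inheritanceScalar = 1.0) {
  if (theta < 0 || m < 0) stop("theta and m must be non-negative")
  if (mutationRatePerYear <= 0 || generationTimeYears <= 0 ||
      inheritanceScalar <= 0)
    stop("rescaling constants must be strictly positive")
  uG <- mutationRatePerYear * generationTimeYears
  list(N = theta / (4 * uG * inheritanceScalar), twoNm = theta * m / 2)
}
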