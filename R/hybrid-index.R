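.freqOrZero <- function(f, allele) if (allele %in% names(f)) f[[allele]] else 0

#' Diagnostic-allele hybrid index
#'
#' The mean, over all allele copies at the scored markers, of the
#' equal-prior posterior probability that the copy originated in species A:
#' \deqn{P(A \mid x) = f_A(x) / (f_A(x) + f_B(x)).}
#' With fixed differences each heterozygous marker contributes exactly 0.5;
#' a marker whose species-B allele also segregates in species A pulls a
#' heterozygote slightly above 0.5 (the reason fully heterozygous F1s score
#' 0.51 rather than 0.50 on the canonical five-marker panel).
#'
#' @param genotype a [MultilocusGenotype-class]; every scored marker must be
#'   genotyped (no missing alleles).
#' @param panel a [MarkerPanel-class].
#' @param diagnosticOnly if \code{TRUE} (default) only markers flagged
#'   diagnostic in the panel are scored.
#' @param orientation \code{"A1"} (default): pure species A scores 1;
#'   \code{"B1"}: pure species B scores 1.
#' @return the index, a number in [0, 1].
#' @examples
#' fx <- buildAlbatrossFixture()
#' diagnosticIndex(fx$genotype, fx$panel)  # 0.5091
#' @export
diagnosticIndex <- function(genotype, panel, diagnosticOnly = TRUE,
                            orientation = c("A1", "B1")) {
  orientation <- match.arg(orientation)
  stopifnot(is(genotype, "MultilocusGenotype"), is(panel, "MarkerPanel"))
  al <- genotypeAlleles(genotype)
  use <- colnames(al)
  if (diagnosticOnly) use <- use[isDiagnostic(panel)[use]]
  if (length(use) == 0L) stop("no markers to score")
  post <- numeric(0)
  for (mk in use) {
    fA <- alleleFreq(panel, mk, "A")
    fB <- alleleFreq(panel, mk, "B")
    for (a in al[, mk]) {
      if (is.na(a)) stop("marker '", mk, "' is not genotyped")
      pA <- .freqOrZero(fA, a)
      pB <- .freqOrZero(fB, a)
      if (pA + pB == 0)
        stop("allele '", a, "' at marker '", mk,
          "' is absent from both parental panels")
      post <- c(post, pA / (pA + pB))
    }
  }
  idx <- mean(post)
  if (orientation == "B1") 1 - idx else idx
}

# log-likelihood of ancestry proportion h (species A fraction) for one
# multilocus genotype under independent markers and allele-pooling:
# q(x) = h * fA(x) + (1 - h) * fB(x)
.hybridLogLik <- function(h, al, panel) {
  ll <- 0
  for (mk in colnames(al)) {
    fA <- alleleFreq(panel, mk, "A")
    fB <- alleleFreq(panel, mk, "B")
    a <- al[1L, mk]; b <- al[2L, mk]
    if (is.na(a) || is.na(b)) next
    qa <- h * .freqOrZero(fA, a) + (1 - h) * .freqOrZero(fB, a)
    qb <- h * .freqOrZero(fA, b) + (1 - h) * .freqOrZero(fB, b)
    p <- qa * qb * (if (a != b) 2 else 1)
    if (p <= 0) return(-Inf)
    ll <- ll + log(p)
  }
  ll
}

#' Maximum-likelihood hybrid index with profile-likelihood interval
#'
#' Maximizes \eqn{L(h) = \prod_m P(\text{genotype}_m \mid h)} over
#' \eqn{h \in [0,1]}, where the probability of an unordered allele pair
#' \eqn{(a, b)} is \eqn{q(a) q(b)} (times 2 when heterozygous) and
#' \eqn{q(x) = h f_A(x) + (1-h) f_B(x)}. All markers with frequencies in
#' both panels are used, diagnostic or not. The 95\% confidence interval is
#' the profile-likelihood set \eqn{\{h : \log L(h) \ge \log L(\hat h) -
#' 1.92\}} (the chi-squared(1) half-width) intersected with [0, 1].
#'
#' Optimization is by golden-section/parabolic search ([stats::optimize()])
#' at tolerance 1e-6, with the boundary values compared explicitly; a tie
#' with a boundary resolves to the boundary.
#'
#' @inheritParams diagnosticIndex
#' @return a list with \code{h} (the MLE), \code{ciLow}, \code{ciHigh} and
#'   \code{logLik}.
#' @examples
#' fx <- buildAlbatrossFixture()
#' mlHybridIndex(fx$genotype, fx$panel)$h
#' @export
mlHybridIndex <- function(genotype, panel, orientation = c("A1", "B1")) {
  orientation <- match.arg(orientation)
  stopifnot(is(genotype, "MultilocusGenotype"), is(panel, "MarkerPanel"))
  al <- genotypeAlleles(genotype)
  for (mk in colnames(al)) {
    fA <- alleleFreq(panel, mk, "A")
    fB <- alleleFreq(panel, mk, "B")
    for (a in al[, mk]) {
      if (!is.na(a) && .freqOrZero(fA, a) + .freqOrZero(fB, a) == 0)
        stop("allele '", a, "' at marker '", mk,
          "' has no panel frequency in either species")
    }
  }
  f <- function(h) .hybridLogLik(h, al, panel)
  opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- c(0, opt$maximum, 1)
  vals <- vapply(cand, f, numeric(1))
  # ties resolve toward the boundary (boundaries listed first/last win ties
  # against the interior point up to optimizer tolerance)
  best <- which(vals >= max(vals) - 1e-10)
  pick <- if (1L %in% best) 1L else if (3L %in% best) 3L else best[1L]
  hHat <- cand[pick]
  llMax <- vals[pick]
  thr <- llMax - 1.92
  # clamp -Inf so uniroot sees finite endpoint values at impossible h
  g <- function(h) max(f(h), llMax - 1e6) - thr
  ciLow <- if (g(0) >= 0) 0 else
    stats::uniroot(g, c(0, hHat), tol = 1e-8)$root
  ciHigh <- if (g(1) >= 0) 1 else
    stats::uniroot(g, c(hHat, 1), tol = 1e-8)$root
  if (orientation == "B1") {
    res <- list(h = 1 - hHat, ciLow = 1 - ciHigh, ciHigh = 1 - ciLow,
      logLik = llMax)
  } else {
    res <- list(h = hHat, ciLow = ciLow, ciHigh = ciHigh, logLik = llMax)
  }
  res
}
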