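.MISSING <- c("N", "-", ".", "?")

#' Per-site allele frequencies of a haplotype alignment
#'
#' Frequencies at each site are computed over non-missing calls only:
#' haplotypes carrying \code{N} or a gap at a site are dropped from that
#' site's denominator.
#'
#' @param alignment a [LocusAlignment-class].
#' @return a list with one element per site (0-based position names); each
#'   element is a named numeric vector of allele frequencies summing to 1,
#'   or an empty vector if every call at the site is missing.
#' @examples
#' aln <- LocusAlignment("x", c("AAG", "AAG", "ATG"))
#' alleleFrequencies(aln)
#' @export
alleleFrequencies <- function(alignment) {
  stopifnot(is(alignment, "LocusAlignment"))
  if (nHaplotypes(alignment) < 1L) stop("empty alignment")
  m <- haplotypeMatrix(alignment)
  out <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[!col %in% .MISSING]
    if (length(col) == 0L) return(numeric(0))
    tab <- table(col)
    f <- as.numeric(tab) / length(col)
    names(f) <- names(tab)
    f
  })
  names(out) <- as.character(seq_len(ncol(m)) - 1L)
  out
}

# counts of segregating sites and per-site heterozygosity-based pi,
# missing-aware; internal shared machinery
.siteSummaries <- function(alignment) {
  freqs <- alleleFrequencies(alignment)
  S <- 0L
  pi <- 0
  for (f in freqs) {
    if (length(f) < 2L) next
    S <- S + 1L
  }
  m <- haplotypeMatrix(alignment)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[!col %in% .MISSING]
    nS <- length(col)
    if (nS < 2L) next
    cnt <- table(col)
    if (length(cnt) < 2L) next
    same <- sum(choose(as.numeric(cnt), 2))
    pi <- pi + (1 - same / choose(nS, 2))
  }
  list(S = S, pi = pi)
}

#' Tajima's D and summary statistics for one locus panel
#'
#' Computes the number of segregating sites S, mean pairwise differences
#' (pi), the Watterson estimator, and Tajima's (1989) D
#' \deqn{D = (\pi - \theta_W) / \sqrt{e_1 S + e_2 S (S-1)}}
#' with the standard a1, a2, b1, b2, c1, c2, e1, e2 coefficients. D is
#' undefined (reported as \code{NA}) exactly when S = 0, i.e. when the
#' locus shows no variation in the panel. Sites with missing calls
#' contribute to pi with their per-site sample size.
#'
#' @param alignment a [LocusAlignment-class] with at least 3 haplotypes.
#' @return a list with elements \code{n}, \code{S}, \code{pi},
#'   \code{thetaW}, \code{tajimaD} (numeric, \code{NA} iff \code{S == 0}).
#' @examples
#' aln <- LocusAlignment("x", c("AAA", "AAT", "ATT", "TTT"))
#' tajimasD(aln)$tajimaD
#' @export
tajimasD <- function(alignment) {
  stopifnot(is(alignment, "LocusAlignment"))
  n <- nHaplotypes(alignment)
  if (n < 3L) stop("Tajima's D requires at least 3 haplotypes, got ", n)
  ss <- .siteSummaries(alignment)
  S <- ss$S
  a1 <- sum(1 / seq_len(n - 1L))
  thetaW <- S / a1
  if (S == 0L) {
    return(list(n = n, S = 0L, pi = ss$pi, thetaW = 0, tajimaD = NA_real_))
  }
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (ss$pi - thetaW) / sqrt(e1 * S + e2 * S * (S - 1))
  list(n = n, S = S, pi = ss$pi, thetaW = thetaW, tajimaD = D)
}

# biallelic 0/1 site matrix from an alignment: multi-allelic and
# invariant sites are dropped; missing calls become NA
.binarySiteMatrix <- function(alignment) {
  m <- haplotypeMatrix(alignment)
  cols <- list()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col[col %in% .MISSING] <- NA
    al <- sort(unique(col[!is.na(col)]))
    if (length(al) != 2L) next
    cols[[length(cols) + 1L]] <- as.integer(col == al[2L])
  }
  if (length(cols) == 0L)
    return(matrix(integer(0), nrow = nrow(m), ncol = 0L))
  do.call(cbind, cols)
}

#' Hudson-Kaplan minimum number of recombination events (four-gamete test)
#'
#' Scans every pair of biallelic sites for the presence of all four gametes
#' (00, 01, 10, 11), which under the infinite-sites model implies at least
#' one recombination event between them, and returns Rm: the maximum number
#' of pairwise-disjoint incompatible site intervals (Hudson & Kaplan 1985).
#' \code{Rm == 0} means no evidence of recombination.
#'
#' @param haplotypes either a [LocusAlignment-class] (biallelic segregating
#'   sites are extracted; multi-allelic sites are excluded) or a numeric/
#'   integer matrix of 0/1 haplotype rows. Haplotype vectors must have equal
#'   length. Missing calls (\code{NA}) are ignored pairwise.
#' @return non-negative integer Rm.
#' @examples
#' fourGameteRm(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
#' @export
fourGameteRm <- function(haplotypes) {
  if (is(haplotypes, "LocusAlignment")) {
    mat <- .binarySiteMatrix(haplotypes)
  } else if (is.list(haplotypes)) {
    len <- lengths(haplotypes)
    if (length(unique(len)) > 1L)
      stop("ragged haplotype input: all haplotypes must have equal length")
    mat <- do.call(rbind, haplotypes)
  } else {
    mat <- as.matrix(haplotypes)
  }
  if (ncol(mat) < 2L) return(0L)
  if (!all(mat %in% c(0L, 1L, NA)))
    stop("haplotype matrix must be binary (0/1)")
  nsite <- ncol(mat)
  lo <- integer(0); hi <- integer(0)
  for (i in seq_len(nsite - 1L)) {
    for (j in (i + 1L):nsite) {
      ok <- !is.na(mat[, i]) & !is.na(mat[, j])
      g <- unique(mat[ok, i] * 2L + mat[ok, j])
      if (length(g) == 4L) {
        lo <- c(lo, i); hi <- c(hi, j)
      }
    }
  }
  .disjointIntervalCount(lo, hi)
}

# greedy maximum set of pairwise-disjoint open intervals (lo, hi):
# sort by right endpoint; (a,b) and (b,c) are disjoint (recombination
# breakpoints fall strictly between sites)
.disjointIntervalCount <- function(lo, hi) {
  if (length(lo) == 0L) return(0L)
  o <- order(hi, lo)
  lo <- lo[o]; hi <- hi[o]
  count <- 0L
  lastHi <- -Inf
  for (k in seq_along(lo)) {
    if (lo[k] >= lastHi) {
      count <- count + 1L
      lastHi <- hi[k]
    }
  }
  count
}

#' Per-locus summary-statistics table for a set of panels
#'
#' Convenience wrapper producing one row per alignment with n, S, pi,
#' Watterson's theta, Tajima's D (\code{NA} when the locus is invariant)
#' and the four-gamete Rm.
#'
#' @param alignments list of [LocusAlignment-class] objects.
#' @return a data.frame with columns locus, species, n, S, pi, theta_w,
#'   tajima_d, rm.
#' @export
locusStatsTable <- function(alignments) {
  rows <- lapply(alignments, function(a) {
    st <- tajimasD(a)
    data.frame(locus = locusId(a), species = speciesLabel(a),
      n = st$n, S = st$S, pi = st$pi, theta_w = st$thetaW,
      tajima_d = st$tajimaD, rm = fourGameteRm(a),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
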