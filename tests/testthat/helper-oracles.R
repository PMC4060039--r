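# Independent brute-force oracles, deliberately coded by a different route
# than the package implementations they check.

# Tajima's D: explicit pairwise-difference double loop and term-by-term
# coefficient evaluation
oracleTajimaD <- function(haps) {
  m <- do.call(rbind, strsplit(haps, ""))
  n <- nrow(m)
  miss <- c("N", "-", ".", "?")
  S <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j][!m[, j] %in% miss]
    if (length(unique(col)) > 1L) S <- S + 1L
  }
  pi <- 0
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    ok <- which(!col %in% miss)
    if (length(ok) < 2L) next
    d <- 0L; np <- 0L
    for (a in seq_along(ok)[-length(ok)]) {
      for (b in (a + 1L):length(ok)) {
        d <- d + (col[ok[a]] != col[ok[b]])
        np <- np + 1L
      }
    }
    # rescale each site to the full n-choose-2 denominator used when data
    # are complete; with complete data np == choose(n, 2)
    pi <- pi + d / np
  }
  a1 <- sum(1 / seq_len(n - 1))
  if (S == 0L) return(list(pi = pi, thetaW = 0, D = NA_real_))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(pi = pi, thetaW = S / a1,
    D = (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1)))
}

# four-gamete Rm: enumerate every subset of incompatible intervals and
# take the largest pairwise-disjoint one (open-interval disjointness)
oracleRm <- function(mat) {
  nsite <- ncol(mat)
  iv <- list()
  if (nsite >= 2L) {
    for (i in seq_len(nsite - 1L)) {
      for (j in (i + 1L):nsite) {
        g <- unique(paste(mat[, i], mat[, j]))
        if (length(g) == 4L) iv[[length(iv) + 1L]] <- c(i, j)
      }
    }
  }
  k <- length(iv)
  if (k == 0L) return(0L)
  best <- 0L
  for (mask in seq_len(2^k) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    if (length(sel) > 1L) {
      for (a in seq_along(sel)[-length(sel)]) {
        for (b in (a + 1L):length(sel)) {
          x <- iv[[sel[a]]]; y <- iv[[sel[b]]]
          if (max(x[1], y[1]) < min(x[2], y[2])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) best <- length(sel)
  }
  best
}

# dense grid-search maximizer of the hybrid-index likelihood
oracleGridML <- function(genotype, panel, step = 1e-4) {
  al <- genotypeAlleles(genotype)
  hs <- seq(0, 1, by = step)
  ll <- vapply(hs, function(h) {
    tot <- 0
    for (mk in colnames(al)) {
      fA <- alleleFreq(panel, mk, "A")
      fB <- alleleFreq(panel, mk, "B")
      q <- function(x) {
        h * (if (x %in% names(fA)) fA[[x]] else 0) +
          (1 - h) * (if (x %in% names(fB)) fB[[x]] else 0)
      }
      a <- al[1, mk]; b <- al[2, mk]
      p <- q(a) * q(b) * (if (a != b) 2 else 1)
      tot <- tot + if (p > 0) log(p) else -Inf
    }
    tot
  }, numeric(1))
  hs[which.max(ll)]
}

# exhaustive shortest-window scan for the HPD oracle
oracleHpd <- function(x, mass) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- NULL
  for (i in seq_len(n - m + 1L)) {
    w <- x[i + m - 1L] - x[i]
    if (is.null(best) || w < best$w) best <- list(w = w, lo = x[i],
      hi = x[i + m - 1L])
  }
  c(best$lo, best$hi)
}

# random small alignment generator for property tests
randomAlignment <- function(n, L, alphabet = c("A", "C", "G", "T"),
                            pMiss = 0) {
  m <- matrix(sample(alphabet, n * L, replace = TRUE), n, L)
  if (pMiss > 0) m[runif(n * L) < pMiss] <- "N"
  LocusAlignment("rand", apply(m, 1, paste, collapse = ""))
}

# two-marker toy panel with a shared polymorphism, for enumeration tests
toyPanel <- function() {
  MarkerPanel(
    freqA = list(m1 = c(A = 1), m2 = c(A = 0.7, G = 0.3)),
    freqB = list(m1 = c(G = 1), m2 = c(G = 0.8, `T` = 0.2)))
}

# all unordered genotype pairs over the alleles seen at a marker
allPairs <- function(alleles) {
  out <- list()
  for (i in seq_along(alleles)) {
    for (j in i:length(alleles)) {
      out[[length(out) + 1L]] <- c(alleles[i], alleles[j])
    }
  }
  out
}
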