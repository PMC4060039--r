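#' Specify a two-population isolation-with-migration model
#'
#' Parameters follow the mutation-scaled IM convention: population sizes
#' \eqn{\theta = 4 N u g} per locus, migration rates \eqn{m = M/u} per
#' lineage, and times in mutation units (expected mutations per lineage).
#' Looking backwards in time, lineages coalesce within deme \eqn{i} at rate
#' \eqn{k_i (k_i - 1) / (\theta_i g)} for \eqn{k_i} lineages (\eqn{g} the
#' locus inheritance scalar), migrate between demes at the per-lineage rate
#' \code{m0to1}/\code{m1to0} before \code{splitTime}, and merge into a
#' single ancestral deme of size \code{thetaAncestral} at \code{splitTime}.
#' Mutations are dropped on the genealogy under the infinite-sites model at
#' rate 1 per lineage per unit time, so a single deme of size \eqn{\theta}
#' has expected pairwise diversity \eqn{\theta g} and expected segregating
#' sites \eqn{\theta g \sum_{i=1}^{n-1} 1/i}.
#'
#' @param theta0,theta1,thetaAncestral mutation-scaled sizes (>= 0) of
#'   demes 0, 1 and the ancestral deme.
#' @param splitTime divergence time in mutation units (>= 0); 0 puts all
#'   samples directly in the ancestral deme (single-population semantics).
#' @param m0to1,m1to0 backward per-lineage migration rates (>= 0):
#'   \code{m0to1} is the rate at which a lineage currently in deme 0 moves
#'   to deme 1, looking back in time.
#' @param loci data.frame with columns \code{locus_id}, \code{length_bp},
#'   \code{scalar} (inheritance scalar, e.g. 1.0 nuclear / 0.25 mtDNA) and
#'   \code{n0}, \code{n1} (haplotypes sampled per deme).
#' @return a validated list of class \code{"IMModelSpec"}.
#' @examples
#' spec <- imModelSpec(5, 5, 5, splitTime = 2, m0to1 = 0.1, m1to0 = 0,
#'   loci = data.frame(locus_id = "L1", length_bp = 500, scalar = 1,
#'     n0 = 5, n1 = 5))
#' @export
imModelSpec <- function(theta0, theta1, thetaAncestral, splitTime,
                        m0to1 = 0, m1to0 = 0, loci) {
  vals <- c(theta0, theta1, thetaAncestral, splitTime, m0to1, m1to0)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all rates, sizes and times must be finite and >= 0")
  stopifnot(is.data.frame(loci),
    all(c("locus_id", "length_bp", "scalar", "n0", "n1") %in% names(loci)))
  if (any(loci$scalar <= 0)) stop("inheritance scalars must be positive")
  if (any(loci$n0 + loci$n1 < 1)) stop("each locus needs at least one sample")
  structure(list(theta0 = theta0, theta1 = theta1,
    thetaAncestral = thetaAncestral, splitTime = splitTime,
    m0to1 = m0to1, m1to0 = m1to0, loci = loci), class = "IMModelSpec")
}

# sample() that never interprets a length-1 x as 1:x
.safeSample <- function(x, size) x[sample.int(length(x), size)]

# structured-coalescent genealogy for one locus; returns branches as
# (descendant sample set, length) pairs. Time runs backwards from 0.
.simGenealogy <- function(nSamples, deme, theta0, theta1, thetaAnc,
                          splitTime, m01, m10, scalar) {
  n <- nSamples
  desc <- lapply(seq_len(n), identity)      # per active lineage
  birth <- numeric(n)                        # time each lineage started
  branches <- list()
  t <- 0
  if (splitTime <= 0) deme <- rep(2L, n)     # ancestral deme directly
  repeat {
    k <- length(desc)
    if (k == 1L) break
    k0 <- sum(deme == 0L); k1 <- sum(deme == 1L); k2 <- sum(deme == 2L)
    rates <- c(
      coal0 = if (theta0 > 0) k0 * (k0 - 1) / (theta0 * scalar) else
        if (k0 > 1) Inf else 0,
      coal1 = if (theta1 > 0) k1 * (k1 - 1) / (theta1 * scalar) else
        if (k1 > 1) Inf else 0,
      coal2 = if (thetaAnc > 0) k2 * (k2 - 1) / (thetaAnc * scalar) else
        if (k2 > 1) Inf else 0,
      mig01 = k0 * m01,
      mig10 = k1 * m10)
    total <- sum(rates)
    if (any(is.infinite(rates))) {
      ev <- names(rates)[which(is.infinite(rates))[1L]]
      dt <- 0
    } else if (total == 0) {
      # nothing can happen before the split merges the demes
      if (t < splitTime) {
        i <- deme < 2L
        deme[i] <- 2L
        t <- splitTime
        next
      }
      stop("coalescence starved: ancestral theta is 0 with one lineage left")
    } else {
      dt <- stats::rexp(1L, total)
      if (t < splitTime && t + dt >= splitTime) {
        deme[deme < 2L] <- 2L
        t <- splitTime
        next
      }
      ev <- sample(names(rates), 1L, prob = rates / total)
    }
    t <- t + dt
    if (startsWith(ev, "coal")) {
      d <- as.integer(substring(ev, 5L))
      pair <- .safeSample(which(deme == d), 2L)
      for (i in pair)
        branches[[length(branches) + 1L]] <-
          list(desc = desc[[i]], len = t - birth[i])
      desc[[pair[1L]]] <- c(desc[[pair[1L]]], desc[[pair[2L]]])
      birth[pair[1L]] <- t
      desc[[pair[2L]]] <- NULL
      deme <- deme[-pair[2L]]
      birth <- birth[-pair[2L]]
    } else if (ev == "mig01") {
      deme[.safeSample(which(deme == 0L), 1L)] <- 1L
    } else {
      deme[.safeSample(which(deme == 1L), 1L)] <- 0L
    }
  }
  branches
}

#' Simulate sequence panels under a two-population IM model
#'
#' Generates, per locus, a structured-coalescent genealogy (see
#' [imModelSpec()] for rates and time units) and drops infinite-sites
#' mutations on it: each branch receives a Poisson(branch length) number of
#' mutations, each creating a new biallelic site whose derived allele
#' (\code{T}) is carried by the branch's descendant samples and whose
#' ancestral allele is \code{A}. Mutations are placed at distinct random
#' positions along the locus; remaining positions are monomorphic \code{A}.
#' There is no intra-locus recombination, so every locus has a single
#' genealogy and the four-gamete test finds \code{Rm = 0}. Deterministic
#' under a fixed seed.
#'
#' @param spec an \code{IMModelSpec} from [imModelSpec()].
#' @param seed integer RNG seed.
#' @param pad if \code{TRUE} (default) alignments have width
#'   \code{length_bp} with monomorphic sites padded in; if \code{FALSE}
#'   they contain only the segregating sites (faster for statistics that
#'   ignore invariant sites).
#' @return a named list (one element per locus) of lists with components
#'   \code{pop0} and \code{pop1}, each a [LocusAlignment-class] holding
#'   that deme's sampled haplotypes (an element may have zero samples in
#'   one deme only if that deme's \code{n} is 0, in which case it is
#'   \code{NULL}).
#' @examples
#' spec <- imModelSpec(5, 5, 5, splitTime = 0,
#'   loci = data.frame(locus_id = "L1", length_bp = 100, scalar = 1,
#'     n0 = 10, n1 = 0))
#' sim <- coalescentIMSimulate(spec, seed = 1)
#' tajimasD(sim$L1$pop0)$S
#' @export
coalescentIMSimulate <- function(spec, seed, pad = TRUE) {
  stopifnot(inherits(spec, "IMModelSpec"))
  set.seed(seed)
  out <- list()
  for (r in seq_len(nrow(spec$loci))) {
    li <- spec$loci[r, ]
    n0 <- li$n0; n1 <- li$n1
    nTot <- n0 + n1
    if (nTot < 1L) stop("locus '", li$locus_id, "' has no samples")
    if (nTot == 1L) {
      seqs <- paste(rep("A", li$length_bp), collapse = "")
      mat <- matrix(seqs, 1L, 1L)
      haps <- seqs
    } else {
      deme <- rep(c(0L, 1L), c(n0, n1))
      branches <- .simGenealogy(nTot, deme, spec$theta0, spec$theta1,
        spec$thetaAncestral, spec$splitTime, spec$m0to1, spec$m1to0,
        li$scalar)
      # one logical column per mutation; grouped per branch
      cols <- list()
      for (br in branches) {
        nMut <- stats::rpois(1L, br$len)
        if (nMut == 0L) next
        col <- rep(FALSE, nTot)
        col[br$desc] <- TRUE
        cols <- c(cols, rep(list(col), nMut))
      }
      S <- length(cols)
      siteMat <- if (S > 0L) do.call(cbind, cols) else
        matrix(logical(0), nTot, 0L)
      if (pad && li$length_bp >= S) {
        full <- matrix("A", nTot, li$length_bp)
        if (S > 0L) {
          pos <- sort(sample.int(li$length_bp, S))
          sub <- full[, pos, drop = FALSE]
          sub[siteMat] <- "T"
          full[, pos] <- sub
        }
        charMat <- full
      } else {
        charMat <- matrix("A", nTot, S)
        charMat[siteMat] <- "T"
      }
      haps <- apply(charMat, 1L, paste, collapse = "")
      if (ncol(charMat) == 0L) haps <- rep("", nTot)
    }
    mk <- function(idx, label) {
      if (length(idx) == 0L) return(NULL)
      h <- haps[idx]
      if (all(nchar(h) == 0L)) h <- rep("A", length(h))  # degenerate width-0
      LocusAlignment(li$locus_id, h, label)
    }
    out[[li$locus_id]] <- list(pop0 = mk(seq_len(n0), "pop0"),
      pop1 = mk(n0 + seq_len(n1), "pop1"))
  }
  out
}
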