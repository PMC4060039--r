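# vectorized draw of n alleles from a named frequency vector
.sampleAlleles <- function(f, n) {
  sample(names(f), n, replace = TRUE, prob = f)
}

# vectorized gamete draws for n offspring from a parent of the given type
# at one marker (see .gameteDist for the marginal argument)
.sampleGametes <- function(type, marker, panel, n) {
  .sampleAlleles(.gameteDist(type, marker, panel), n)
}

#' Simulate a pure parental panel of multilocus genotypes
#'
#' Draws each individual's two allele copies per marker independently from
#' the species' panel frequencies (Hardy-Weinberg) and assigns the species'
#' own mtDNA lineage. Deterministic under a fixed seed.
#'
#' @param panel a [MarkerPanel-class].
#' @param species \code{"A"} or \code{"B"}.
#' @param n number of individuals (>= 1).
#' @param seed integer RNG seed.
#' @return a [GenotypeSet-class] of \code{n} individuals.
#' @examples
#' fx <- buildAlbatrossFixture()
#' simulateParentalPanel(fx$panel, "A", 3, seed = 1)
#' @export
simulateParentalPanel <- function(panel, species, n, seed) {
  if (!species %in% c("A", "B")) stop("unknown species label: ", species)
  stopifnot(is(panel, "MarkerPanel"), n >= 1)
  set.seed(seed)
  mks <- markerIds(panel)
  a1 <- a2 <- matrix(NA_character_, n, length(mks),
    dimnames = list(NULL, mks))
  for (mk in mks) {
    f <- alleleFreq(panel, mk, species)
    a1[, mk] <- .sampleAlleles(f, n)
    a2[, mk] <- .sampleAlleles(f, n)
  }
  GenotypeSet(sprintf("%s_%06d", species, seq_len(n)), a1, a2,
    mtdna = species, sex = "unknown")
}

#' Simulate offspring of a pedigree cross
#'
#' For each offspring, parents are drawn per the cross class (pure parents
#' from their species' panel frequencies; F1 parents generated as
#' unconditioned F1s, one gamete from each species), each parent transmits
#' one allele per marker with fair Mendelian probability 1/2, markers are
#' unlinked, and mtDNA propagates strictly maternally through the pedigree.
#' Monte-Carlo genotype-match frequencies from this simulator converge to
#' the exact values of [genotypeProbGivenCross()], which shares none of its
#' code path. Deterministic under a fixed seed.
#'
#' @param panel a [MarkerPanel-class].
#' @param cross one of [crossClasses()].
#' @param n number of offspring (>= 1).
#' @param seed integer RNG seed.
#' @param f1Maternal maternal species of any F1 parent (\code{"A"} default).
#' @return a [GenotypeSet-class] of \code{n} offspring.
#' @examples
#' fx <- buildAlbatrossFixture()
#' off <- simulateCrossOffspring(fx$panel, "F1_motherA", 5, seed = 7)
#' mtdnaLineages(off)
#' @export
simulateCrossOffspring <- function(panel, cross, n, seed, f1Maternal = "A") {
  stopifnot(is(panel, "MarkerPanel"), n >= 1)
  ped <- .crossPedigree(cross, f1Maternal)
  set.seed(seed)
  mks <- markerIds(panel)
  a1 <- a2 <- matrix(NA_character_, n, length(mks),
    dimnames = list(NULL, mks))
  for (mk in mks) {
    a1[, mk] <- .sampleGametes(ped$dam, mk, panel, n)
    a2[, mk] <- .sampleGametes(ped$sire, mk, panel, n)
  }
  GenotypeSet(sprintf("%s_%06d", cross, seq_len(n)), a1, a2,
    mtdna = ped$mt, sex = sample(c("female", "male"), n, replace = TRUE))
}

#' Fraction of a simulated cohort matching a target genotype
#'
#' Compares unordered allele pairs at every marker and, unless the target's
#' mtDNA is \code{"unknown"}, the mtDNA lineage.
#'
#' @param cohort a [GenotypeSet-class].
#' @param genotype the target [MultilocusGenotype-class].
#' @return the matching fraction in [0, 1].
#' @export
genotypeMatchFraction <- function(cohort, genotype) {
  al <- genotypeAlleles(genotype)
  match <- rep(TRUE, length(cohort))
  for (mk in colnames(al)) {
    pair <- sort(al[, mk])
    match <- match & cohort@allele1[, mk] == pair[1L] &
      cohort@allele2[, mk] == pair[2L]
  }
  mt <- mtdnaLineage(genotype)
  if (mt != "unknown") match <- match & cohort@mtdna == mt
  mean(match)
}
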