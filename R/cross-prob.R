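#' Pedigree cross classes
#'
#' The enumerated pedigree classes over which hybrids are classified:
#' the two pure classes, both reciprocal F1s (named by the maternal
#' species, which fixes the mtDNA lineage), the four first-generation
#' backcrosses (by the F1 parent's sex and the recurrent species), and F2.
#' The F1 parent inside BC and F2 classes carries species-A mtDNA by
#' default (see the \code{f1Maternal} argument of the probability
#' functions), mirroring a system where all F1s have species-A mothers.
#'
#' @return character vector of the nine class names.
#' @examples
#' crossClasses()
#' @export
crossClasses <- function() {
  c("PURE_A", "PURE_B", "F1_motherA", "F1_motherB",
    "BC_F1female_x_Amale", "BC_F1male_x_Afemale",
    "BC_F1female_x_Bmale", "BC_F1male_x_Bfemale", "F2")
}

# dam/sire parent types and the offspring's maternal mtDNA lineage for each
# class; parent types: "A", "B" (pure) or "F1". "F1" maternal lineage is
# substituted from f1Maternal at lookup time.
.crossPedigree <- function(cross, f1Maternal = "A") {
  if (!cross %in% crossClasses())
    stop("unknown cross class: ", cross)
  if (!f1Maternal %in% c("A", "B"))
    stop("f1Maternal must be 'A' or 'B'")
  ped <- switch(cross,
    PURE_A = list(dam = "A", sire = "A", mt = "A"),
    PURE_B = list(dam = "B", sire = "B", mt = "B"),
    F1_motherA = list(dam = "A", sire = "B", mt = "A"),
    F1_motherB = list(dam = "B", sire = "A", mt = "B"),
    BC_F1female_x_Amale = list(dam = "F1", sire = "A", mt = f1Maternal),
    BC_F1male_x_Afemale = list(dam = "A", sire = "F1", mt = "A"),
    BC_F1female_x_Bmale = list(dam = "F1", sire = "B", mt = f1Maternal),
    BC_F1male_x_Bfemale = list(dam = "B", sire = "F1", mt = "B"),
    F2 = list(dam = "F1", sire = "F1", mt = f1Maternal))
  ped
}

# allele distribution of a gamete transmitted by a parent of the given type
# at one marker. A pure parent's genotype is drawn from its species' panel
# in Hardy-Weinberg proportions, so its transmitted allele is marginally a
# draw from the panel frequencies. An (unconditioned) F1 parent carries one
# allele drawn from each species' panel and transmits either with
# probability 1/2, so its gamete distribution is the equal mixture.
.gameteDist <- function(type, marker, panel) {
  fA <- alleleFreq(panel, marker, "A")
  fB <- alleleFreq(panel, marker, "B")
  if (type == "A") return(fA)
  if (type == "B") return(fB)
  alleles <- union(names(fA), names(fB))
  f <- vapply(alleles, function(x)
    0.5 * .freqOrZero(fA, x) + 0.5 * .freqOrZero(fB, x), numeric(1))
  names(f) <- alleles
  f
}

# probability that gametes from the two given distributions form the
# unordered pair (a, b)
.pairProb <- function(a, b, damDist, sireDist) {
  pa1 <- .freqOrZero(damDist, a) * .freqOrZero(sireDist, b)
  if (a == b) return(pa1)
  pa1 + .freqOrZero(damDist, b) * .freqOrZero(sireDist, a)
}

#' Exact probability of a multilocus genotype under a pedigree class
#'
#' Computes, by exact enumeration of parental gametes, the probability that
#' an offspring of the given cross carries the observed multilocus genotype
#' and mtDNA lineage. Markers are treated as unlinked and multiplied.
#' Each pure parent's genotype is drawn from its species' panel frequencies;
#' an F1 parent is generated recursively as an unconditioned F1 (one gamete
#' from each species' panel), not conditioned on any observed F1 genotype.
#' Gametes follow fair Mendelian (1/2) transmission. The mtDNA factor is 0
#' or 1 by strict maternal inheritance through the pedigree: the offspring's
#' mtDNA is its dam's maternal lineage. If the genotype's mtDNA is
#' \code{"unknown"} the factor is omitted.
#'
#' @param genotype a [MultilocusGenotype-class].
#' @param cross one of [crossClasses()].
#' @param panel a [MarkerPanel-class].
#' @param f1Maternal maternal species of any F1 parent inside BC/F2 classes
#'   (\code{"A"} default).
#' @return the probability, in [0, 1].
#' @examples
#' fx <- buildAlbatrossFixture()
#' genotypeProbGivenCross(fx$genotype, "F1_motherA", fx$panel)       # 0.90
#' genotypeProbGivenCross(fx$genotype, "BC_F1female_x_Bmale", fx$panel)
#' @export
genotypeProbGivenCross <- function(genotype, cross, panel, f1Maternal = "A") {
  stopifnot(is(genotype, "MultilocusGenotype"), is(panel, "MarkerPanel"))
  ped <- .crossPedigree(cross, f1Maternal)
  mt <- mtdnaLineage(genotype)
  mtFactor <- if (mt == "unknown") 1 else as.numeric(mt == ped$mt)
  if (mtFactor == 0) return(0)
  al <- genotypeAlleles(genotype)
  p <- 1
  for (mk in colnames(al)) {
    a <- al[1L, mk]; b <- al[2L, mk]
    if (is.na(a) || is.na(b)) next
    damDist <- .gameteDist(ped$dam, mk, panel)
    sireDist <- .gameteDist(ped$sire, mk, panel)
    p <- p * .pairProb(a, b, damDist, sireDist)
  }
  p * mtFactor
}

#' Posterior classification of a hybrid over pedigree classes
#'
#' Raw genotype probabilities from [genotypeProbGivenCross()] for each
#' candidate class, plus prior-weighted renormalized posteriors (uniform
#' prior by default). If every raw probability is zero the genotype is
#' inconsistent with all candidate classes: posteriors are \code{NA} and
#' the returned data.frame carries attribute \code{inconsistent = TRUE}.
#'
#' @inheritParams genotypeProbGivenCross
#' @param classes character vector of candidate classes
#'   (subset of [crossClasses()]).
#' @param priors optional named numeric vector of prior weights over
#'   \code{classes} (normalized internally); default uniform.
#' @return data.frame with columns \code{class}, \code{probability},
#'   \code{posterior}, ordered by decreasing posterior.
#' @examples
#' fx <- buildAlbatrossFixture()
#' classifyHybrid(fx$genotype, fx$panel,
#'   c("F1_motherA", "BC_F1female_x_Bmale"))
#' @export
classifyHybrid <- function(genotype, panel, classes = crossClasses(),
                           priors = NULL, f1Maternal = "A") {
  if (length(classes) == 0L) stop("classes must be non-empty")
  if (is.null(priors)) {
    priors <- rep(1 / length(classes), length(classes))
    names(priors) <- classes
  } else {
    if (!all(classes %in% names(priors)))
      stop("priors must name every candidate class")
    priors <- priors[classes] / sum(priors[classes])
  }
  probs <- vapply(classes, function(cl)
    genotypeProbGivenCross(genotype, cl, panel, f1Maternal), numeric(1))
  weighted <- probs * priors
  out <- data.frame(class = classes, probability = probs,
    posterior = NA_real_, stringsAsFactors = FALSE)
  if (sum(weighted) > 0) {
    out$posterior <- weighted / sum(weighted)
  } else {
    attr(out, "inconsistent") <- TRUE
  }
  out <- out[order(-replace(out$posterior, is.na(out$posterior), -1),
    out$class), ]
  rownames(out) <- NULL
  out
}
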