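#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
NULL

#' LocusAlignment: one locus's haplotype alignment for one species panel
#'
#' A set of phased, aligned haplotype sequences sampled from a single
#' parental species at a single locus. All sequences must have equal length.
#' The alphabet is IUPAC nucleotides plus \code{-} (gap) and \code{N};
#' gaps and Ns are treated as missing data by all per-site statistics.
#'
#' @slot locusId single non-empty character, the locus name.
#' @slot speciesLabel single character, the species panel label.
#' @slot haplotypes a \link[Biostrings]{DNAStringSet} of equal-width
#'   haplotype sequences (at least one).
#'
#' @seealso [LocusAlignment()] for the constructor,
#'   [alleleFrequencies()], [tajimasD()], [fourGameteRm()].
#' @exportClass LocusAlignment
setClass("LocusAlignment",
  representation(
    locusId = "character",
    speciesLabel = "character",
    haplotypes = "DNAStringSet"
  )
)

setValidity("LocusAlignment", function(object) {
  msg <- character()
  if (length(object@locusId) != 1L || !nzchar(object@locusId))
    msg <- c(msg, "locusId must be a single non-empty string")
  if (length(object@speciesLabel) != 1L)
    msg <- c(msg, "speciesLabel must be a single string")
  if (length(object@haplotypes) < 1L)
    msg <- c(msg, "at least one haplotype is required")
  w <- Biostrings::width(object@haplotypes)
  if (length(w) > 0L && length(unique(w)) != 1L)
    msg <- c(msg, "all haplotypes must have equal length")
  if (length(msg)) msg else TRUE
})

#' Construct a LocusAlignment
#'
#' @param locusId locus name.
#' @param haplotypes character vector of equal-length nucleotide strings,
#'   or a \link[Biostrings]{DNAStringSet}. Sequences are upper-cased.
#' @param speciesLabel species panel label (default \code{""}).
#' @return a [LocusAlignment-class] object.
#' @examples
#' aln <- LocusAlignment("locus1", c("ACGT", "ACTT"), "A")
#' nHaplotypes(aln)
#' @export
LocusAlignment <- function(locusId, haplotypes, speciesLabel = "") {
  if (is.character(haplotypes))
    haplotypes <- Biostrings::DNAStringSet(toupper(haplotypes))
  new("LocusAlignment",
    locusId = as.character(locusId),
    speciesLabel = as.character(speciesLabel),
    haplotypes = haplotypes)
}

#' @describeIn LocusAlignment number of haplotypes in the panel
#' @param x,object a \code{LocusAlignment}
#' @export
nHaplotypes <- function(x) length(x@haplotypes)

#' @describeIn LocusAlignment alignment length in bp
#' @export
locusLength <- function(x) {
  if (length(x@haplotypes) == 0L) 0L else Biostrings::width(x@haplotypes)[1L]
}

#' @describeIn LocusAlignment locus identifier
#' @export
locusId <- function(x) x@locusId

#' @describeIn LocusAlignment species panel label
#' @export
speciesLabel <- function(x) x@speciesLabel

#' @describeIn LocusAlignment haplotypes as a character matrix
#'   (rows = haplotypes, columns = sites)
#' @export
haplotypeMatrix <- function(x) {
  m <- as.matrix(x@haplotypes)
  rownames(m) <- names(x@haplotypes)
  m
}

setMethod("show", "LocusAlignment", function(object) {
  cat(sprintf("LocusAlignment '%s' [%s]: %d haplotypes x %d bp\n",
    object@locusId, object@speciesLabel,
    nHaplotypes(object), locusLength(object)))
})

#' MarkerPanel: per-marker parental allele frequencies for two species
#'
#' Holds, for each marker, the allele frequency spectrum observed in each of
#' two parental species panels (A and B). Frequencies at each marker within
#' each species must sum to 1. Markers may be single SNPs or linked haplotype
#' blocks whose alleles are concatenated site states (e.g. \code{"CAG"}).
#'
#' Orientation convention throughout the package: species A scores 1 on the
#' hybrid index, species B scores 0 (switchable via \code{orientation}
#' arguments).
#'
#' @slot speciesA,speciesB display labels for the two parental species.
#' @slot freqA,freqB named lists (one element per marker) of named numeric
#'   vectors mapping allele to frequency within the species.
#' @slot diagnostic named logical vector: is each marker diagnostic?
#'
#' @seealso [MarkerPanel()], [buildAlbatrossFixture()], [diagnosticIndex()],
#'   [genotypeProbGivenCross()].
#' @exportClass MarkerPanel
setClass("MarkerPanel",
  representation(
    speciesA = "character",
    speciesB = "character",
    freqA = "list",
    freqB = "list",
    diagnostic = "logical"
  )
)

setValidity("MarkerPanel", function(object) {
  msg <- character()
  if (!identical(names(object@freqA), names(object@freqB)))
    msg <- c(msg, "freqA and freqB must have identical marker names")
  if (is.null(names(object@freqA)) || anyDuplicated(names(object@freqA)))
    msg <- c(msg, "markers must be uniquely named")
  for (mk in names(object@freqA)) {
    for (f in list(object@freqA[[mk]], object@freqB[[mk]])) {
      if (!is.numeric(f) || is.null(names(f)))
        return(sprintf("marker '%s': frequencies must be a named numeric vector", mk))
      if (any(f < 0))
        msg <- c(msg, sprintf("marker '%s': negative frequency", mk))
      if (abs(sum(f) - 1) > 1e-9)
        msg <- c(msg, sprintf("marker '%s': frequencies must sum to 1", mk))
    }
  }
  if (length(object@diagnostic) != length(object@freqA))
    msg <- c(msg, "diagnostic flag needed for every marker")
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerPanel
#'
#' @param freqA,freqB named lists of named numeric allele-frequency vectors,
#'   one element per marker, in matching order. Each vector must sum to 1.
#' @param diagnostic logical vector flagging diagnostic markers
#'   (default all \code{TRUE}).
#' @param speciesA,speciesB species display labels.
#' @return a [MarkerPanel-class] object.
#' @examples
#' pan <- MarkerPanel(
#'   freqA = list(m1 = c(A = 1)),
#'   freqB = list(m1 = c(G = 1)))
#' markerIds(pan)
#' @export
MarkerPanel <- function(freqA, freqB, diagnostic = NULL,
                        speciesA = "A", speciesB = "B") {
  if (is.null(diagnostic)) diagnostic <- rep(TRUE, length(freqA))
  names(diagnostic) <- names(freqA)
  new("MarkerPanel", speciesA = speciesA, speciesB = speciesB,
    freqA = freqA, freqB = freqB, diagnostic = diagnostic)
}

#' @describeIn MarkerPanel marker identifiers
#' @param x,object a \code{MarkerPanel}
#' @export
markerIds <- function(x) names(x@freqA)

#' @describeIn MarkerPanel allele-frequency map for one marker in one species
#' @param marker marker id
#' @param species \code{"A"} or \code{"B"}
#' @export
alleleFreq <- function(x, marker, species = c("A", "B")) {
  species <- match.arg(species)
  f <- if (species == "A") x@freqA[[marker]] else x@freqB[[marker]]
  if (is.null(f)) stop("unknown marker: ", marker)
  f
}

#' @describeIn MarkerPanel logical vector of diagnostic flags
#' @export
isDiagnostic <- function(x) x@diagnostic

#' @describeIn MarkerPanel panel with species A and B swapped
#' @export
swapSpecies <- function(x) {
  MarkerPanel(freqA = x@freqB, freqB = x@freqA,
    diagnostic = x@diagnostic, speciesA = x@speciesB, speciesB = x@speciesA)
}

setMethod("show", "MarkerPanel", function(object) {
  cat(sprintf("MarkerPanel: %d markers (%d diagnostic); species A = '%s', B = '%s'\n",
    length(object@freqA), sum(object@diagnostic),
    object@speciesA, object@speciesB))
  for (mk in names(object@freqA)) {
    cat(sprintf("  %s%s  A: {%s}  B: {%s}\n", mk,
      if (object@diagnostic[[mk]]) "*" else " ",
      paste(sprintf("%s=%.3g", names(object@freqA[[mk]]),
        object@freqA[[mk]]), collapse = ", "),
      paste(sprintf("%s=%.3g", names(object@freqB[[mk]]),
        object@freqB[[mk]]), collapse = ", ")))
  }
})

#' MultilocusGenotype: one individual's marker genotypes plus mtDNA lineage
#'
#' Nuclear genotypes are unordered allele pairs at each marker of a
#' [MarkerPanel-class]; the mtDNA field records which species' maternally
#' inherited haplotype the individual carries (\code{"A"}, \code{"B"} or
#' \code{"unknown"}).
#'
#' @slot sampleId sample identifier.
#' @slot alleles 2 x m character matrix (columns named by marker); each
#'   column is the unordered allele pair, stored in lexicographic order.
#'   \code{NA} marks a missing genotype.
#' @slot mtdna \code{"A"}, \code{"B"} or \code{"unknown"}.
#' @slot sex \code{"male"}, \code{"female"} or \code{"unknown"} (stored,
#'   never inferred).
#'
#' @seealso [MultilocusGenotype()], [diagnosticIndex()], [classifyHybrid()].
#' @exportClass MultilocusGenotype
setClass("MultilocusGenotype",
  representation(
    sampleId = "character",
    alleles = "matrix",
    mtdna = "character",
    sex = "character"
  )
)

setValidity("MultilocusGenotype", function(object) {
  msg <- character()
  if (nrow(object@alleles) != 2L)
    msg <- c(msg, "alleles must be a 2 x m matrix")
  if (ncol(object@alleles) < 1L)
    msg <- c(msg, "at least one marker genotype is required")
  if (is.null(colnames(object@alleles)))
    msg <- c(msg, "allele matrix columns must be named by marker")
  if (!object@mtdna %in% c("A", "B", "unknown"))
    msg <- c(msg, "mtdna must be 'A', 'B' or 'unknown'")
  if (!object@sex %in% c("male", "female", "unknown"))
    msg <- c(msg, "sex must be 'male', 'female' or 'unknown'")
  if (length(msg)) msg else TRUE
})

#' Construct a MultilocusGenotype
#'
#' @param sampleId sample identifier.
#' @param alleles named list of length-2 character vectors (unordered allele
#'   pairs, one per marker), or a 2 x m character matrix with marker column
#'   names. Pairs are stored lexicographically sorted.
#' @param mtdna mtDNA species lineage: \code{"A"}, \code{"B"} or
#'   \code{"unknown"}.
#' @param sex \code{"male"}, \code{"female"} or \code{"unknown"}.
#' @return a [MultilocusGenotype-class] object.
#' @examples
#' g <- MultilocusGenotype("h1",
#'   list(m1 = c("A", "G"), m2 = c("C", "C")), mtdna = "A")
#' genotypeAlleles(g)
#' @export
MultilocusGenotype <- function(sampleId, alleles, mtdna = "unknown",
                               sex = "unknown") {
  if (is.list(alleles)) {
    nm <- names(alleles)
    alleles <- vapply(alleles, function(p) sort(as.character(p))[1:2],
      character(2))
    colnames(alleles) <- nm
  } else {
    alleles <- apply(alleles, 2L, function(p) sort(p, na.last = TRUE))
  }
  new("MultilocusGenotype", sampleId = as.character(sampleId),
    alleles = alleles, mtdna = mtdna, sex = sex)
}

#' @describeIn MultilocusGenotype the 2 x m allele matrix
#' @param x,object a \code{MultilocusGenotype}
#' @export
genotypeAlleles <- function(x) x@alleles

#' @describeIn MultilocusGenotype mtDNA species lineage
#' @export
mtdnaLineage <- function(x) x@mtdna

#' @describeIn MultilocusGenotype sample identifier
#' @export
sampleId <- function(x) x@sampleId

setMethod("show", "MultilocusGenotype", function(object) {
  gt <- apply(object@alleles, 2L, paste, collapse = "/")
  cat(sprintf("MultilocusGenotype '%s' (mtDNA %s, sex %s)\n  %s\n",
    object@sampleId, object@mtdna, object@sex,
    paste(sprintf("%s:%s", names(gt), gt), collapse = "  ")))
})

#' GenotypeSet: a cohort of multilocus genotypes
#'
#' Column-oriented container for many individuals genotyped at the same
#' markers; used by the cross simulators, where cohorts can be large.
#'
#' @slot sampleId character vector of sample ids.
#' @slot allele1,allele2 n x m character matrices of the unordered allele
#'   pairs (allele1 <= allele2 lexicographically, columns named by marker).
#' @slot mtdna character vector of mtDNA lineages per individual.
#' @slot sex character vector per individual.
#'
#' @seealso [simulateCrossOffspring()], [readGenotypeTable()].
#' @exportClass GenotypeSet
setClass("GenotypeSet",
  representation(
    sampleId = "character",
    allele1 = "matrix",
    allele2 = "matrix",
    mtdna = "character",
    sex = "character"
  )
)

setValidity("GenotypeSet", function(object) {
  n <- length(object@sampleId)
  msg <- character()
  if (nrow(object@allele1) != n || nrow(object@allele2) != n)
    msg <- c(msg, "allele matrices must have one row per sample")
  if (!identical(dim(object@allele1), dim(object@allele2)) ||
      !identical(colnames(object@allele1), colnames(object@allele2)))
    msg <- c(msg, "allele1 and allele2 must have identical shape and marker names")
  if (is.null(colnames(object@allele1)))
    msg <- c(msg, "allele matrix columns must be named by marker")
  if (length(object@mtdna) != n || length(object@sex) != n)
    msg <- c(msg, "mtdna and sex must have one entry per sample")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeSet
#'
#' @param sampleId character vector of sample ids.
#' @param allele1,allele2 n x m character matrices (marker column names
#'   required); pairs are normalized so allele1 <= allele2 per cell.
#' @param mtdna,sex per-individual vectors (recycled if length 1).
#' @return a [GenotypeSet-class] object.
#' @export
GenotypeSet <- function(sampleId, allele1, allele2,
                        mtdna = "unknown", sex = "unknown") {
  n <- length(sampleId)
  swap <- !is.na(allele1) & !is.na(allele2) & allele1 > allele2
  if (any(swap)) {
    tmp <- allele1[swap]
    allele1[swap] <- allele2[swap]
    allele2[swap] <- tmp
  }
  new("GenotypeSet", sampleId = as.character(sampleId),
    allele1 = allele1, allele2 = allele2,
    mtdna = rep_len(as.character(mtdna), n),
    sex = rep_len(as.character(sex), n))
}

setMethod("show", "GenotypeSet", function(object) {
  cat(sprintf("GenotypeSet: %d individuals x %d markers; mtDNA: %s\n",
    length(object@sampleId), ncol(object@allele1),
    paste(sprintf("%s=%d", names(table(object@mtdna)),
      as.integer(table(object@mtdna))), collapse = ", ")))
})

setMethod("length", "GenotypeSet", function(x) length(x@sampleId))

#' Extract one individual from a GenotypeSet
#'
#' @param gs a [GenotypeSet-class]
#' @param i index
#' @return a [MultilocusGenotype-class]
#' @export
getGenotype <- function(gs, i) {
  al <- rbind(gs@allele1[i, ], gs@allele2[i, ])
  colnames(al) <- colnames(gs@allele1)
  MultilocusGenotype(gs@sampleId[i], al, mtdna = gs@mtdna[i], sex = gs@sex[i])
}

#' @describeIn GenotypeSet mtDNA lineage vector of a cohort
#' @param x a \code{GenotypeSet}
#' @export
mtdnaLineages <- function(x) x@mtdna
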