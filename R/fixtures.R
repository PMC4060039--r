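#' Canonical five-marker albatross panel and observed hybrid genotype
#'
#' Builds the parental allele-frequency panel behind the Black-footed x
#' Laysan Albatross hybrid analysis: five diagnostic nuclear markers, four
#' with fixed differences between the species and one (the \code{1FWD}
#' marker) whose Black-footed allele also segregates at frequency 0.10 in
#' Laysan Albatrosses, plus the canonical observed hybrid genotype:
#' heterozygous at all five markers with the Laysan (species A) mtDNA
#' haplotype. Species A is Laysan, species B is Black-footed. The
#' \code{1REV} marker is a three-SNP linked haplotype block
#' (\code{CAG}/\code{TGC}).
#'
#' Reference points: [diagnosticIndex()] of the genotype is 0.5091 (0.51 at
#' two decimals); [genotypeProbGivenCross()] gives 0.90 for an F1 with a
#' Laysan mother, 0.028125 for an F1 female backcrossed to a Black-footed
#' male, 0.03375 for either backcross to a Laysan parent, and 0 for any
#' cross with a Black-footed dam.
#'
#' @return list with elements \code{panel} (a [MarkerPanel-class]) and
#'   \code{genotype} (a [MultilocusGenotype-class]).
#' @examples
#' fx <- buildAlbatrossFixture()
#' round(diagnosticIndex(fx$genotype, fx$panel), 2)
#' @export
buildAlbatrossFixture <- function() {
  freqA <- list(
    MHC  = c(A = 1),
    `1FWD` = c(A = 0.9, C = 0.1),
    `1REV` = c(CAG = 1),
    `4FWD` = c(C = 1),
    `4REV` = c(A = 1))
  freqB <- list(
    MHC  = c(G = 1),
    `1FWD` = c(C = 1),
    `1REV` = c(TGC = 1),
    `4FWD` = c(`T` = 1),
    `4REV` = c(C = 1))
  panel <- MarkerPanel(freqA, freqB, speciesA = "LA", speciesB = "BF")
  genotype <- MultilocusGenotype("hybrid",
    list(MHC = c("A", "G"), `1FWD` = c("A", "C"),
      `1REV` = c("CAG", "TGC"), `4FWD` = c("C", "T"),
      `4REV` = c("A", "C")),
    mtdna = "A", sex = "unknown")
  list(panel = panel, genotype = genotype)
}

#' Synthetic parental haplotype alignments matching the five-marker panel
#'
#' Constructs small synthetic per-locus haplotype alignments whose per-site
#' allele frequencies reproduce the canonical panel of
#' [buildAlbatrossFixture()] exactly: 20 haplotypes per species per locus,
#' with 18/20 = 0.90 of Laysan haplotypes carrying the Laysan allele at the
#' shared-polymorphism site of \code{1FWD}. The \code{1REV} locus carries
#' its three diagnostic SNPs at separate sites (collapsed into one block
#' marker by [findDiagnosticMarkers()]). A non-diagnostic locus
#' (\code{6FWD}) segregating the same two alleles at 0.5/0.5 in species A
#' is included to exercise marker exclusion. Monomorphic spacer columns pad
#' each locus.
#'
#' @param nPerSpecies haplotypes per species panel; must be a multiple of
#'   10 so the 0.90 frequency is exact (default 20).
#' @return list with \code{panelA} and \code{panelB}, each a list of
#'   [LocusAlignment-class] objects (species A = Laysan-like, B =
#'   Black-footed-like).
#' @examples
#' panels <- buildAlbatrossAlignments()
#' findDiagnosticMarkers(panels$panelA, panels$panelB)$locus_id
#' @export
buildAlbatrossAlignments <- function(nPerSpecies = 20L) {
  if (nPerSpecies %% 10L != 0L)
    stop("nPerSpecies must be a multiple of 10")
  n <- nPerSpecies
  pad <- function(core) paste0("G", core, "G")  # monomorphic flanks
  mkAln <- function(locus, seqsA, seqsB) {
    list(A = LocusAlignment(locus, pad(seqsA), "LA"),
      B = LocusAlignment(locus, pad(seqsB), "BF"))
  }
  alns <- list(
    mkAln("MHC", rep("A", n), rep("G", n)),
    mkAln("1FWD", rep(c("A", "C"), c(0.9 * n, 0.1 * n)), rep("C", n)),
    mkAln("1REV", rep("CAG", n), rep("TGC", n)),
    mkAln("4FWD", rep("C", n), rep("T", n)),
    mkAln("4REV", rep("A", n), rep("C", n)),
    mkAln("6FWD", rep(c("A", "C"), c(n / 2, n / 2)), rep("C", n)))
  list(panelA = lapply(alns, `[[`, "A"), panelB = lapply(alns, `[[`, "B"))
}
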