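#' Discover diagnostic markers between two parental species panels
#'
#' A site qualifies as diagnostic when species A's majority allele reaches
#' frequency \code{>= threshold} within A and \code{<= 1 - threshold} in B,
#' and symmetrically for species B's majority allele. With the default
#' threshold of 0.90 this operationalizes "at least a 90\% probability of
#' distinguishing" the species: an allele read at a qualifying site points
#' to the right species at least 90\% of the time. Qualifying sites within
#' one locus are collapsed into a single marker whose alleles are the
#' concatenated per-site states (a linked haplotype block, e.g.
#' \code{"CAG"} vs \code{"TGC"}); the reported block frequencies are the
#' frequencies of the full concatenated haplotype in each panel.
#'
#' @param panelA,panelB lists of [LocusAlignment-class] objects covering the
#'   same loci at the same alignment lengths.
#' @param threshold diagnostic frequency threshold in (0.5, 1]; default 0.90.
#' @return a data.frame with one row per diagnostic marker: \code{locus_id},
#'   \code{sites} (list column of 0-based site positions), \code{allele_A},
#'   \code{allele_B}, \code{freq_A_in_A}, \code{freq_B_in_B}. Zero rows if
#'   no site qualifies.
#' @examples
#' a <- list(LocusAlignment("L1", c("AA", "AA"), "spA"))
#' b <- list(LocusAlignment("L1", c("GA", "GA"), "spB"))
#' findDiagnosticMarkers(a, b)
#' @export
findDiagnosticMarkers <- function(panelA, panelB, threshold = 0.90) {
  if (!is.numeric(threshold) || threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  idsA <- vapply(panelA, locusId, character(1))
  idsB <- vapply(panelB, locusId, character(1))
  if (!setequal(idsA, idsB))
    stop("panels cover different locus sets: ",
      paste(union(setdiff(idsA, idsB), setdiff(idsB, idsA)), collapse = ", "))
  names(panelA) <- idsA
  names(panelB) <- idsB

  rows <- list()
  for (loc in idsA) {
    alnA <- panelA[[loc]]
    alnB <- panelB[[loc]]
    if (locusLength(alnA) != locusLength(alnB))
      stop("locus '", loc, "': alignment lengths differ between panels")
    fA <- alleleFrequencies(alnA)
    fB <- alleleFrequencies(alnB)
    sites <- integer(0)
    for (j in seq_along(fA)) {
      a <- fA[[j]]; b <- fB[[j]]
      if (length(a) == 0L || length(b) == 0L) next
      majA <- names(a)[which.max(a)]
      majB <- names(b)[which.max(b)]
      if (majA == majB) next
      tol <- 1e-12  # guard exact boundary frequencies against fp error
      okA <- a[[majA]] >= threshold - tol &&
        (if (majA %in% names(b)) b[[majA]] else 0) <= 1 - threshold + tol
      okB <- b[[majB]] >= threshold - tol &&
        (if (majB %in% names(a)) a[[majB]] else 0) <= 1 - threshold + tol
      if (okA && okB) sites <- c(sites, j - 1L)
    }
    if (length(sites) == 0L) next
    mA <- haplotypeMatrix(alnA)[, sites + 1L, drop = FALSE]
    mB <- haplotypeMatrix(alnB)[, sites + 1L, drop = FALSE]
    blockA <- apply(mA, 1L, paste, collapse = "")
    blockB <- apply(mB, 1L, paste, collapse = "")
    alleleA <- names(sort(table(blockA), decreasing = TRUE))[1L]
    alleleB <- names(sort(table(blockB), decreasing = TRUE))[1L]
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = loc,
      sites = I(list(sites)),
      allele_A = alleleA,
      allele_B = alleleB,
      freq_A_in_A = mean(blockA == alleleA),
      freq_B_in_B = mean(blockB == alleleB),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(locus_id = character(0), sites = I(list()),
      allele_A = character(0), allele_B = character(0),
      freq_A_in_A = numeric(0), freq_B_in_B = numeric(0)))
  do.call(rbind, rows)
}

#' Build a MarkerPanel from discovered diagnostic markers
#'
#' Converts [findDiagnosticMarkers()] output plus the parental alignments
#' into a [MarkerPanel-class] holding each marker's (block-)allele frequency
#' spectra in both species.
#'
#' @param markers data.frame from [findDiagnosticMarkers()].
#' @param panelA,panelB the parental alignment lists the markers came from.
#' @param speciesA,speciesB display labels.
#' @return a [MarkerPanel-class].
#' @export
markerPanelFromAlignments <- function(markers, panelA, panelB,
                                      speciesA = "A", speciesB = "B") {
  names(panelA) <- vapply(panelA, locusId, character(1))
  names(panelB) <- vapply(panelB, locusId, character(1))
  freqA <- list(); freqB <- list()
  for (i in seq_len(nrow(markers))) {
    loc <- markers$locus_id[i]
    sites <- markers$sites[[i]] + 1L
    blockFreq <- function(aln) {
      m <- haplotypeMatrix(aln)[, sites, drop = FALSE]
      keep <- !apply(m, 1L, function(r) any(r %in% .MISSING))
      blocks <- apply(m[keep, , drop = FALSE], 1L, paste, collapse = "")
      tab <- table(blocks)
      f <- as.numeric(tab) / sum(tab)
      names(f) <- names(tab)
      f
    }
    freqA[[loc]] <- blockFreq(panelA[[loc]])
    freqB[[loc]] <- blockFreq(panelB[[loc]])
  }
  MarkerPanel(freqA, freqB, diagnostic = rep(TRUE, nrow(markers)),
    speciesA = speciesA, speciesB = speciesB)
}
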