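#' Read per-locus, per-species FASTA panels from a directory
#'
#' Expects files named \code{{locus}.{species}.fasta}. Sequences are
#' upper-cased; within each file all sequences must have equal length, and
#' a ragged file raises an error naming the file and the offending record.
#'
#' @param dir directory containing the FASTA files.
#' @param species optional species label; if given, only that species'
#'   files are read.
#' @return a list of [LocusAlignment-class] objects (named
#'   \code{locus.species}).
#' @seealso [writeLocusAlignment()]
#' @export
readFastaPanels <- function(dir, species = NULL) {
  files <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  if (!is.null(species)) {
    files <- files[grepl(paste0("\\.", species, "\\.fasta$"),
      basename(files))]
  }
  if (length(files) == 0L) stop("no FASTA panels found in ", dir)
  out <- list()
  for (f in files) {
    parts <- strsplit(sub("\\.fasta$", "", basename(f)), ".",
      fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      stop("file '", basename(f), "' does not match {locus}.{species}.fasta")
    sp <- parts[length(parts)]
    loc <- paste(parts[-length(parts)], collapse = ".")
    seqs <- Biostrings::readDNAStringSet(f)
    w <- Biostrings::width(seqs)
    if (length(unique(w)) > 1L) {
      bad <- names(seqs)[which(w != stats::median(w))[1L]]
      stop("ragged alignment in '", basename(f), "': record '", bad,
        "' has length ", w[which(w != stats::median(w))[1L]])
    }
    aln <- LocusAlignment(loc, toupper(as.character(seqs)), sp)
    names(aln@haplotypes) <- names(seqs)
    out[[paste(loc, sp, sep = ".")]] <- aln
  }
  out
}

#' Write a LocusAlignment to FASTA
#'
#' @param alignment a [LocusAlignment-class].
#' @param path output file (conventionally
#'   \code{{locus}.{species}.fasta}).
#' @return invisibly, \code{path}.
#' @export
writeLocusAlignment <- function(alignment, path) {
  seqs <- alignment@haplotypes
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("%s_%s_%d", locusId(alignment),
      speciesLabel(alignment), seq_along(seqs))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a multilocus genotype table
#'
#' Tab-separated, with comment lines starting \code{#} ignored. Required
#' columns \code{sample_id}, \code{sex}, \code{mtdna}; every remaining
#' column is a marker holding \code{allele1/allele2} pairs (order
#' irrelevant: \code{a/b} and \code{b/a} parse identically). Empty cells
#' and \code{NA} record a missing genotype. An unknown mtDNA label raises
#' an error naming the row.
#'
#' @param path TSV file path.
#' @return a [GenotypeSet-class] (zero-length, with a warning, for an
#'   empty table).
#' @seealso [writeGenotypeTable()]
#' @export
readGenotypeTable <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
    check.names = FALSE, colClasses = "character")
  req <- c("sample_id", "sex", "mtdna")
  if (!all(req %in% names(df)))
    stop("genotype table must have columns: ", paste(req, collapse = ", "))
  mks <- setdiff(names(df), req)
  if (length(mks) == 0L) stop("genotype table defines no marker columns")
  if (nrow(df) == 0L) {
    warning("empty genotype table: ", path)
    a <- matrix(character(0), 0L, length(mks), dimnames = list(NULL, mks))
    return(GenotypeSet(character(0), a, a,
      mtdna = character(0), sex = character(0)))
  }
  bad <- which(!df$mtdna %in% c("A", "B", "unknown"))
  if (length(bad))
    stop("row ", bad[1L], " (sample '", df$sample_id[bad[1L]],
      "'): unknown mtDNA label '", df$mtdna[bad[1L]], "'")
  n <- nrow(df)
  a1 <- a2 <- matrix(NA_character_, n, length(mks),
    dimnames = list(NULL, mks))
  for (mk in mks) {
    cell <- df[[mk]]
    empty <- is.na(cell) | cell == "" | cell == "NA"
    parts <- strsplit(cell, "/", fixed = TRUE)
    badRow <- which(!empty & lengths(parts) != 2L)
    if (length(badRow))
      stop("row ", badRow[1L], ", marker '", mk,
        "': malformed genotype '", cell[badRow[1L]], "'")
    a1[!empty, mk] <- vapply(parts[!empty], `[`, character(1), 1L)
    a2[!empty, mk] <- vapply(parts[!empty], `[`, character(1), 2L)
  }
  GenotypeSet(df$sample_id, a1, a2, mtdna = df$mtdna, sex = df$sex)
}

#' Write a GenotypeSet as a genotype TSV
#'
#' Columns \code{sample_id}, \code{sex}, \code{mtdna}, then one column per
#' marker with \code{allele1/allele2} values (lexicographic order, so the
#' writer is deterministic); missing genotypes are written as \code{NA}.
#' Header comment lines record the package version and any supplied
#' metadata (e.g. seed).
#'
#' @param gs a [GenotypeSet-class].
#' @param path output path.
#' @param meta optional named character vector written as
#'   \code{# name: value} header lines.
#' @return invisibly, \code{path}.
#' @export
writeGenotypeTable <- function(gs, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hybridcross %s",
    as.character(utils::packageVersion("hybridcross"))), con)
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  mks <- colnames(gs@allele1)
  pair <- matrix(paste(gs@allele1, gs@allele2, sep = "/"),
    nrow = length(gs), dimnames = list(NULL, mks))
  pair[is.na(gs@allele1) | is.na(gs@allele2)] <- NA
  df <- data.frame(sample_id = gs@sampleId, sex = gs@sex,
    mtdna = gs@mtdna, pair, check.names = FALSE,
    stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a model-fit table for AIC ranking
#'
#' Tab-separated with columns \code{label}, \code{logL}, \code{k} and
#' optionally \code{fixed_params} (semicolon-separated labels). The table
#' of isolation-with-migration fits shipped with the package can be read
#' with the default \code{path}.
#'
#' @param path TSV path; defaults to the packaged IM model-fit table.
#' @return data.frame suitable for [aicRank()].
#' @export
readModelFits <- function(path = system.file("extdata",
                            "im_model_fits.tsv", package = "hybridcross")) {
  df <- utils::read.delim(path, comment.char = "#",
    stringsAsFactors = FALSE)
  req <- c("label", "logL", "k")
  if (!all(req %in% names(df)))
    stop("model-fit table must have columns: ", paste(req, collapse = ", "))
  if (any(is.na(df$logL)) || any(is.na(df$k)))
    stop("model-fit table contains missing logL or k values")
  df
}

#' Write a generic report table with a metadata header
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta optional named character vector of \code{# name: value}
#'   header lines (version is always written).
#' @return invisibly, \code{path}.
#' @export
writeReport <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hybridcross %s",
    as.character(utils::packageVersion("hybridcross"))), con)
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
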