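#' Select Potentially Amplifiable Loci (PAL)
#'
#' Filters mined SSR loci to those suitable for PCR primer design: flanking
#' sequence strictly longer than `minFlank` on each side and at least
#' `minUnitsPAL` repeat units. With `dedupe = TRUE`, loci whose canonical
#' motif and both full flanking sequences exactly duplicate an earlier
#' retained locus are dropped (assembly redundancy: the same genomic locus
#' assembled into several transcripts would otherwise yield several
#' primer candidates amplifying one locus).
#'
#' @param loci GRanges from [findSSRs()].
#' @param transcripts the sequences the loci were mined from.
#' @param minFlank flank threshold in bp; flanks must exceed it (default 50,
#'   i.e. at least 51 bp).
#' @param minUnitsPAL minimum repeat units for a PAL (default 8). PAL
#'   candidates need more units than the mining floor because longer repeats
#'   are more likely polymorphic.
#' @param dedupe drop exact duplicates (default TRUE).
#' @return GRanges of retained loci with extra metadata columns
#'   `leftFlankSeq` and `rightFlankSeq`. Duplicates that were removed are
#'   recorded in `S4Vectors::metadata()$redundant`, a data.frame with the
#'   duplicate's transcript id and the transcript it repeats
#'   (`redundant_of`).
#' @export
selectPALs <- function(loci, transcripts, minFlank = 50L, minUnitsPAL = 8L,
                       dedupe = TRUE) {
  seqs <- .asSequenceVector(transcripts)
  tid <- as.character(GenomicRanges::seqnames(loci))
  if (length(loci) && !all(tid %in% names(seqs)))
    stop("loci reference transcripts absent from the input")
  mc <- S4Vectors::mcols(loci)
  keep <- mc$leftFlank > minFlank & mc$rightFlank > minFlank &
    mc$repeatCount >= minUnitsPAL
  pals <- loci[keep]
  tid <- tid[keep]
  lf <- substr(seqs[tid], 1L, GenomicRanges::start(pals) - 1L)
  rf <- substr(seqs[tid], GenomicRanges::end(pals) + 1L, nchar(seqs[tid]))
  S4Vectors::mcols(pals)$leftFlankSeq <- unname(lf)
  S4Vectors::mcols(pals)$rightFlankSeq <- unname(rf)
  redundant <- data.frame(transcript_id = character(),
                          redundant_of = character(),
                          stringsAsFactors = FALSE)
  if (dedupe && length(pals) > 1L) {
    key <- paste(S4Vectors::mcols(pals)$canonicalMotif, lf, rf, sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      first <- match(key[dup], key)
      redundant <- data.frame(
        transcript_id = tid[dup],
        redundant_of = tid[first],
        stringsAsFactors = FALSE)
      pals <- pals[!dup]
    }
  }
  S4Vectors::metadata(pals)$redundant <- redundant
  pals
}

#' Per-motif-length PAL counts
#'
#' @param pals GRanges from [selectPALs()].
#' @return list with `byMotifLen` (named counts for motif lengths 2..10)
#'   and `total`.
#' @export
palReport <- function(pals) {
  mlen <- S4Vectors::mcols(pals)$motifLen
  by <- table(factor(mlen, levels = 2:10))
  list(byMotifLen = stats::setNames(as.integer(by), names(by)),
       total = length(pals))
}

#' Write PAL records and their flank sequences
#'
#' Writes a TSV of PAL records and a FASTA of flanking sequences with two
#' records per PAL (`<transcript>_L`, `<transcript>_R`), ready for primer
#' design tools.
#'
#' @param pals GRanges from [selectPALs()].
#' @param tsvFile,fastaFile output paths (either may be NULL to skip).
#' @return invisible NULL.
#' @export
writePALs <- function(pals, tsvFile = NULL, fastaFile = NULL) {
  mc <- S4Vectors::mcols(pals)
  tid <- as.character(GenomicRanges::seqnames(pals))
  if (!is.null(tsvFile)) {
    df <- data.frame(
      transcript_id = tid,
      motif = mc$motif,
      canonical_motif = mc$canonicalMotif,
      motif_len = mc$motifLen,
      repeat_count = mc$repeatCount,
      start = GenomicRanges::start(pals) - 1L,
      end = GenomicRanges::end(pals),
      left_flank = mc$leftFlank,
      right_flank = mc$rightFlank,
      stringsAsFactors = FALSE)
    utils::write.table(df, tsvFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(fastaFile)) {
    flanks <- c(rbind(mc$leftFlankSeq, mc$rightFlankSeq))
    names(flanks) <- c(rbind(paste0(tid, "_L"), paste0(tid, "_R")))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(flanks), fastaFile)
  }
  invisible(NULL)
}
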