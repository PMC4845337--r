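#' Canonical form of a microsatellite motif
#'
#' Collapses the rotational and strand ambiguity of a repeat motif: (GA)n,
#' (AG)n, (TC)n and (CT)n name the same repeat class depending on where the
#' repeat is read and on which strand. The canonical form is the
#' lexicographically smallest string among all rotations of the motif and
#' all rotations of its reverse complement, so every member of a class maps
#' to the same representative.
#'
#' @param motif character vector of motifs over {A,C,G,T}; each must be
#'   primitive (not itself a repetition of a shorter motif).
#' @return character vector of canonical motifs, same length as the input.
#' @examples
#' canonicalMotif(c("AC", "GA", "TTA"))  # "AC" "AG" "AAT"
#' @export
canonicalMotif <- function(motif) {
  vapply(as.character(motif), function(m) {
    m <- toupper(m)
    chars <- strsplit(m, "", fixed = TRUE)[[1L]]
    if (length(chars) == 0L || !all(chars %in% c("A", "C", "G", "T")))
      stop("invalid motif (non-ACGT character): ", m)
    if (!.isPrimitive(chars))
      stop("invalid motif (not primitive): ", m)
    rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[chars])
    min(c(.rotations(chars), .rotations(rc)))
  }, character(1L), USE.NAMES = FALSE)
}

# all rotations of a character vector, as strings
.rotations <- function(chars) {
  k <- length(chars)
  vapply(seq_len(k), function(i) {
    paste(chars[c(i:k, seq_len(i - 1L))], collapse = "")
  }, character(1L))
}

# primitive = not a whole-number repetition of a shorter motif
.isPrimitive <- function(chars) {
  k <- length(chars)
  if (k == 1L) return(TRUE)
  divs <- seq_len(k - 1L)
  divs <- divs[k %% divs == 0L]
  !any(vapply(divs, function(d) {
    all(chars == rep_len(chars[seq_len(d)], k))
  }, logical(1L)))
}

#' Find perfect microsatellites in transcript sequences
#'
#' Scans each sequence for maximal perfect tandem repeats with primitive
#' motif length in `motifLenRange` and at least `minUnits` complete repeat
#' units. A repeat is reported at its shortest primitive motif only, so a
#' region that is both (AT)6 and (ATAT)3 yields a single dinucleotide locus;
#' homopolymer runs (period 1) are never reported because their period-2+
#' motifs are not primitive. Reported loci are maximal: the run cannot be
#' extended by one full motif copy on either side. Loci of different motif
#' lengths may overlap; trailing partial units are left in the flanks.
#'
#' Ambiguity codes: with `nPolicy = "break_run"` (default) any non-ACGT
#' character interrupts repeat runs, so an interrupted repeat appears as
#' separate loci if each run alone reaches `minUnits`; with
#' `"skip_transcript"` a sequence containing any non-ACGT character yields
#' no loci at all.
#'
#' @param x sequences: a [Biostrings::DNAStringSet], or a named character
#'   vector of nucleotide strings (case-insensitive).
#' @param minUnits minimum number of complete repeat units (default 5).
#' @param motifLenRange integer pair, smallest and largest motif length
#'   searched (default `c(2, 10)`).
#' @param nPolicy `"break_run"` or `"skip_transcript"` (see Details).
#' @return A [GenomicRanges::GRanges] on the transcripts (1-based
#'   coordinates, seqlengths set to transcript lengths) with metadata
#'   columns `motif` (as found), `canonicalMotif`, `motifLen`,
#'   `repeatCount`, `leftFlank` and `rightFlank` (flank lengths in bp).
#'   Loci are sorted by transcript then start.
#' @examples
#' findSSRs(c(t1 = "GGACACACACACACGG"))
#' @export
findSSRs <- function(x, minUnits = 5L, motifLenRange = c(2L, 10L),
                     nPolicy = c("break_run", "skip_transcript")) {
  nPolicy <- match.arg(nPolicy)
  minUnits <- as.integer(minUnits)
  if (minUnits < 2L) stop("minUnits must be >= 2")
  mlo <- as.integer(motifLenRange[1L])
  mhi <- as.integer(motifLenRange[2L])
  if (mlo < 2L || mhi > 10L || mlo > mhi)
    stop("motifLenRange must lie within 2..10")
  seqs <- .asSequenceVector(x)
  ids <- names(seqs)
  hits <- vector("list", length(seqs))
  for (s in seq_along(seqs)) {
    hits[[s]] <- .scanOne(seqs[[s]], ids[[s]], minUnits, mlo, mhi, nPolicy)
  }
  hits <- do.call(rbind, hits)
  lens <- nchar(seqs)
  names(lens) <- ids
  if (is.null(hits) || nrow(hits) == 0L) {
    gr <- GenomicRanges::GRanges(seqlengths = lens)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      motif = character(), canonicalMotif = character(),
      motifLen = integer(), repeatCount = integer(),
      leftFlank = integer(), rightFlank = integer())
    return(gr)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(hits$transcript, levels = ids),
    ranges = IRanges::IRanges(start = hits$start, end = hits$end),
    seqlengths = lens,
    motif = hits$motif,
    canonicalMotif = canonicalMotif(hits$motif),
    motifLen = hits$motifLen,
    repeatCount = hits$repeatCount,
    leftFlank = hits$start - 1L,
    rightFlank = lens[hits$transcript] - hits$end)
  names(gr) <- NULL
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

# normalize input to an uppercase named character vector
.asSequenceVector <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    seqs <- as.character(x)
  } else if (is.character(x)) {
    seqs <- toupper(x)
  } else {
    stop("x must be a DNAStringSet or character vector")
  }
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  if (anyDuplicated(names(seqs)))
    stop("transcript ids must be unique")
  seqs
}

# scan one sequence for all maximal primitive repeats; returns a data.frame
.scanOne <- function(seq, id, minUnits, mlo, mhi, nPolicy) {
  L <- nchar(seq)
  if (L == 0L) return(NULL)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ok <- chars %in% c("A", "C", "G", "T")
  if (!all(ok) && nPolicy == "skip_transcript") return(NULL)
  out <- list()
  for (m in mlo:mhi) {
    if (L < m * minUnits) break
    # eq[j] <=> position j matches position j+m and both are unambiguous
    head_i <- seq_len(L - m)
    eq <- chars[head_i] == chars[head_i + m] & ok[head_i] & ok[head_i + m]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= (minUnits - 1L) * m)) {
      i <- starts[k]
      span <- r$lengths[k] + m        # bases in the period-m run
      count <- span %/% m
      if (count < minUnits) next
      motif <- chars[i:(i + m - 1L)]
      if (!.isPrimitive(motif)) next  # reported at its shorter period
      out[[length(out) + 1L]] <- data.frame(
        transcript = id,
        motif = paste(motif, collapse = ""),
        motifLen = m,
        repeatCount = count,
        start = i,
        end = i + m * count - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Summarize an SSR mining run
#'
#' Tabulates, per motif-length class, how many transcripts carry at least
#' one SSR of that class and how many loci were found, alongside totals,
#' the SSR density (kb of transcriptome per SSR) and the percentage of
#' transcripts carrying any SSR. A transcript carrying both a di- and a
#' trinucleotide repeat counts once in each class but only once in the
#' overall `transcriptsWithSSR`.
#'
#' @param transcripts the mined sequences (DNAStringSet or named character).
#' @param loci the [GenomicRanges::GRanges] returned by [findSSRs()].
#' @return A `MiningSummary`: a list with elements `transcriptsTotal`,
#'   `transcriptsWithSSR`, `ssrLociTotal`, `transcriptsByMotifLen`,
#'   `lociByMotifLen`, `totalBases`, `densityKbPerSSR` (NA when no loci),
#'   `pctTranscriptsWithSSR` and `pctLociDinucleotide`.
#' @export
summarizeMining <- function(transcripts, loci) {
  seqs <- .asSequenceVector(transcripts)
  tid <- as.character(GenomicRanges::seqnames(loci))
  if (length(loci) && !all(tid %in% names(seqs)))
    stop("loci reference transcripts absent from the input")
  mlen <- S4Vectors::mcols(loci)$motifLen
  classes <- as.character(2:10)
  lociBy <- stats::setNames(integer(9L), classes)
  transBy <- stats::setNames(integer(9L), classes)
  if (length(loci)) {
    tab <- table(factor(mlen, levels = 2:10))
    lociBy[] <- as.integer(tab)
    ut <- unique(data.frame(tid = tid, m = mlen))
    tab2 <- table(factor(ut$m, levels = 2:10))
    transBy[] <- as.integer(tab2)
  }
  total <- length(loci)
  withSSR <- length(unique(tid))
  bases <- sum(nchar(seqs))
  structure(list(
    transcriptsTotal = length(seqs),
    transcriptsWithSSR = withSSR,
    ssrLociTotal = total,
    transcriptsByMotifLen = transBy,
    lociByMotifLen = lociBy,
    totalBases = bases,
    densityKbPerSSR = if (total > 0L) bases / total / 1000 else NA_real_,
    pctTranscriptsWithSSR = 100 * withSSR / length(seqs),
    pctLociDinucleotide =
      if (total > 0L) 100 * lociBy[["2"]] / total else NA_real_
  ), class = "MiningSummary")
}

#' Mining summary from per-class counts
#'
#' Builds the same summary as [summarizeMining()] directly from per-motif-
#' length counts, as published mining tables report them. Useful to check a
#' published table's internal consistency: the all-motif total, the
#' dinucleotide proportion, the fraction of transcripts carrying an SSR and
#' the density in kb per SSR are all recomputed from the class counts.
#'
#' Published tables of this kind typically assign each transcript to a
#' single motif class (the class counts sum to the transcript total), so by
#' default the per-class transcript counts are also used as locus counts.
#'
#' @param countsByMotifLen named numeric vector, counts per motif length
#'   (names "2".."10"; missing classes count 0).
#' @param transcriptsTotal total number of transcripts screened.
#' @param totalBases total transcriptome length in bases.
#' @param lociByMotifLen optional distinct per-class locus counts; defaults
#'   to `countsByMotifLen`.
#' @return A `MiningSummary` (see [summarizeMining()]).
#' @examples
#' miningSummaryFromCounts(c(`2` = 80, `3` = 15, `4` = 5),
#'                         transcriptsTotal = 250, totalBases = 5e5)
#' @export
miningSummaryFromCounts <- function(countsByMotifLen, transcriptsTotal,
                                    totalBases,
                                    lociByMotifLen = countsByMotifLen) {
  classes <- as.character(2:10)
  transBy <- stats::setNames(numeric(9L), classes)
  transBy[names(countsByMotifLen)] <- countsByMotifLen
  lociBy <- stats::setNames(numeric(9L), classes)
  lociBy[names(lociByMotifLen)] <- lociByMotifLen
  total <- sum(lociBy)
  withSSR <- sum(transBy)
  structure(list(
    transcriptsTotal = transcriptsTotal,
    transcriptsWithSSR = withSSR,
    ssrLociTotal = total,
    transcriptsByMotifLen = transBy,
    lociByMotifLen = lociBy,
    totalBases = totalBases,
    densityKbPerSSR = if (total > 0) totalBases / total / 1000 else NA_real_,
    pctTranscriptsWithSSR = 100 * withSSR / transcriptsTotal,
    pctLociDinucleotide =
      if (total > 0) 100 * lociBy[["2"]] / total else NA_real_
  ), class = "MiningSummary")
}

#' @export
print.MiningSummary <- function(x, ...) {
  cat("SSR mining summary\n")
  cat("  transcripts screened:   ", x$transcriptsTotal, "\n")
  cat("  transcripts with SSR:   ", x$transcriptsWithSSR,
      sprintf(" (%.2f%%)", x$pctTranscriptsWithSSR), "\n", sep = "")
  cat("  SSR loci:               ", x$ssrLociTotal, "\n")
  if (!is.na(x$densityKbPerSSR))
    cat(sprintf("  density:                one SSR per %.1f kb\n",
                x$densityKbPerSSR))
  if (!is.na(x$pctLociDinucleotide))
    cat(sprintf("  dinucleotide loci:      %.2f%%\n", x$pctLociDinucleotide))
  invisible(x)
}

#' Write SSR loci as a TSV table
#'
#' Emits one row per locus with 0-based half-open `start`/`end` columns (so
#' `end - start == motifLen * repeatCount` and `leftFlank == start`).
#'
#' @param loci GRanges from [findSSRs()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeSSRTable <- function(loci, file) {
  df <- data.frame(
    transcript_id = as.character(GenomicRanges::seqnames(loci)),
    motif = S4Vectors::mcols(loci)$motif,
    canonical_motif = S4Vectors::mcols(loci)$canonicalMotif,
    motif_len = S4Vectors::mcols(loci)$motifLen,
    repeat_count = S4Vectors::mcols(loci)$repeatCount,
    start = GenomicRanges::start(loci) - 1L,
    end = GenomicRanges::end(loci),
    left_flank = S4Vectors::mcols(loci)$leftFlank,
    right_flank = S4Vectors::mcols(loci)$rightFlank,
    stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
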