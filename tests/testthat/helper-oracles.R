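# Independent oracles used across the suite. These re-derive expected
# results by direct enumeration / substring comparison and deliberately
# share no code with the package internals.

# Brute-force SSR scanner: tests every (start, motif_len) pair by direct
# substring comparison, counting how many full motif copies fit, and keeps
# maximal runs (the copy count cannot grow and the run cannot be shifted
# one base left) with a primitive motif and >= minUnits copies.
bruteSSRs <- function(seq, minUnits = 5L, motifLens = 2:10) {
  seq <- toupper(seq)
  L <- nchar(seq)
  out <- list()
  for (m in motifLens) {
    nStart <- L - 2L * m + 1L
    if (nStart < 1L) next
    starts <- seq_len(nStart)
    motifs <- substring(seq, starts, starts + m - 1L)
    valid <- !grepl("[^ACGT]", motifs)
    counts <- rep(1L, nStart)
    alive <- valid
    cpy <- 1L
    while (any(alive)) {
      i <- starts[alive]
      nxt <- substring(seq, i + cpy * m, i + (cpy + 1L) * m - 1L)
      still <- nxt == motifs[alive] & !grepl("[^ACGT]", nxt)
      counts[alive][still] <- cpy + 1L
      alive[alive] <- still
      cpy <- cpy + 1L
    }
    hit <- which(valid & counts >= minUnits)
    for (i in hit) {
      # run-start condition: shifting one base left must not extend the
      # period-m run (the base before the start differs from the motif's
      # last base)
      if (i > 1L &&
          substr(seq, i - 1L, i - 1L) == substr(seq, i + m - 1L, i + m - 1L))
        next
      if (!bruteIsPrimitive(motifs[i])) next
      out[[length(out) + 1L]] <- data.frame(
        start = i, motifLen = m, repeatCount = counts[i],
        motif = motifs[i], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), motifLen = integer(),
                      repeatCount = integer(), motif = character()))
  df <- do.call(rbind, out)
  df[order(df$start, df$motifLen), , drop = FALSE]
}

bruteIsPrimitive <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), k / d)) return(FALSE)
  }
  TRUE
}

# Brute-force canonical motif: enumerate every rotation of the motif and
# of its reverse complement, take the lexicographic minimum.
bruteCanonical <- function(motif) {
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", motif), "")[[1]]),
              collapse = "")
  rots <- function(s) {
    k <- nchar(s)
    vapply(seq_len(k), function(i)
      paste0(substr(s, i, k), substr(s, 1, i - 1)), character(1))
  }
  min(c(rots(motif), rots(rc)))
}

randomSeq <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Random diploid matrix with missing calls, for round-trip properties.
randomGenotypeMatrix <- function(nInd = 12L, nLoci = 4L, missingRate = 0.1,
                                 label = "simpop") {
  sizes <- lapply(seq_len(nLoci), function(l)
    sample(80:320, sample(2:6, 1)))
  a1 <- sapply(sizes, function(s) sample(s, nInd, replace = TRUE))
  a2 <- sapply(sizes, function(s) sample(s, nInd, replace = TRUE))
  miss <- matrix(runif(nInd * nLoci) < missingRate, nInd, nLoci)
  a1[miss] <- NA
  a2[miss] <- NA
  GenotypeMatrix(a1, a2, speciesLabel = label,
                 lociNames = paste0("loc", seq_len(nLoci)))
}

# One-locus matrix drawn under exact Hardy-Weinberg sampling.
simHWEMatrix <- function(n, freqs, baseSize = 100L, unit = 2L) {
  g1 <- sample(seq_along(freqs), n, replace = TRUE, prob = freqs)
  g2 <- sample(seq_along(freqs), n, replace = TRUE, prob = freqs)
  sz <- baseSize + unit * (seq_along(freqs) - 1L)
  GenotypeMatrix(cbind(sz[g1]), cbind(sz[g2]), "hwe")
}

# Grid-search maximizer of the conditional null-allele likelihood for a
# two-visible-allele table (step 1e-3 in both p1 and r).
gridNullAllele <- function(counts, step = 1e-3) {
  gc <- counts$genotypeCounts
  al <- as.character(counts$alleles)
  stopifnot(length(al) == 2L)
  n11 <- unname(gc[paste(al[1], al[1], sep = "/")])
  n22 <- unname(gc[paste(al[2], al[2], sep = "/")])
  n12 <- unname(gc[paste(al[1], al[2], sep = "/")])
  n11 <- ifelse(is.na(n11), 0, n11)
  n22 <- ifelse(is.na(n22), 0, n22)
  n12 <- ifelse(is.na(n12), 0, n12)
  n <- n11 + n22 + n12
  g <- expand.grid(p1 = seq(step, 1 - step, by = step),
                   r = seq(0, 0.6, by = step))
  g <- g[g$p1 + g$r < 1, ]
  p2 <- 1 - g$p1 - g$r
  ll <- n12 * log(2 * g$p1 * p2) +
    n11 * log(g$p1 * (g$p1 + 2 * g$r)) +
    n22 * log(p2 * (p2 + 2 * g$r)) -
    n * log(1 - g$r^2)
  g$r[which.max(ll)]
}

extdata <- function(f) system.file("extdata", f, package = "SSRpanel")

# Published panel tables used as worked-example inputs.
readPanelFixtures <- function() {
  list(
    counts = read.delim(extdata("nudifrons_mining_counts.tsv")),
    totals = jsonlite::read_json(extdata("mining_totals.json")),
    status = read.delim(extdata("nudifrons_panel_status.tsv"),
                        check.names = FALSE),
    stats = read.delim(extdata("nudifrons_locus_stats.tsv"))
  )
}
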