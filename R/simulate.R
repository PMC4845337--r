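# Named substreams: every stage derives its own 32-bit seed from the
# top-level seed so stages can be regenerated independently.
.substreamSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_len(nchar(name)))
  as.integer((as.double(seed) * 7919 + h) %% .Machine$integer.max)
}

# random primitive motif of length m (never a homopolymer repetition)
.randomMotif <- function(m) {
  bases <- c("A", "C", "G", "T")
  repeat {
    chars <- sample(bases, m, replace = TRUE)
    if (.isPrimitive(chars)) return(chars)
  }
}

#' Simulate a transcriptome with planted microsatellites
#'
#' Generates random transcript sequences (log-normal lengths, fixed GC
#' content) and plants one perfect SSR in a random subset of them, at a
#' uniform random position. Guard bases flanking each planted repeat are
#' forced to differ from the bases that would extend the repeat run, so
#' the planted coordinates are exactly what a maximal-repeat scanner must
#' report. Transcripts drawn too short to host their planted repeat plus
#' guards have their length resampled.
#'
#' Defaults emulate a spleen transcriptome assembly of a non-model fish:
#' dinucleotide-dominated motif spectrum (weights follow the published
#' class proportions of such assemblies: ~82% di-, ~16% tri-, rest longer
#' motifs), minimum 5 repeat units with a truncated-geometric unit count.
#'
#' @param nTranscripts number of transcripts.
#' @param lengthMedian,lengthSigma log-normal transcript length parameters
#'   (median bp and sdlog); default 600 bp median, sigma 0.7 (assemblies
#'   with a 300 bp cutoff).
#' @param gc GC content (default 0.45).
#' @param plantRate probability a transcript receives a planted SSR.
#' @param motifLengthWeights named weights for motif lengths 2..10.
#' @param minUnits minimum planted repeat units (default 5).
#' @param meanExtraUnits mean of the geometric number of units above
#'   `minUnits` (default 3, i.e. mean 8 units).
#' @param seed integer seed (required: the truth table is only meaningful
#'   for a reproducible draw).
#' @return list with `sequences` (named [Biostrings::DNAStringSet]) and
#'   `truth`, a [GenomicRanges::GRanges] of planted loci (1-based, with
#'   `motif`, `motifLen`, `repeatCount` metadata).
#' @export
simulateTranscriptome <- function(nTranscripts = 500L,
                                  lengthMedian = 600, lengthSigma = 0.7,
                                  gc = 0.45, plantRate = 0.4,
                                  motifLengthWeights = c(
                                    `2` = 0.825, `3` = 0.160, `4` = 0.012,
                                    `5` = 0.001, `6` = 0.001, `7` = 0.0002,
                                    `8` = 0.0003, `9` = 0.0003,
                                    `10` = 0.0002),
                                  minUnits = 5L, meanExtraUnits = 3,
                                  seed) {
  if (missing(seed)) stop("seed is required")
  bases <- c("A", "C", "G", "T")
  baseProb <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  mlens <- as.integer(names(motifLengthWeights))
  w <- motifLengthWeights / sum(motifLengthWeights)
  set.seed(.substreamSeed(seed, "transcriptome"))
  ids <- sprintf("tx%05d", seq_len(nTranscripts))
  lens <- pmax(300L, as.integer(round(stats::rlnorm(
    nTranscripts, log(lengthMedian), lengthSigma))))
  planted <- stats::runif(nTranscripts) < plantRate
  seqs <- character(nTranscripts)
  truth <- vector("list", nTranscripts)
  pGeom <- 1 / (1 + meanExtraUnits)
  for (i in seq_len(nTranscripts)) {
    if (!planted[i]) {
      seqs[i] <- paste(sample(bases, lens[i], replace = TRUE,
                              prob = baseProb), collapse = "")
      next
    }
    m <- sample(mlens, 1L, prob = w)
    motif <- .randomMotif(m)
    count <- minUnits + stats::rgeom(1L, pGeom)
    need <- m * count + 2L  # repeat + one guard base each side
    while (lens[i] < need) {
      lens[i] <- pmax(300L, as.integer(round(stats::rlnorm(
        1L, log(lengthMedian), lengthSigma))))
    }
    chars <- sample(bases, lens[i], replace = TRUE, prob = baseProb)
    offsets <- 2:(lens[i] - m * count)
    start <- offsets[sample.int(length(offsets), 1L)]
    end <- start + m * count - 1L
    chars[start:end] <- rep_len(motif, m * count)
    # guards: left guard must not extend the period-m run backwards
    # (s[start-1] == motif[m] would), right guard must not extend it
    # forwards (s[end+1] == motif[1] would)
    chars[start - 1L] <- sample(setdiff(bases, motif[m]), 1L)
    chars[end + 1L] <- sample(setdiff(bases, motif[1L]), 1L)
    seqs[i] <- paste(chars, collapse = "")
    truth[[i]] <- data.frame(
      transcript = ids[i], start = start, end = end,
      motif = paste(motif, collapse = ""), motifLen = m,
      repeatCount = count, stringsAsFactors = FALSE)
  }
  names(seqs) <- ids
  tt <- do.call(rbind, truth)
  lensNamed <- stats::setNames(nchar(seqs), ids)
  truthGr <- if (is.null(tt)) {
    GenomicRanges::GRanges(seqlengths = lensNamed)
  } else {
    GenomicRanges::GRanges(
      seqnames = factor(tt$transcript, levels = ids),
      ranges = IRanges::IRanges(tt$start, tt$end),
      seqlengths = lensNamed,
      motif = tt$motif, motifLen = tt$motifLen,
      repeatCount = tt$repeatCount)
  }
  list(sequences = Biostrings::DNAStringSet(seqs), truth = truthGr)
}

#' Locus specification helper for genotype simulation
#'
#' Builds the per-locus piece of a genotype simulation: allele sizes on a
#' `baseSize + k * repeatUnit` ladder with the given visible frequencies
#' and an optional null-allele frequency.
#'
#' @param name locus label.
#' @param freqs visible allele frequencies (will be rescaled to sum to
#'   `1 - nullFreq`).
#' @param baseSize size of the smallest allele in bp.
#' @param repeatUnit ladder step in bp (default 2, dinucleotide).
#' @param nullFreq null-allele frequency r (default 0).
#' @return list consumed by [simulateGenotypes()].
#' @export
simLocus <- function(name, freqs, baseSize = 100L, repeatUnit = 2L,
                     nullFreq = 0) {
  if (nullFreq < 0 || nullFreq >= 1) stop("nullFreq must be in [0, 1)")
  freqs <- freqs / sum(freqs) * (1 - nullFreq)
  sizes <- baseSize + repeatUnit * (seq_along(freqs) - 1L)
  list(name = name, sizes = sizes, freqs = freqs,
       repeatUnit = as.integer(repeatUnit), nullFreq = nullFreq)
}

#' Simulate a diploid genotype matrix
#'
#' Draws genotypes locus by locus under an inbreeding/Wahlund model with
#' optional null alleles, then adds Gaussian fragment-size noise and bins
#' the sizes back to integer alleles with [binAlleles()] (the same path
#' real fragment data takes). Gametes are drawn from the augmented
#' frequency vector (visible alleles plus the null): with probability
#' `fis` the second gamete copies the first, giving
#' `P(A_i A_i) = p_i^2 + fis * p_i (1 - p_i)`. A null/null genotype is a
#' missing call; null/visible appears homozygous for the visible allele.
#'
#' @param nInd number of individuals.
#' @param loci list of locus specifications from [simLocus()].
#' @param fis inbreeding coefficient in [0, 1) (default 0).
#' @param missingRate additional random call dropout (default 0).
#' @param sizeNoiseSd fragment-size noise SD in bp before binning
#'   (default 0.15, typical capillary scatter on a 2-bp ladder).
#' @param speciesLabel label for the resulting matrix.
#' @param seed integer seed (required).
#' @return list with `matrix` (a [GenotypeMatrix-class]) and `truth`: the
#'   true gamete draws (`gametes`, an nInd x nLoci x 2 array of allele
#'   sizes with NA for null gametes) and the simulation parameters.
#' @export
simulateGenotypes <- function(nInd, loci, fis = 0, missingRate = 0,
                              sizeNoiseSd = 0.15, speciesLabel = "sim",
                              seed) {
  if (missing(seed)) stop("seed is required")
  if (fis < 0 || fis >= 1) stop("fis must be in [0, 1)")
  nl <- length(loci)
  lociNames <- vapply(loci, `[[`, character(1L), "name")
  a1 <- matrix(NA_integer_, nInd, nl)
  a2 <- matrix(NA_integer_, nInd, nl)
  gametes <- array(NA_real_, dim = c(nInd, nl, 2L))
  set.seed(.substreamSeed(seed, "genotypes"))
  for (l in seq_len(nl)) {
    sp <- loci[[l]]
    aug <- c(sp$freqs, sp$nullFreq)       # last slot = null allele
    augSizes <- c(sp$sizes, NA_real_)
    g1 <- sample.int(length(aug), nInd, replace = TRUE, prob = aug)
    copy <- stats::runif(nInd) < fis
    g2 <- ifelse(copy, g1,
                 sample.int(length(aug), nInd, replace = TRUE, prob = aug))
    s1 <- augSizes[g1]
    s2 <- augSizes[g2]
    gametes[, l, 1L] <- s1
    gametes[, l, 2L] <- s2
    vis1 <- ifelse(is.na(s1), s2, s1)     # null/visible looks homozygous
    vis2 <- ifelse(is.na(s2), s1, s2)
    drop <- is.na(vis1)                   # null/null -> missing
    if (missingRate > 0)
      drop <- drop | stats::runif(nInd) < missingRate
    raw1 <- vis1 + stats::rnorm(nInd, 0, sizeNoiseSd)
    raw2 <- vis2 + stats::rnorm(nInd, 0, sizeNoiseSd)
    obs <- c(raw1[!drop], raw2[!drop])
    if (length(obs)) {
      bm <- binAlleles(obs, repeatUnit = sp$repeatUnit,
                       locusName = sp$name)
      b1 <- applyBinning(bm, raw1)
      b2 <- applyBinning(bm, raw2)
      b1[drop] <- NA_integer_
      b2[drop] <- NA_integer_
      a1[, l] <- b1
      a2[, l] <- b2
    }
  }
  mat <- GenotypeMatrix(a1, a2, speciesLabel = speciesLabel,
                        lociNames = lociNames)
  list(matrix = mat,
       truth = list(gametes = gametes, loci = loci, fis = fis,
                    missingRate = missingRate,
                    sizeNoiseSd = sizeNoiseSd, seed = seed))
}
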