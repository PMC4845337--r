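test_that("canonicalMotif collapses rotation and strand classes", {
  expect_identical(canonicalMotif("AC"), "AC")
  expect_identical(canonicalMotif("GA"), "AG")
  expect_identical(canonicalMotif("TTA"), "AAT")
  # whole-class collapse: every name of the GA class maps to AG
  expect_identical(canonicalMotif(c("GA", "AG", "TC", "CT")),
                   rep("AG", 4))
  expect_error(canonicalMotif("AXC"), "non-ACGT")
  expect_error(canonicalMotif("ATAT"), "primitive")
})

test_that("canonicalMotif agrees with brute enumeration and is invariant", {
  set.seed(11)
  for (i in 1:200) {
    m <- sample(2:10, 1)
    motif <- randomSeq(m)
    if (!bruteIsPrimitive(motif)) next
    can <- canonicalMotif(motif)
    expect_identical(can, bruteCanonical(motif))
    # idempotent and invariant under rotation + reverse complement
    expect_identical(canonicalMotif(can), can)
    rot <- paste0(substr(motif, 2, m), substr(motif, 1, 1))
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", motif), "")[[1]]),
                collapse = "")
    expect_identical(canonicalMotif(rot), can)
    expect_identical(canonicalMotif(rc), can)
  }
})

test_that("findSSRs reports maximal primitive repeats at the unit floor", {
  # 6 x AC from position 1
  gr <- findSSRs(c(t = "ACACACACACAC"))
  expect_equal(length(gr), 1L)
  expect_equal(GenomicRanges::start(gr), 1L)
  expect_equal(GenomicRanges::end(gr), 12L)
  expect_equal(S4Vectors::mcols(gr)$repeatCount, 6L)
  expect_identical(S4Vectors::mcols(gr)$motif, "AC")
  # 4 repeat units stay below the floor of 5
  expect_equal(length(findSSRs(c(t = "ATATATAT"))), 0L)
  # homopolymers have no primitive motif of length >= 2
  expect_equal(length(findSSRs(c(t = strrep("A", 30)))), 0L)
  # empty-ish input
  expect_equal(length(findSSRs(c(t = "ACGT"))), 0L)
})

test_that("findSSRs handles ambiguity codes per policy", {
  s <- c(t = paste0("ACACACACACAC", "N", "ACACACACACAC"))
  br <- findSSRs(s, nPolicy = "break_run")
  expect_equal(length(br), 2L)  # two separate runs of 6 units each
  expect_equal(S4Vectors::mcols(br)$repeatCount, c(6L, 6L))
  expect_equal(length(findSSRs(s, nPolicy = "skip_transcript")), 0L)
})

test_that("a region valid at two motif lengths is reported once, shortest", {
  gr <- findSSRs(c(t = "GGATATATATATATGG"), minUnits = 3)
  expect_equal(length(gr), 1L)
  expect_equal(S4Vectors::mcols(gr)$motifLen, 2L)
})

test_that("findSSRs equals the brute-force scanner on random sequences", {
  set.seed(42)
  for (i in 1:300) {
    len <- sample(20:400, 1)
    # low-complexity alphabet raises repeat density so disagreements
    # would actually surface
    s <- paste(sample(c("A", "C"), len, replace = TRUE), collapse = "")
    found <- findSSRs(stats::setNames(s, "t"))
    got <- data.frame(start = GenomicRanges::start(found),
                      motifLen = S4Vectors::mcols(found)$motifLen,
                      repeatCount = S4Vectors::mcols(found)$repeatCount,
                      motif = S4Vectors::mcols(found)$motif)
    want <- bruteSSRs(s)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("seq", i))
  }
})

test_that("reported loci are maximal under full motif-copy extension", {
  set.seed(7)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G"), 300, replace = TRUE), collapse = "")
    gr <- findSSRs(stats::setNames(s, "t"), minUnits = 3)
    for (j in seq_along(gr)) {
      st <- GenomicRanges::start(gr)[j]
      en <- GenomicRanges::end(gr)[j]
      motif <- S4Vectors::mcols(gr)$motif[j]
      m <- nchar(motif)
      if (st - m >= 1)
        expect_false(substr(s, st - m, st - 1) == motif)
      if (en + m <= nchar(s))
        expect_false(substr(s, en + 1, en + m) == motif)
    }
  }
})

test_that("summarizeMining tallies classes, density and percentages", {
  set.seed(1)
  s <- c(a = paste0(strrep("AC", 6), randomSeq(100)),
         b = paste0(strrep("AGG", 6), strrep("TG", 7)),
         c = randomSeq(388))
  loci <- findSSRs(s)
  ms <- summarizeMining(s, loci)
  expect_equal(ms$ssrLociTotal, length(loci))
  expect_lte(ms$transcriptsWithSSR, ms$transcriptsTotal)
  expect_equal(sum(ms$lociByMotifLen), ms$ssrLociTotal)
  # b carries a di- and a trinucleotide: counts once in each class
  expect_equal(unname(ms$transcriptsByMotifLen["2"]), 2L)
  expect_equal(unname(ms$transcriptsByMotifLen["3"]), 1L)
  expect_equal(ms$transcriptsWithSSR, 2L)
  expect_equal(ms$totalBases, sum(nchar(s)))
  expect_equal(ms$densityKbPerSSR, sum(nchar(s)) / length(loci) / 1000)
  # one 2000-bp transcript with one SSR -> 2 kb per SSR
  one <- c(x = paste0(randomSeq(988), strrep("AC", 6), randomSeq(1000)))
  expect_equal(nchar(one[[1]]), 2000L)
  l1 <- findSSRs(one)
  expect_equal(summarizeMining(one, l1)$densityKbPerSSR, 2.0)
  # zero loci -> density absent, not zero
  none <- c(y = randomSeq(50))
  expect_true(is.na(summarizeMining(none, findSSRs(none))$densityKbPerSSR))
})
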