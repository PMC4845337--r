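#' Tally genotype and allele counts at one locus
#'
#' Collects the sufficient statistics used by every per-locus test:
#' number of scored individuals, per-allele counts, per-genotype counts and
#' the heterozygote count. Missing calls are excluded.
#'
#' @param x a [GenotypeMatrix-class].
#' @param locus locus name or index.
#' @return A `LocusCounts` list with `locus`, `n`, `h` (heterozygous
#'   individuals), `alleles` (sorted allele sizes), `alleleCounts` (named,
#'   summing to 2n), `genotypeCounts` (named `"a/b"`, a <= b) and
#'   `nMissing`; or `NULL` when every call is missing (failed locus).
#' @export
tallyLocus <- function(x, locus) {
  calls <- genotypeCalls(x, locus)
  if (is.character(locus)) nm <- locus else nm <- lociNames(x)[locus]
  ok <- !is.na(calls[, 1L])
  nMissing <- sum(!ok)
  calls <- calls[ok, , drop = FALSE]
  if (nrow(calls) == 0L) return(NULL)
  alleles <- sort(unique(as.vector(calls)))
  ac <- table(factor(as.vector(calls), levels = alleles))
  gkey <- paste(calls[, 1L], calls[, 2L], sep = "/")
  gc <- table(gkey)
  structure(list(
    locus = nm,
    n = nrow(calls),
    h = sum(calls[, 1L] != calls[, 2L]),
    alleles = alleles,
    alleleCounts = stats::setNames(as.integer(ac), alleles),
    genotypeCounts = stats::setNames(as.integer(gc), names(gc)),
    nMissing = nMissing
  ), class = "LocusCounts")
}

#' Observed heterozygosity
#'
#' Fraction of scored individuals that are heterozygous: h / n.
#'
#' @param counts a `LocusCounts` from [tallyLocus()].
#' @return numeric in [0, 1]; NA if no individuals were scored.
#' @export
observedHet <- function(counts) {
  if (is.null(counts) || counts$n < 1L) return(NA_real_)
  counts$h / counts$n
}

#' Expected heterozygosity (gene diversity)
#'
#' By default the unbiased small-sample estimator
#' He = 2n/(2n - 1) * (1 - sum p_i^2), with p_i the sample allele
#' frequencies; `unbiased = FALSE` gives the plug-in form.
#'
#' @param counts a `LocusCounts` from [tallyLocus()].
#' @param unbiased apply the 2n/(2n-1) correction (default TRUE).
#' @return numeric; NA when fewer than 2 individuals were scored.
#' @export
expectedHet <- function(counts, unbiased = TRUE) {
  if (is.null(counts) || counts$n < 2L) return(NA_real_)
  twoN <- 2L * counts$n
  p <- counts$alleleCounts / twoN
  he <- 1 - sum(p^2)
  if (unbiased) he <- he * twoN / (twoN - 1L)
  he
}

# log conditional probability of a genotype table given allele counts:
# P = n! prod(a_i!) 2^h / ((2n)! prod(n_ij!))
# constant part (depends only on allele counts) is passed in as logConst.
.logTableProb <- function(logConst, h, logFactNij) {
  logConst + h * log(2) - logFactNij
}

#' Exact Hardy-Weinberg probability test
#'
#' Computes the exact probability-test p-value on the conditional
#' distribution of genotype tables given the observed allele counts. The
#' probability of a table is
#' `P(table) = n! prod(a_i!) 2^h / ((2n)! prod(n_ij!))`
#' and the p-value is the total conditional probability of all tables with
#' the same allele counts whose probability does not exceed the observed
#' table's (ties counted in the tail, to within relative 1e-12).
#'
#' `method = "enumerate"` enumerates every table; `"monte_carlo"` samples
#' tables from the conditional null by randomly pairing the allele multiset
#' and reports `(1 + #{P <= P_obs}) / (reps + 1)`; `"auto"` enumerates
#' unless the table count exceeds `enumTableLimit`, then falls back to
#' Monte Carlo.
#'
#' @param counts a `LocusCounts` from [tallyLocus()].
#' @param method `"auto"`, `"enumerate"` or `"monte_carlo"`.
#' @param mcReps Monte Carlo samples (default 1e5).
#' @param enumTableLimit largest table count enumerated under `"auto"`
#'   (default 1e6).
#' @param seed optional integer seed for the Monte Carlo path.
#' @return list with `p`, `method` used, and either `nTables` and
#'   `totalProb` (enumeration; `totalProb` must be 1 up to round-off) or
#'   `reps` (Monte Carlo). For a monomorphic locus the p-value is NA.
#' @export
hweExactTest <- function(counts, method = c("auto", "enumerate",
                                            "monte_carlo"),
                         mcReps = 1e5L, enumTableLimit = 1e6L,
                         seed = NULL) {
  method <- match.arg(method)
  if (is.null(counts) || length(counts$alleles) < 2L)
    return(list(p = NA_real_, method = "none"))
  a <- unname(counts$alleleCounts)
  n <- counts$n
  logConst <- lfactorial(n) + sum(lfactorial(a)) - lfactorial(2L * n)
  obs <- .observedTail(counts)
  logPobs <- .logTableProb(logConst, obs$h, obs$logFactNij)
  tol <- 1e-12
  if (method != "monte_carlo") {
    enum <- .hweEnumerate(a, logConst, logPobs + tol,
                          limit = enumTableLimit)
    if (!is.null(enum)) {
      return(list(p = enum$tail, method = "enumerate",
                  nTables = enum$nTables, totalProb = enum$total))
    }
    if (method == "enumerate")
      stop("table count exceeds enumTableLimit; use monte_carlo")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- length(a)
  pool <- rep.int(seq_len(k), a)
  hits <- 0L
  for (b in seq_len(mcReps)) {
    perm <- sample(pool)
    i <- perm[c(TRUE, FALSE)]
    j <- perm[c(FALSE, TRUE)]
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    cnt <- tabulate((lo - 1L) * k + hi, nbins = k * k)
    h <- sum(lo != hi)
    lp <- .logTableProb(logConst, h, sum(lfactorial(cnt[cnt > 0L])))
    if (lp <= logPobs + tol) hits <- hits + 1L
  }
  list(p = (1 + hits) / (mcReps + 1), method = "monte_carlo", reps = mcReps)
}

# observed table's h and sum(lfactorial(n_ij))
.observedTail <- function(counts) {
  gc <- counts$genotypeCounts
  parts <- strsplit(names(gc), "/", fixed = TRUE)
  het <- vapply(parts, function(p) p[1L] != p[2L], logical(1L))
  list(h = sum(gc[het]), logFactNij = sum(lfactorial(gc)))
}

# Enumerate all genotype tables with allele count vector a.
# Accumulates total probability and the tail (logP <= cutLogP).
# Returns NULL if more than `limit` tables exist.
.hweEnumerate <- function(a, logConst, cutLogP, limit = 1e6L) {
  k <- length(a)
  env <- new.env(parent = emptyenv())
  env$total <- 0
  env$tail <- 0
  env$nTables <- 0L
  env$aborted <- FALSE
  rec <- function(r, h, logFactNij) {
    if (env$aborted) return()
    i <- which(r > 0L)[1L]
    if (is.na(i)) {
      env$nTables <- env$nTables + 1L
      if (env$nTables > limit) {
        env$aborted <- TRUE
        return()
      }
      lp <- .logTableProb(logConst, h, logFactNij)
      p <- exp(lp)
      env$total <- env$total + p
      if (lp <= cutLogP) env$tail <- env$tail + p
      return()
    }
    ri <- r[i]
    for (nii in 0:(ri %/% 2L)) {
      x <- ri - 2L * nii  # copies of allele i in heterozygotes with j > i
      distribute <- function(j, left, r2, lf) {
        if (env$aborted) return()
        if (left == 0L) {
          r3 <- r2
          r3[i] <- 0L
          rec(r3, h + (ri - 2L * nii), lf)
          return()
        }
        if (j > k) return()
        # remaining capacity check
        if (sum(pmin(r2[seq(j, k)], Inf)) < left) return()
        for (nij in 0:min(left, r2[j])) {
          r4 <- r2
          r4[j] <- r4[j] - nij
          distribute(j + 1L, left - nij, r4, lf + lfactorial(nij))
        }
      }
      distribute(i + 1L, x, r, logFactNij + lfactorial(nii))
    }
  }
  rec(a, 0L, 0)
  if (env$aborted) return(NULL)
  list(tail = env$tail, total = env$total, nTables = env$nTables)
}

#' Maximum-likelihood null-allele frequency (EM)
#'
#' Fits, by expectation-maximization, the frequency r of a non-amplifying
#' (null) allele that best explains the observed genotype classes under
#' Hardy-Weinberg proportions. Class probabilities: visible heterozygote
#' (i, j) `2 p_i p_j`; visible homozygote (i) `p_i^2 + 2 p_i r` (true
#' homozygotes plus null carriers that appear homozygous); blank `r^2`.
#' With `includeMissingAsBlanks = FALSE` (default) the likelihood is
#' conditioned on a visible genotype (class probabilities divided by
#' `1 - r^2`) and missing calls are ignored; with TRUE, missing calls are
#' treated as null homozygotes.
#'
#' The E-step splits observed homozygotes into true homozygotes and null
#' heterozygotes with posterior weight `p_i / (p_i + 2r)`, and (in the
#' conditional fit) imputes the expected number of unobserved blanks
#' `n r^2 / (1 - r^2)`; the M-step re-estimates p and r from the completed
#' counts. The observed-data log-likelihood is non-decreasing across
#' iterations.
#'
#' @param counts a `LocusCounts` from [tallyLocus()].
#' @param includeMissingAsBlanks treat missing calls as null homozygotes.
#' @param tol stop when the log-likelihood gain falls below this
#'   (default 1e-8).
#' @param maxIter iteration cap (default 10000).
#' @return list with `r` (null frequency estimate), `p` (named visible
#'   allele frequencies; `sum(p) + r == 1`), `loglik` (trace, one value per
#'   iteration), `converged`, `iterations`. NA result when fewer than two
#'   visible alleles.
#' @export
nullAlleleML <- function(counts, includeMissingAsBlanks = FALSE,
                         tol = 1e-8, maxIter = 10000L) {
  if (is.null(counts) || length(counts$alleles) < 2L)
    return(list(r = NA_real_, p = NULL, loglik = numeric(),
                converged = NA, iterations = 0L))
  alleles <- as.character(counts$alleles)
  k <- length(alleles)
  gc <- counts$genotypeCounts
  parts <- strsplit(names(gc), "/", fixed = TRUE)
  hom <- stats::setNames(numeric(k), alleles)
  hetA <- stats::setNames(numeric(k), alleles)  # allele copies in hets
  hetPairs <- list()
  for (g in seq_along(gc)) {
    p1 <- parts[[g]][1L]
    p2 <- parts[[g]][2L]
    if (p1 == p2) {
      hom[p1] <- hom[p1] + gc[g]
    } else {
      hetA[p1] <- hetA[p1] + gc[g]
      hetA[p2] <- hetA[p2] + gc[g]
      hetPairs[[length(hetPairs) + 1L]] <- c(p1, p2, gc[g])
    }
  }
  nVis <- counts$n
  b0 <- if (includeMissingAsBlanks) counts$nMissing else 0
  # observed-data log-likelihood
  ll <- function(p, r) {
    v <- 0
    for (hp in hetPairs)
      v <- v + as.numeric(hp[3L]) * log(2 * p[hp[1L]] * p[hp[2L]])
    pos <- hom > 0
    v <- v + sum(hom[pos] * log(p[pos] * (p[pos] + 2 * r)))
    if (includeMissingAsBlanks) {
      if (b0 > 0) v <- v + b0 * log(r^2)
    } else {
      v <- v - nVis * log1p(-r^2)
    }
    v
  }
  p <- counts$alleleCounts / (2 * nVis)
  r <- 0.05
  p <- p * (1 - r)
  trace <- numeric()
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    trace[it] <- ll(p, r)
    if (it > 1L && trace[it] - trace[it - 1L] < tol) {
      converged <- TRUE
      break
    }
    bExp <- if (includeMissingAsBlanks) b0 else nVis * r^2 / (1 - r^2)
    w <- ifelse(p + 2 * r > 0, p / (p + 2 * r), 1)
    tHom <- hom * w           # expected true homozygotes
    nullHet <- hom - tHom     # expected null/visible heterozygotes
    denom <- 2 * (nVis + bExp)
    pNew <- (2 * tHom + nullHet + hetA) / denom
    rNew <- (sum(nullHet) + 2 * bExp) / denom
    p <- pNew
    r <- rNew
  }
  # Boundary check: when there is no homozygote excess the MLE sits at
  # r = 0, which EM approaches only sublinearly. The r = 0 profile maximum
  # has p = sample allele frequencies; if it matches or beats the fitted
  # likelihood, report the boundary solution exactly.
  if (!(includeMissingAsBlanks && b0 > 0)) {
    p0 <- counts$alleleCounts / (2 * nVis)
    ll0 <- ll(p0, 0)
    if (is.finite(ll0) && ll0 >= trace[length(trace)] - 1e-10) {
      return(list(r = 0, p = p0,
                  loglik = c(trace, max(ll0, trace[length(trace)])),
                  converged = TRUE, iterations = length(trace)))
    }
  }
  list(r = max(r, 0), p = p, loglik = trace,
       converged = converged, iterations = length(trace))
}

#' Permutation G-test of genotypic disequilibrium
#'
#' Tests non-random association of genotypes at two loci within one sample.
#' Individuals missing either call are excluded; the statistic is the
#' log-likelihood-ratio G on the genotype x genotype contingency table, and
#' the null distribution is built by permuting one locus's genotype column
#' across individuals. `p = (1 + #{G_perm >= G_obs}) / (permutations + 1)`.
#'
#' @param x a [GenotypeMatrix-class].
#' @param locusA,locusB locus names or indices.
#' @param permutations number of permutations (default 10000).
#' @param seed optional integer seed.
#' @return list with `p`, `G`, `permutations`, `n` (individuals used); `p`
#'   is NA when either locus shows fewer than 2 distinct genotypes.
#' @export
genotypicLDTest <- function(x, locusA, locusB, permutations = 10000L,
                            seed = NULL) {
  ca <- genotypeCalls(x, locusA)
  cb <- genotypeCalls(x, locusB)
  ok <- !is.na(ca[, 1L]) & !is.na(cb[, 1L])
  ga <- paste(ca[ok, 1L], ca[ok, 2L], sep = "/")
  gb <- paste(cb[ok, 1L], cb[ok, 2L], sep = "/")
  fa <- as.integer(factor(ga))
  fb <- as.integer(factor(gb))
  ka <- max(fa, 0L)
  kb <- max(fb, 0L)
  if (length(fa) == 0L || ka < 2L || kb < 2L)
    return(list(p = NA_real_, G = NA_real_, permutations = permutations,
                n = sum(ok)))
  n <- length(fa)
  rowc <- tabulate(fa, ka)
  colc <- tabulate(fb, kb)
  loge <- log(outer(rowc, colc) / n)  # expected counts (log), fixed margins
  gstat <- function(fbv) {
    cnt <- tabulate((fa - 1L) * kb + fbv, nbins = ka * kb)
    pos <- cnt > 0L
    2 * sum(cnt[pos] * (log(cnt[pos]) - loge[pos]))
  }
  gObs <- gstat(fb)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(permutations)) {
    if (gstat(sample(fb)) >= gObs - 1e-12) hits <- hits + 1L
  }
  list(p = (1 + hits) / (permutations + 1), G = gObs,
       permutations = permutations, n = n)
}

#' Bonferroni correction
#'
#' Flags p-values significant at the Bonferroni-corrected threshold
#' alpha / k, where k counts the defined (non-NA) p-values.
#'
#' @param pvals numeric vector, may contain NA (skipped).
#' @param alpha nominal significance level (default 0.05).
#' @return list with `threshold`, `flags` (logical, NA where p undefined)
#'   and `k`.
#' @export
bonferroni <- function(pvals, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  k <- sum(!is.na(pvals))
  if (k == 0L)
    return(list(threshold = NA_real_, flags = rep(NA, length(pvals)),
                k = 0L))
  thr <- alpha / k
  list(threshold = thr, flags = pvals <= thr, k = k)
}

#' Per-locus summary statistics for one population sample
#'
#' Computes, for every locus of a [GenotypeMatrix-class], the sample size,
#' allele-size range, number of alleles (Na), observed and unbiased
#' expected heterozygosity, the exact Hardy-Weinberg p-value and the ML
#' null-allele frequency (both only for polymorphic loci), and a status
#' code: `"P"` polymorphic, `"M"` monomorphic, `"F"` failed (no scored
#' calls).
#'
#' @param x a [GenotypeMatrix-class].
#' @param hweMethod,mcReps,enumTableLimit passed to [hweExactTest()].
#' @param seed integer; per-locus seeds are derived from it so results do
#'   not depend on locus order.
#' @return data.frame with one row per locus: `locus`, `n`, `sizeMin`,
#'   `sizeMax`, `na`, `ho`, `he`, `pHWE`, `nullFreq`, `status`.
#' @export
locusStats <- function(x, hweMethod = "auto", mcReps = 1e5L,
                       enumTableLimit = 1e6L, seed = NULL) {
  loci <- lociNames(x)
  rows <- lapply(seq_along(loci), function(i) {
    cnt <- tallyLocus(x, loci[i])
    if (is.null(cnt)) {
      return(data.frame(locus = loci[i], n = 0L,
                        sizeMin = NA_integer_, sizeMax = NA_integer_,
                        na = NA_integer_, ho = NA_real_, he = NA_real_,
                        pHWE = NA_real_, nullFreq = NA_real_,
                        status = "F", stringsAsFactors = FALSE))
    }
    na <- length(cnt$alleles)
    poly <- na >= 2L
    pH <- NA_real_
    nf <- NA_real_
    if (poly) {
      locSeed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
      pH <- hweExactTest(cnt, method = hweMethod, mcReps = mcReps,
                         enumTableLimit = enumTableLimit,
                         seed = locSeed)$p
      nf <- nullAlleleML(cnt)$r
    }
    data.frame(locus = loci[i], n = cnt$n,
               sizeMin = min(cnt$alleles), sizeMax = max(cnt$alleles),
               na = na, ho = observedHet(cnt),
               he = if (cnt$n >= 2L) expectedHet(cnt) else NA_real_,
               pHWE = pH, nullFreq = nf,
               status = if (poly) "P" else "M",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
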