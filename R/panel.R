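#' Classify locus status from allele counts
#'
#' Maps per-locus allele counts to the status codes used in marker panel
#' grids: `"P"` (polymorphic, 2+ alleles), `"M"` (monomorphic, one allele),
#' `"F"` (failed: no allele count, i.e. the locus could not be genotyped in
#' that sample; printed as "-" in panel tables).
#'
#' @param na integer vector of allele counts; NA marks a failed locus.
#' @return character vector of "P"/"M"/"F".
#' @examples
#' classifyLocus(c(17, 1, NA))  # "P" "M" "F"
#' @export
classifyLocus <- function(na) {
  ifelse(is.na(na), "F", ifelse(na >= 2, "P", "M"))
}

#' Panel-level summary across species
#'
#' Assembles a marker-panel report from per-species locus statistics: a
#' locus x species status grid, per-species means and standard deviations
#' of Na / Ho / He over polymorphic loci only (monomorphic loci carry no
#' variability information and would dilute the panel description), the
#' allele-number range, and the number of loci transferable from the
#' source species (successfully genotyped, i.e. status P or M, in every
#' other species).
#'
#' @param statsBySpecies named list (species -> data.frame as returned by
#'   [locusStats()]; minimally columns `locus`, `na`, `ho`, `he`, and
#'   optionally `status` which otherwise is derived from `na`). A locus
#'   absent from a species' table is treated as failed there.
#' @param sourceSpecies label of the species the markers were developed
#'   in; transferability is assessed over the remaining species. NULL
#'   (default) requires success in all species.
#' @return list with `statusGrid` (data.frame locus x species),
#'   `perSpecies` (data.frame: species, nPolymorphic, nMonomorphic,
#'   nFailed, meanNa, sdNa, meanHo, sdHo, meanHe, sdHe, naMin, naMax) and
#'   `nTransferable`. SDs use the n-1 denominator.
#' @export
summarizePanel <- function(statsBySpecies, sourceSpecies = NULL) {
  species <- names(statsBySpecies)
  if (is.null(species) || any(!nzchar(species)))
    stop("statsBySpecies must be a named list")
  loci <- unique(unlist(lapply(statsBySpecies, `[[`, "locus")))
  grid <- data.frame(locus = loci, stringsAsFactors = FALSE)
  per <- list()
  for (sp in species) {
    st <- statsBySpecies[[sp]]
    i <- match(loci, st$locus)
    na <- st$na[i]
    status <- if ("status" %in% names(st)) st$status[i] else classifyLocus(na)
    status[is.na(status)] <- "F"
    grid[[sp]] <- status
    poly <- status == "P"
    naP <- na[poly]
    hoP <- st$ho[i][poly]
    heP <- st$he[i][poly]
    per[[sp]] <- data.frame(
      species = sp,
      nPolymorphic = sum(poly),
      nMonomorphic = sum(status == "M"),
      nFailed = sum(status == "F"),
      meanNa = mean(naP), sdNa = stats::sd(naP),
      meanHo = mean(hoP), sdHo = stats::sd(hoP),
      meanHe = mean(heP), sdHe = stats::sd(heP),
      naMin = if (any(poly)) min(naP) else NA_integer_,
      naMax = if (any(poly)) max(naP) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  target <- setdiff(species, sourceSpecies)
  okAll <- rep(TRUE, length(loci))
  for (sp in target) okAll <- okAll & grid[[sp]] != "F"
  list(statusGrid = grid,
       perSpecies = do.call(rbind, c(per, list(make.row.names = FALSE))),
       nTransferable = sum(okAll))
}

#' Full panel report from genotype matrices
#'
#' Runs [locusStats()] on each species sample and assembles the panel
#' summary, with Bonferroni flags on the Hardy-Weinberg p-values within
#' each species.
#'
#' @param matrices list of [GenotypeMatrix-class] objects (names default
#'   to their species labels).
#' @param sourceSpecies see [summarizePanel()].
#' @param alpha nominal significance level for the Bonferroni correction.
#' @param ... passed to [locusStats()] (hweMethod, mcReps, seed, ...).
#' @return list with `stats` (named list of per-species locus tables, each
#'   with an added `hweSignif` column), plus the [summarizePanel()]
#'   elements.
#' @export
panelReport <- function(matrices, sourceSpecies = NULL, alpha = 0.05, ...) {
  if (methods::is(matrices, "GenotypeMatrix"))
    matrices <- list(matrices)
  if (is.null(names(matrices)))
    names(matrices) <- vapply(matrices, speciesLabel, character(1L))
  stats <- lapply(matrices, locusStats, ...)
  for (sp in names(stats)) {
    bc <- bonferroni(stats[[sp]]$pHWE, alpha)
    stats[[sp]]$hweSignif <- bc$flags
  }
  c(list(stats = stats), summarizePanel(stats, sourceSpecies))
}
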