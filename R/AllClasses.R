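#' GenotypeMatrix: diploid microsatellite calls for one population sample
#'
#' Stores allele-size calls (integer base pairs) for a set of individuals
#' genotyped at a set of loci in a single population/species sample. Each
#' call is an unordered pair of allele codes; internally the pair is stored
#' sorted (smaller allele first) so that identical genotypes compare equal.
#' Missing calls are `NA` in both allele matrices, never the 0 code used on
#' disk by the Genepop format.
#'
#' Allele codes must fit the Genepop 3-digit convention (1..999); with
#' fragment-size alleles this means raw sizes below 1000 bp, which covers
#' capillary fragment analysis.
#'
#' @slot speciesLabel single character, the population/species label.
#' @slot individualIds character vector of row (individual) identifiers.
#' @slot lociNames character vector of column (locus) identifiers.
#' @slot allele1,allele2 integer matrices (individuals x loci) holding the
#'   smaller and larger allele of each call; `NA` in both marks a missing
#'   call.
#'
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  slots = c(
    speciesLabel  = "character",
    individualIds = "character",
    lociNames     = "character",
    allele1       = "matrix",
    allele2       = "matrix"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  a1 <- object@allele1
  a2 <- object@allele2
  ni <- length(object@individualIds)
  nl <- length(object@lociNames)
  if (length(object@speciesLabel) != 1L)
    msg <- c(msg, "speciesLabel must be a single string")
  if (!identical(dim(a1), c(ni, nl)) || !identical(dim(a2), c(ni, nl)))
    msg <- c(msg, "allele matrices must be individuals x loci")
  if (anyDuplicated(object@lociNames))
    msg <- c(msg, "locus names must be unique")
  if (anyDuplicated(object@individualIds))
    msg <- c(msg, "individual ids must be unique")
  if (!identical(is.na(a1), is.na(a2)))
    msg <- c(msg, "missing calls must be NA in both allele matrices")
  ok <- !is.na(a1)
  if (any(a1[ok] < 1L) || any(a2[ok] < 1L) ||
      any(a1[ok] > 999L) || any(a2[ok] > 999L))
    msg <- c(msg, "allele codes must lie in 1..999 (Genepop 3-digit coding)")
  if (any(a1[ok] > a2[ok]))
    msg <- c(msg, "allele pairs must be stored sorted (allele1 <= allele2)")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param allele1,allele2 numeric matrices (individuals x loci) of allele
#'   codes; the pair order per call is irrelevant (pairs are sorted on
#'   construction). Use `NA` in both for a missing call; if only one of the
#'   two is `NA` the whole call is set missing.
#' @param speciesLabel population/species label.
#' @param individualIds,lociNames identifiers; default to dimnames of
#'   `allele1` or generated names.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' a1 <- matrix(c(100, 100, 102, 104), 2, 2)
#' a2 <- matrix(c(102, 100, 102, 104), 2, 2)
#' gm <- GenotypeMatrix(a1, a2, speciesLabel = "sp1")
#' nInd(gm)
#' @export
GenotypeMatrix <- function(allele1, allele2, speciesLabel = "pop",
                           individualIds = NULL, lociNames = NULL) {
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  if (!identical(dim(allele1), dim(allele2)))
    stop("allele1 and allele2 must have identical dimensions")
  if (is.null(individualIds))
    individualIds <- rownames(allele1) %||%
      paste0("ind", seq_len(nrow(allele1)))
  if (is.null(lociNames))
    lociNames <- colnames(allele1) %||%
      paste0("locus", seq_len(ncol(allele1)))
  miss <- is.na(allele1) | is.na(allele2)
  lo <- pmin(allele1, allele2)
  hi <- pmax(allele1, allele2)
  lo[miss] <- NA
  hi[miss] <- NA
  storage.mode(lo) <- "integer"
  storage.mode(hi) <- "integer"
  dimnames(lo) <- dimnames(hi) <- list(individualIds, lociNames)
  methods::new("GenotypeMatrix",
    speciesLabel = as.character(speciesLabel),
    individualIds = as.character(individualIds),
    lociNames = as.character(lociNames),
    allele1 = lo, allele2 = hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
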