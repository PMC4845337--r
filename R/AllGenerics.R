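#' @name GenotypeMatrix-accessors
#' @title Accessors for GenotypeMatrix objects
#' @param x a [GenotypeMatrix-class] object.
#' @param locus a locus name or index.
#' @description `speciesLabel()`, `individualIds()`, `lociNames()`,
#'   `nInd()` and `nLoci()` return the corresponding slots/dimensions;
#'   `genotypeCalls()` returns the two-column matrix of sorted allele pairs
#'   for one locus (one row per individual, `NA` rows for missing calls).
NULL

#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("speciesLabel", function(x) standardGeneric("speciesLabel"))

#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))

#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname GenotypeMatrix-accessors
#' @export
setGeneric("genotypeCalls", function(x, locus) standardGeneric("genotypeCalls"))
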