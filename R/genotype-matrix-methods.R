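#' @rdname GenotypeMatrix-accessors
setMethod("speciesLabel", "GenotypeMatrix", function(x) x@speciesLabel)

#' @rdname GenotypeMatrix-accessors
setMethod("individualIds", "GenotypeMatrix", function(x) x@individualIds)

#' @rdname GenotypeMatrix-accessors
setMethod("lociNames", "GenotypeMatrix", function(x) x@lociNames)

#' @rdname GenotypeMatrix-accessors
setMethod("nInd", "GenotypeMatrix", function(x) length(x@individualIds))

#' @rdname GenotypeMatrix-accessors
setMethod("nLoci", "GenotypeMatrix", function(x) length(x@lociNames))

#' @rdname GenotypeMatrix-accessors
setMethod("genotypeCalls", "GenotypeMatrix", function(x, locus) {
  if (is.character(locus)) {
    if (!locus %in% x@lociNames)
      stop("unknown locus: ", locus)
  } else {
    locus <- x@lociNames[locus]
  }
  cbind(a1 = x@allele1[, locus], a2 = x@allele2[, locus])
})

setMethod("show", "GenotypeMatrix", function(object) {
  nmiss <- sum(is.na(object@allele1))
  cat("GenotypeMatrix: ", object@speciesLabel, "\n",
      "  ", length(object@individualIds), " individuals x ",
      length(object@lociNames), " loci; ",
      nmiss, " missing call(s)\n", sep = "")
  show_n <- min(5L, length(object@lociNames))
  if (show_n > 0L)
    cat("  loci: ", paste(utils::head(object@lociNames, show_n),
                          collapse = ", "),
        if (length(object@lociNames) > show_n) ", ..." else "", "\n",
        sep = "")
})
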