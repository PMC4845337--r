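#' Bin raw fragment sizes into integer alleles
#'
#' Capillary electrophoresis reports fragment sizes as non-integer values
#' that scatter around the true allele lengths. This binner clusters the
#' observed sizes by sorting them and opening a new bin whenever the gap
#' between consecutive sorted sizes exceeds `minGap`; each bin's centre is
#' the mean of its members rounded to the nearest integer, and every member
#' maps to that centre. With well-behaved data on a `repeatUnit` ladder,
#' `minGap = repeatUnit / 2` (the default) separates adjacent alleles.
#'
#' @param rawSizes numeric vector of observed fragment sizes (bp).
#' @param repeatUnit repeat unit length in bp (used for the default gap).
#' @param minGap gap (bp) that opens a new bin; default `repeatUnit / 2`.
#' @param locusName optional label stored in the map.
#' @return A `BinningMap`: list with `locusName`, `repeatUnit`, `minGap`,
#'   `binCenters` (sorted integers) and `rawToBinned` (data.frame with
#'   columns `raw`, `binned`, one row per distinct input size).
#' @examples
#' bm <- binAlleles(c(100.1, 100.3, 102.0, 102.2), repeatUnit = 2)
#' bm$binCenters
#' @export
binAlleles <- function(rawSizes, repeatUnit = 2L, minGap = repeatUnit / 2,
                       locusName = NA_character_) {
  if (length(rawSizes) == 0L) stop("rawSizes must be non-empty")
  if (!is.finite(minGap) || minGap <= 0) stop("minGap must be > 0")
  s <- sort(unique(as.numeric(rawSizes)))
  newBin <- c(TRUE, diff(s) > minGap)
  bin <- cumsum(newBin)
  centers <- as.integer(round(tapply(s, bin, mean)))
  map <- data.frame(raw = s, binned = centers[bin])
  structure(list(locusName = locusName,
                 repeatUnit = as.integer(repeatUnit),
                 minGap = minGap,
                 binCenters = unname(centers),
                 rawToBinned = map),
            class = "BinningMap")
}

#' Apply a binning map to fragment sizes
#'
#' Sizes seen when the map was built map to their bin; unseen sizes map to
#' the nearest bin centre (ties to the smaller centre, deterministically).
#'
#' @param map a `BinningMap` from [binAlleles()].
#' @param sizes numeric vector of fragment sizes; NA passes through.
#' @return integer vector of binned allele sizes.
#' @export
applyBinning <- function(map, sizes) {
  centers <- map$binCenters
  out <- rep(NA_integer_, length(sizes))
  ok <- !is.na(sizes)
  if (any(ok)) {
    hit <- match(sizes[ok], map$rawToBinned$raw)
    res <- map$rawToBinned$binned[hit]
    un <- is.na(hit)
    if (any(un)) {
      # nearest centre; midpoints assign ties to the smaller centre
      cuts <- (utils::head(centers, -1L) + utils::tail(centers, -1L)) / 2
      res[un] <- centers[findInterval(sizes[ok][un], cuts,
                                      left.open = TRUE) + 1L]
    }
    out[ok] <- as.integer(res)
  }
  out
}

#' @export
print.BinningMap <- function(x, ...) {
  cat("BinningMap", if (!is.na(x$locusName)) paste0("(", x$locusName, ")"),
      "\n  ", length(x$binCenters), " bin(s): ",
      paste(x$binCenters, collapse = ", "),
      "\n  repeat unit ", x$repeatUnit, " bp, min gap ", x$minGap,
      " bp\n", sep = "")
  invisible(x)
}
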