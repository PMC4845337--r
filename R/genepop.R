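#' Read a Genepop file
#'
#' Parses the standard Genepop text format: a title line, locus names (one
#' per line or comma-separated), then one `POP` block per population with
#' individual lines of the form `id ,  aabb aabb ...` using 2- or 3-digit
#' diploid allele coding. The coding width is detected from the data.
#' All-zero codes (`0000` / `000000`, and any call with a zero allele) are
#' read as missing. The species/population label of each block is taken
#' from the last whitespace-separated token of the block's first
#' individual id.
#'
#' @param file path to a Genepop file, or a character vector of lines
#'   (anything with more than one element is treated as lines).
#' @return list of [GenotypeMatrix-class] objects, one per POP block.
#' @export
readGenepop <- function(file) {
  lines <- if (length(file) > 1L || grepl("\n", file[1L], fixed = TRUE)) {
    unlist(strsplit(file, "\n", fixed = TRUE))
  } else {
    readLines(file)
  }
  lines <- sub("[\r]+$", "", lines)
  if (length(lines) < 3L)
    stop("Genepop format error: file too short")
  isPop <- toupper(trimws(lines)) == "POP"
  popAt <- which(isPop)
  if (length(popAt) == 0L)
    stop("Genepop format error: no POP line found")
  # locus names: lines 2 .. first POP - 1, possibly comma-separated
  locusLines <- trimws(lines[2:(popAt[1L] - 1L)])
  loci <- trimws(unlist(strsplit(locusLines[nzchar(locusLines)], ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L)
    stop("Genepop format error: no locus names before first POP")
  blocks <- Map(function(from, to) {
    idx <- seq(from + 1L, to)
    idx[nzchar(trimws(lines[idx]))]
  }, popAt, c(popAt[-1L] - 1L, length(lines)))
  width <- NULL
  lapply(blocks, function(idx) {
    if (length(idx) == 0L)
      stop("Genepop format error: empty POP block")
    n <- length(idx)
    a1 <- matrix(NA_integer_, n, length(loci))
    a2 <- matrix(NA_integer_, n, length(loci))
    ids <- character(n)
    for (r in seq_len(n)) {
      ln <- idx[r]
      parts <- strsplit(lines[ln], ",", fixed = TRUE)[[1L]]
      if (length(parts) < 2L)
        stop("Genepop format error at line ", ln,
             ": expected 'id , genotypes'")
      ids[r] <- trimws(parts[1L])
      toks <- strsplit(trimws(paste(parts[-1L], collapse = ",")),
                       "[[:space:]]+")[[1L]]
      if (length(toks) != length(loci))
        stop("Genepop format error at line ", ln, ": ", length(toks),
             " genotype(s) for ", length(loci), " loci")
      w <- nchar(toks)
      if (any(w != w[1L]) || !(w[1L] %in% c(4L, 6L)))
        stop("Genepop format error at line ", ln,
             ": allele strings must all be 4 or 6 digits")
      half <- w[1L] %/% 2L
      if (is.null(width)) width <<- half
      else if (width != half)
        stop("Genepop format error at line ", ln,
             ": mixed 2- and 3-digit coding")
      x1 <- as.integer(substr(toks, 1L, half))
      x2 <- as.integer(substr(toks, half + 1L, 2L * half))
      if (anyNA(x1) || anyNA(x2))
        stop("Genepop format error at line ", ln, ": non-numeric allele")
      miss <- x1 == 0L | x2 == 0L
      x1[miss] <- NA_integer_
      x2[miss] <- NA_integer_
      a1[r, ] <- x1
      a2[r, ] <- x2
    }
    label <- utils::tail(strsplit(ids[1L], "[[:space:]]+")[[1L]], 1L)
    GenotypeMatrix(a1, a2, speciesLabel = label,
                   individualIds = make.unique(ids), lociNames = loci)
  })
}

#' Write Genepop text
#'
#' Writes one or more [GenotypeMatrix-class] objects as a Genepop file with
#' 3-digit allele coding; missing calls become `000000`. Output is
#' deterministic (byte-stable for identical input).
#'
#' @param matrices a GenotypeMatrix or list of them (one POP block each);
#'   all must share the same loci in the same order.
#' @param file output path, or NULL to return the lines.
#' @param title title line content.
#' @return the lines invisibly (visibly when `file` is NULL).
#' @export
writeGenepop <- function(matrices, file = NULL,
                         title = "SSRpanel genotype export") {
  if (methods::is(matrices, "GenotypeMatrix"))
    matrices <- list(matrices)
  loci <- lociNames(matrices[[1L]])
  for (m in matrices) {
    if (!identical(lociNames(m), loci))
      stop("all matrices must share the same loci")
    ok <- !is.na(m@allele1)
    if (any(m@allele2[ok] > 999L))
      stop("allele code > 999 cannot be written in 3-digit coding")
  }
  out <- c(title, loci)
  for (m in matrices) {
    out <- c(out, "POP")
    a1 <- m@allele1
    a2 <- m@allele2
    for (r in seq_len(nInd(m))) {
      x1 <- a1[r, ]
      x2 <- a2[r, ]
      g <- sprintf("%03d%03d", ifelse(is.na(x1), 0L, x1),
                   ifelse(is.na(x2), 0L, x2))
      out <- c(out, paste0(individualIds(m)[r], " ,  ",
                           paste(g, collapse = " ")))
    }
  }
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}
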