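#' Run the marker-development workflow end to end
#'
#' Orchestrates the two tracks of the workflow. The discovery track
#' (given a FASTA of transcripts) mines SSRs, selects PALs and writes
#' `ssr.tsv`, `pal.tsv`, `pal_flanks.fasta` and `mining_summary.json`.
#' The characterization track (given a Genepop file, one POP block per
#' species) computes per-locus statistics and the panel summary and
#' writes `locus_stats.tsv`, `status_grid.tsv` and `panel_summary.json`.
#' Every run writes a `manifest.json` recording the package version,
#' parameters, input checksums, seed and timestamp; reruns with the same
#' inputs and seed produce identical report files.
#'
#' @param fastaFile path to transcript FASTA (discovery track), or NULL.
#' @param genepopFile path to a Genepop genotype file (characterization
#'   track), or NULL. At least one of the two must be given.
#' @param outDir output directory (created if absent).
#' @param minUnits,motifLenRange mining parameters (see [findSSRs()]).
#' @param minFlank,minUnitsPAL PAL parameters (see [selectPALs()]).
#' @param hweMethod,mcReps HWE test parameters (see [hweExactTest()]).
#' @param alpha nominal significance level.
#' @param sourceSpecies see [summarizePanel()].
#' @param seed integer seed for all stochastic steps.
#' @return invisibly, a named list of the files written.
#' @export
runPipeline <- function(fastaFile = NULL, genepopFile = NULL, outDir,
                        minUnits = 5L, motifLenRange = c(2L, 10L),
                        minFlank = 50L, minUnitsPAL = 8L,
                        hweMethod = "auto", mcReps = 1e5L, alpha = 0.05,
                        sourceSpecies = NULL, seed = 1L) {
  if (is.null(fastaFile) && is.null(genepopFile))
    stop("provide a FASTA (discovery) and/or a Genepop file ",
         "(characterization)")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  .log <- function(...) message(format(Sys.time(), "%H:%M:%OS1"),
                                " [INFO] ", ...)
  writeJson <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    path
  }
  if (!is.null(fastaFile)) {
    if (!file.exists(fastaFile))
      stop("input not found (discovery stage): ", fastaFile)
    .log("discovery: reading ", fastaFile)
    seqs <- Biostrings::readDNAStringSet(fastaFile)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    loci <- findSSRs(seqs, minUnits = minUnits,
                     motifLenRange = motifLenRange)
    .log("discovery: ", length(loci), " SSR loci in ", length(seqs),
         " transcripts")
    files$ssr <- writeSSRTable(loci, file.path(outDir, "ssr.tsv"))
    pals <- selectPALs(loci, seqs, minFlank = minFlank,
                       minUnitsPAL = minUnitsPAL)
    .log("discovery: ", length(pals), " PAL")
    writePALs(pals, file.path(outDir, "pal.tsv"),
              file.path(outDir, "pal_flanks.fasta"))
    files$pal <- file.path(outDir, "pal.tsv")
    files$palFlanks <- file.path(outDir, "pal_flanks.fasta")
    ms <- summarizeMining(seqs, loci)
    files$miningSummary <- writeJson(unclass(ms),
                                     file.path(outDir,
                                               "mining_summary.json"))
  }
  if (!is.null(genepopFile)) {
    if (!file.exists(genepopFile))
      stop("input not found (characterization stage): ", genepopFile)
    .log("characterization: reading ", genepopFile)
    mats <- readGenepop(genepopFile)
    names(mats) <- vapply(mats, speciesLabel, character(1L))
    rep <- panelReport(mats, sourceSpecies = sourceSpecies, alpha = alpha,
                       hweMethod = hweMethod, mcReps = mcReps, seed = seed)
    .log("characterization: ", length(mats), " population(s), ",
         nrow(rep$statusGrid), " loci")
    allStats <- do.call(rbind, Map(function(sp, st) {
      cbind(species = sp, st, stringsAsFactors = FALSE)
    }, names(rep$stats), rep$stats))
    files$locusStats <- file.path(outDir, "locus_stats.tsv")
    utils::write.table(allStats, files$locusStats, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files$statusGrid <- file.path(outDir, "status_grid.tsv")
    utils::write.table(rep$statusGrid, files$statusGrid, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files$panelSummary <- writeJson(
      list(perSpecies = rep$perSpecies,
           nTransferable = rep$nTransferable,
           sourceSpecies = sourceSpecies,
           alpha = alpha),
      file.path(outDir, "panel_summary.json"))
  }
  inputs <- c(fasta = fastaFile, genepop = genepopFile)
  manifest <- list(
    tool = "SSRpanel",
    version = as.character(utils::packageVersion("SSRpanel")),
    parameters = list(minUnits = minUnits,
                      motifLenRange = motifLenRange,
                      minFlank = minFlank, minUnitsPAL = minUnitsPAL,
                      hweMethod = hweMethod, mcReps = mcReps,
                      alpha = alpha, sourceSpecies = sourceSpecies),
    seed = seed,
    inputs = lapply(inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  files$manifest <- writeJson(manifest, file.path(outDir, "manifest.json"))
  invisible(files)
}
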