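# End-to-end orchestration of the synthetic screen pipeline with a
# single config object, stage manifests and resumable reruns.

#' Pipeline configuration with protocol defaults
#'
#' Aggregates every stage parameter at its protocol default: 51-nt tiles
#' stepping 15 nt (17-aa peptides, 36-nt overlaps), per-bin
#' normalization to 1e6 reads, single-mismatch matching, 50-read
#' training filter, PSI label thresholds 2.2 / 2.8, ridge lambda 0.001,
#' 5-residue running median, degron cutoff 0.85 and 1.4-A ASA probe.
#' Overrides are supplied as named arguments; unknown names error.
#'
#' @param ... Named overrides of the defaults.
#' @param sim A [simConfig()] for the simulation stage.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(..., sim = simConfig()) {
  cfg <- list(
    tile_nt = 51L, step_nt = 15L, peptide_len = 17L,
    anchor_final = FALSE,
    flank5 = DEFAULT_FLANK5, flank3 = DEFAULT_FLANK3,
    normalize_total = 1e6, max_mismatch = 1L, ambiguous = "drop",
    min_reads = 50L, psi_lo = 2.2, psi_hi = 2.8,
    lambda = 0.001, feature_mode = "counts",
    smoothing_window = 5L, track = "coverage-mean",
    cutoff = 0.85, min_degron_length = 1L,
    probe_radius = 1.4, n_sphere_points = 960L,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$sim <- sim
  structure(cfg, class = "PipelineConfig")
}

#' Write / read a pipeline config as YAML
#'
#' Round-trips losslessly (the nested sim config included).
#' @param cfg A [pipelineConfig()].
#' @param path YAML path.
#' @return Invisibly `path`; `readPipelineConfig()` returns the config.
#' @export
writePipelineConfig <- function(cfg, path) {
  x <- unclass(cfg)
  x$sim <- unclass(x$sim)
  x$sim$trueWeights <- as.list(x$sim$trueWeights)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  simArgs <- x$sim
  simArgs$trueWeights <- unlist(simArgs$trueWeights)
  sim <- do.call(simConfig, simArgs)
  x$sim <- NULL
  do.call(pipelineConfig, c(x, list(sim = sim)))
}

#' Run the full synthetic-screen pipeline
#'
#' Stages: `simulate` (proteome, tiles, bin counts, reads) -> `count`
#' (trim, match, normalize) -> `psi` (peptide PSI + residue tracks) ->
#' `train` (ridge logistic degron model) -> `predict` (proteome scan +
#' degron calls) -> `features` (hydropathy report). Each stage writes
#' its outputs under `dir` and a `manifest.json` records parameters and
#' output checksums. With `resume = TRUE`, stages whose outputs already
#' exist are skipped until the first missing output, after which all
#' downstream stages are rerun.
#'
#' @param cfg A [pipelineConfig()].
#' @param dir Run directory.
#' @param resume Skip up-to-date leading stages.
#' @param emitRawReads Emit and re-count raw per-bin reads (the full
#'   sequencing path); if `FALSE` the simulator's count table is used
#'   directly.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(cfg = pipelineConfig(), dir, resume = FALSE,
                        emitRawReads = TRUE) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stageOut <- list(
    simulate = c("library_tiles.tsv", "ground_truth.tsv",
                 "sim_counts.tsv", "proteome.fasta"),
    count = "counts.tsv",
    psi = c("psi.tsv", "residue_tracks.tsv"),
    train = "model.json",
    predict = c("scan.tsv", "degron_calls.tsv"),
    features = "hydropathy.tsv")
  done <- function(stage)
    all(file.exists(file.path(dir, stageOut[[stage]])))
  todo <- names(stageOut)
  if (resume) {
    while (length(todo) && done(todo[1])) todo <- todo[-1]
  }
  res <- list()
  runStage <- function(stage, fn) {
    if (!stage %in% todo) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      rec <- list(stage = stage, error = conditionMessage(e))
      jsonlite::write_json(rec, file.path(dir, "error.json"),
                           auto_unbox = TRUE)
      stop("pipeline stage '", stage, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }

  runStage("simulate", function() {
    cds <- generateProteome(cfg$sim)
    tiles <- tileLibrary(cds, cfg$tile_nt, cfg$step_nt, cfg$anchor_final,
                         skipShort = TRUE)
    sim <- simulateBins(tiles, cfg$sim)
    writeTileManifest(tiles, file.path(dir, "library_tiles.tsv"))
    write.table(as.data.frame(sim$truth),
                file.path(dir, "ground_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeCountTable(sim$counts, file.path(dir, "sim_counts.tsv"))
    aa <- attr(cds, "aa")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(aa),
                                file.path(dir, "proteome.fasta"))
    res$tiles <<- tiles; res$sim <<- sim; res$proteome <<- aa
  })
  if (is.null(res$tiles)) {
    res$tiles <- readTileManifest(file.path(dir, "library_tiles.tsv"))
    res$sim <- list(counts = readCountTable(file.path(dir, "sim_counts.tsv")))
    aa <- Biostrings::readAAStringSet(file.path(dir, "proteome.fasta"))
    res$proteome <- setNames(as.character(aa), names(aa))
  }

  runStage("count", function() {
    counts <- if (emitRawReads) {
      reads <- emitReads(res$sim$counts, res$tiles, cfg$sim)
      idx <- buildMatchIndex(res$tiles)
      countBins(reads, idx, trim = list(anchor = cfg$flank5),
                policy = cfg$ambiguous)
    } else res$sim$counts
    counts <- normalizeBins(counts)
    writeCountTable(counts, file.path(dir, "counts.tsv"))
    res$counts <<- counts
  })
  if (is.null(res$counts))
    res$counts <- readCountTable(file.path(dir, "counts.tsv"))

  runStage("psi", function() {
    psis <- psiTable(res$counts)
    writePsiTable(psis, file.path(dir, "psi.tsv"))
    tracks <- residueProfiles(psis, res$tiles, cfg$track,
                              cfg$smoothing_window)
    writeResidueProfiles(tracks, file.path(dir, "residue_tracks.tsv"))
    res$psis <<- psis; res$tracks <<- tracks
  })
  if (is.null(res$psis))
    res$psis <- as(read.table(file.path(dir, "psi.tsv"), header = TRUE,
                              sep = "\t",
                              colClasses = c(peptide_id = "character",
                                             protein_id = "character")),
                   "DataFrame")

  runStage("train", function() {
    ts <- buildTrainingSet(res$psis, tilePeptides(res$tiles),
                           cfg$min_reads, cfg$psi_lo, cfg$psi_hi)
    model <- trainDegronModel(ts, cfg$lambda, cfg$feature_mode)
    writeDegronModel(model, file.path(dir, "model.json"))
    res$model <<- model
  })
  if (is.null(res$model))
    res$model <- readDegronModel(file.path(dir, "model.json"))

  runStage("predict", function() {
    scan <- scanProteome(res$model, res$proteome, cfg$cutoff,
                         cfg$min_degron_length)
    write.table(as.data.frame(scan$profiles), file.path(dir, "scan.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeDegronCalls(scan$calls, file.path(dir, "degron_calls.tsv"))
    res$scan <<- scan
  })

  runStage("features", function() {
    hv <- hydropathyVsProbability(tilePeptides(res$tiles), res$model)
    write.table(hv, file.path(dir, "hydropathy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res$hydropathy <<- hv
    res$spearman <<- attr(hv, "spearman")
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("degronScan")),
    parameters = unclass(cfg)[setdiff(names(unclass(cfg)), "sim")],
    sim = lapply(unclass(cfg$sim), function(x)
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x),
    outputs = local({
      fs <- unlist(stageOut, use.names = FALSE)
      fs <- fs[file.exists(file.path(dir, fs))]
      setNames(as.list(unname(tools::md5sum(file.path(dir, fs)))), fs)
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
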