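# Pipeline orchestration: a single config drives simulate -> (render/extract)
# -> detect -> kinetics, with CSV/JSON artifacts and a reproducibility
# manifest.

.allowedKeys <- list(
  top = c("seed", "output_dir", "log_level", "simulation", "camera",
          "step_detection", "analysis", "pipeline"),
  simulation = c("n_molecules", "duration_s", "frame_interval_s", "mode",
                 "k_close", "k_open", "p_uncoupled", "sync_jitter_frames",
                 "k_bleach_green", "k_bleach_red", "o2_application_s",
                 "dspo_mean_delay_s"),
  camera = c("image_size", "pixel_size_nm", "psf_sigma_px",
             "photons_per_frame_open", "background_photons", "read_noise",
             "gain"),
  step_detection = c("smooth_sigma_frames", "scales", "threshold_c",
                     "min_separation_frames", "min_relative_amplitude"),
  analysis = c("sync_window_frames", "bleach_tail_policy", "model_selection"),
  pipeline = c("use_images", "roi_half_width_px", "coloc_tol_px",
               "n_beads", "shot_noise"))

.checkKeys <- function(block, name) {
  if (is.null(block)) return(invisible())
  bad <- setdiff(names(block), .allowedKeys[[name]])
  if (length(bad))
    stop(sprintf("unknown key(s) in '%s' config block: %s", name,
                 paste(bad, collapse = ", ")))
}

.mergeArgs <- function(block, map) {
  args <- list()
  for (key in names(map)) if (!is.null(block[[key]])) args[[map[[key]]]] <- block[[key]]
  args
}

#' Validate a pipeline configuration and build the typed config objects
#'
#' Unknown keys anywhere in the configuration are rejected before any stage
#' runs; value constraints are enforced by the validity methods of the
#' underlying S4 config classes.
#'
#' @param config nested list, e.g. from \code{\link{readPipelineConfig}}.
#' @return list with elements \code{sim} (\linkS4class{SimulationConfig}),
#'   \code{camera}, \code{step} (\linkS4class{StepDetectionConfig}),
#'   \code{analysis} (\linkS4class{AnalysisConfig}), \code{pipeline} (list),
#'   \code{seed}, \code{logLevel}.
#' @export
validatePipelineConfig <- function(config) {
  .checkKeys(config, "top")
  for (b in c("simulation", "camera", "step_detection", "analysis",
              "pipeline"))
    .checkKeys(config[[b]], b)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  simArgs <- .mergeArgs(config$simulation, list(
    n_molecules = "nMolecules", duration_s = "durationS",
    frame_interval_s = "frameIntervalS", mode = "mode", k_close = "kClose",
    k_open = "kOpen", p_uncoupled = "pUncoupled",
    sync_jitter_frames = "syncJitterFrames",
    k_bleach_green = "kBleachGreen", k_bleach_red = "kBleachRed",
    o2_application_s = "o2ApplicationS", dspo_mean_delay_s = "dspoMeanDelayS"))
  simArgs$seed <- seed
  sim <- do.call(SimulationConfig, simArgs)
  camera <- do.call(CameraModel, .mergeArgs(config$camera, list(
    image_size = "imageSize", pixel_size_nm = "pixelSizeNm",
    psf_sigma_px = "psfSigmaPx",
    photons_per_frame_open = "photonsPerFrameOpen",
    background_photons = "backgroundPhotons", read_noise = "readNoise",
    gain = "gain")))
  step <- do.call(StepDetectionConfig, .mergeArgs(config$step_detection, list(
    smooth_sigma_frames = "smoothSigmaFrames", scales = "scales",
    threshold_c = "thresholdC", min_separation_frames = "minSeparationFrames",
    min_relative_amplitude = "minRelativeAmplitude")))
  anArgs <- .mergeArgs(config$analysis, list(
    sync_window_frames = "syncWindowFrames",
    bleach_tail_policy = "bleachTailPolicy",
    model_selection = "modelSelection"))
  anArgs$frameIntervalS <- sim@frameIntervalS
  if (sim@mode == "ampnp_onecolour") anArgs$o2ApplicationS <- sim@o2ApplicationS
  analysis <- do.call(AnalysisConfig, anArgs)
  pl <- config$pipeline
  pipeline <- list(
    useImages = isTRUE(pl$use_images),
    roiHalfWidthPx = if (!is.null(pl$roi_half_width_px))
      as.integer(pl$roi_half_width_px) else 3L,
    colocTolPx = if (!is.null(pl$coloc_tol_px)) pl$coloc_tol_px else 2,
    nBeads = if (!is.null(pl$n_beads)) as.integer(pl$n_beads) else 12L,
    shotNoise = if (!is.null(pl$shot_noise)) isTRUE(pl$shot_noise) else TRUE)
  list(sim = sim, camera = camera, step = step, analysis = analysis,
       pipeline = pipeline, seed = seed,
       logLevel = if (!is.null(config$log_level)) config$log_level else "info",
       outputDir = config$output_dir)
}

#' Read a pipeline YAML configuration
#'
#' @param path YAML file mirroring the simulation / camera / step_detection
#'   / analysis / pipeline blocks.
#' @return the validated config (see \code{\link{validatePipelineConfig}}).
#' @export
readPipelineConfig <- function(path) {
  validatePipelineConfig(yaml::read_yaml(path))
}

.stageLog <- function(logLevel, stage, ...) {
  if (identical(logLevel, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, paste0(...)))
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

.kineticsJson <- function(kin, nMolecules) {
  perCh <- lapply(kin@perChannel, function(x) {
    fitJson <- function(f) if (is.null(f)) NULL else
      list(amplitudes = f@amplitudes, taus_s = f@taus,
           n_components = f@nComponents, rss = f@rss, bic = f@bic,
           n_dwells = f@nDwells)
    list(open_fit = fitJson(x$openFit), closed_fit = fitJson(x$closedFit),
         k_c_per_min = x$kC, k_o_per_min = x$kO,
         n_open_dwells = x$nOpen, n_closed_dwells = x$nClosed)
  })
  list(n_molecules = nMolecules,
       counts = list(synchronous = kin@nSynchronous,
                     non_synchronous = kin@nNonSynchronous),
       percent_non_synchronous = list(
         ratio_to_synchronous = kin@percentNonSyncRatio,
         fraction_of_total = kin@percentNonSyncTotal),
       k_c_per_min = kin@kC, k_o_per_min = kin@kO,
       per_channel = perCh)
}

#' Run the full simulate-to-kinetics pipeline
#'
#' Executes the stages in order — simulation, trace generation (direct
#' trace rendering by default; via image stacks, localization,
#' registration and ROI extraction when \code{pipeline$use_images}), step
#' detection and kinetic analysis — writing CSV/JSON artifacts and a run
#' manifest with file checksums. Identical config + seed reproduces
#' identical checksums.
#'
#' @param config a raw nested list, a YAML path, or the result of
#'   \code{\link{validatePipelineConfig}}.
#' @param outDir output directory (created if absent); defaults to the
#'   config's \code{output_dir}.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  if (!is.list(config) || !methods::is(config[["sim"]], "SimulationConfig"))
    config <- validatePipelineConfig(config)
  if (is.null(outDir)) outDir <- config[["outputDir"]]
  if (is.null(outDir)) stop("no output directory given")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  lg <- config$logLevel
  times <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  .stageLog(lg, "simulate", "drawing ", config$sim@nMolecules,
            " clamp trajectories (mode ", config$sim@mode, ")")
  traj <- simulateClampTrajectories(config$sim)
  writeEventLog(traj, file.path(outDir, "ground_truth_events.json"))
  times["simulate"] <- tic() - t0

  t0 <- tic()
  if (config$pipeline$useImages) {
    .stageLog(lg, "render", "rendering image stacks and bead frames")
    stack <- renderImageStack(traj, config$camera, seed = config$seed + 1L)
    beads <- makeBeadFrames(config$pipeline$nBeads, config$camera,
                            seed = config$seed + 2L)
    .stageLog(lg, "extract", "localizing, registering, extracting traces")
    b1 <- detectSpots(beads$green, 5, config$camera@psfSigmaPx)
    b2 <- detectSpots(beads$red, 5, config$camera@psfSigmaPx)
    transform <- registerChannels(b1, b2)
    writeTransform(transform, file.path(outDir, "transform.json"))
    ref1 <- detectSpots(maxProjection(stack$stacks[[1L]]), 5,
                        config$camera@psfSigmaPx)
    ref2 <- detectSpots(maxProjection(stack$stacks[[2L]]), 5,
                        config$camera@psfSigmaPx)
    rois <- colocalize(ref1, ref2, transform, config$pipeline$colocTolPx)
    utils::write.csv(rois, file.path(outDir, "rois.csv"), row.names = FALSE)
    traces <- extractTraces(stack$stacks, rois,
                            config$pipeline$roiHalfWidthPx,
                            config$sim@frameIntervalS)
  } else {
    .stageLog(lg, "render", "rendering intensity traces (trace-level path)")
    traces <- renderTraces(traj, config$camera, seed = config$seed + 1L,
                           shotNoise = config$pipeline$shotNoise)
  }
  writeTraces(traces, file.path(outDir, "traces.csv"))
  times["traces"] <- tic() - t0

  t0 <- tic()
  .stageLog(lg, "detect", "idealizing traces (multiscale-product detector)")
  ideal <- idealizeTraces(traces, config$step)
  utils::write.csv(ideal$steps, file.path(outDir, "steps.csv"),
                   row.names = FALSE)
  times["detect"] <- tic() - t0

  t0 <- tic()
  .stageLog(lg, "kinetics", "classifying transitions and fitting dwells")
  if (config$sim@mode == "ampnp_onecolour") {
    pet <- identifyPetEvents(ideal$steps, config$sim@o2ApplicationS,
                             config$sim@frameIntervalS, config$sim@durationS)
    utils::write.csv(pet, file.path(outDir, "pet_events.csv"),
                     row.names = FALSE)
    kinJson <- list(
      n_molecules = config$sim@nMolecules,
      n_quench_events = nrow(pet),
      n_pet_confirmed = sum(pet$pet_confirmed),
      percent_pet_confirmed = if (nrow(pet)) 100 * mean(pet$pet_confirmed)
                              else NA_real_)
  } else {
    # molecules with a flagged (no-signal) channel are excluded, as in the
    # experimental two-colour co-localization selection
    bad <- unique(ideal$flagged$molecule_id[ideal$flagged$flagged])
    steps <- ideal$steps[!ideal$steps$molecule_id %in% bad, , drop = FALSE]
    events <- classifyTransitions(steps, config$analysis)
    utils::write.csv(events, file.path(outDir, "events.csv"),
                     row.names = FALSE)
    dwells <- extractDwells(steps, ideal$nFrames, config$analysis, events)
    utils::write.csv(dwells, file.path(outDir, "dwells.csv"),
                     row.names = FALSE)
    kin <- analyzeKinetics(steps, ideal$nFrames, config$analysis)
    kinJson <- .kineticsJson(kin, config$sim@nMolecules)
  }
  jsonlite::write_json(kinJson, file.path(outDir, "kinetics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  times["kinetics"] <- tic() - t0

  files <- list.files(outDir, pattern = "\\.(csv|json)$", full.names = TRUE)
  files <- setdiff(files, file.path(outDir, "manifest.json"))
  checksums <- as.list(tools::md5sum(files))
  names(checksums) <- basename(files)
  slotsOf <- function(obj) {
    sn <- methods::slotNames(class(obj))
    stats::setNames(lapply(sn, function(s) methods::slot(obj, s)), sn)
  }
  manifest <- list(
    config_hash = .configHash(list(
      seed = config$seed, simulation = slotsOf(config$sim),
      camera = slotsOf(config$camera), step = slotsOf(config$step),
      analysis = slotsOf(config$analysis), pipeline = config$pipeline)),
    package_version = as.character(utils::packageVersion("smPET")),
    stage_seconds = as.list(round(times, 3)),
    file_md5 = checksums)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .stageLog(lg, "done", "artifacts written to ", outDir)
  invisible(manifest)
}

.bootstrapRates <- function(dwells, channel, B = 200L, seed = 1L) {
  d <- dwells[dwells$channel == channel & !dwells$left_censored &
              !dwells$right_censored, ]
  mols <- unique(d$molecule_id)
  if (length(mols) < 3L) return(c(kC = NA_real_, kO = NA_real_))
  rateOf <- function(dd, state) {
    x <- dd$duration_s[dd$state == state]
    if (length(x) < 10L) return(NA_real_)
    60 / mean(x)      # mono-exponential amplitude-weighted mean rate
  }
  res <- .withSeed(seed, {
    vapply(seq_len(B), function(b) {
      pick <- sample(mols, length(mols), replace = TRUE)
      dd <- do.call(rbind, lapply(pick, function(m) d[d$molecule_id == m, ]))
      c(rateOf(dd, "open"), rateOf(dd, "closed"))
    }, numeric(2L))
  })
  c(kC = stats::sd(res[1L, ], na.rm = TRUE),
    kO = stats::sd(res[2L, ], na.rm = TRUE))
}

#' Summarize a pipeline results directory
#'
#' Builds the per-construct summary table (transition counts, both
#' non-synchronous-percentage conventions, per-colour rate constants with
#' bootstrap standard deviations over molecules) and writes cumulative-sum
#' plots with fitted curves plus their underlying plot data as CSV.
#'
#' @param resultsDir directory written by \code{\link{runPipeline}}.
#' @param bootstrapB number of bootstrap resamples over molecules.
#' @param seed RNG seed for the bootstrap.
#' @param makePlots logical; write cumulative-sum plot files.
#' @return list with \code{table} (data.frame) and \code{plotFiles}.
#' @export
pipelineReport <- function(resultsDir, bootstrapB = 200L, seed = 1L,
                           makePlots = TRUE) {
  kinPath <- file.path(resultsDir, "kinetics.json")
  dwPath <- file.path(resultsDir, "dwells.csv")
  missing <- c(kinPath, dwPath)[!file.exists(c(kinPath, dwPath))]
  if (length(missing))
    stop("missing pipeline outputs: ", paste(basename(missing),
                                             collapse = ", "))
  kin <- jsonlite::read_json(kinPath, simplifyVector = TRUE)
  dwells <- utils::read.csv(dwPath)
  chans <- names(kin$per_channel)
  rows <- list(); plotFiles <- character(0)
  fmt <- function(x, sdx) {
    if (is.null(x) || !length(x) || !is.finite(x)) return("n/a")
    if (is.finite(sdx)) sprintf("%.3g +/- %.2g", x, sdx) else sprintf("%.3g", x)
  }
  for (ch in chans) {
    sds <- .bootstrapRates(dwells, ch, B = bootstrapB, seed = seed)
    pc <- kin$per_channel[[ch]]
    rows[[ch]] <- data.frame(
      channel = ch,
      n_synchronous = kin$counts$synchronous,
      n_non_synchronous = kin$counts$non_synchronous,
      pct_ns_ratio = round(kin$percent_non_synchronous$ratio_to_synchronous, 1),
      pct_ns_total = round(kin$percent_non_synchronous$fraction_of_total, 1),
      k_c_per_min = fmt(pc$k_c_per_min, sds["kC"]),
      k_o_per_min = fmt(pc$k_o_per_min, sds["kO"]),
      stringsAsFactors = FALSE)
    if (!any(is.finite(c(pc$k_c_per_min, pc$k_o_per_min))))
      warning("no rate constants available for channel ", ch)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  utils::write.csv(tab, file.path(resultsDir, "summary_table.csv"),
                   row.names = FALSE)
  if (makePlots) {
    ok <- !dwells$left_censored & !dwells$right_censored
    for (state in c("open", "closed")) {
      d <- dwells$duration_s[ok & dwells$state == state]
      if (length(d) < 2L) {
        warning("no uncensored ", state, " dwells to plot")
        next
      }
      curve <- dwellCumSum(d)
      fit <- tryCatch(fitExponentialCdf(curve, "bic"), error = function(e) NULL)
      tGrid <- seq(0, max(curve$duration), length.out = 200L)
      fitted <- if (!is.null(fit))
        length(d) * rowSums(sapply(seq_along(fit@taus), function(i)
          fit@amplitudes[i] * (1 - exp(-tGrid / fit@taus[i]))))
      else rep(NA_real_, length(tGrid))
      pdat <- data.frame(t = tGrid, fitted = fitted)
      utils::write.csv(curve,
                       file.path(resultsDir,
                                 sprintf("cumsum_%s_data.csv", state)),
                       row.names = FALSE)
      utils::write.csv(pdat,
                       file.path(resultsDir,
                                 sprintf("cumsum_%s_fit.csv", state)),
                       row.names = FALSE)
      p <- ggplot2::ggplot(curve, ggplot2::aes(x = duration, y = count)) +
        ggplot2::geom_step() +
        ggplot2::geom_line(data = pdat,
                           ggplot2::aes(x = t, y = fitted),
                           colour = "cyan3", na.rm = TRUE) +
        ggplot2::labs(x = "dwell time (s)", y = "cumulative count",
                      title = sprintf("%s-state dwell times", state)) +
        ggplot2::theme_classic()
      pf <- file.path(resultsDir, sprintf("cumsum_%s.pdf", state))
      ggplot2::ggsave(pf, p, width = 5, height = 4)
      plotFiles <- c(plotFiles, pf)
    }
  }
  list(table = tab, plotFiles = plotFiles)
}
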