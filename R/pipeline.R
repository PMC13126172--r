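## Pipeline orchestration: a single entry point that runs the analysis
## stages in dependency order from a YAML config, with seeds, logging,
## a resolved-config snapshot and a machine-readable JSON report.

pipelineStages <- c("simulate", "fit-binding", "reduce", "phase",
                    "profile", "water", "shells")

#' Validate a pipeline run configuration
#'
#' The config is a plain list (usually read from YAML): required keys are
#' \code{stages} (subset of simulate, fit-binding, reduce, phase, profile,
#' water, shells), \code{outdir} and \code{seed}. Physical quantities carry
#' explicit unit suffixes in their key names (e.g.
#' \code{peptide_conc_umol_per_L}, \code{d_angstrom}).
#'
#' @param config list, or path to a YAML file.
#' @return the validated config list (with defaults filled in).
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path", call. = FALSE)
  if (is.null(config$stages) || !length(config$stages))
    stop("config key 'stages' must list at least one stage", call. = FALSE)
  bad <- setdiff(config$stages, pipelineStages)
  if (length(bad))
    stop("config key 'stages' has unknown stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  config$seed <- config$seed %||% 1L
  if (!is.numeric(config$seed) || length(config$seed) != 1)
    stop("config key 'seed' must be a single integer", call. = FALSE)
  config$outdir <- config$outdir %||% stop("config key 'outdir' is required",
                                           call. = FALSE)
  config$log_level <- config$log_level %||% "info"
  ## order stages by dependency
  config$stages <- pipelineStages[pipelineStages %in% config$stages]
  config
}

pipeLog <- function(state, level, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), msg)
  cat(line, "\n", file = state$logCon, append = TRUE)
  if (state$logLevel != "quiet") message(line)
  invisible(NULL)
}

#' Run the analysis pipeline from a config
#'
#' Executes the requested stages in dependency order
#' (simulate -> fit-binding | reduce -> phase -> profile -> water | shells),
#' writing per-stage outputs, a resolved-config snapshot, a timestamped log
#' (with package version, seeds and input checksums) and an aggregated JSON
#' report to the output directory. Reruns from the snapshot reproduce
#' outputs bit-for-bit for deterministic stages.
#'
#' Simulate presets: \code{popc-titration}, \code{pops-titration} (Langmuir
#' titrations with the corresponding planted parameters),
#' \code{nd-contrast} (H2O/2H2O contrast series, labeled + unlabeled),
#' \code{xrd-two-phase} (superposed lattices), \code{shells} (hydration
#' frames). Outputs are written in exactly the formats the analysis stages
#' read.
#'
#' @param config list or YAML path, see \code{\link{validateRunConfig}}.
#' @return invisibly, the report list; component \code{ok} is FALSE when any
#'   stage raised a fatal flag.
#' @export
runPipeline <- function(config) {
  config <- validateRunConfig(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  state$logCon <- file.path(config$outdir, "run.log")
  cat("", file = state$logCon)
  state$logLevel <- config$log_level
  report <- list(package_version = as.character(utils::packageVersion("lamellar")),
                 seed = config$seed, stages = list(), flags = character(),
                 ok = TRUE)
  yaml::write_yaml(config, file.path(config$outdir, "config.resolved.yaml"))
  pipeLog(state, "info", sprintf("lamellar %s, seed %d, stages: %s",
                                 report$package_version, config$seed,
                                 paste(config$stages, collapse = ", ")))
  for (f in unlist(config[c("inputs")], use.names = FALSE)) {
    if (is.character(f) && file.exists(f))
      pipeLog(state, "info", sprintf("input %s md5 %s", f, tools::md5sum(f)[[1]]))
  }

  for (stage in config$stages) {
    pipeLog(state, "info", paste("stage:", stage))
    res <- switch(stage,
      "simulate" = stageSimulate(config, state),
      "fit-binding" = stageFitBinding(config, state),
      "reduce" = stageReduce(config, state),
      "phase" = stagePhase(config, state),
      "profile" = stageProfile(config, state),
      "water" = stageWater(config, state),
      "shells" = stageShells(config, state))
    report$stages[[stage]] <- res$report
    report$flags <- c(report$flags, res$flags)
    if (isTRUE(res$fatal)) {
      report$ok <- FALSE
      pipeLog(state, "error", paste("fatal flag in stage", stage))
    }
  }
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipeLog(state, "info", "done")
  invisible(report)
}

titrationPresets <- list(
  "popc-titration" = list(kd = 11.2e-6, n = 19, nmreMax = 14.7),
  "pops-titration" = list(kd = 1.9e-6, n = 25, nmreMax = 13.0)
)

stageSimulate <- function(config, state) {
  sim <- config$simulate %||% list()
  preset <- sim$preset %||% "popc-titration"
  seed <- as.integer(sim$seed %||% config$seed)
  out <- list()
  if (preset %in% names(titrationPresets)) {
    tp <- titrationPresets[[preset]]
    truth <- bindingParameters(tp$kd, tp$n, tp$nmreMax)
    cur <- generateTitration(truth,
                             noiseSd = sim$noise_sd_nmre %||% 0.3,
                             seed = seed, compositionLabel = preset)
    state$curve <- cur
    path <- file.path(config$outdir, "titration.csv")
    utils::write.csv(cur@points, path, row.names = FALSE)
    jsonlite::write_json(cur@groundTruth[c("kd", "nLipids", "nmreMax",
                                           "noiseSd", "seed")],
                         file.path(config$outdir, "titration.truth.json"),
                         auto_unbox = TRUE, digits = NA)
    out$titration <- path
  } else if (preset == "nd-contrast") {
    mU <- bilayerModel(d = sim$d_angstrom %||% 54.9)
    mL <- bilayerModel(d = sim$d_angstrom %||% 54.9,
                       d7Fraction = sim$d7_fraction %||% 5 / 6)
    state$series <- generateContrastSeries(mU, relSd = sim$rel_sd %||% 0.05,
                                           seed = seed)
    state$labeledSeries <- generateContrastSeries(mL,
                                                  relSd = sim$rel_sd %||% 0.05,
                                                  seed = seed + 1)
    k <- 0
    for (nm in c("series", "labeledSeries")) {
      for (s in get(nm, envir = state)@sets) {
        k <- k + 1
        p <- file.path(config$outdir, sprintf("sf_%02d.csv", k))
        writeStructureFactorSet(s, p)
        out[[sprintf("sf_%02d", k)]] <- p
      }
    }
    jsonlite::write_json(state$series@groundTruth$model@groundTruth,
                         file.path(config$outdir, "contrast.truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (preset == "xrd-two-phase") {
    pat <- generateTwoPhasePattern(d1 = sim$d1_angstrom %||% 58.6,
                                   d2 = sim$d2_angstrom %||% 55.3,
                                   weight = sim$weight %||% 0.5, seed = seed)
    state$pattern <- pat
    p <- file.path(config$outdir, "pattern.dat")
    writeDiffractionPattern(pat, p)
    jsonlite::write_json(pat@groundTruth,
                         file.path(config$outdir, "pattern.truth.json"),
                         auto_unbox = TRUE, digits = NA)
    out$pattern <- p
  } else if (preset == "shells") {
    fr <- generateHydrationFrames(
      shellRadii = sim$shell_radii_angstrom %||% c(2.5, 3.7),
      shellCounts = sim$shell_counts %||% c(32, 74),
      nFrames = sim$n_frames %||% 5, seed = seed)
    state$frames <- fr$frames
    p <- file.path(config$outdir, "frames.xyz")
    writeXYZFrames(fr$frames, p)
    jsonlite::write_json(fr$groundTruth,
                         file.path(config$outdir, "frames.truth.json"),
                         auto_unbox = TRUE, digits = NA)
    out$frames <- p
  } else stop("unknown simulate preset: ", preset, call. = FALSE)
  list(report = list(preset = preset, outputs = out), flags = character(),
       fatal = FALSE)
}

stageFitBinding <- function(config, state) {
  fb <- config$fit_binding %||% list()
  cur <- state$curve
  if (is.null(cur)) {
    path <- fb$input %||% stop("fit-binding needs 'fit_binding: input:' or a simulate stage",
                               call. = FALSE)
    if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
    pts <- utils::read.csv(path)
    cur <- new("TitrationCurve", peptideConc = max(pts$peptideConc),
               points = pts[, c("lipidConc", "peptideConc", "mre222", "nmre")],
               compositionLabel = fb$label %||% "file", nmreMin = 1,
               flags = character(), groundTruth = list())
  }
  fit <- fitBinding(cur, nGenerations = fb$n_generations %||% 2500,
                    nWalkers = fb$n_walkers %||% 16,
                    seed = as.integer(fb$seed %||% config$seed))
  if (!isTRUE(fit@diagnostics$noBinding)) {
    utils::write.csv(as.data.frame(fit@samples),
                     file.path(config$outdir, "posterior_samples.csv"),
                     row.names = FALSE)
  }
  summ <- list(medians = as.list(fit@medians),
               ci68 = if (ncol(fit@ci68)) as.data.frame(fit@ci68) else list(),
               diagnostics = fit@diagnostics[c("acceptance", "converged",
                                               "noBinding", "nWalkers",
                                               "nGenerations", "burnIn")])
  jsonlite::write_json(summ, file.path(config$outdir, "posterior.json"),
                       auto_unbox = TRUE, digits = NA)
  state$bindingFit <- fit
  list(report = summ, flags = flags(fit),
       fatal = FALSE)
}

stageReduce <- function(config, state) {
  rd <- config$reduce %||% list()
  pat <- state$pattern
  if (is.null(pat)) {
    path <- rd$input %||% stop("reduce needs 'reduce: input:' or a simulate stage",
                               call. = FALSE)
    if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
    pat <- readDiffractionPattern(path)
  }
  peaks <- detectPeaks(pat)
  utils::write.csv(peaks, file.path(config$outdir, "peaks.csv"),
                   row.names = FALSE)
  fl <- character()
  rep <- list(nPeaks = nrow(peaks))
  if (nrow(peaks) >= 4 && isTRUE(rd$two_lattice %||% TRUE)) {
    dec <- deconvolveTwoLattices(peaks)
    rep$lattices <- lapply(dec$lattices, function(l)
      list(d = l@d, dSd = l@dSd, orders = l@orders))
    rep$split <- dec$split
    fl <- unlist(lapply(dec$lattices, flags))
    state$lattice <- dec$lattices[[1]]
  } else if (nrow(peaks) >= 1) {
    lat <- indexAndFitLattice(peaks)
    rep$lattices <- list(list(d = lat@d, dSd = lat@dSd, orders = lat@orders))
    fl <- flags(lat)
    state$lattice <- lat
  } else {
    fl <- "no.peaks"
  }
  if (!is.null(state$lattice)) {
    sfs <- integrateStructureFactors(pat, state$lattice)
    writeStructureFactorSet(sfs, file.path(config$outdir, "structure_factors.csv"))
    state$reducedSet <- sfs
  }
  jsonlite::write_json(rep, file.path(config$outdir, "lattice.json"),
                       auto_unbox = TRUE, digits = NA)
  list(report = rep, flags = fl, fatal = identical(fl, "no.peaks"))
}

stagePhase <- function(config, state) {
  ph <- config$phase %||% list()
  ser <- state$series
  if (is.null(ser)) {
    paths <- ph$inputs %||% stop("phase needs 'phase: inputs:' or a simulate stage",
                                 call. = FALSE)
    sets <- lapply(paths, readStructureFactorSet)
    ser <- contrastSeries(sets)
  }
  signed <- phaseByContrast(ser)
  for (j in seq_along(signed))
    writeStructureFactorSet(signed[[j]],
                            file.path(config$outdir, sprintf("sf_signed_%02d.csv", j)))
  state$signedSets <- signed
  fl <- unique(unlist(lapply(signed, flags)))
  list(report = list(signMatrix = attr(signed, "signMatrix")),
       flags = fl, fatal = FALSE)
}

stageProfile <- function(config, state) {
  if (is.null(state$signedSets))
    stop("profile stage requires the phase stage", call. = FALSE)
  pr <- config$profile %||% list()
  paths <- character()
  for (j in seq_along(state$signedSets)) {
    prof <- fourierSynthesis(state$signedSets[[j]],
                             nGrid = pr$n_grid %||% 512)
    p <- file.path(config$outdir, sprintf("profile_%02d.txt", j))
    writeSLDProfile(prof, p)
    paths <- c(paths, p)
  }
  state$profiles <- lapply(state$signedSets, fourierSynthesis,
                           nGrid = pr$n_grid %||% 512)
  list(report = list(profiles = paths), flags = character(), fatal = FALSE)
}

stageWater <- function(config, state) {
  wt <- config$water %||% list()
  if (is.null(state$series) || is.null(state$labeledSeries))
    stop("water stage requires simulated or loaded labeled + unlabeled series",
         call. = FALSE)
  wq <- quantifyWater(state$series, state$labeledSeries,
                      peptidePerLipid = wt$peptide_per_lipid %||%
                        state$series@composition$peptidePerLipid %||% 1 / 25,
                      watersPerLipid = wt$waters_per_lipid %||% 9.4,
                      nExchangeable = wt$n_exchangeable %||% 57,
                      nMock = wt$n_mock %||% 100,
                      seed = as.integer(wt$seed %||% config$seed))
  rep <- list(watersPerPeptide = wq@watersPerPeptide, sd = wq@sd,
              inputs = wq@inputs, flags = flags(wq))
  jsonlite::write_json(rep, file.path(config$outdir, "water.json"),
                       auto_unbox = TRUE, digits = NA)
  list(report = rep, flags = flags(wq), fatal = FALSE)
}

stageShells <- function(config, state) {
  sh <- config$shells %||% list()
  frames <- state$frames
  if (is.null(frames)) {
    path <- sh$input %||% stop("shells needs 'shells: input:' or a simulate stage",
                               call. = FALSE)
    if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
    frames <- readXYZFrames(path, soluteLabels = sh$solute_labels %||% "P")
  }
  g <- radialDistribution(frames, rMax = sh$r_max_angstrom %||% 8,
                          binWidth = sh$bin_width_angstrom %||% 0.1)
  utils::write.csv(g, file.path(config$outdir, "gr.csv"), row.names = FALSE)
  bounds <- shellBoundaries(g, nShells = sh$n_shells %||% 3)
  summ <- if (nrow(bounds)) countWatersInShells(frames, bounds) else
    data.frame()
  jsonlite::write_json(list(boundaries = bounds, shells = summ),
                       file.path(config$outdir, "shells.json"),
                       auto_unbox = TRUE, digits = NA)
  list(report = list(boundaries = bounds, shells = summ),
       flags = if (isTRUE(attr(bounds, "short"))) "fewer.minima.than.requested"
       else character(),
       fatal = FALSE)
}
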