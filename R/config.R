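#' Default run configuration
#'
#' A single nested list drives every command-line stage so an end-to-end run
#' is reproducible from one file.  Sections: \code{phantom} (fixture
#' geometry seed, scatterer density), \code{probe} (preset name),
#' \code{psf}, \code{basis}, \code{grid}, \code{simulate}, \code{match},
#' \code{eval} and \code{paths}.
#'
#' @return Nested named list of defaults.
#' @export
defaultRunConfig <- function() {
  list(
    phantom = list(seed = 1L, density = 5, sphere_amplitude = 3),
    probe = list(preset = "endoscopic_linear"),
    psf = list(lateral_sigma_range = c(0.3, 2.0), elevation_slab = 5,
               rf_oversample = 4),
    basis = list(templates = 1:8, edge_splits = c(0.25, 0.5, 0.75),
                 scales = 0:3, base_support = 12L, stride_factor = 1,
                 match_size = c(128L, 128L)),
    grid = list(n_offsets = 10L, offset_step = 5, rotations = c(0, 15, -15),
                extent = c(80, 80)),
    simulate = list(dynamic_range = 60, median_window = 5L),
    match = list(per_scale = TRUE, centered = TRUE),
    eval = list(target_seed = 501L, noise_sigma_frac = 0.05,
                noise_seed = 901L,
                ## each entry is one scale set, scales comma-separated
                sweep_scales = c("0", "3"), sweep_basis_counts = c(4L, 8L),
                sweep_seeds = 1:10),
    paths = list(run_dir = "eustrack_run")
  )
}

## Recursive merge: values in `cfg` override `defaults`.
.mergeConfig <- function(defaults, cfg) {
  for (nm in names(cfg)) {
    if (is.list(cfg[[nm]]) && is.list(defaults[[nm]]) &&
        !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], cfg[[nm]])
    else defaults[[nm]] <- cfg[[nm]]
  }
  defaults
}

#' Read, resolve and hash run configurations
#'
#' \code{readRunConfig} loads a YAML or JSON file and fills every missing
#' entry from \code{\link{defaultRunConfig}}; \code{writeRunConfig} writes
#' YAML that round-trips losslessly through \code{readRunConfig};
#' \code{configHash} is a stable md5 of the canonical text rendering of the
#' resolved configuration, logged by every command.
#'
#' @param path Config file (.yaml/.yml or .json).
#' @param config A (possibly partial) config list.
#' @return \code{readRunConfig}: the resolved config list;
#'   \code{configHash}: a hex string.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .eusStop("eus_input_error", "no such file: %s", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  resolveRunConfig(cfg)
}

#' @rdname readRunConfig
#' @export
resolveRunConfig <- function(config = list()) {
  cfg <- .mergeConfig(defaultRunConfig(), config)
  .assertParam(cfg$phantom$density > 0, "phantom density must be > 0")
  .assertParam(cfg$grid$n_offsets >= 1, "grid n_offsets must be >= 1")
  cfg
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname readRunConfig
#' @export
configHash <- function(config) .hashText(.canonicalText(config))

## ---- derived objects ------------------------------------------------------

.configBasis <- function(cfg) {
  haarBasisSet(templates = as.integer(cfg$basis$templates),
               edgeSplits = cfg$basis$edge_splits,
               scales = as.integer(cfg$basis$scales),
               baseSupport = as.integer(cfg$basis$base_support),
               strideFactor = cfg$basis$stride_factor,
               matchSize = as.integer(cfg$basis$match_size))
}

.configPsf <- function(cfg) {
  psfModel(lateralSigmaRange = cfg$psf$lateral_sigma_range,
           elevationSlab = cfg$psf$elevation_slab,
           rfOversample = cfg$psf$rf_oversample)
}

.configStudy <- function(cfg) {
  study <- phantomStudy(seed = as.integer(cfg$phantom$seed),
                        density = cfg$phantom$density,
                        nOffsets = as.integer(cfg$grid$n_offsets),
                        offsetStep = cfg$grid$offset_step,
                        rotations = cfg$grid$rotations,
                        extent = cfg$grid$extent,
                        matchSize = as.integer(cfg$basis$match_size))
  study$probe <- makeProbePreset(cfg$probe$preset)
  study$psf <- .configPsf(cfg)
  study
}

.logCmd <- function(cfg, what) {
  message(sprintf("[eusTracker] %s (config hash %s)", what, configHash(cfg)))
}

## ---- commands (thin wrappers used by inst/cli/eustrack) -------------------

#' Command-stage entry points
#'
#' Thin, file-oriented wrappers around the package pipeline, one per
#' command-line stage.  Every command resolves its configuration, logs the
#' config hash, and writes its outputs under \code{paths$run_dir}.
#' \code{cmdPhantom} writes the synthetic training-phantom volume, masks and
#' scatterer field; \code{cmdBuildDict} builds and persists the feature
#' dictionary; \code{cmdMatch} matches a target image (PNG) against the
#' persisted dictionary; \code{cmdEval} runs the marker-based localization
#' evaluation; \code{cmdSweep} runs the scale/basis-count sweep.
#'
#' @param config A (partial) run-config list or a path readable by
#'   \code{\link{readRunConfig}}.
#' @param targetImage Path to the target EUS image PNG (cmdMatch).
#' @return Invisibly, the main output path (or result object).
#' @name commands
NULL

.resolveCfgArg <- function(config) {
  if (is.character(config)) readRunConfig(config) else resolveRunConfig(config)
}

#' @rdname commands
#' @export
cmdPhantom <- function(config = list()) {
  cfg <- .resolveCfgArg(config)
  .logCmd(cfg, "phantom")
  dir <- cfg$paths$run_dir
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir))
    .eusStop("eus_input_error", "cannot create run directory '%s'", dir)
  toy <- generateToyVolume("eus_training_phantom",
                           seed = as.integer(cfg$phantom$seed))
  writeVolume(toy$volume, file.path(dir, "phantom.nii.gz"))
  writeMaskStack(toy$masks, toy$volume, file.path(dir, "phantom_masks.nii.gz"))
  field <- sampleGeometricScatterers(toy$spec, cfg$phantom$density,
                                     seed = as.integer(cfg$phantom$seed))
  writeScattererField(field, file.path(dir, "scatterers.csv"))
  jsonlite::write_json(
    list(spheres = toy$spec@spheres, channel_radius = toy$spec@channelRadius,
         box = toy$spec@box, config_hash = configHash(cfg)),
    file.path(dir, "phantom_spec.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname commands
#' @export
cmdBuildDict <- function(config = list()) {
  cfg <- .resolveCfgArg(config)
  .logCmd(cfg, "build-dict")
  study <- .configStudy(cfg)
  basis <- .configBasis(cfg)
  dict <- buildDictionary(study$field, study$grid, study$probe, study$psf,
                          basis, dynamicRange = cfg$simulate$dynamic_range,
                          medianWindow = cfg$simulate$median_window)
  out <- file.path(cfg$paths$run_dir, "dictionary")
  saveDictionary(dict, out)
  invisible(out)
}

#' @rdname commands
#' @export
cmdMatch <- function(config = list(), targetImage) {
  cfg <- .resolveCfgArg(config)
  .logCmd(cfg, "match")
  dict <- loadDictionary(file.path(cfg$paths$run_dir, "dictionary"))
  target <- readGrayImage(targetImage)
  basis <- .configBasis(cfg)
  res <- findBestMatch(dict, target, basis,
                       medianWindow = cfg$simulate$median_window,
                       perScale = cfg$match$per_scale,
                       centered = cfg$match$centered)
  out <- file.path(cfg$paths$run_dir, "match_result.json")
  writeMatchResult(res, out)
  if (length(dict@images) && !is.null(dict@images[[res@bestIndex]])) {
    tgt <- resizeImage(target, dim(dict@images[[res@bestIndex]]))
    pair <- cbind(tgt@values, dict@images[[res@bestIndex]]@values)
    writeGrayImage(GrayImage(pair, tgt@pixelSpacing, tgt@origin),
                   file.path(cfg$paths$run_dir, "match_side_by_side.png"))
  }
  invisible(res)
}

#' @rdname commands
#' @export
cmdEval <- function(config = list()) {
  cfg <- .resolveCfgArg(config)
  .logCmd(cfg, "eval")
  study <- .configStudy(cfg)
  basis <- .configBasis(cfg)
  dictDir <- file.path(cfg$paths$run_dir, "dictionary")
  dict <- if (file.exists(file.path(dictDir, "manifest.json")))
    loadDictionary(dictDir)
  else buildDictionary(study$field, study$grid, study$probe, study$psf,
                       basis, dynamicRange = cfg$simulate$dynamic_range,
                       medianWindow = cfg$simulate$median_window)
  ev <- evaluatePhantomLocalization(
    study, dict, basis, targetSeed = as.integer(cfg$eval$target_seed),
    noiseSigmaFrac = cfg$eval$noise_sigma_frac,
    noiseSeed = as.integer(cfg$eval$noise_seed),
    dynamicRange = cfg$simulate$dynamic_range,
    medianWindow = cfg$simulate$median_window)
  dir <- cfg$paths$run_dir
  utils::write.csv(ev$report@perMarker, file.path(dir, "marker_errors.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(max_abs_error_mm = ev$report@maxAbsError,
         mean_abs_error_mm = ev$report@meanAbsError,
         matches = ev$matches, config_hash = configHash(cfg)),
    file.path(dir, "eval_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(ev)
}

#' @rdname commands
#' @export
cmdSweep <- function(config = list()) {
  cfg <- .resolveCfgArg(config)
  .logCmd(cfg, "sweep")
  study <- .configStudy(cfg)
  scalesList <- lapply(strsplit(as.character(cfg$eval$sweep_scales), ","),
                       as.integer)
  sw <- sweepMatchingConfig(
    study, scalesList = scalesList,
    basisCounts = as.integer(cfg$eval$sweep_basis_counts),
    seeds = as.integer(cfg$eval$sweep_seeds),
    baseSupport = as.integer(cfg$basis$base_support),
    matchSize = as.integer(cfg$basis$match_size),
    dynamicRange = cfg$simulate$dynamic_range,
    medianWindow = cfg$simulate$median_window,
    noiseSigmaFrac = cfg$eval$noise_sigma_frac)
  dir <- cfg$paths$run_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sw, file.path(dir, "sweep.csv"), row.names = FALSE)
  utils::write.csv(summarizeSweep(sw), file.path(dir, "sweep_summary.csv"),
                   row.names = FALSE)
  invisible(sw)
}
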