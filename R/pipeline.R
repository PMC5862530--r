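#' Predicted mean interaction volume at a given colony state
#'
#' The zero-free-parameter composition of the volume law with representative
#' recipient sampling: `<v>(F) = (C0 / lambda0) * (1 - F)`.
#'
#' @param F colony state in \[0, 1\]
#' @param lambda0,C0 volume-law parameters
#' @return predicted mean volume(s)
#' @export
predictedMeanVolume <- function(F, lambda0, C0) {
  if (lambda0 <= 0) stop("lambda0 must be > 0")
  (C0 / lambda0) * (1 - F)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: obtain an experiment (simulate, or
#' import from the canonical CSVs), compute the colony state, fit the
#' per-forager flow law, extract foraging cycles and the frequency/vacancy
#' fit, fit the conditional exponential volume law and its collapse, the
#' interaction-rate and unloading-rate decompositions, and the exit-decision
#' fits under the three decision-rate models.
#'
#' @param config list with exactly one of `simulate` (a
#'   [simulationConfig()]) or `import` (list with `interactions`,
#'   `feedings`, `timelines` and optional `mapping` file paths); optional
#'   `state_bins` (default 5), `crop_bins` (7), `delta_crop` (0.10),
#'   `smooth_window` (2000), `diff_window` (300), `seed`.
#' @param out_dir optional directory; when given, tidy CSVs (state series,
#'   cycles, decision points), a JSON summary of all fitted constants, and a
#'   run manifest are written there.
#' @return list with the experiment, intermediate objects, and `summary`
#'   (named list of all fitted constants)
#' @export
runPipeline <- function(config, out_dir = NULL) {
  has_sim <- !is.null(config$simulate)
  has_imp <- !is.null(config$import)
  if (has_sim == has_imp)
    stop("config must contain exactly one input source: ",
         "'simulate' or 'import'")
  state_bins <- config$state_bins %||% 5
  crop_bins <- config$crop_bins %||% 7
  delta_crop <- config$delta_crop %||% 0.10
  sw <- config$smooth_window %||% 2000
  dw <- config$diff_window %||% 300

  if (has_sim) {
    sim_cfg <- config$simulate
    if (!is.null(config$seed)) sim_cfg$seed <- config$seed
    if (is.null(sim_cfg$seed))
      stop("a seed is mandatory for simulated pipeline runs")
    exp0 <- simulateColony(sim_cfg)
  } else {
    exp0 <- readColonyExperiment(config$import$interactions,
                                 config$import$feedings,
                                 config$import$timelines,
                                 config$import$mapping)
  }

  series <- computeColonyState(exp0, smooth_window = sw)
  flow <- fitIndividualFlow(series, onsets = onsetTimes(exp0),
                            smooth_window = sw, diff_window = dw)
  cycles <- extractForagingCycles(exp0, series)
  freq <- tryCatch(fitFrequencyVsVacancy(cycles, n_bins = state_bins),
                   error = function(e) NULL)

  pos <- positiveInteractions(exp0)
  # on simulated data the generator records which draws were truncated at a
  # physical limit; those censored draws are excluded from the volume-law fit
  pos_fit <- pos
  if (methods::is(exp0, "SyntheticColonyExperiment") &&
      length(groundTruth(exp0)$censored) == nrow(interactions(exp0)))
    pos_fit <- pos[!groundTruth(exp0)$censored[as.integer(rownames(pos))], ,
                   drop = FALSE]
  vol_law <- fitLambdaVsCrop(pos_fit, "recipient", n_bins = crop_bins)
  collapse <- collapseNormalizedVolumes(pos_fit, vol_law$C0,
                                        n_bins = crop_bins)
  rate <- tryCatch(fitInteractionRate(exp0, series, n_bins = state_bins),
                   error = function(e) NULL)
  decomp <- if (!is.null(rate))
    tryCatch(unloadingRateDecomposition(exp0, series, cycles, rate,
                                        n_bins = state_bins),
             error = function(e) NULL)

  exp_exit <- normalizeCrops(exp0, "per_forager")
  septest <- separationOfVariablesTest(exp_exit, series, delta_crop)
  g_crop <- fitExitLogistic(
    extractDecisionPoints(exp_exit, "unloading_rate", series, delta_crop),
    covariates = "crop")

  summary <- list(
    m = flow$m,
    m_i = as.list(flow$m_i),
    lambda0 = vol_law$lambda0,
    C0 = vol_law$C0,
    volume_law_r_squared = vol_law$r_squared,
    collapse_mean_fraction = collapse$mean_fraction,
    negative_interaction_count = attr(pos, "n_negative"),
    negative_flow_fraction = attr(pos, "negative_flow_fraction"),
    rate_fit = if (!is.null(rate)) list(r0 = rate$r0, r1 = rate$r1,
                                        r_squared = rate$r_squared),
    frequency_fit = if (!is.null(freq))
      list(intercept = freq$intercept, slope = freq$slope,
           r_squared = freq$r_squared),
    unloading_r_squared = if (!is.null(decomp)) as.list(decomp$r_squared),
    exit_coefficients = lapply(septest$fits, function(f)
      as.list(f$coefficients)),
    exit_crop_slope = unname(g_crop$coefficients["crop"]),
    seed = config$seed
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(data.frame(t = stateTimes(series),
                                F = colonyState(series)),
                     file.path(out_dir, "colony_state.csv"),
                     row.names = FALSE)
    utils::write.csv(cycles, file.path(out_dir, "cycles.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    manifest <- list(
      package_version = as.character(utils::packageVersion("cropflow")),
      seed = config$seed,
      config_hash = .configHash(config),
      timestamp_format = "unix",
      n_interactions = nrow(interactions(exp0)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }

  list(experiment = exp0, series = series, flow = flow, cycles = cycles,
       frequency = freq, volume_law = vol_law, collapse = collapse,
       rate = rate, decomposition = decomp, separation = septest,
       g_crop = g_crop, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}
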