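#' Configuration for the agent-based colony simulator
#'
#' Defaults are the measured microscopic rules of the study system
#' (a *Camponotus* colony replenishing after starvation): interaction volumes
#' are exponential random fractions (mean `1/lambda0`) of the recipient's
#' remaining crop space; per-ant crop targets are mildly heterogeneous around
#' the mean target `crop_target_mean` (the constant usually written C0);
#' foragers attempt unloading interactions at rate `r(F) = rate_intercept -
#' rate_slope * F` per second while in the nest (the rate decline is off by
#' default — interaction volumes, not rates, dominate the inflow feedback);
#' after every cumulative `delta_crop` fraction of capacity unloaded, the
#' forager makes a Bernoulli exit decision with probability
#' `plogis(exit_intercept + exit_crop_coef * crop + exit_colony_coef * colony)`
#' (crop-only by default, i.e. `exit_colony_coef = 0`); the outdoor (feeding)
#' phase has constant duration. Forager onsets are staggered uniformly over
#' the first tenth of the run unless given.
#'
#' @param n_ants total ants, foragers included (queen/brood not modelled).
#' @param n_foragers number of consistent foragers.
#' @param duration run length, seconds.
#' @param dt time grid spacing, seconds (0.5 Hz sampling).
#' @param crop_target_mean mean per-ant crop-load target, in
#'   between-experiment normalized units.
#' @param crop_target_sd standard deviation of per-ant targets (truncated at
#'   zero); set 0 for identical targets.
#' @param lambda0 rate scale of the exponential volume rule (1/mean fraction).
#' @param rate_intercept,rate_slope interaction-attempt rate
#'   `r(F) = rate_intercept - rate_slope * F`, per second per forager in nest.
#' @param outdoor_duration constant duration of the feeding trip, seconds.
#' @param delta_crop crop-unload increment (fraction of forager capacity)
#'   that triggers one exit decision.
#' @param exit_intercept,exit_crop_coef,exit_colony_coef logistic
#'   exit-decision coefficients on the (crop, colony) unit scales.
#' @param forager_onsets optional vector of first-return times (seconds).
#' @param perturbation optional `list(time =, n_added_hungry =)`: at `time`,
#'   that many hungry (empty-crop) non-foragers join the colony and the
#'   colony-state normalizer is recomputed over the enlarged colony.
#' @param forced_exit_crop crop level (fraction of capacity) below which a
#'   forager leaves to reload regardless of the decision rule; an emptied
#'   crop can no longer trigger unload-increment decisions.
#' @param seed optional integer seed; same seed, same event logs, bitwise.
#' @return a `simulation_config` list
#' @seealso [simulateColony()]
#' @export
simulationConfig <- function(n_ants = 60, n_foragers = 4, duration = 14400,
                             dt = 2, crop_target_mean = 1.14,
                             crop_target_sd = 0.05 * crop_target_mean,
                             lambda0 = 7.01, rate_intercept = 0.032,
                             rate_slope = 0, outdoor_duration = 120,
                             delta_crop = 0.10, exit_intercept = 0,
                             exit_crop_coef = -1.93, exit_colony_coef = 0,
                             forager_onsets = NULL, perturbation = NULL,
                             forced_exit_crop = 0.02, seed = NULL) {
  if (lambda0 <= 0) stop("lambda0 must be > 0")
  if (delta_crop <= 0 || delta_crop > 1)
    stop("delta_crop must be in (0, 1]")
  if (dt <= 0) stop("dt must be > 0")
  if (n_foragers >= n_ants) stop("need at least one non-forager")
  if (is.null(forager_onsets)) {
    forager_onsets <- if (n_foragers > 0)
      seq(outdoor_duration, outdoor_duration + 0.1 * duration,
          length.out = n_foragers)
    else numeric(0)
  }
  if (length(forager_onsets) != n_foragers)
    stop("forager_onsets must have one entry per forager")
  if (n_foragers > 0 &&
      (any(forager_onsets < 0) || any(forager_onsets > duration)))
    stop("forager onsets must lie within [0, duration]")
  if (!is.null(perturbation)) {
    if (is.null(perturbation$time) || is.null(perturbation$n_added_hungry))
      stop("perturbation needs elements 'time' and 'n_added_hungry'")
    if (perturbation$time < 0 || perturbation$time > duration)
      stop("perturbation time outside the run")
  }
  structure(list(
    n_ants = n_ants, n_foragers = n_foragers, duration = duration, dt = dt,
    crop_target_mean = crop_target_mean, crop_target_sd = crop_target_sd,
    lambda0 = lambda0, rate_intercept = rate_intercept,
    rate_slope = rate_slope, outdoor_duration = outdoor_duration,
    delta_crop = delta_crop, exit_intercept = exit_intercept,
    exit_crop_coef = exit_crop_coef, exit_colony_coef = exit_colony_coef,
    forager_onsets = forager_onsets, perturbation = perturbation,
    forced_exit_crop = forced_exit_crop, seed = seed
  ), class = "simulation_config")
}

#' Draw trophallactic interaction volumes
#'
#' The generative volume rule: the transferred volume is an exponentially
#' distributed random fraction (mean `1/lambda0`) of the space left to fill
#' in the recipient's crop, truncated at the physical limits — the donor
#' cannot give more than she carries and the recipient cannot exceed her
#' target. Truncated draws are flagged `censored` so estimators can exclude
#' them.
#'
#' Vectorised over the first three arguments.
#'
#' @param donor_load donor crop load (use `Inf` for a non-binding donor).
#' @param recipient_load,recipient_target recipient crop load and target, in
#'   the same units.
#' @param lambda0 exponential rate of the fraction.
#' @return list with numeric `volume`, latent fraction `vtilde`, and logical
#'   `censored`.
#' @export
drawInteractionVolume <- function(donor_load, recipient_load,
                                  recipient_target, lambda0) {
  if (lambda0 <= 0) stop("lambda0 must be > 0")
  n <- max(length(donor_load), length(recipient_load),
           length(recipient_target))
  donor_load <- rep_len(donor_load, n)
  recipient_load <- rep_len(recipient_load, n)
  recipient_target <- rep_len(recipient_target, n)
  if (any(donor_load < 0) || any(recipient_load < 0))
    stop("crop loads must be non-negative")
  avail <- pmax(recipient_target - recipient_load, 0)
  vtilde <- stats::rexp(n, rate = lambda0)
  raw <- vtilde * avail
  volume <- pmin(raw, donor_load, avail)
  list(volume = volume, vtilde = vtilde, censored = volume < raw)
}

#' Add hungry ants to a running simulation state
#'
#' Appends `n_added_hungry` empty-crop non-foragers to the recipient pool and
#' enlarges the colony-state normalizer accordingly, so the colony state
#' drops discontinuously by the added vacancy fraction. Called by
#' [simulateColony()] at the configured perturbation time; exported so the
#' mechanics can be tested in isolation.
#'
#' @param state simulator state environment (see [simulateColony()]).
#' @param n_added_hungry number of hungry ants to add; 0 is a no-op that
#'   consumes no random numbers.
#' @return the state, modified in place and returned invisibly
#' @export
applyPerturbation <- function(state, n_added_hungry) {
  if (n_added_hungry < 0) stop("n_added_hungry must be >= 0")
  if (n_added_hungry == 0) return(invisible(state))
  cfg <- state$config
  new_ids <- paste0("P", seq_len(n_added_hungry) + state$n_added)
  state$n_added <- state$n_added + n_added_hungry
  tg <- .drawTargets(n_added_hungry, cfg$crop_target_mean,
                     cfg$crop_target_sd)
  state$nf_ids <- c(state$nf_ids, new_ids)
  state$nf_crop <- c(state$nf_crop, rep(0, n_added_hungry))
  state$nf_target <- c(state$nf_target, tg)
  state$joined_at <- c(state$joined_at,
                       stats::setNames(rep(state$now, n_added_hungry),
                                       new_ids))
  invisible(state)
}

.drawTargets <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  tg <- stats::rnorm(n, mean, sd)
  while (any(tg <= 0)) tg[tg <= 0] <- stats::rnorm(sum(tg <= 0), mean, sd)
  tg
}

#' Simulate a colony food-accumulation experiment
#'
#' Runs the agent-based model defined by a [simulationConfig()] and emits a
#' [SyntheticColonyExperiment-class]: canonical event logs and crop timelines
#' on the `dt` grid, plus the generative ground truth (latent volume
#' fractions, censoring flags, the forager decision-point log, per-ant
#' targets). Food mass is conserved exactly: every transferred volume is
#' debited from the donor and credited to the recipient.
#'
#' Each forager cycles between a constant-duration outdoor phase, in which
#' her crop refills linearly to capacity at the food source, and an in-nest
#' phase in which she attempts unloading interactions with uniformly chosen
#' non-forager partners. The colony state used by the rate and decision rules
#' is the total food held by non-foragers divided by the sum of their
#' targets.
#'
#' @param config a [simulationConfig()]
#' @return a [SyntheticColonyExperiment-class]
#' @export
simulateColony <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_ants - config$n_foragers <= 0)
    stop("configuration error: zero non-foragers")
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  dt <- cfg$dt
  ticks <- seq(0, cfg$duration, by = dt)
  nT <- length(ticks)
  nF <- cfg$n_foragers
  nNF0 <- cfg$n_ants - nF
  n_pert <- if (is.null(cfg$perturbation)) 0L
            else cfg$perturbation$n_added_hungry
  f_ids <- if (nF > 0) sprintf("F%02d", seq_len(nF)) else character(0)

  state <- new.env(parent = emptyenv())
  state$config <- cfg
  state$now <- 0
  state$n_added <- 0L
  state$nf_ids <- sprintf("A%03d", seq_len(nNF0))
  state$nf_crop <- rep(0, nNF0)
  state$nf_target <- .drawTargets(nNF0, cfg$crop_target_mean,
                                  cfg$crop_target_sd)
  state$joined_at <- stats::setNames(rep(0, nNF0), state$nf_ids)

  # forager state
  capacity <- 1.0
  onset <- cfg$forager_onsets
  depart <- pmax(onset - cfg$outdoor_duration, 0)
  phase <- rep("pre", nF)            # pre -> outdoor -> nest -> outdoor ...
  f_crop <- rep(0, nF)
  return_time <- rep(Inf, nF)
  exit_crop <- rep(0, nF)
  exit_time <- rep(0, nF)
  unload_acc <- rep(0, nF)

  # storage (preallocate for the possible perturbation ants too)
  n_all_max <- nF + nNF0 + n_pert
  crop_mat <- matrix(NA_real_, n_all_max, nT)
  troph_mat <- matrix(FALSE, n_all_max, nT)
  innest_mat <- matrix(FALSE, n_all_max, nT)
  atfood_mat <- matrix(FALSE, n_all_max, nT)

  ia <- .growingLog(c("t_start", "t_end", "donor_id", "recipient_id",
                      "volume", "donor_crop", "recipient_crop"))
  fe <- .growingLog(c("forager_id", "t_start", "t_end"))
  dec <- .growingLog(c("t", "forager_id", "crop", "colony", "exit",
                       "forced"))
  vt_log <- numeric(0); cens_log <- logical(0)

  # the initial outdoor trip of every forager is one feeding record
  for (k in seq_len(nF)) fe$add(list(f_ids[k], depart[k], onset[k]))

  pert_done <- is.null(cfg$perturbation)

  for (i in seq_len(nT)) {
    t <- ticks[i]
    state$now <- t
    if (!pert_done && t >= cfg$perturbation$time) {
      applyPerturbation(state, cfg$perturbation$n_added_hungry)
      pert_done <- TRUE
    }
    nNF <- length(state$nf_ids)
    Fcol <- sum(state$nf_crop) / sum(state$nf_target)

    # forager phase transitions due at this tick
    for (k in seq_len(nF)) {
      if (phase[k] == "pre" && t >= depart[k]) {
        phase[k] <- "outdoor"; return_time[k] <- onset[k]
        exit_crop[k] <- 0; exit_time[k] <- depart[k]
      }
      if (phase[k] == "leaving") {
        # one tick elapses between the exit decision and the departure, so
        # the post-decision crop is observable at an in-nest grid point
        phase[k] <- "outdoor"
        exit_crop[k] <- f_crop[k]
        exit_time[k] <- t
        return_time[k] <- t + cfg$outdoor_duration
        fe$add(list(f_ids[k], t, return_time[k]))
      }
      if (phase[k] == "outdoor" && t >= return_time[k]) {
        phase[k] <- "nest"; f_crop[k] <- capacity; unload_acc[k] <- 0
      }
    }

    # record grid-point state (before this tick's events)
    for (k in seq_len(nF)) {
      crop_mat[k, i] <- if (phase[k] == "outdoor") {
        frac <- min(1, (t - exit_time[k]) /
                      max(return_time[k] - exit_time[k], dt))
        exit_crop[k] + frac * (capacity - exit_crop[k])
      } else f_crop[k]
      innest_mat[k, i] <- phase[k] != "outdoor"
      atfood_mat[k, i] <- phase[k] == "outdoor"
    }
    idx_nf <- nF + seq_len(nNF)
    crop_mat[idx_nf, i] <- state$nf_crop
    innest_mat[idx_nf, i] <- TRUE

    if (i == nT) break

    # in-nest unloading attempts
    r <- max(cfg$rate_intercept - cfg$rate_slope * Fcol, 0)
    for (k in seq_len(nF)) {
      if (phase[k] != "nest") next
      exited <- FALSE
      if (stats::runif(1) < r * dt && f_crop[k] > 0) {
        j <- if (nNF == 1L) 1L else sample.int(nNF, 1L)
        dr <- drawInteractionVolume(f_crop[k], state$nf_crop[j],
                                    state$nf_target[j], cfg$lambda0)
        v <- dr$volume
        ia$add(list(t, t + dt, f_ids[k], state$nf_ids[j], v,
                    f_crop[k], state$nf_crop[j]))
        vt_log <- c(vt_log, dr$vtilde)
        cens_log <- c(cens_log, dr$censored)
        troph_mat[k, i] <- TRUE
        troph_mat[nF + j, i] <- TRUE
        f_crop[k] <- f_crop[k] - v
        state$nf_crop[j] <- state$nf_crop[j] + v
        Fcol <- sum(state$nf_crop) / sum(state$nf_target)
        unload_acc[k] <- unload_acc[k] + v
        # one Bernoulli exit decision per completed delta_crop increment
        while (unload_acc[k] >= cfg$delta_crop * capacity) {
          unload_acc[k] <- unload_acc[k] - cfg$delta_crop * capacity
          p_exit <- stats::plogis(cfg$exit_intercept +
                                    cfg$exit_crop_coef * f_crop[k] / capacity +
                                    cfg$exit_colony_coef * Fcol)
          go <- stats::runif(1) < p_exit
          dec$add(list(t, f_ids[k], f_crop[k] / capacity, Fcol, go, FALSE))
          if (go) { exited <- TRUE; break }
        }
      }
      if (!exited && f_crop[k] < cfg$forced_exit_crop * capacity) {
        # an emptied crop cannot trigger further unload increments;
        # the forager leaves to reload
        dec$add(list(t, f_ids[k], f_crop[k] / capacity, Fcol, TRUE, TRUE))
        exited <- TRUE
      }
      if (exited) phase[k] <- "leaving"
    }
  }

  # ---- assemble the experiment ----
  all_ids <- c(f_ids, state$nf_ids)
  joined <- c(stats::setNames(rep(0, nF), f_ids), state$joined_at)
  roles <- c(rep("forager", nF), rep("non-forager", length(state$nf_ids)))
  ants <- data.frame(ant_id = all_ids, role = roles,
                     stringsAsFactors = FALSE)

  keep <- outer(joined[all_ids], ticks, "<=")
  tl <- data.frame(
    ant_id = rep(all_ids, each = nT)[t(keep)],
    t = rep(ticks, length(all_ids))[t(keep)],
    crop = as.vector(t(crop_mat[seq_along(all_ids), , drop = FALSE]))[t(keep)],
    in_trophallaxis = as.vector(t(troph_mat[seq_along(all_ids), ,
                                            drop = FALSE]))[t(keep)],
    at_food = as.vector(t(atfood_mat[seq_along(all_ids), ,
                                     drop = FALSE]))[t(keep)],
    in_nest = as.vector(t(innest_mat[seq_along(all_ids), ,
                                     drop = FALSE]))[t(keep)],
    experiment_id = "sim", stringsAsFactors = FALSE)

  iadf <- ia$df()
  if (nrow(iadf)) {
    iadf$forager_is_donor <- TRUE
    iadf$experiment_id <- "sim"
  } else {
    iadf <- data.frame(t_start = numeric(0), t_end = numeric(0),
                       donor_id = character(0), recipient_id = character(0),
                       volume = numeric(0), donor_crop = numeric(0),
                       recipient_crop = numeric(0),
                       forager_is_donor = logical(0),
                       experiment_id = character(0))
  }
  fedf <- fe$df()
  if (nrow(fedf)) fedf$experiment_id <- "sim"
  else fedf <- data.frame(forager_id = character(0), t_start = numeric(0),
                          t_end = numeric(0), experiment_id = character(0))
  decdf <- dec$df()

  methods::new("SyntheticColonyExperiment",
    ants = ants, interactions = iadf, feedings = fedf, timelines = tl,
    intakeTarget = sum(state$nf_target),
    onsetTimes = stats::setNames(onset, f_ids),
    metadata = list(seed = cfg$seed, dt = dt),
    groundTruth = list(config = cfg, vtilde = vt_log, censored = cens_log,
                       decisions = decdf,
                       crop_targets = stats::setNames(state$nf_target,
                                                      state$nf_ids)))
}

# simple amortised append log; columns typed from the first row added
.growingLog <- function(cols) {
  buf <- vector("list", 256L); n <- 0L
  add <- function(row) {
    n <<- n + 1L
    if (n > length(buf)) length(buf) <<- 2L * n
    buf[[n]] <<- row
  }
  df <- function() {
    if (n == 0L)
      return(stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))),
                             cols))
    rows <- buf[seq_len(n)]
    out <- lapply(seq_along(cols), function(j)
      unlist(lapply(rows, `[[`, j), use.names = FALSE))
    stats::setNames(as.data.frame(out, stringsAsFactors = FALSE), cols)
  }
  list(add = add, df = df)
}
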