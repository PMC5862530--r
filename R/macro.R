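#' Compute the colony state series from the interaction log
#'
#' The colony state \eqn{F(t)} is the cumulative signed volume of all
#' forager/non-forager interactions divided by the colony intake target, and
#' decomposes exactly into per-forager contributions \eqn{f_i(t)} (each
#' forager's cumulative signed volume; positive sign = food delivered by the
#' forager). Volumes are credited at the interaction end time.
#'
#' If the experiment's intake target is `NA` it is estimated post hoc from
#' the accumulation plateau: the mean of the smoothed accumulated food over
#' the final tenth of the record, with a warning flag if the accumulation
#' still rose by more than 2\% over the last hour (no stable plateau).
#'
#' @param x a [ColonyExperiment-class]
#' @param smooth_window smoothing window (seconds) used by the plateau
#'   estimator.
#' @return a [ColonyStateSeries-class]
#' @export
computeColonyState <- function(x, smooth_window = 2000) {
  fids <- foragerIds(x)
  tl <- timelines(x)
  if (!nrow(tl)) stop("experiment has no timelines")
  t_grid <- sort(unique(tl$t))
  dt <- gridStep(x)
  ia <- interactions(x)
  ia <- ia[ia$donor_id %in% fids | ia$recipient_id %in% fids, , drop = FALSE]
  if (!nrow(ia)) {
    warning("no forager interactions; colony state is identically zero")
    fi <- matrix(0, length(t_grid), length(fids),
                 dimnames = list(NULL, fids))
    return(methods::new("ColonyStateSeries", tGrid = t_grid,
                        F = rep(0, length(t_grid)), fi = fi,
                        intakeTarget = if (is.na(intakeTarget(x))) 1
                                       else intakeTarget(x)))
  }
  fi_abs <- matrix(0, length(t_grid), length(fids),
                   dimnames = list(NULL, fids))
  for (k in seq_along(fids)) {
    sel <- ia$donor_id == fids[k] | ia$recipient_id == fids[k]
    if (!any(sel)) next
    ev_t <- ia$t_end[sel]
    ev_v <- ia$volume[sel]          # signed: positive = from the forager
    ord <- order(ev_t)
    steps <- stats::stepfun(ev_t[ord], c(0, cumsum(ev_v[ord])))
    fi_abs[, k] <- steps(t_grid)
  }
  target <- intakeTarget(x)
  if (is.na(target)) {
    acc <- rowSums(fi_abs)
    sm <- movingAverage(acc, max(1L, round(smooth_window / dt)))
    tail_idx <- t_grid >= t_grid[1] + 0.9 * diff(range(t_grid))
    target <- mean(sm[tail_idx])
    if (target <= 0) stop("estimated intake target is not positive")
    hour_idx <- sum(t_grid <= max(t_grid) - 3600)
    if (hour_idx >= 1 && sm[hour_idx] > 0 &&
        (sm[length(sm)] - sm[hour_idx]) / target > 0.02)
      warning("accumulated food still rising in the final hour; ",
              "post-hoc intake target may be unreliable")
  }
  fi <- fi_abs / target
  methods::new("ColonyStateSeries", tGrid = t_grid, F = rowSums(fi), fi = fi,
               intakeTarget = target)
}

#' @describeIn ColonyStateSeries-class colony state vector
#' @param x a `ColonyStateSeries`
#' @export
colonyState <- function(x) x@F

#' @describeIn ColonyStateSeries-class time grid
#' @export
stateTimes <- function(x) x@tGrid

#' @describeIn ColonyStateSeries-class per-forager contribution matrix
#' @export
foragerContributions <- function(x) x@fi

# centred moving average; the window shrinks symmetrically at the edges
movingAverage <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  if (k > n) stop("smoothing window longer than the series")
  h <- (k - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Smooth an accumulation series and differentiate it into a flow
#'
#' Applies a centred moving average wide enough to bridge several discrete
#' trophallactic events, then a centred finite difference over a shorter
#' window. The integral of the returned flow reproduces the net accumulation
#' (differentiation and integration are adjoint up to edge effects).
#'
#' @param x accumulation values on a uniform grid.
#' @param dt grid spacing, seconds.
#' @param smooth_window moving-average window, seconds (default 2000).
#' @param diff_window differentiation window, seconds (default 300; the
#'   useful range is roughly 200–500).
#' @return list with `smoothed` and `flow` (same length as `x`)
#' @export
smoothAndDifferentiate <- function(x, dt, smooth_window = 2000,
                                   diff_window = 300) {
  if (smooth_window < dt || diff_window < dt)
    stop("windows must be at least one grid step")
  n <- length(x)
  k <- max(1L, round(smooth_window / dt))
  if (k > n || round(diff_window / dt) > n)
    stop("window longer than the series")
  sm <- movingAverage(x, k)
  h <- max(1L, round(diff_window / (2 * dt)))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  flow <- (sm[hi] - sm[lo]) / ((hi - lo) * dt)
  list(smoothed = sm, flow = flow)
}

#' Fit the per-forager flow feedback law
#'
#' For each forager, fits the proportionality `dfi/dt = m_i (1 - F)` by least
#' squares through the origin, restricted to the forager's active window
#' (from her onset to the end of the record). The pooled `m` is the mean of
#' the per-forager slopes. That the same `m_i` fits foragers with different
#' onset times is the signature of state-dependent (not history-dependent)
#' feedback.
#'
#' @param series a [ColonyStateSeries-class]
#' @param onsets named onset times (seconds); defaults to time zero for all.
#' @param smooth_window,diff_window passed to [smoothAndDifferentiate()].
#' @return object of class `flow_fit`: per-forager `m_i`, `r_squared`,
#'   pooled `m`
#' @export
fitIndividualFlow <- function(series, onsets = NULL, smooth_window = 2000,
                              diff_window = 300) {
  t_grid <- stateTimes(series)
  dt <- diff(t_grid[1:2])
  Fser <- movingAverage(colonyState(series),
                        max(1L, round(smooth_window / dt)))
  fi <- foragerContributions(series)
  ids <- colnames(fi)
  if (is.null(onsets)) onsets <- stats::setNames(rep(t_grid[1], ncol(fi)), ids)
  m_i <- r2 <- stats::setNames(rep(NA_real_, ncol(fi)), ids)
  for (k in seq_len(ncol(fi))) {
    sd <- smoothAndDifferentiate(fi[, k], dt, smooth_window, diff_window)
    # trim half a smoothing window at both ends: there the moving average
    # shrinks and the differentiated flow is biased toward zero
    act <- t_grid >= onsets[[ids[k]]] + smooth_window / 2 &
      t_grid <= max(t_grid) - smooth_window / 2
    yy <- sd$flow[act]; xx <- 1 - Fser[act]
    if (stats::sd(xx) == 0)
      stop("degenerate fit: (1 - F) has zero variance in the active window")
    m_i[k] <- sum(yy * xx) / sum(xx * xx)
    r2[k] <- 1 - sum((yy - m_i[k] * xx)^2) / sum((yy - mean(yy))^2)
  }
  structure(list(m_i = m_i, r_squared = r2, m = mean(m_i)),
            class = "flow_fit")
}

#' @export
print.flow_fit <- function(x, ...) {
  cat("Per-forager flow fit dfi/dt = m_i (1 - F)\n")
  print(data.frame(m_i = x$m_i, R2 = x$r_squared))
  cat("pooled m =", format(x$m, digits = 4), "\n")
  invisible(x)
}

#' Predict the colony trajectory from the feedback law
#'
#' Integrates `dF/dt = n(t) m (1 - F)` where `n(t)` counts the foragers that
#' have begun foraging by time `t`. With constant `n = N` this has the closed
#' form `F(t) = 1 - (1 - F0) exp(-N m t)` (logistic-type saturation).
#'
#' @param m pooled per-forager flow constant (1/seconds).
#' @param onsets forager onset times, seconds.
#' @param t_grid evaluation times.
#' @param F0 initial colony state.
#' @return numeric F(t) on `t_grid`
#' @export
predictColonyTrajectory <- function(m, onsets, t_grid, F0 = 0) {
  if (!is.finite(m) || m < 0) stop("m must be a non-negative number")
  n_of_t <- function(t) sum(onsets <= t)
  sol <- deSolve::lsoda(
    y = c(F = F0), times = t_grid,
    func = function(t, y, parms) list(n_of_t(t) * m * (1 - y)),
    rtol = 1e-10, atol = 1e-12)
  unname(sol[, "F"])
}

#' Extract foraging cycles
#'
#' A cycle spans two consecutive feeding starts of one forager. Its indoor
#' duration is the in-nest time within the cycle (from the `in_nest` timeline
#' flag), the outdoor duration is the remainder, `colony_state_at_cycle` is
#' F at the cycle start, `crop_at_exit` is the forager's crop at the nest
#' exit instant (the first grid point at which `in_nest` flips false), and
#' `n_interactions_in_visit` counts her interactions within the cycle.
#'
#' @param x a [ColonyExperiment-class]
#' @param series optional precomputed [ColonyStateSeries-class]
#' @return data.frame of cycles, one row per consecutive feeding pair
#' @export
extractForagingCycles <- function(x, series = NULL) {
  if (is.null(series)) series <- computeColonyState(x)
  fe <- feedings(x)
  ia <- interactions(x)
  tl <- timelines(x)
  t_grid <- stateTimes(series)
  Fs <- colonyState(series)
  dt <- gridStep(x)
  out <- list()
  for (id in foragerIds(x)) {
    starts <- sort(fe$t_start[fe$forager_id == id])
    if (length(starts) < 2) {
      warning("forager '", id, "' has fewer than 2 feedings; no cycles")
      next
    }
    tli <- tl[tl$ant_id == id, , drop = FALSE]
    tli <- tli[order(tli$t), , drop = FALSE]
    for (j in seq_len(length(starts) - 1)) {
      a <- starts[j]; b <- starts[j + 1]
      win <- tli$t >= a & tli$t < b
      indoor <- sum(tli$in_nest[win]) * dt
      # exit instant: first in-nest -> out-of-nest flip; the closing flip
      # coincides with the next feeding start, so include the endpoint
      win2 <- tli$t >= a & tli$t <= b
      wt <- tli$t[win2]; wn <- tli$in_nest[win2]; wc <- tli$crop[win2]
      flip <- which(!wn & c(FALSE, wn[-length(wn)]))
      crop_exit <- if (length(flip)) wc[flip[1]] else NA_real_
      Fat <- stats::approx(t_grid, Fs, xout = a, rule = 2)$y
      n_int <- if (nrow(ia))
        sum((ia$donor_id == id | ia$recipient_id == id) &
              ia$t_start >= a & ia$t_start < b)
      else 0L
      out[[length(out) + 1L]] <- data.frame(
        forager_id = id, t_feed_start = a, cycle_interval = b - a,
        indoor_duration = indoor, outdoor_duration = (b - a) - indoor,
        colony_state_at_cycle = Fat, crop_at_exit = crop_exit,
        n_interactions_in_visit = n_int, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(forager_id = character(0), t_feed_start = numeric(0),
                      cycle_interval = numeric(0),
                      indoor_duration = numeric(0),
                      outdoor_duration = numeric(0),
                      colony_state_at_cycle = numeric(0),
                      crop_at_exit = numeric(0),
                      n_interactions_in_visit = integer(0)))
  do.call(rbind, out)
}

# equal-width bins; empty bins collapsed (dropped) with a warning
.binMeans <- function(value, by, n_bins, lim = range(by)) {
  edges <- seq(lim[1], lim[2], length.out = n_bins + 1)
  idx <- findInterval(by, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  agg <- lapply(seq_len(n_bins), function(b) {
    v <- value[idx == b]
    c(center = mean(by[idx == b]), mean = mean(v),
      sem = stats::sd(v) / sqrt(length(v)), n = length(v))
  })
  df <- as.data.frame(do.call(rbind, agg))
  if (any(df$n == 0)) {
    warning(sum(df$n == 0), " empty bin(s) collapsed")
    df <- df[df$n > 0, , drop = FALSE]
  }
  df
}

#' Fit foraging frequency against colony vacancy
#'
#' Bins cycle frequencies (1 / cycle interval) into equally spaced colony-
#' state bins and fits the bin means linearly against the vacancy `1 - F`.
#' Spearman rank correlations of the indoor and outdoor phase durations with
#' F are reported alongside: the indoor phase carries the trend.
#'
#' @param cycles data.frame from [extractForagingCycles()]
#' @param n_bins number of colony-state bins (default 5)
#' @param weighted if TRUE, weight bin means by 1/SEM^2 in the fit
#' @return object of class `frequency_fit` with `intercept`, `slope` (per
#'   second per unit vacancy), `r_squared`, the binned table, and the two
#'   Spearman tests
#' @export
fitFrequencyVsVacancy <- function(cycles, n_bins = 5, weighted = FALSE) {
  if (nrow(cycles) < 2) stop("need at least two cycles")
  bins <- .binMeans(1 / cycles$cycle_interval,
                    cycles$colony_state_at_cycle, n_bins)
  if (nrow(bins) < 2)
    stop("need at least two non-empty colony-state bins")
  w <- if (weighted) 1 / pmax(bins$sem, 1e-12)^2 else rep(1, nrow(bins))
  fit <- stats::lm(mean ~ I(1 - center), data = bins, weights = w)
  sp_in <- suppressWarnings(
    stats::cor.test(cycles$indoor_duration, cycles$colony_state_at_cycle,
                    method = "spearman", exact = FALSE))
  sp_out <- suppressWarnings(
    stats::cor.test(cycles$outdoor_duration, cycles$colony_state_at_cycle,
                    method = "spearman", exact = FALSE))
  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    r_squared = summary(fit)$r.squared,
    bins = bins,
    spearman_indoor = c(rho = unname(sp_in$estimate), p = sp_in$p.value),
    spearman_outdoor = c(rho = unname(sp_out$estimate), p = sp_out$p.value)),
    class = "frequency_fit")
}

#' @export
print.frequency_fit <- function(x, ...) {
  cat("Foraging frequency vs vacancy: freq =",
      format(x$intercept, digits = 3), "+",
      format(x$slope, digits = 3), "* (1 - F), R2 =",
      format(x$r_squared, digits = 3), "\n")
  cat("Spearman vs F  indoor rho =",
      format(x$spearman_indoor["rho"], digits = 2),
      " outdoor rho =", format(x$spearman_outdoor["rho"], digits = 2), "\n")
  invisible(x)
}

#' In-nest durations around a perturbation
#'
#' Bins forager in-nest (indoor) durations into equal time bins and reports
#' the mean ± SEM per bin together with a before/after contrast: the mean of
#' the last pre-perturbation bin minus the mean of the first post-
#' perturbation bin. A positive contrast means the introduction of hungry
#' ants shortened the foragers' stays in the nest.
#'
#' @param cycles data.frame with `t_feed_start` and `indoor_duration`
#'   (from [extractForagingCycles()])
#' @param perturbation_time seconds
#' @param n_bins number of time bins across the record
#' @return list with the binned table and `contrast`
#' @export
perturbationResponse <- function(cycles, perturbation_time, n_bins = 6) {
  tt <- cycles$t_feed_start
  if (!any(tt >= perturbation_time))
    stop("no post-perturbation data")
  if (!any(tt < perturbation_time))
    stop("no pre-perturbation data")
  bins <- .binMeans(cycles$indoor_duration, tt, n_bins)
  pre <- bins[bins$center < perturbation_time, , drop = FALSE]
  post <- bins[bins$center >= perturbation_time, , drop = FALSE]
  contrast <- if (nrow(pre) && nrow(post))
    pre$mean[nrow(pre)] - post$mean[1]
  else NA_real_
  list(bins = bins, contrast = contrast,
       perturbation_time = perturbation_time)
}
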