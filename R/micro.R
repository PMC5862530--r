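#' Fit an exponential rate to a sample of interaction volumes
#'
#' Fits the exponential density `lambda * exp(-lambda * v)` to the
#' normalized histogram of the volumes by least squares at the bin centres,
#' repeated over a sweep of histogram binwidths; the reported rate is the
#' mean ± SD across binwidths. The closed-form maximum-likelihood estimate
#' (1 / sample mean) is returned as a cross-check — the two agree closely
#' for genuinely exponential samples.
#'
#' @param volumes strictly positive volumes; negative (recipient-to-forager)
#'   interactions must be excluded upstream.
#' @param binwidths histogram binwidths to sweep (default 17 values uniform
#'   on \[0.01, 0.09\], in the same units as `volumes`).
#' @param min_n minimum sample size.
#' @return list with `lambda` (mean over binwidths), `lambda_sd`,
#'   `lambda_mle`, and `per_binwidth`
#' @export
fitExponentialHistogram <- function(volumes,
                                    binwidths = seq(0.01, 0.09,
                                                    length.out = 17),
                                    min_n = 20) {
  volumes <- volumes[is.finite(volumes)]
  if (length(volumes) < min_n)
    stop("insufficient data: need at least ", min_n, " volumes, got ",
         length(volumes))
  if (any(volumes <= 0))
    stop("volumes must be strictly positive (exclude negative interactions)")
  if (stats::sd(volumes) == 0)
    stop("degenerate sample: zero-variance volumes")
  fits <- vapply(binwidths, function(bw) {
    breaks <- seq(0, max(volumes) + bw, by = bw)
    h <- graphics::hist(volumes, breaks = breaks, plot = FALSE)
    lo <- utils::head(h$breaks, -1)
    hi <- utils::tail(h$breaks, -1)
    dd <- h$density
    # model density averaged over each bin (exact integral / binwidth):
    # evaluating lambda*exp(-lambda*v) at the bin centre instead biases
    # the fit upward where the density decays within a few bins
    obj <- function(lam) {
      mdl <- (exp(-lam * lo) - exp(-lam * hi)) / (hi - lo)
      sum((dd - mdl)^2)
    }
    # the LS objective is multimodal in lambda (it plateaus as the model
    # density vanishes); bracket the minimum with a log-grid scan around
    # the MLE before refining
    cand <- (1 / mean(volumes)) * 2^seq(-4, 4, length.out = 33)
    best <- which.min(vapply(cand, obj, numeric(1)))
    bracket <- c(cand[max(best - 1L, 1L)], cand[min(best + 1L, length(cand))])
    stats::optimize(obj, bracket, tol = 1e-8 / mean(volumes))$minimum
  }, numeric(1))
  list(lambda = mean(fits), lambda_sd = stats::sd(fits),
       lambda_mle = 1 / mean(volumes),
       per_binwidth = data.frame(binwidth = binwidths, lambda = fits))
}

#' Positive forager-to-non-forager interactions
#'
#' Selects the interactions used by the volume-law fits: forager is the
#' donor and the transferred volume is positive. The count and summed volume
#' of the excluded negative (recipient-to-forager) interactions are attached
#' as attributes so the discarded fraction of total flow can be reported.
#'
#' @param x a [ColonyExperiment-class]
#' @return the filtered interaction data.frame, with attributes
#'   `n_negative` and `negative_flow_fraction`
#' @export
positiveInteractions <- function(x) {
  ia <- interactions(x)
  fids <- foragerIds(x)
  ia <- ia[ia$donor_id %in% fids | ia$recipient_id %in% fids, , drop = FALSE]
  pos <- ia[ia$forager_is_donor & ia$volume > 0, , drop = FALSE]
  neg <- ia[!(ia$forager_is_donor & ia$volume > 0), , drop = FALSE]
  attr(pos, "n_negative") <- nrow(neg)
  attr(pos, "negative_flow_fraction") <-
    if (nrow(ia)) sum(abs(neg$volume)) / sum(abs(ia$volume)) else 0
  pos
}

#' Fit the conditional exponential volume law
#'
#' Bins positive interactions by the conditioning ant's crop load, fits an
#' exponential rate `lambda_c` per bin (binwidth-swept histogram fit), and
#' then fits the hyperbolic law across bins. In `recipient` mode the law is
#' `lambda_c = lambda0 / (C0 - c)`: volumes scale with the space left in the
#' recipient's crop, and `C0` is the average crop-load target. In `forager`
#' mode the alternative `lambda_c = const / c` (volumes as fractions of the
#' donor's load) is fit and compared against a constant — on data whose
#' volumes do not depend on the donor the hyperbola is no better than the
#' constant and its R² is at or below zero.
#'
#' @param interactions positive-interaction data.frame (see
#'   [positiveInteractions()]); needs `volume` and the conditioning crop
#'   column.
#' @param condition_on `"recipient"` or `"forager"`.
#' @param n_bins number of crop bins (default 7).
#' @param binwidths passed to [fitExponentialHistogram()].
#' @return object of class `volume_law_fit`: per-bin table (`crop`,
#'   `lambda`, `lambda_sd`, `n`), and in recipient mode `lambda0`, `C0` and
#'   `r_squared`; in forager mode `const`, `r_squared` (may be negative) and
#'   `r_squared_constant`.
#' @export
fitLambdaVsCrop <- function(interactions, condition_on = c("recipient",
                                                           "forager"),
                            n_bins = 7,
                            binwidths = seq(0.01, 0.09, length.out = 17)) {
  condition_on <- match.arg(condition_on)
  crop <- if (condition_on == "recipient") interactions$recipient_crop
          else interactions$donor_crop
  v <- interactions$volume
  keep <- is.finite(crop) & is.finite(v) & v > 0
  crop <- crop[keep]; v <- v[keep]
  if (!length(crop)) stop("no usable interactions")
  edges <- seq(min(crop), max(crop), length.out = n_bins + 1)
  idx <- findInterval(crop, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  tab <- lapply(seq_len(n_bins), function(b) {
    vb <- v[idx == b]
    if (length(vb) < 20) return(NULL)
    f <- fitExponentialHistogram(vb, binwidths)
    data.frame(crop = mean(crop[idx == b]), lambda = f$lambda,
               lambda_sd = f$lambda_sd, n = length(vb))
  })
  dropped <- sum(vapply(tab, is.null, logical(1)))
  if (dropped) warning(dropped, " crop bin(s) too sparse, dropped")
  tab <- do.call(rbind, tab)
  if (is.null(tab) || nrow(tab) < 3)
    stop("too few populated crop bins for the hyperbolic fit")
  r2 <- function(obs, fit) 1 - sum((obs - fit)^2) / sum((obs - mean(obs))^2)
  if (condition_on == "recipient") {
    start <- list(lambda0 = tab$lambda[1] * (max(tab$crop) + 0.2 -
                                               tab$crop[1]),
                  C0 = max(tab$crop) + 0.2)
    fit <- minpack.lm::nlsLM(lambda ~ lambda0 / (C0 - crop), data = tab,
                             start = start,
                             lower = c(1e-8, max(tab$crop) + 1e-6),
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200))
    co <- stats::coef(fit)
    flagged <- co[["C0"]] <= max(crop)
    if (flagged)
      warning("fitted C0 lies below the largest observed crop load ",
              "(expected when per-ant targets vary around the mean); ",
              "C0 is the mean crop-load target")
    structure(list(condition_on = condition_on, bins = tab,
                   lambda0 = co[["lambda0"]], C0 = co[["C0"]],
                   r_squared = r2(tab$lambda, stats::fitted(fit)),
                   nonphysical = flagged),
              class = "volume_law_fit")
  } else {
    fit <- minpack.lm::nlsLM(lambda ~ const / crop, data = tab,
                             start = list(const = mean(tab$lambda * tab$crop)))
    structure(list(condition_on = condition_on, bins = tab,
                   const = stats::coef(fit)[["const"]],
                   r_squared = r2(tab$lambda, stats::fitted(fit)),
                   r_squared_constant = r2(tab$lambda,
                                           rep(mean(tab$lambda),
                                               nrow(tab)))),
              class = "volume_law_fit")
  }
}

#' @export
print.volume_law_fit <- function(x, ...) {
  if (x$condition_on == "recipient")
    cat("Volume law lambda_c = lambda0 / (C0 - c):",
        "lambda0 =", format(x$lambda0, digits = 4),
        " C0 =", format(x$C0, digits = 4),
        " R2 =", format(x$r_squared, digits = 3), "\n")
  else
    cat("Donor-conditioned law lambda_c = const / c:",
        "R2 =", format(x$r_squared, digits = 3),
        "(constant model R2 =",
        format(x$r_squared_constant, digits = 3), ")\n")
  invisible(x)
}

#' Collapse of volume distributions under available-space normalization
#'
#' Normalizes every interaction volume by the space left in the recipient's
#' crop, `vtilde = v / (C0 - c)`. If volumes are exponential fractions of
#' that space, the per-crop-bin distributions of `vtilde` collapse onto a
#' single exponential whose mean is `1/lambda0`. Records with
#' `c >= C0` are excluded (their available space is undefined) and counted.
#'
#' @param interactions positive-interaction data.frame.
#' @param C0 average crop-load target from [fitLambdaVsCrop()].
#' @param n_bins crop bins used for the pairwise collapse check.
#' @param binwidths passed to [fitExponentialHistogram()].
#' @return list with `vtilde`, the fitted `mean_fraction` (= 1/rate) and
#'   `lambda` from the histogram fit, the MLE, a Kolmogorov–Smirnov
#'   goodness-of-fit p-value against the fitted exponential, the matrix of
#'   pairwise two-sample KS p-values between crop bins, and `n_excluded`.
#' @export
collapseNormalizedVolumes <- function(interactions, C0, n_bins = 7,
                                      binwidths = seq(0.01, 0.09,
                                                      length.out = 17)) {
  v <- interactions$volume
  c_r <- interactions$recipient_crop
  keep <- v > 0 & c_r < C0
  n_excluded <- sum(!keep)
  v <- v[keep]; c_r <- c_r[keep]
  vt <- v / (C0 - c_r)
  if (stats::sd(vt) < 1e-12 * mean(vt))
    stop("degenerate normalized volumes (deterministic transfer rule?)")
  f <- fitExponentialHistogram(vt, binwidths)
  ks <- stats::ks.test(vt, "pexp", rate = f$lambda_mle)
  edges <- seq(min(c_r), max(c_r), length.out = n_bins + 1)
  idx <- findInterval(c_r, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  groups <- split(vt, idx)
  groups <- groups[vapply(groups, length, 1L) >= 10]
  np <- length(groups)
  pmat <- matrix(NA_real_, np, np)
  if (np > 1)
    for (a in 1:(np - 1)) for (b in (a + 1):np)
      pmat[a, b] <- suppressWarnings(
        stats::ks.test(groups[[a]], groups[[b]])$p.value)
  list(vtilde = vt, lambda = f$lambda, mean_fraction = 1 / f$lambda,
       lambda_mle = f$lambda_mle, ks_p = ks$p.value,
       pairwise_ks_p = pmat, n_excluded = n_excluded)
}

#' Parameter-recovery experiment for the volume law
#'
#' Generates synthetic interactions directly from the generative volume
#' rule — recipient crop loads uniform on `crop_range`, volumes exponential
#' with rate `lambda0 / (C0 - c)`, a non-binding donor — and runs the full
#' estimation chain ([fitLambdaVsCrop()]) on them. Used to validate that
#' the estimator recovers the constants that generated the data.
#'
#' @param n number of interactions
#' @param lambda0,C0 generative constants
#' @param crop_range range of recipient crop loads
#' @param n_bins,binwidths passed to [fitLambdaVsCrop()]
#' @return a `volume_law_fit` (recipient mode)
#' @export
recoverVolumeLaw <- function(n = 10000, lambda0 = 7.01, C0 = 1.14,
                             crop_range = c(0, 1), n_bins = 7,
                             binwidths = seq(0.01, 0.09, length.out = 17)) {
  crops <- stats::runif(n, crop_range[1], crop_range[2])
  dr <- drawInteractionVolume(Inf, crops, C0, lambda0)
  ia <- data.frame(volume = dr$volume, recipient_crop = crops,
                   donor_crop = Inf)[!dr$censored, ]
  fitLambdaVsCrop(ia, "recipient", n_bins = n_bins, binwidths = binwidths)
}

# colony state at given times, via linear interpolation of the smoothed F;
# the smoothing window is capped at the series length for short records
.stateAt <- function(series, times, smooth_window = 2000) {
  tg <- stateTimes(series)
  dt <- diff(tg[1:2])
  k <- min(max(1L, round(smooth_window / dt)), length(tg))
  Fs <- movingAverage(colonyState(series), k)
  stats::approx(tg, Fs, xout = times, rule = 2)$y
}

#' Mean interaction volume versus colony state
#'
#' Bins positive interaction volumes by the colony state at which they
#' occurred and overlays the parameter-free prediction of the volume law:
#' once recipients constitute a representative sample of the colony, the
#' mean volume is `(C0 / lambda0) * (1 - F)`. The discrepancy per bin is
#' reported in SEM units.
#'
#' @param interactions positive-interaction data.frame.
#' @param series a [ColonyStateSeries-class].
#' @param lambda0,C0 volume-law parameters.
#' @param n_bins colony-state bins (default 5).
#' @return list with the binned table (`center`, `mean`, `sem`, `n`,
#'   `predicted`, `discrepancy_sem`) and the prediction slope `C0/lambda0`
#' @export
meanVolumeVsState <- function(interactions, series, lambda0, C0,
                              n_bins = 5) {
  Fat <- .stateAt(series, interactions$t_end)
  bins <- .binMeans(interactions$volume, Fat, n_bins)
  bins$predicted <- (C0 / lambda0) * (1 - bins$center)
  bins$discrepancy_sem <- (bins$mean - bins$predicted) /
    pmax(bins$sem, 1e-12)
  list(bins = bins, slope = C0 / lambda0)
}

#' Forager interaction rate versus colony state
#'
#' Intervals between a forager's consecutive interactions within one nest
#' visit are binned by the colony state at the interval midpoint; the rate
#' per bin is the inverse of the bin's mean interval (the Poisson-rate
#' maximum-likelihood estimate — averaging inverse intervals directly is
#' divergent for exponential waiting times), and the bin rates are fit
#' linearly, `r(F) = r0 - r1 * F`.
#'
#' @param x a [ColonyExperiment-class]
#' @param series a [ColonyStateSeries-class]
#' @param n_bins colony-state bins (default 5)
#' @return object of class `rate_fit`: `r0`, `r1`, `r_squared`, binned table
#' @export
fitInteractionRate <- function(x, series, n_bins = 5) {
  ia <- interactions(x)
  fe <- feedings(x)
  ivs <- numeric(0); mids <- numeric(0)
  for (id in foragerIds(x)) {
    iai <- ia[ia$donor_id == id | ia$recipient_id == id, , drop = FALSE]
    if (nrow(iai) < 2) next
    iai <- iai[order(iai$t_start), , drop = FALSE]
    # visit boundaries: interactions separated by a feeding are in
    # different visits
    fts <- sort(fe$t_start[fe$forager_id == id])
    visit <- findInterval(iai$t_start, fts)
    for (vv in unique(visit)) {
      tt <- iai$t_start[visit == vv]
      if (length(tt) < 2) next      # single interaction: no interval
      iv <- diff(tt)
      ok <- iv > 0
      ivs <- c(ivs, iv[ok])
      mids <- c(mids, (tt[-length(tt)] + iv / 2)[ok])
    }
  }
  if (length(ivs) < n_bins) stop("too few interaction intervals")
  Fat <- .stateAt(series, mids)
  bins <- .binMeans(ivs, Fat, n_bins)
  # per-bin rate: inverse of the mean interval; SEM by the delta method
  bins$sem <- bins$sem / bins$mean^2
  bins$mean <- 1 / bins$mean
  fit <- stats::lm(mean ~ center, data = bins)
  structure(list(r0 = unname(stats::coef(fit)[1]),
                 r1 = -unname(stats::coef(fit)[2]),
                 r_squared = summary(fit)$r.squared, bins = bins),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("Interaction rate r(F) =", format(x$r0, digits = 3), "-",
      format(x$r1, digits = 3), "* F, R2 =",
      format(x$r_squared, digits = 3), "\n")
  invisible(x)
}

#' Decompose the forager unloading rate into rate and volume components
#'
#' The per-visit unloading rate — (crop at entry − crop at exit) / indoor
#' duration — is binned by colony state and fit against three one-parameter
#' proportionality models: interaction rate only (`k * r(F)`), mean
#' interaction volume only (`k * v(F)` with `v(F)` the linear mean-volume
#' fit), and their product. Interaction volumes, not rates, carry the
#' feedback, so the volume-only R² exceeds the rate-only R², and the
#' combined model does at least as well.
#'
#' @param x a [ColonyExperiment-class]
#' @param series a [ColonyStateSeries-class]
#' @param cycles optional precomputed [extractForagingCycles()] output
#' @param rate_fit optional precomputed [fitInteractionRate()] output
#' @param n_bins colony-state bins (default 5)
#' @return object of class `unloading_decomposition` with the three R²
#'   values, the component fits, and the binned unloading rates
#' @export
unloadingRateDecomposition <- function(x, series, cycles = NULL,
                                       rate_fit = NULL, n_bins = 5) {
  if (is.null(cycles)) cycles <- extractForagingCycles(x, series)
  if (is.null(rate_fit)) rate_fit <- fitInteractionRate(x, series)
  tl <- timelines(x)
  # per-visit unloading rate needs crop at entry; entry crop is the
  # forager's crop at the first in-nest grid point of the cycle
  entry_crop <- vapply(seq_len(nrow(cycles)), function(i) {
    id <- cycles$forager_id[i]
    a <- cycles$t_feed_start[i]
    b <- a + cycles$cycle_interval[i]
    tli <- tl[tl$ant_id == id & tl$t >= a & tl$t < b & tl$in_nest, ,
              drop = FALSE]
    if (nrow(tli)) tli$crop[order(tli$t)][1] else NA_real_
  }, numeric(1))
  unload <- entry_crop - cycles$crop_at_exit
  dur <- cycles$indoor_duration
  ok <- is.finite(unload) & is.finite(dur) & dur > 0
  if (any(!ok & is.finite(dur) & dur <= 0))
    warning(sum(dur <= 0, na.rm = TRUE),
            " cycle(s) with non-positive indoor duration dropped")
  urate <- unload[ok] / dur[ok]
  Fat <- cycles$colony_state_at_cycle[ok]
  bins <- .binMeans(urate, Fat, n_bins)
  # linear mean-volume fit v(F) = a + b F over the same state bins
  vol_fit <- stats::lm(mean ~ center,
                       data = .binMeans(
                         interactions(x)$volume[interactions(x)$volume > 0],
                         .stateAt(series,
                                  interactions(x)$t_end[
                                    interactions(x)$volume > 0]),
                         n_bins))
  a_v <- unname(stats::coef(vol_fit)[1]); b_v <- unname(stats::coef(vol_fit)[2])
  rate_pred <- pmax(rate_fit$r0 - rate_fit$r1 * bins$center, 0)
  vol_pred <- pmax(a_v + b_v * bins$center, 0)
  fit_prop <- function(pred) {
    k <- sum(bins$mean * pred) / sum(pred^2)
    1 - sum((bins$mean - k * pred)^2) /
      sum((bins$mean - mean(bins$mean))^2)
  }
  structure(list(
    r_squared = c(rate_only = fit_prop(rate_pred),
                  volume_only = fit_prop(vol_pred),
                  combined = fit_prop(rate_pred * vol_pred)),
    volume_fit = c(intercept = a_v, slope = b_v),
    rate_fit = rate_fit, bins = bins), class = "unloading_decomposition")
}

#' @export
print.unloading_decomposition <- function(x, ...) {
  cat("Unloading-rate model comparison (R2):\n")
  print(round(x$r_squared, 3))
  invisible(x)
}

#' Are interaction partners a representative sample of the colony?
#'
#' Compares, per colony-state bin, the crop loads of the non-foragers that
#' actually interacted with foragers against snapshot crop loads of all
#' non-foragers in the colony. If foragers sample partners without regard to
#' crop load, the two distributions share their mean (within sampling
#' error); partner means below the population mean indicate biased sampling
#' of emptier recipients.
#'
#' @param x a [ColonyExperiment-class]
#' @param series a [ColonyStateSeries-class]
#' @param n_bins colony-state bins (default 5)
#' @param n_population snapshot sample size per bin
#' @return data.frame per bin: partner mean ± SEM, population mean ± SEM,
#'   and their difference in SEM units
#' @export
recipientRepresentativeness <- function(x, series, n_bins = 5,
                                        n_population = 202) {
  ia <- positiveInteractions(x)
  Fat <- .stateAt(series, ia$t_end)
  tl <- timelines(x)
  nf_ids <- ants(x)$ant_id[ants(x)$role == "non-forager"]
  tl <- tl[tl$ant_id %in% nf_ids, , drop = FALSE]
  Ftl <- .stateAt(series, tl$t)
  edges <- seq(0, max(c(Fat, Ftl)), length.out = n_bins + 1)
  idxp <- findInterval(Fat, edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  idxa <- findInterval(Ftl, edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  out <- lapply(seq_len(n_bins), function(b) {
    partners <- ia$recipient_crop[idxp == b]
    pop <- tl$crop[idxa == b]
    if (length(pop) > n_population)
      pop <- pop[round(seq(1, length(pop), length.out = n_population))]
    if (!length(partners) || !length(pop)) return(NULL)
    psem <- stats::sd(partners) / sqrt(length(partners))
    asem <- stats::sd(pop) / sqrt(length(pop))
    data.frame(state_bin = mean(edges[b:(b + 1)]),
               partner_mean = mean(partners), partner_sem = psem,
               population_mean = mean(pop), population_sem = asem,
               n_partners = length(partners), n_population = length(pop),
               diff_sem = (mean(partners) - mean(pop)) /
                 sqrt(psem^2 + asem^2))
  })
  do.call(rbind, out)
}
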