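#' Extract forager exit-decision points under a decision-rate model
#'
#' The rate of observed nest exits is modelled as a Markovian product of a
#' decision rate and a per-decision exit probability. Since actual decision
#' times are unobservable, three candidate decision schedules are supported:
#'
#' * `constant` — every in-nest grid sample outside trophallaxis is a
#'   decision point;
#' * `interaction_rate` — the first sample after each trophallactic
#'   interaction ends;
#' * `unloading_rate` — one point each time the forager's crop has dropped
#'   by a further `delta_crop` (fraction of her capacity) since nest entry;
#'   within-visit crop increases are rare and reset the accumulator.
#'
#' A point is labelled an exit when the forager leaves the nest before her
#' next decision point of the same model, so within a visit at most the
#' final point is an exit. Crop loads are taken from the timelines, which
#' should be per-forager normalized (see [normalizeCrops()]); the colony
#' state is interpolated from `series`.
#'
#' @param x a [ColonyExperiment-class]
#' @param model `"constant"`, `"interaction_rate"` or `"unloading_rate"`
#' @param series optional [ColonyStateSeries-class] (computed if missing)
#' @param delta_crop unloading increment (unloading_rate model only)
#' @return object of class `decision_points`: data.frame `points`
#'   (`t`, `forager_id`, `crop`, `colony`, `exit`) plus the model tag
#' @export
extractDecisionPoints <- function(x, model = c("constant",
                                               "interaction_rate",
                                               "unloading_rate"),
                                  series = NULL, delta_crop = 0.10) {
  model <- match.arg(model)
  if (is.null(series)) series <- computeColonyState(x)
  tl <- timelines(x)
  ia <- interactions(x)
  pts <- list()
  for (id in foragerIds(x)) {
    tli <- tl[tl$ant_id == id, , drop = FALSE]
    tli <- tli[order(tli$t), , drop = FALSE]
    if (!nrow(tli)) next
    # contiguous in-nest visits
    runs <- rle(tli$in_nest)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    visits <- cbind(starts, ends)[runs$values, , drop = FALSE]
    iai <- ia[ia$donor_id == id | ia$recipient_id == id, , drop = FALSE]
    for (r in seq_len(nrow(visits))) {
      seg <- tli[visits[r, 1]:visits[r, 2], , drop = FALSE]
      # the visit ends in an exit only if the record continues afterwards
      ends_in_exit <- visits[r, 2] < nrow(tli)
      sel <- switch(model,
        constant = which(!seg$in_trophallaxis),
        interaction_rate = {
          t_ends <- iai$t_end[iai$t_start >= seg$t[1] &
                                iai$t_start <= seg$t[nrow(seg)]]
          if (length(t_ends))
            unique(vapply(t_ends, function(te) {
              w <- which(seg$t >= te)
              if (length(w)) w[1] else NA_integer_
            }, integer(1)))
          else integer(0)
        },
        unloading_rate = {
          acc <- 0; last <- seg$crop[1]; keep <- integer(0)
          for (i in seq_len(nrow(seg))[-1]) {
            d <- last - seg$crop[i]
            if (d < 0) acc <- 0          # crop rose: reset the accumulator
            else acc <- acc + d
            last <- seg$crop[i]
            if (acc >= delta_crop) {
              keep <- c(keep, i)
              acc <- acc - delta_crop * floor(acc / delta_crop)
            }
          }
          keep
        })
      sel <- sort(sel[!is.na(sel)])
      if (!length(sel)) next
      n_sel <- length(sel)
      exit <- rep(FALSE, n_sel)
      if (ends_in_exit) exit[n_sel] <- TRUE
      pts[[length(pts) + 1L]] <- data.frame(
        t = seg$t[sel], forager_id = id, crop = seg$crop[sel],
        colony = .stateAt(series, seg$t[sel]), exit = exit,
        stringsAsFactors = FALSE)
    }
  }
  points <- if (length(pts)) do.call(rbind, pts)
            else data.frame(t = numeric(0), forager_id = character(0),
                            crop = numeric(0), colony = numeric(0),
                            exit = logical(0))
  structure(list(points = points, model = model,
                 delta_crop = if (model == "unloading_rate") delta_crop
                              else NA_real_),
            class = "decision_points")
}

#' @export
print.decision_points <- function(x, ...) {
  cat("Decision points (", x$model, " model): ", nrow(x$points),
      " points, ", sum(x$points$exit), " exits\n", sep = "")
  invisible(x)
}

#' k-nearest-neighbour exit probability surface
#'
#' For each evaluation point on the (crop, colony) unit square, the `n`
#' nearest observations (Euclidean distance on the normalized axes) define
#' one surface sample: its probability is the fraction of exits among those
#' observations and its plotted location is their mean position.
#'
#' @param points decision-point data.frame (`crop`, `colony`, `exit`) or a
#'   `decision_points` object
#' @param n_neighbors neighbourhood size (the study used 300 for the dense
#'   constant-rate point set and 30 for the sparser event-based sets)
#' @param grid_n evaluation grid resolution per axis
#' @return data.frame `crop`, `colony` (mean neighbour locations),
#'   `probability`
#' @export
knnExitSurface <- function(points, n_neighbors = 30, grid_n = 25) {
  if (inherits(points, "decision_points")) points <- points$points
  n <- nrow(points)
  if (n_neighbors > n)
    stop("n_neighbors exceeds the number of decision points")
  gx <- seq(0, 1, length.out = grid_n)
  ev <- expand.grid(crop = gx, colony = gx)
  out <- matrix(NA_real_, nrow(ev), 3)
  for (i in seq_len(nrow(ev))) {
    d2 <- (points$crop - ev$crop[i])^2 + (points$colony - ev$colony[i])^2
    nb <- order(d2)[seq_len(n_neighbors)]
    out[i, ] <- c(mean(points$crop[nb]), mean(points$colony[nb]),
                  mean(points$exit[nb]))
  }
  data.frame(crop = out[, 1], colony = out[, 2], probability = out[, 3])
}

#' Logistic fit of the exit decision
#'
#' Maximum-likelihood logistic regression of the binary exit outcome on the
#' requested covariates, with Wald 95\% confidence intervals. For the
#' one-dimensional crop-only fit (the projection `G(crop)`), points in the
#' lowest crop interval are excluded: an empty crop forces an exit, so its
#' probability is 1 by construction and would dominate the fit.
#'
#' Two R²-type diagnostics are reported: the squared Pearson correlation
#' between the fitted probabilities and a kNN surface estimate evaluated at
#' the observation points, and McFadden's pseudo-R².
#'
#' @param points decision-point data.frame or `decision_points` object
#' @param covariates character subset of `c("crop", "colony")`
#' @param exclude_lowest_crop lowest-crop cutoff for the 1-D fit (default
#'   1/7 of the crop range when fitting crop only, 0 otherwise)
#' @param n_neighbors neighbourhood size of the kNN diagnostic
#' @return object of class `exit_fit`: `coefficients`, `ci` (2.5/97.5%),
#'   `r_squared_knn`, `mcfadden`, the `glm` fit, and flags
#' @export
fitExitLogistic <- function(points, covariates = c("crop", "colony"),
                            exclude_lowest_crop = NULL,
                            n_neighbors = min(30, nrow(df) - 1)) {
  if (inherits(points, "decision_points")) points <- points$points
  covariates <- match.arg(covariates, c("crop", "colony"),
                          several.ok = TRUE)
  df <- points
  if (is.null(exclude_lowest_crop))
    exclude_lowest_crop <- if (identical(covariates, "crop"))
      min(df$crop) + diff(range(df$crop)) / 7 else -Inf
  df <- df[df$crop > exclude_lowest_crop, , drop = FALSE]
  if (!any(df$exit) || all(df$exit))
    stop("need both exit and stay labels to fit")
  form <- stats::as.formula(paste("exit ~",
                                  paste(covariates, collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(), data = df)
  separated <- !fit$converged || any(abs(stats::coef(fit)) > 50)
  if (separated) {
    warning("possible complete separation; refitting with a ridge penalty")
    fit <- .ridgeLogistic(df, covariates)
  }
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  ci <- cbind(lower = co - 1.96 * se, upper = co + 1.96 * se)
  p_hat <- stats::fitted(fit)
  r2_knn <- NA_real_
  if (nrow(df) > n_neighbors && length(unique(df$crop)) > 2) {
    # evaluate the kNN diagnostic at a deterministic subsample of points;
    # the surface estimate itself still uses all observations
    eval_idx <- if (nrow(df) > 2000)
      unique(round(seq(1, nrow(df), length.out = 2000)))
    else seq_len(nrow(df))
    knn_p <- vapply(eval_idx, function(i) {
      d2 <- (df$crop - df$crop[i])^2 +
        if ("colony" %in% covariates) (df$colony - df$colony[i])^2 else 0
      mean(df$exit[order(d2)[seq_len(n_neighbors)]])
    }, numeric(1))
    if (stats::sd(knn_p) > 0 && stats::sd(p_hat[eval_idx]) > 0)
      r2_knn <- stats::cor(p_hat[eval_idx], knn_p)^2
  }
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(stats::glm(exit ~ 1,
                                             family = stats::binomial(),
                                             data = df)))
  structure(list(coefficients = co, ci = ci, r_squared_knn = r2_knn,
                 mcfadden = 1 - ll / ll0, separated = separated,
                 n = nrow(df), fit = fit, covariates = covariates),
            class = "exit_fit")
}

# weak L2 penalty via data augmentation; used only under separation
.ridgeLogistic <- function(df, covariates) {
  aug <- df[rep(1, 2 * (length(covariates) + 1)), , drop = FALSE]
  aug$exit <- rep(c(TRUE, FALSE), length.out = nrow(aug))
  aug$crop <- mean(df$crop); aug$colony <- mean(df$colony)
  form <- stats::as.formula(paste("exit ~",
                                  paste(covariates, collapse = " + ")))
  stats::glm(form, family = stats::binomial(), data = rbind(df, aug))
}

#' @export
print.exit_fit <- function(x, ...) {
  cat("Logistic exit fit (", paste(x$covariates, collapse = " + "),
      "), n = ", x$n, "\n", sep = "")
  print(cbind(coef = x$coefficients, x$ci))
  cat("R2 vs kNN surface =", format(x$r_squared_knn, digits = 3),
      " McFadden =", format(x$mcfadden, digits = 3), "\n")
  invisible(x)
}

#' Separation-of-variables test for the exit rule
#'
#' Fits the two-covariate exit logistic under all three decision-rate
#' models. If exits are truly generated by a crop-only decision rule whose
#' decision *rate* tracks the unloading rate (itself controlled by the
#' colony), then the apparent colony effect is an artefact of the decision
#' schedule: it is largest under the constant-rate model, smaller under the
#' interaction-rate model, and shrinks toward zero under the unloading-rate
#' model, where the exit rate factorizes as `U(colony) * G(crop)`.
#'
#' @param x a [ColonyExperiment-class], or a list of them — decision points
#'   from several colonies are then pooled before fitting, as the study
#'   pools its observation colonies
#' @param series optional [ColonyStateSeries-class] (or list matching `x`)
#' @param delta_crop unloading increment for the unloading-rate model
#' @return object of class `separation_test`: per-model coefficient table
#'   and the fits
#' @export
separationOfVariablesTest <- function(x, series = NULL, delta_crop = 0.10) {
  if (!is.list(x)) x <- list(x)
  if (is.null(series)) series <- lapply(x, computeColonyState)
  if (!is.list(series)) series <- list(series)
  stopifnot(length(series) == length(x))
  models <- c("constant", "interaction_rate", "unloading_rate")
  fits <- lapply(models, function(mo) {
    pts <- do.call(rbind, lapply(seq_along(x), function(i)
      extractDecisionPoints(x[[i]], mo, series[[i]], delta_crop)$points))
    fitExitLogistic(pts, covariates = c("crop", "colony"))
  })
  names(fits) <- models
  tab <- do.call(rbind, lapply(models, function(mo) {
    f <- fits[[mo]]
    data.frame(model = mo,
               crop = unname(f$coefficients["crop"]),
               colony = unname(f$coefficients["colony"]),
               colony_lo = f$ci["colony", "lower"],
               colony_hi = f$ci["colony", "upper"],
               colony_vs_crop = abs(unname(f$coefficients["colony"])) /
                 abs(unname(f$coefficients["crop"])),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    table = tab, fits = fits,
    colony_effect_shrinks = all(diff(abs(tab$colony)) < 0),
    relative_colony_effect_shrinks = all(diff(tab$colony_vs_crop) < 0),
    colony_ci_covers_zero =
      tab$colony_lo[3] <= 0 && tab$colony_hi[3] >= 0),
    class = "separation_test")
}

#' @export
print.separation_test <- function(x, ...) {
  cat("Separation-of-variables test (colony coefficient by decision",
      "model):\n")
  print(x$table, row.names = FALSE)
  cat("colony effect relative to crop effect",
      if (x$relative_colony_effect_shrinks) "shrinks monotonically"
      else "does NOT shrink monotonically",
      "toward the unloading-rate model\n")
  cat("unloading-rate model colony CI",
      if (x$colony_ci_covers_zero) "covers" else "does not cover",
      "zero\n")
  invisible(x)
}
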