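#' @import methods
NULL

INTERACTION_COLS <- c("t_start", "t_end", "donor_id", "recipient_id", "volume",
                      "donor_crop", "recipient_crop", "forager_is_donor",
                      "experiment_id")
FEEDING_COLS <- c("forager_id", "t_start", "t_end", "experiment_id")
TIMELINE_COLS <- c("ant_id", "t", "crop", "in_trophallaxis", "at_food",
                   "in_nest", "experiment_id")

#' ColonyExperiment: event logs and crop timelines of one colony
#'
#' The central container of the package. It holds the three canonical event
#' tables of a food-accumulation experiment — trophallactic interactions,
#' food-source feedings, and per-ant crop-load timelines on a uniform time
#' grid — together with ant roles, per-forager onset times (a forager's first
#' return to the nest from the food source) and the colony intake target used
#' to normalise the colony state \eqn{F(t)}.
#'
#' Sign convention (fixed package-wide): an interaction `volume` is positive
#' when food flows from the forager side to the non-forager side and negative
#' when it flows back to the forager.
#'
#' @slot ants data.frame with columns `ant_id`, `role`
#'   (`"forager"`, `"non-forager"` or `"queen"`).
#' @slot interactions data.frame of trophallactic events, columns
#'   `t_start`, `t_end`, `donor_id`, `recipient_id`, `volume`, `donor_crop`,
#'   `recipient_crop`, `forager_is_donor`, `experiment_id`.
#' @slot feedings data.frame of feeding events at the food source, columns
#'   `forager_id`, `t_start`, `t_end`, `experiment_id`.
#' @slot timelines long data.frame of per-ant crop loads on a uniform grid,
#'   columns `ant_id`, `t`, `crop`, `in_trophallaxis`, `at_food`, `in_nest`,
#'   `experiment_id`.
#' @slot intakeTarget numeric(1); the post-hoc saturation level of total
#'   accumulated food (the colony's intake volume target). `NA` until set or
#'   estimated.
#' @slot onsetTimes named numeric; per-forager time of first return to the
#'   nest, the start of each forager's analysis window.
#' @slot metadata list of free-form provenance (normalizers applied, seeds,
#'   configuration).
#'
#' @seealso [readColonyExperiment()], [simulateColony()],
#'   [computeColonyState()]
#' @export
setClass("ColonyExperiment",
  representation(
    ants = "data.frame",
    interactions = "data.frame",
    feedings = "data.frame",
    timelines = "data.frame",
    intakeTarget = "numeric",
    onsetTimes = "numeric",
    metadata = "list"
  ),
  prototype(
    ants = data.frame(ant_id = character(), role = character()),
    interactions = data.frame(),
    feedings = data.frame(),
    timelines = data.frame(),
    intakeTarget = NA_real_,
    onsetTimes = numeric(0),
    metadata = list()
  )
)

setValidity("ColonyExperiment", function(object) {
  msgs <- character(0)
  if (!all(c("ant_id", "role") %in% names(object@ants)))
    msgs <- c(msgs, "'ants' must have columns ant_id and role")
  ia <- object@interactions
  if (nrow(ia)) {
    miss <- setdiff(INTERACTION_COLS, names(ia))
    if (length(miss))
      msgs <- c(msgs, paste0("interactions missing column(s): ",
                             paste(miss, collapse = ", ")))
    else {
      if (any(ia$t_end < ia$t_start))
        msgs <- c(msgs, "interactions with t_end < t_start")
      if (any(ia$donor_crop < 0, na.rm = TRUE) ||
          any(ia$recipient_crop < 0, na.rm = TRUE))
        msgs <- c(msgs, "negative crop loads in interactions")
      ids <- object@ants$ant_id
      if (!all(c(ia$donor_id, ia$recipient_id) %in% ids))
        msgs <- c(msgs, "interaction participant not listed in 'ants'")
    }
  }
  fe <- object@feedings
  if (nrow(fe)) {
    miss <- setdiff(FEEDING_COLS, names(fe))
    if (length(miss))
      msgs <- c(msgs, paste0("feedings missing column(s): ",
                             paste(miss, collapse = ", ")))
    else if (any(fe$t_end < fe$t_start))
      msgs <- c(msgs, "feedings with t_end < t_start")
  }
  tl <- object@timelines
  if (nrow(tl)) {
    miss <- setdiff(TIMELINE_COLS, names(tl))
    if (length(miss))
      msgs <- c(msgs, paste0("timelines missing column(s): ",
                             paste(miss, collapse = ", ")))
    else {
      bad <- vapply(split(tl$t, tl$ant_id), function(tt) {
        d <- diff(tt)
        length(d) > 0 && (any(d <= 0) || diff(range(d)) > 1e-8 * max(d))
      }, logical(1))
      if (any(bad))
        msgs <- c(msgs, paste0("non-uniform or non-increasing time grid for ",
                               "ant(s): ",
                               paste(names(bad)[bad], collapse = ", ")))
    }
  }
  if (length(object@intakeTarget) != 1L)
    msgs <- c(msgs, "intakeTarget must be a single number (possibly NA)")
  else if (!is.na(object@intakeTarget) && object@intakeTarget <= 0)
    msgs <- c(msgs, "intakeTarget must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticColonyExperiment: a simulated colony with its ground truth
#'
#' Extends [ColonyExperiment-class] with the generative record of a simulation
#' run: the configuration, per-interaction latent draws (the exponential
#' fraction of the recipient's available crop space, and whether the draw was
#' censored at a physical limit), and the forager decision-point log.
#'
#' @slot groundTruth list with elements `config` (the [simulationConfig()]
#'   used), `vtilde` (latent exponential fraction per interaction),
#'   `censored` (logical per interaction; TRUE when the drawn volume was
#'   truncated by the donor load or the recipient's remaining space),
#'   `decisions` (data.frame `t`, `forager_id`, `crop`, `colony`, `exit`),
#'   and `crop_targets` (named per-ant targets).
#' @export
setClass("SyntheticColonyExperiment",
  contains = "ColonyExperiment",
  representation(groundTruth = "list"),
  prototype(groundTruth = list())
)

#' ColonyStateSeries: colony state and per-forager contributions
#'
#' The colony state \eqn{F(t)} is the total food accumulated in the colony
#' divided by the intake target, decomposed as the sum of per-forager
#' contributions \eqn{F(t) = \sum_i f_i(t)}. The identity holds exactly at
#' every grid point by construction and is enforced by the validity method.
#'
#' @slot tGrid numeric; uniform time grid (seconds).
#' @slot F numeric; colony state on the grid.
#' @slot fi numeric matrix, one column per forager, rows matching `tGrid`.
#' @slot intakeTarget numeric(1); the normalizer used.
#' @export
setClass("ColonyStateSeries",
  representation(
    tGrid = "numeric",
    F = "numeric",
    fi = "matrix",
    intakeTarget = "numeric"
  )
)

setValidity("ColonyStateSeries", function(object) {
  msgs <- character(0)
  n <- length(object@tGrid)
  if (length(object@F) != n)
    msgs <- c(msgs, "F and tGrid lengths differ")
  if (nrow(object@fi) != n)
    msgs <- c(msgs, "fi rows must match tGrid")
  if (n > 1 && any(diff(object@tGrid) <= 0))
    msgs <- c(msgs, "tGrid must be strictly increasing")
  if (ncol(object@fi) > 0 && n > 0) {
    if (max(abs(rowSums(object@fi) - object@F)) > 1e-10 * max(1, max(abs(object@F))))
      msgs <- c(msgs, "F(t) must equal the sum of per-forager contributions")
  }
  if (length(msgs)) msgs else TRUE
})

# ---- accessors ----

#' @describeIn ColonyExperiment-class interaction event table
#' @param x a `ColonyExperiment`
#' @export
interactions <- function(x) x@interactions

#' @describeIn ColonyExperiment-class feeding event table
#' @export
feedings <- function(x) x@feedings

#' @describeIn ColonyExperiment-class long-format crop timelines
#' @export
timelines <- function(x) x@timelines

#' @describeIn ColonyExperiment-class ant roster with roles
#' @export
ants <- function(x) x@ants

#' @describeIn ColonyExperiment-class ids of classified foragers
#' @export
foragerIds <- function(x) x@ants$ant_id[x@ants$role == "forager"]

#' @describeIn ColonyExperiment-class colony intake target (NA if unset)
#' @export
intakeTarget <- function(x) x@intakeTarget

#' @describeIn ColonyExperiment-class per-forager first-return times
#' @export
onsetTimes <- function(x) x@onsetTimes

#' @describeIn SyntheticColonyExperiment-class simulation ground truth
#' @param x a `SyntheticColonyExperiment`
#' @export
groundTruth <- function(x) x@groundTruth

#' Grid spacing of an experiment's timelines
#'
#' @param x a `ColonyExperiment`
#' @return dt in seconds
#' @export
gridStep <- function(x) {
  tl <- timelines(x)
  if (!nrow(tl)) stop("experiment has no timelines")
  tt <- sort(unique(tl$t))
  if (length(tt) < 2) stop("timeline grid has fewer than two points")
  diff(tt[1:2])
}

setMethod("show", "ColonyExperiment", function(object) {
  nf <- sum(object@ants$role == "forager")
  cat("A", class(object), "with", nrow(object@ants), "ants (", nf,
      "foragers )\n")
  cat("  interactions:", nrow(object@interactions),
      " feedings:", nrow(object@feedings),
      " timeline rows:", nrow(object@timelines), "\n")
  cat("  intake target:",
      if (is.na(object@intakeTarget)) "unset (estimated on demand)"
      else format(object@intakeTarget, digits = 4), "\n")
  invisible(object)
})

setMethod("show", "ColonyStateSeries", function(object) {
  cat("A ColonyStateSeries:", length(object@tGrid), "grid points,",
      ncol(object@fi), "foragers\n")
  if (length(object@F))
    cat("  F range:", format(range(object@F), digits = 4),
        " intake target:", format(object@intakeTarget, digits = 4), "\n")
  invisible(object)
})
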