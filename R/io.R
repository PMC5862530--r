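#' Read a colony experiment from canonical event-log CSV files
#'
#' Imports the three canonical tables (trophallactic interactions, feeding
#' events, crop timelines), validates them against the documented schemas,
#' classifies foragers from the feeding log, and determines per-forager onset
#' times (first return to the nest after the first feeding). Column names in
#' external files can be remapped through a YAML mapping file with one block
#' per table, e.g. `interactions: {start_time: t_start}` maps the external
#' column `start_time` to the canonical `t_start`.
#'
#' @param interactions_path,feedings_path,timelines_path CSV file paths.
#' @param mapping_path optional YAML column-remapping file.
#' @param intake_target optional known intake target; left `NA` to be
#'   estimated post hoc from the accumulation plateau by
#'   [computeColonyState()].
#' @return a validated [ColonyExperiment-class]
#' @export
readColonyExperiment <- function(interactions_path, feedings_path,
                                 timelines_path, mapping_path = NULL,
                                 intake_target = NA_real_) {
  mapping <- if (!is.null(mapping_path)) yaml::read_yaml(mapping_path)
             else list()
  ia <- .readTable(interactions_path, INTERACTION_COLS,
                   mapping$interactions, "interactions")
  fe <- .readTable(feedings_path, FEEDING_COLS, mapping$feedings, "feedings")
  tl <- .readTable(timelines_path, TIMELINE_COLS, mapping$timelines,
                   "timelines")
  for (col in c("in_trophallaxis", "at_food", "in_nest"))
    tl[[col]] <- as.logical(tl[[col]])
  ia$forager_is_donor <- as.logical(ia$forager_is_donor)

  # timeline grid must be strictly increasing and uniform within each ant
  for (id in unique(tl$ant_id)) {
    tt <- tl$t[tl$ant_id == id]
    d <- diff(tt)
    if (length(d) && (any(d <= 0) || diff(range(d)) > 1e-8 * max(d)))
      stop("non-monotone or non-uniform timeline grid for ant '", id, "'")
  }

  cls <- classifyForagers(fe)
  all_ids <- unique(c(tl$ant_id, ia$donor_id, ia$recipient_id, fe$forager_id))
  role <- ifelse(all_ids %in% cls$forager, "forager", "non-forager")
  ants <- data.frame(ant_id = all_ids, role = role,
                     stringsAsFactors = FALSE)
  if (length(cls$review))
    warning("ambiguous feeding counts, flagged for manual review: ",
            paste(cls$review, collapse = ", "))

  onsets <- .firstReturnTimes(fe, tl, cls$forager)
  methods::new("ColonyExperiment", ants = ants, interactions = ia,
               feedings = fe, timelines = tl,
               intakeTarget = intake_target, onsetTimes = onsets,
               metadata = list(sources = c(interactions = interactions_path,
                                           feedings = feedings_path,
                                           timelines = timelines_path)))
}

.readTable <- function(path, required, mapping, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (length(mapping)) {
    idx <- match(names(mapping), names(df))
    names(df)[idx[!is.na(idx)]] <- unlist(mapping)[!is.na(idx)]
  }
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema error in ", what, " file: missing mandatory column(s) ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning("ignoring unknown column(s) in ", what, ": ",
            paste(extra, collapse = ", "))
    df <- df[required]
  }
  df
}

.firstReturnTimes <- function(feedings, timelines, forager_ids) {
  onsets <- vapply(forager_ids, function(id) {
    fe <- feedings[feedings$forager_id == id, , drop = FALSE]
    if (!nrow(fe)) return(NA_real_)
    first_end <- min(fe$t_end)
    tl <- timelines[timelines$ant_id == id & timelines$t >= first_end &
                      timelines$in_nest, , drop = FALSE]
    if (nrow(tl)) min(tl$t) else first_end
  }, numeric(1))
  names(onsets) <- forager_ids
  onsets[order(onsets)]
}

#' Write a colony experiment back to the canonical CSV files
#'
#' Inverse of [readColonyExperiment()]; `read(write(x))` reproduces the event
#' tables field for field.
#'
#' @param x a [ColonyExperiment-class]
#' @param dir output directory (created if absent)
#' @return invisibly, the three file paths written
#' @export
writeColonyExperiment <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("interactions.csv", "feedings.csv",
                            "timelines.csv"))
  utils::write.csv(interactions(x), paths[1], row.names = FALSE)
  utils::write.csv(feedings(x), paths[2], row.names = FALSE)
  utils::write.csv(timelines(x), paths[3], row.names = FALSE)
  invisible(paths)
}

#' Classify foragers from the feeding log
#'
#' Ants that fed from the food source at least `min_cycles` times are
#' consistent foragers; ants with at most `max_casual_visits` visits are
#' non-foragers. Counts strictly between the two thresholds are flagged for
#' manual review rather than silently assigned — the study colonies showed a
#' clean gap between casual visitors and consistent foragers.
#'
#' @param feedings feeding-event data.frame (`forager_id`, `t_start`,
#'   `t_end`, ...)
#' @param min_cycles minimum feeding count for a consistent forager
#' @param max_casual_visits maximum feeding count for a non-forager
#' @return list with character vectors `forager`, `non_forager`, `review`
#' @export
classifyForagers <- function(feedings, min_cycles = 8,
                             max_casual_visits = 4) {
  if (!nrow(feedings))
    return(list(forager = character(0), non_forager = character(0),
                review = character(0)))
  counts <- table(feedings$forager_id)
  ids <- names(counts)
  list(forager = ids[counts >= min_cycles],
       non_forager = ids[counts <= max_casual_visits],
       review = ids[counts > max_casual_visits & counts < min_cycles])
}

#' Normalize crop-load measurements
#'
#' Two normalizations are used by downstream stages. `between_experiments`
#' divides every crop and volume measurement of an experiment by the
#' experiment's 90th-percentile crop-load measurement (an order statistic: an
#' actually observed value, which therefore maps to exactly 1), making
#' absolute loads comparable across experiments — used by the interaction-
#' volume analyses. `per_forager` divides each forager's crop measurements by
#' her own maximum, expressing her relative satiety — used by the
#' exit-decision analyses; non-forager timelines are left untouched in this
#' mode.
#'
#' @param x a [ColonyExperiment-class]
#' @param mode `"between_experiments"` or `"per_forager"`
#' @return the experiment with rescaled timelines (and, in
#'   `between_experiments` mode, rescaled interaction volumes and crops and
#'   intake target); normalizers are recorded in `x@metadata$normalizers`.
#' @export
normalizeCrops <- function(x, mode = c("between_experiments", "per_forager")) {
  mode <- match.arg(mode)
  tl <- timelines(x)
  if (!nrow(tl)) stop("experiment has no timelines to normalize")
  if (mode == "between_experiments") {
    norms <- list()
    ia <- interactions(x)
    for (ex in unique(tl$experiment_id)) {
      sel <- tl$experiment_id == ex
      q90 <- .orderStatPercentile(tl$crop[sel], 0.9)
      if (q90 <= 0) stop("normalizer undefined: all crop measurements are ",
                         "zero in experiment '", ex, "'")
      tl$crop[sel] <- tl$crop[sel] / q90
      if (nrow(ia)) {
        isel <- ia$experiment_id == ex
        ia$volume[isel] <- ia$volume[isel] / q90
        ia$donor_crop[isel] <- ia$donor_crop[isel] / q90
        ia$recipient_crop[isel] <- ia$recipient_crop[isel] / q90
      }
      norms[[as.character(ex)]] <- q90
    }
    x@interactions <- ia
    if (!is.na(x@intakeTarget) && length(norms) == 1L)
      x@intakeTarget <- x@intakeTarget / norms[[1L]]
  } else {
    norms <- list()
    for (id in foragerIds(x)) {
      sel <- tl$ant_id == id
      mx <- max(tl$crop[sel])
      if (!is.finite(mx) || mx <= 0)
        stop("normalizer undefined: forager '", id,
             "' has no positive crop measurement")
      tl$crop[sel] <- tl$crop[sel] / mx
      norms[[id]] <- mx
    }
  }
  x@timelines <- tl
  x@metadata$normalizers <- c(x@metadata$normalizers,
                              stats::setNames(list(norms), mode))
  x
}

# order-statistic percentile: the smallest measurement with at least
# p of the sample at or below it (quantile type 1)
.orderStatPercentile <- function(x, p) {
  xs <- sort(x)
  xs[ceiling(p * length(xs))]
}
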