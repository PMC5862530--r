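# Shared simulated colonies, memoized for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# default study-condition colony
sim_default <- function() {
  .cached("sim_default", simulateColony(simulationConfig(seed = 101)))
}

series_default <- function() {
  .cached("series_default", computeColonyState(sim_default()))
}

# two further study-condition colonies; pooled with the default one for
# the separation-of-variables analysis, as the study pools its three
# observation colonies
sims_all <- function() {
  .cached("sims_all", c(list(sim_default()),
                        lapply(c(102, 103), function(s)
                          simulateColony(simulationConfig(seed = s)))))
}

series_all <- function() {
  .cached("series_all", lapply(sims_all(), computeColonyState))
}

pooled_separation <- function() {
  .cached("pooled_separation",
          separationOfVariablesTest(lapply(sims_all(), normalizeCrops,
                                           "per_forager"),
                                    series_all()))
}

# perturbation run: hungry ants introduced after the first plateau
sim_perturbed <- function() {
  .cached("sim_perturbed", simulateColony(simulationConfig(
    seed = 7, duration = 16000, n_foragers = 5,
    perturbation = list(time = 9000, n_added_hungry = 30))))
}

# negative control for the separation-of-variables test: the exit rule
# itself depends on the colony state
sim_colony_rule <- function() {
  .cached("sim_colony_rule", simulateColony(simulationConfig(
    seed = 3, duration = 12000, exit_colony_coef = -3,
    exit_intercept = 1.5)))
}

# micro->macro composition config: a negligible outdoor phase keeps the
# forager duty cycle at ~1 so the flow constant composes analytically as
# m = r / (lambda0 * n_nonforagers); constant targets keep C0 exact
composition_config <- function(seed) {
  simulationConfig(seed = seed, duration = 14400, n_ants = 40,
                   n_foragers = 3, outdoor_duration = 2,
                   crop_target_sd = 0, forager_onsets = c(2, 400, 1200))
}

composition_m <- function(cfg) {
  cfg$rate_intercept / (cfg$lambda0 * (cfg$n_ants - cfg$n_foragers))
}

# hand-built single-forager experiment on a 2 s grid: one feeding cycle
# with known indoor/outdoor split and a linear unloading ramp
hand_experiment <- function(dt = 2, crop_from = 0.95, crop_to = 0.60) {
  t_grid <- seq(0, 600, by = dt)
  n <- length(t_grid)
  # feeding (outdoor) during [0, 200); in nest [200, 600); second feeding
  # starts at 600
  in_nest <- t_grid >= 200 & t_grid < 600
  crop <- numeric(n)
  crop[!in_nest] <- 1
  ramp <- seq(crop_from, crop_to, length.out = sum(in_nest))
  crop[in_nest] <- ramp
  # at the exit instant (t = 600) the crop has not refilled yet
  crop[t_grid == 600] <- crop_to
  tl_f <- data.frame(ant_id = "F01", t = t_grid, crop = crop,
                     in_trophallaxis = FALSE, at_food = !in_nest,
                     in_nest = in_nest, experiment_id = "toy")
  tl_a <- data.frame(ant_id = "A001", t = t_grid, crop = 0,
                     in_trophallaxis = FALSE, at_food = FALSE,
                     in_nest = TRUE, experiment_id = "toy")
  # after the cycle the forager feeds again at t = 600
  fe <- data.frame(forager_id = "F01", t_start = c(0, 600),
                   t_end = c(200, 620), experiment_id = "toy")
  ia <- data.frame(t_start = c(300, 400), t_end = c(302, 402),
                   donor_id = "F01", recipient_id = "A001",
                   volume = c(0.2, 0.15), donor_crop = c(0.9, 0.7),
                   recipient_crop = c(0, 0.2), forager_is_donor = TRUE,
                   experiment_id = "toy")
  methods::new("ColonyExperiment",
               ants = data.frame(ant_id = c("F01", "A001"),
                                 role = c("forager", "non-forager")),
               interactions = ia, feedings = fe,
               timelines = rbind(tl_f, tl_a),
               intakeTarget = 1, onsetTimes = c(F01 = 200),
               metadata = list())
}

# minimal experiment wrapping a given interaction table on a uniform grid
mini_experiment <- function(interactions, t_max = 100, dt = 2,
                            intake_target = NA_real_) {
  t_grid <- seq(0, t_max, by = dt)
  ids <- unique(c("F01", interactions$donor_id, interactions$recipient_id))
  tl <- do.call(rbind, lapply(ids, function(id)
    data.frame(ant_id = id, t = t_grid, crop = 0, in_trophallaxis = FALSE,
               at_food = FALSE, in_nest = TRUE, experiment_id = "mini")))
  methods::new("ColonyExperiment",
               ants = data.frame(ant_id = ids,
                                 role = c("forager",
                                          rep("non-forager",
                                              length(ids) - 1))),
               interactions = interactions,
               feedings = data.frame(forager_id = character(0),
                                     t_start = numeric(0),
                                     t_end = numeric(0),
                                     experiment_id = character(0)),
               timelines = tl, intakeTarget = intake_target,
               onsetTimes = c(F01 = 0), metadata = list())
}

interaction_row <- function(t_start, volume, donor = "F01",
                            recipient = "A001", donor_crop = 1,
                            recipient_crop = 0) {
  data.frame(t_start = t_start, t_end = t_start + 2, donor_id = donor,
             recipient_id = recipient, volume = volume,
             donor_crop = donor_crop, recipient_crop = recipient_crop,
             forager_is_donor = volume >= 0, experiment_id = "mini")
}
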