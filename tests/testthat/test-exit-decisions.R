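test_that("decision points follow the hand-traced schedules", {
  # crop enters at 0.95 and ramps down to 0.60: with delta_crop = 0.10
  # there are floor(0.35 / 0.10) = 3 unloading-rate decision points
  x <- hand_experiment(crop_from = 0.95, crop_to = 0.60)
  ser <- computeColonyState(x)
  dpu <- extractDecisionPoints(x, "unloading_rate", ser, delta_crop = 0.10)
  expect_equal(nrow(dpu$points), 3)
  # the visit ends at the next feeding, so the final point is the exit
  expect_equal(dpu$points$exit, c(FALSE, FALSE, TRUE))
  # crops at the crossings are just past 0.85, 0.75, 0.65
  expect_true(all(abs(dpu$points$crop - c(0.85, 0.75, 0.65)) < 0.01))

  # constant model: one point per 2-s in-nest sample outside trophallaxis,
  # only the last labelled exit
  dpc <- extractDecisionPoints(x, "constant", ser)
  tl <- timelines(x)
  expect_equal(nrow(dpc$points),
               sum(tl$in_nest[tl$ant_id == "F01"]))
  expect_equal(sum(dpc$points$exit), 1)
  expect_true(dpc$points$exit[nrow(dpc$points)])

  # interaction-rate model: one point per interaction end
  dpi <- extractDecisionPoints(x, "interaction_rate", ser)
  expect_equal(nrow(dpi$points), 2)
  expect_equal(sum(dpi$points$exit), 1)

  expect_error(extractDecisionPoints(x, "hourly", ser), "arg")
})

test_that("unloading decisions count the unloaded increments", {
  # noiseless trace: points per visit = floor(total unloaded / delta) +- 1
  for (drop_to in c(0.15, 0.42, 0.73)) {
    x <- hand_experiment(crop_from = 1.0, crop_to = drop_to)
    dp <- extractDecisionPoints(x, "unloading_rate",
                                computeColonyState(x), 0.10)
    expect_lte(abs(nrow(dp$points) - floor((1.0 - drop_to) / 0.10)), 1)
  }
})

test_that("kNN surfaces estimate local exit fractions", {
  # all exits: the surface is identically one
  pts <- data.frame(crop = runif(50), colony = runif(50), exit = TRUE)
  s <- knnExitSurface(pts, n_neighbors = 10, grid_n = 5)
  expect_true(all(s$probability == 1))
  # two tight clusters, one all-exit and one all-stay, n = 2
  pts2 <- data.frame(crop = c(0.1, 0.11, 0.9, 0.91),
                     colony = c(0.1, 0.11, 0.9, 0.91),
                     exit = c(TRUE, TRUE, FALSE, FALSE))
  s2 <- knnExitSurface(pts2, n_neighbors = 2, grid_n = 4)
  expect_setequal(round(unique(s2$probability), 6), c(0, 1))
  expect_true(all(s2$crop %in% c(mean(c(0.1, 0.11)), mean(c(0.9, 0.91)))))
  expect_error(knnExitSurface(pts2, n_neighbors = 10), "exceeds")
  # probabilities bounded, and smoothing never increases roughness
  set.seed(6)
  pts3 <- data.frame(crop = runif(400), colony = runif(400),
                     exit = runif(400) < 0.3)
  tv <- sapply(c(10, 50, 150), function(k) {
    s3 <- knnExitSurface(pts3, k, grid_n = 15)
    expect_true(all(s3$probability >= 0 & s3$probability <= 1))
    sum(abs(diff(s3$probability)))
  })
  expect_true(all(diff(tv) <= 0))
})

test_that("logistic exit fits recover a known decision rule", {
  set.seed(15)
  n <- 5000
  crop <- runif(n); colony <- runif(n)
  p <- plogis(0.4 - 2.1 * crop - 0.8 * colony)
  pts <- data.frame(crop = crop, colony = colony, exit = runif(n) < p)
  f <- fitExitLogistic(pts)
  expect_true(f$ci["crop", "lower"] <= -2.1 &&
                -2.1 <= f$ci["crop", "upper"])
  expect_true(f$ci["colony", "lower"] <= -0.8 &&
                -0.8 <= f$ci["colony", "upper"])
  # null: labels independent of both covariates
  set.seed(16)
  pts0 <- data.frame(crop = runif(n), colony = runif(n),
                     exit = runif(n) < 0.25)
  f0 <- fitExitLogistic(pts0)
  expect_true(f0$ci["crop", "lower"] <= 0 && 0 <= f0$ci["crop", "upper"])
  expect_true(f0$ci["colony", "lower"] <= 0 &&
                0 <= f0$ci["colony", "upper"])
  expect_error(fitExitLogistic(pts0[pts0$exit, ]), "both exit and stay")
})

test_that("the crop-only projection excludes the forced lowest interval", {
  pts <- do.call(rbind, lapply(seq_along(sims_all()), function(i)
    extractDecisionPoints(normalizeCrops(sims_all()[[i]], "per_forager"),
                          "unloading_rate",
                          series_all()[[i]])$points))
  f <- fitExitLogistic(pts, covariates = "crop")
  cutoff <- min(pts$crop) + diff(range(pts$crop)) / 7
  expect_equal(f$n, sum(pts$crop > cutoff))
  # the generator's crop slope lies inside the 95% CI
  truth <- groundTruth(sim_default())$config$exit_crop_coef
  expect_true(f$ci["crop", "lower"] <= truth &&
                truth <= f$ci["crop", "upper"])
})

test_that("a crop-only exit rule separates the variables", {
  # pooled over the three simulated observation colonies
  st <- pooled_separation()
  tab <- st$table
  # the apparent colony effect, relative to the crop effect, shrinks
  # monotonically from the constant to the unloading-rate schedule
  expect_true(st$relative_colony_effect_shrinks)
  # the absolute colony coefficient is smallest under unloading
  expect_lt(abs(tab$colony[tab$model == "unloading_rate"]),
            abs(tab$colony[tab$model == "constant"]))
  expect_lt(abs(tab$colony[tab$model == "unloading_rate"]),
            abs(tab$colony[tab$model == "interaction_rate"]))
  # and it is weak compared to the crop effect
  expect_lt(tab$colony_vs_crop[tab$model == "unloading_rate"], 0.5)
})

test_that("a colony-dependent exit rule fails to separate", {
  sim <- sim_colony_rule()
  st <- separationOfVariablesTest(normalizeCrops(sim, "per_forager"),
                                  computeColonyState(sim))
  tab <- st$table
  # the colony effect survives the unloading-rate schedule: its CI stays
  # clear of zero, it remains comparable to the crop effect, and it does
  # not shrink relative to the constant-rate schedule
  expect_false(st$colony_ci_covers_zero)
  expect_gt(tab$colony_vs_crop[tab$model == "unloading_rate"], 0.5)
  expect_gte(abs(tab$colony[tab$model == "unloading_rate"]),
             abs(tab$colony[tab$model == "constant"]))
})

test_that("fitted exit coefficients are calibrated across replicates", {
  # for data generated from the factorized exit rule, the crop slope lies
  # inside its 95% CI at the nominal rate
  hits <- sapply(1:20, function(s) {
    set.seed(s)
    crop <- runif(2000)
    pts <- data.frame(crop = crop,
                      exit = runif(2000) < plogis(-0.13 - 1.93 * crop))
    f <- fitExitLogistic(pts, "crop", exclude_lowest_crop = -Inf)
    f$ci["crop", "lower"] <= -1.93 && -1.93 <= f$ci["crop", "upper"]
  })
  expect_gte(mean(hits), 0.85)
})
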