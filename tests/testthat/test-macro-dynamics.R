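test_that("colony state accumulates signed volumes against the intake target", {
  # hand summation: volumes +3, -1, +2 against a target of 4
  ia <- rbind(interaction_row(10, 3, donor_crop = 3),
              interaction_row(40, -1, donor_crop = 0),
              interaction_row(70, 2, donor_crop = 2))
  ia$forager_is_donor <- c(TRUE, FALSE, TRUE)
  x <- mini_experiment(ia, intake_target = 4)
  ser <- computeColonyState(x)
  expect_equal(tail(colonyState(ser), 1), 1.0)
  # a single interaction equal to the target steps F from 0 to 1
  y <- mini_experiment(interaction_row(10, 4), intake_target = 4)
  sy <- computeColonyState(y)
  expect_equal(colonyState(sy)[stateTimes(sy) < 10], rep(0, 5))
  expect_equal(unique(colonyState(sy)[stateTimes(sy) >= 12]), 1)
  # no interactions at all: identically zero, with a warning
  z <- mini_experiment(interaction_row(1, 1)[0, ], intake_target = 1)
  expect_warning(sz <- computeColonyState(z), "no forager interactions")
  expect_true(all(colonyState(sz) == 0))
})

test_that("the state decomposes exactly into forager contributions", {
  ser <- series_default()
  expect_lt(max(abs(rowSums(foragerContributions(ser)) -
                      colonyState(ser))), 1e-12)
})

test_that("smoothing and differentiation are mutually consistent", {
  dt <- 2
  t <- seq(0, 4000, by = dt)
  # linear ramp: the flow is the slope everywhere away from the edges
  a <- 3.7e-4
  sd_ <- smoothAndDifferentiate(a * t, dt, smooth_window = 500,
                                diff_window = 200)
  interior <- seq(300, length(t) - 300)
  expect_lt(max(abs(sd_$flow[interior] - a)), 1e-12)
  # step: the flow is a pulse whose integral recovers the step height
  step <- ifelse(t > 2000, 1, 0)
  sd2 <- smoothAndDifferentiate(step, dt, 500, 200)
  expect_lt(abs(sum(sd2$flow) * dt - 1), 0.01)
  expect_error(smoothAndDifferentiate(step, dt, smooth_window = 1e6),
               "longer than the series")
})

test_that("per-forager flow fits recover an exact proportionality", {
  dt <- 2
  t <- seq(0, 14400, by = dt)
  k <- 3e-4
  F <- 1 - exp(-k * t)          # then dF/dt = k (1 - F) exactly
  ser <- methods::new("ColonyStateSeries", tGrid = t, F = F,
                      fi = matrix(F, ncol = 1,
                                  dimnames = list(NULL, "F01")),
                      intakeTarget = 1)
  # short windows: the series is analytic, no event noise to smooth away
  fit <- fitIndividualFlow(ser, smooth_window = 200, diff_window = 100)
  expect_lt(abs(fit$m_i[["F01"]] / k - 1), 0.01)
  expect_gt(fit$r_squared[["F01"]], 0.998)
  # degenerate: (1 - F) has no variance
  serc <- methods::new("ColonyStateSeries", tGrid = t,
                       F = rep(0.5, length(t)),
                       fi = matrix(0.5, length(t), 1,
                                   dimnames = list(NULL, "F01")),
                       intakeTarget = 1)
  expect_error(fitIndividualFlow(serc), "degenerate")
})

test_that("trajectory prediction matches the closed form", {
  t <- seq(0, 10000, by = 10)
  m <- 2e-4
  # no active foragers: the state stays put
  expect_equal(predictColonyTrajectory(m, numeric(0), t, F0 = 0.3),
               rep(0.3, length(t)))
  # one forager from time zero: F = 1 - exp(-m t)
  expect_lt(max(abs(predictColonyTrajectory(m, 0, t) - (1 - exp(-m * t)))),
            1e-6)
  # N simultaneous foragers: rate scales to N m
  expect_lt(max(abs(predictColonyTrajectory(m, rep(0, 4), t) -
                      (1 - exp(-4 * m * t)))), 1e-6)
  expect_error(predictColonyTrajectory(-1, 0, t), "non-negative")
})

test_that("flow fits are state-dependent, not onset-dependent", {
  # the same m_i must emerge for foragers that started foraging at very
  # different times; averaged over runs to suppress sampling noise
  seeds <- 11:16
  ratios <- sapply(seeds, function(s) {
    cfg <- composition_config(s)
    sim <- simulateColony(cfg)
    fit <- fitIndividualFlow(computeColonyState(sim),
                             onsets = onsetTimes(sim))
    fit$m_i / composition_m(cfg)
  })
  per_onset <- rowMeans(ratios)
  expect_lt(max(abs(per_onset / mean(per_onset) - 1)), 0.10)
  # and the pooled constant matches the analytic composition r/(lambda0 N)
  expect_lt(abs(mean(per_onset) - 1), 0.10)
})

test_that("foraging cycles split into indoor and outdoor phases", {
  x <- hand_experiment()
  cyc <- extractForagingCycles(x, computeColonyState(x))
  expect_equal(nrow(cyc), 1)
  expect_equal(cyc$cycle_interval, 600)
  expect_equal(cyc$indoor_duration, 400)
  expect_equal(cyc$outdoor_duration, 200)
  expect_equal(cyc$n_interactions_in_visit, 2)
  expect_equal(cyc$crop_at_exit, 0.60)
  # a forager with fewer than two feedings yields no cycles
  x1 <- hand_experiment()
  x1@feedings <- x1@feedings[1, ]
  expect_warning(cyc1 <- extractForagingCycles(x1, computeColonyState(x1)),
                 "fewer than 2")
  expect_equal(nrow(cyc1), 0)
})

test_that("foraging frequency declines linearly with colony vacancy", {
  # generator oracle: frequencies exactly linear in (1 - F) plus noise
  set.seed(21)
  Fv <- runif(400, 0, 0.95)
  b0 <- 0.8e-3; b1 <- 3.6e-3
  freq <- (b0 + b1 * (1 - Fv)) * exp(rnorm(400, 0, 0.05))
  cyc <- data.frame(cycle_interval = 1 / freq, colony_state_at_cycle = Fv,
                    indoor_duration = 0.8 / freq,
                    outdoor_duration = 0.2 / freq)
  fit <- fitFrequencyVsVacancy(cyc)
  expect_lt(abs(fit$slope / b1 - 1), 0.10)
  expect_gt(fit$r_squared, 0.9)
  # constant intervals: no trend
  cyc0 <- data.frame(cycle_interval = 300, colony_state_at_cycle = Fv,
                     indoor_duration = 200, outdoor_duration = 100)
  fit0 <- suppressWarnings(fitFrequencyVsVacancy(cyc0))
  expect_lt(abs(fit0$slope), 1e-10)
})

test_that("the frequency fit is robust to the bin count", {
  cyc <- extractForagingCycles(sim_default(), series_default())
  slopes <- sapply(4:6, function(nb)
    fitFrequencyVsVacancy(cyc, n_bins = nb)$slope)
  expect_lt(max(abs(slopes / slopes[2] - 1)), 0.20)
  # the indoor phase carries the trend on simulated colonies too
  fit <- fitFrequencyVsVacancy(cyc)
  expect_gt(fit$spearman_indoor["rho"], 0.3)
})

test_that("perturbation contrast requires data on both sides", {
  cyc <- data.frame(t_feed_start = seq(100, 900, by = 100),
                    indoor_duration = 100)
  expect_error(perturbationResponse(cyc, 2000), "post-perturbation")
  expect_error(perturbationResponse(cyc, 0), "pre-perturbation")
})
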