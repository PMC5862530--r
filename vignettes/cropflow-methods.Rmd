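---
title: "Crop loads and collective food intake: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crop loads and collective food intake: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system and the model

A starved ant colony presented with an unlimited food source refills
through a handful of foragers. Each forager loads her crop (the "social
stomach") at the source, returns to the nest, and unloads through
mouth-to-mouth trophallactic interactions with nestmates. The colony as a
whole accumulates food logistically: inflow is fast while the colony is
empty and slows as it approaches a well-defined intake target. `cropflow`
implements the chain of models that connects this colony-scale feedback to
the statistics of single interactions, together with an agent-based
simulator that generates event logs with exactly the statistical structure
the analysis assumes.

**Colony scale.** The colony state is
\(F(t) = \sum_i f_i(t)\), where \(f_i\) is forager *i*'s cumulative signed
delivery divided by the intake target (positive when food flows from the
forager). Each forager's flow obeys a state feedback
\(df_i/dt \approx m\,(1-F)\) with a common constant \(m\), so the global
inflow is \(dF/dt \approx n(t)\, m\,(1-F)\) with \(n(t)\) the number of
foragers active by time \(t\). With constant \(n=N\) this integrates to
\(F(t) = 1-(1-F_0)e^{-Nmt}\). `computeColonyState()`,
`fitIndividualFlow()` and `predictColonyTrajectory()` implement the three
pieces; that the *same* \(m_i\) fits foragers with different onset times
is what distinguishes state feedback from history dependence
(time-triggered slowdown), and is tested as such.

**Interaction scale.** A forager's flow factorizes into interaction rate
times mean interaction volume, \(df_i/dt \approx \langle r(F)\rangle
\langle v(F)\rangle\). The volume term carries the feedback: interaction
volumes conditioned on the recipient's crop load \(c\) are exponential,
\(p(v\mid c) = \lambda_c e^{-\lambda_c v}\) with
\(\lambda_c = \lambda_0/(C_0 - c)\), i.e. each interaction delivers a
random exponential fraction (mean \(1/\lambda_0\)) of the space left in
the recipient's crop, where \(C_0\) is the mean crop-load target.
Normalizing volumes by available space, \(\tilde v = v/(C_0-c)\),
collapses all conditional distributions onto one exponential. Because
forager partners are a representative sample of the colony, averaging the
conditional mean over recipients yields the parameter-free macro
prediction \(\langle v\rangle = (C_0/\lambda_0)(1-F)\) — the micro rule
composes to the colony-scale law. `fitLambdaVsCrop()`,
`collapseNormalizedVolumes()`, `meanVolumeVsState()` and
`recipientRepresentativeness()` implement this chain;
`unloadingRateDecomposition()` ranks rate-only, volume-only and combined
models of the per-visit unloading rate.

**Forager decisions.** Foraging frequency (inverse cycle time) is linear
in the vacancy \(1-F\), driven almost entirely by the indoor (unloading)
phase. The exit decision is modelled as a Markovian product
\(R(\mathrm{exit}\mid crop,colony) = R(\mathrm{decide}) \cdot
P(\mathrm{exit}\mid crop,colony)\). Since decision instants are
unobservable, three schedules are compared: every sample (constant rate),
after each interaction, and after each cumulative \(\Delta crop\) of
unloading. Under the third schedule the apparent colony dependence of
\(P\) collapses, leaving the separation of variables
\(R_{\mathrm{exit}} = U(colony)\,G(crop)\): the colony sets the *pace* of
decisions through the unloading rate, while each decision depends on the
forager's own crop alone. `extractDecisionPoints()`, `knnExitSurface()`,
`fitExitLogistic()` and `separationOfVariablesTest()` implement this
stage.

## The simulator and what it emulates

`simulateColony()` runs an agent-based colony on a 2-s grid (the 0.5 Hz
sampling rate of the imaging system the data model mirrors). Its defaults
are the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_ants`, `n_foragers` | 60, 4 | colony size and consistent foragers (observed colonies: 53–100 ants, 3–5 foragers) |
| `duration`, `dt` | 14 400 s, 2 s | ≥ 4 h of recording after food introduction |
| `lambda0` | 7.01 | rate scale of the exponential volume rule |
| `crop_target_mean` | 1.14 | mean recipient crop target \(C_0\), in between-experiment normalized units |
| `crop_target_sd` | 0.057 | per-ant target spread, Normal truncated at 0; the spread is not reported, so it is configurable and small by default |
| `rate_intercept`, `rate_slope` | 0.032 s⁻¹, 0 | in-nest interaction-attempt rate \(r(F)=r_0-r_1F\); the measured rate decline is second-order and off by default |
| `outdoor_duration` | 120 s | constant feeding-trip length; the outdoor phase is short and roughly state-independent, its exact value unreported |
| `delta_crop` | 0.10 | crop-unload increment triggering one exit decision |
| `exit_intercept`, `exit_crop_coef` | 0, −1.93 | crop-only exit logistic \(G(crop)\); the slope is the measured one-dimensional coefficient, the intercept is free and set so an empty-crop decision exits half the time |
| `forager_onsets` | staggered over first 10% | reproduces the initial inflow rise |

Foragers cycle between a constant outdoor phase (linear crop refill) and
in-nest unloading; partners are drawn uniformly among non-foragers, which
realizes representative recipient sampling with no extra mechanism.
Volumes come from `drawInteractionVolume()` — the exponential fraction
rule truncated at physical limits, with truncation recorded per
interaction so estimators can exclude censored draws (on real data
censoring is unobservable; this is an approximation noted below). After
each cumulative `delta_crop` unloaded, the forager makes one Bernoulli
exit decision with probability `G(crop)`. A forager whose crop falls
below `forced_exit_crop` (2% of capacity) leaves to reload: an emptied
crop can trigger no further unload increments, which also reproduces the
observed certainty of exits at the lowest crop levels. One tick elapses
between an exit decision and departure, so the post-decision crop is
observable at an in-nest grid point, as it is in real recordings where
disengaging and walking out takes finite time. Negative
(recipient-to-forager) volumes are not generated; importers accept them,
and the analysis reports the fraction of flow they carry before excluding
them from exponential fits (12% in the study data).

A mid-run perturbation (`perturbation = list(time=, n_added_hungry=)`)
adds empty-crop non-foragers and recomputes the colony-state normalizer,
dropping \(F\) discontinuously by the added vacancy fraction — the
simulated analogue of releasing hungry nestmates from a blocked chamber.

**What passing tests do and do not show.** The simulator emulates the
statistical structure the analysis assumes: exponential volume fractions,
uniform partner sampling, Poisson-like interaction attempts, a crop-only
exit rule paced by unloading. Parameter recovery on its output therefore
validates the estimators, not the biology. Real data additionally contain
measurement noise in fluorescence-based crop estimates, posture-dependent
intensity fluctuations, non-forager-to-non-forager secondary sharing,
interaction durations of minutes rather than one tick, and negative
interactions — none of which are generated. Recovering \(\lambda_0\) from
a simulated colony is consequently cleaner than from an imaging
experiment.

## Numerical choices

- **Exponential histogram fits.** Rates are fit by least squares to
  histogram densities over a sweep of 17 binwidths on [0.01, 0.09]
  (reported as mean ± SD across binwidths, with the MLE \(1/\bar v\) as a
  cross-check). The model density is evaluated as the exact bin average
  (integral over the bin divided by its width): evaluating
  \(\lambda e^{-\lambda v}\) at the bin *centre* is biased upward
  wherever the density decays within a few bins, which matters in
  near-target crop bins where volumes are small. The least-squares
  objective is multimodal in \(\lambda\) (it plateaus once the model
  density vanishes), so the minimum is bracketed on a log grid around the
  MLE before refinement. Density, not counts, is fitted; the MLE
  cross-check guards the choice.
- **Hyperbolic law.** \(\lambda_c = \lambda_0/(C_0-c)\) is fit by
  Levenberg–Marquardt with \(C_0\) bounded above the largest bin-mean
  crop; a fit converging below the largest *observed* crop is flagged
  non-physical. The bin abscissa is the mean conditioning crop in the
  bin. R² uses the \(1 - SS_{res}/SS_{tot}\) convention so that negative
  values are representable — the donor-conditioned null comparison
  requires them.
- **Interaction rate.** Within-visit intervals are binned by the colony
  state at the interval midpoint; the per-bin rate is the inverse of the
  mean interval (the Poisson-rate MLE). Averaging raw inverse intervals
  is a divergent estimator for exponential waiting times and fails its
  own constant-rate oracle, so it is not used despite being the more
  literal reading of "inverse of all intervals".
- **Smoothing and differentiation.** Accumulation series are smoothed
  with a centred 2000-s moving average (several trophallactic events
  wide) and differentiated with a centred difference over 200–500 s
  (default 300 s). Flow fits trim half a smoothing window from both ends
  of the active window, where the shrinking edge windows bias the
  derivative toward zero.
- **Intake target.** The plateau detector is the mean of the smoothed
  accumulation over the final tenth of the record, flagged if the final
  hour still rises by more than 2% — echoing the stability criterion used
  to time the perturbation.
- **Colony-state bins.** Equal-width, 5 by default (7 for crop bins);
  empty bins are collapsed with a warning. Binned-mean fits are
  unweighted by default, with an inverse-variance option.
- **Trajectory integration.** `deSolve::lsoda` segment-by-segment between
  onset discontinuities at rtol 1e-10; agreement with the constant-\(n\)
  closed form to 1e-6 is a test invariant.
- **Exit fits.** Binary-outcome maximum likelihood (`stats::glm`,
  binomial) with Wald 95% CIs; fitting to the kNN surface instead is
  available through the surface estimator but the binary MLE is the
  default. R² for a logistic fit is not uniquely defined, so two
  diagnostics are reported: squared Pearson correlation between fitted
  probabilities and a kNN estimate at the observation points, and
  McFadden's pseudo-R². The one-dimensional \(G(crop)\) fit excludes the
  lowest crop interval, whose exit probability is 1 by construction.
  Within-visit crop increases reset the \(\Delta crop\) accumulator.
- **kNN surfaces.** For each point of a grid on the (crop, colony) unit
  square, the `n` nearest observations give probability = exit fraction
  and location = their mean position (n = 300 for the dense constant-rate
  point set, 30 otherwise).

## Design decisions that were genuinely open

- **Coefficient naming.** The two-dimensional exit fit reports
  coefficients by covariate name (`crop`, `colony`), never by Greek
  letter: published tables attach the symbols inconsistently, and the
  covariates live on the same [0, 1] scale, so named coefficients are
  directly comparable.
- **Separation-of-variables verdict.** The absolute colony coefficient is
  not monotone across decision schedules even in the published fits; the
  robust orderings are (i) the colony effect *relative to the crop
  effect* shrinks monotonically from constant to unloading schedule, and
  (ii) the absolute colony effect is smallest — and weak versus crop —
  under the unloading schedule. `separationOfVariablesTest()` reports
  both, accepts a list of colonies and pools their decision points, as
  the study pools its three observation colonies. The negative control
  (a generator whose exit rule *does* use the colony state) keeps a
  colony effect comparable to the crop effect under all schedules.
- **Forager classification.** Ants with ≥ 8 feedings are consistent
  foragers and ants with ≤ 4 are not; counts of 5–7 are flagged for
  review rather than assigned, because the observed colonies had a clean
  gap and inventing a cutoff inside it would be arbitrary.
- **Ambiguous cycle counting.** The reported mean of 15.67 cycles per
  forager is inconsistent with 139 feedings by 12 foragers; the importer
  counts feeding events and leaves the discrepancy as a data note.
- **Combined unloading model.** The published combined-model rate term
  differs between two figure panels (0.017 vs 0.071); the package uses
  the rate fit it computes itself and asserts only the R² ordering
  (volume ≥ rate, combined ≥ volume), which is what the comparison
  establishes.
- **Event timing.** Interaction volumes are credited at the interaction
  end time; the analysis window of each forager starts at her first
  return to the nest.

## Problem sizes

Default test and validation runs use colonies of 60 ants (4 foragers) for
4 simulated hours at 0.5 Hz — roughly 1 300 interactions and 200–250
exit-decision points per colony, matching the scale of one observation
experiment; pooled analyses use three such colonies. Parameter-recovery
experiments use 10⁴ direct draws for the volume law and 5×10³ decision
points for the exit rule, sizes at which the estimators' sampling error
sits comfortably inside a 10% band.

## Known limitations

- Censoring of volumes at physical limits is excluded exactly on
  simulated data (the generator records it) but is unobservable in real
  event logs, where the fits carry a small truncation bias.
- The per-sample discreteness of the grid collapses multiple generator
  decisions that fall between consecutive observable crop crossings; the
  extracted unloading-schedule points therefore retain a small residual
  colony dependence even under a strictly crop-only rule, mirroring the
  small nonzero colony coefficient in the published unloading-rate fit.
- Queens, brood, secondary non-forager sharing, spatial structure and
  recruitment signalling are out of scope; forager onsets are inputs,
  not a recruitment model.
- The between-experiment crop normalizer (90th-percentile order
  statistic) makes crop units comparable across experiments but inherits
  that statistic's sampling noise for small colonies.
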