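# cropflow

Multi-scale analysis of collective food intake in ant colonies.

When a starved colony meets an unlimited food source, a few foragers
shuttle between the source and the nest and unload through trophallaxis
(mouth-to-mouth food transfer). The colony's total stored food — the
colony state *F(t)*, normalized by its post-hoc intake target — rises
logistically: inflow is proportional to the remaining vacancy, `dF/dt ≈
n(t)·m·(1 − F)`, where `n(t)` counts active foragers. `cropflow` links
that colony-scale feedback to the statistics of single interactions and
single forager decisions:

- **Volume law.** Interaction volumes conditioned on the recipient's crop
  load `c` are exponential, `p(v|c) = λ_c e^{−λ_c v}` with
  `λ_c = λ0 / (C0 − c)`: each interaction delivers a random exponential
  fraction (mean `1/λ0`) of the space left in the recipient's crop, `C0`
  being the mean crop-load target. Normalizing volumes by available
  space collapses all conditional distributions onto one exponential,
  and averaging over a representative sample of recipients gives the
  parameter-free macro prediction `⟨v⟩ = (C0/λ0)(1 − F)`.
- **Foraging cycles.** Foraging frequency is linear in the vacancy
  `1 − F`, driven by the indoor (unloading) phase; introducing hungry
  ants mid-run drops *F* discontinuously and shortens nest stays.
- **Exit decisions.** The forager exit rate factorizes as
  `R(exit|crop, colony) = U(colony)·G(crop)`: decisions are paced by the
  unloading rate (set by the colony), but each decision depends on the
  forager's own crop alone. Three candidate decision schedules
  (constant, per-interaction, per-Δcrop-unloaded) are compared through
  kNN exit-probability surfaces and logistic fits.

The package ships an agent-based colony simulator
(`simulateColony()`) that generates event logs and crop timelines with
exactly this statistical structure (plus the ground truth that produced
them), a canonical CSV event-log data model with importers/exporters,
and the full analysis pipeline (`runPipeline()`). It is aimed at
researchers in collective animal behaviour who want to re-run the
analysis chain on their own trophallaxis event logs or validate
estimators against a known generative model.

## Worked example

```r
library(cropflow)

colony <- simulateColony(simulationConfig(seed = 17))
colony
#> A SyntheticColonyExperiment with 60 ants ( 4 foragers )
#>   interactions: 1237  feedings: 128  timeline rows: 432060
#>   intake target: 64.27

series <- computeColonyState(colony)
fitIndividualFlow(series, onsets = onsetTimes(colony))
#> Per-forager flow fit dfi/dt = m_i (1 - F)
#>              m_i        R2
#> F01 4.453940e-05 0.7734085
#> F02 5.388031e-05 0.9218497
#> F03 4.566643e-05 0.7348643
#> F04 4.524193e-05 0.8244686
#> pooled m = 4.733e-05

pos <- positiveInteractions(colony)
fitLambdaVsCrop(pos, "recipient")
#> Volume law lambda_c = lambda0 / (C0 - c): lambda0 = 7.185  C0 = 1.14  R2 = 1

fitFrequencyVsVacancy(extractForagingCycles(colony, series))
#> Foraging frequency vs vacancy: freq = 0.00168 + 0.00396 * (1 - F), R2 = 0.967
#> Spearman vs F  indoor rho = 0.56  outdoor rho = NA

separationOfVariablesTest(normalizeCrops(colony, "per_forager"), series)
#> Separation-of-variables test (colony coefficient by decision model):
#>             model       crop    colony colony_lo colony_hi colony_vs_crop
#>          constant  0.5324303 -2.012405 -2.596810 -1.428000      3.7796593
#>  interaction_rate -1.9023227 -3.375993 -4.088754 -2.663233      1.7746690
#>    unloading_rate -2.1977652 -1.485983 -2.452092 -0.519874      0.6761337
#> colony effect relative to crop effect shrinks monotonically toward the unloading-rate model
#> unloading-rate model colony CI does not cover zero
```

Reading the output: each forager's delivery rate is the same multiple
`m` of the colony's remaining vacancy regardless of when she started
(state feedback, not history); the volume-law fit recovers the
generating constants `λ0 = 7.01`, `C0 = 1.14` from the simulated event
log (here 7.185 and 1.140); foraging frequency rises with vacancy with a
slope near the study's `3.6×10⁻³`; and the apparent influence of the
colony state on exit decisions shrinks, relative to the crop's, as the
assumed decision schedule moves from constant to unloading-paced —
the signature of a crop-only decision rule whose *pace* is set by the
colony. (`outdoor rho` is `NA` here because the simulated outdoor phase
is exactly constant.) Pooling several colonies, as the study pools its
three observation experiments, sharpens the verdict:
`separationOfVariablesTest()` accepts a list of experiments.

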