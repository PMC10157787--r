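# thermalscope

Thermal performance and aerobic scope from intermittent-flow respirometry.

`thermalscope` implements the full analysis chain by which raw
dissolved-oxygen traces from intermittent-flow respirometry, cohort survival
records and morphometrics become population-level thermal-performance
conclusions for fish. It was built for acute warming challenges on large
salmonids (two populations acclimated to 12 °C and tested at 12, 18, 21 and
24 °C), but every stage is a plain, configurable function.

## What it computes

Oxygen uptake is estimated from the O2 decline while the chamber is sealed:

    MO2 = |dO2/dt| * (v_R - v_F) / m        [mg O2 kg^-1 min^-1]

where `v_R` is respirometer volume (L), `v_F` fish volume (L, 1 kg = 1 L) and
`m` fish mass (kg). On top of that:

- **RMR** — the 0.10 quantile of all validated overnight MO2 measurements
  (r² ≥ 0.85, at least 60 values).
- **MMR** — steepest ≥ 90 s sliding-window slope with r² > 0.9 inside the
  first post-chase measurement cycle (`MMR_1h`, `MMR_18h`), and
  `MMR_OVERALL`, the maximum over the chases and all validated overnight
  values (more than 60 required).
- **Aerobic scope** — `AAS = MMR_OVERALL − RMR`, `FAS = MMR_OVERALL / RMR`,
  with mortalities scored as zero scope.
- **Recovery** — %AAS and %MMR in 10-min blocks over the first 50 min, time
  to 50 % of chase MMR (first measurement inside the 48–52 % band), and EPOC
  by cubic-smoothing-spline integration of MO2 above RMR, cumulative and in
  hourly blocks.
- **Thermal performance** — quadratic AAS(T) over all fish (mortalities as
  zeros), with closed-form `Topt`, maximum scope, and the upper pejus
  temperature where scope falls to 80 % of maximum; functional warming
  tolerance = max environmental temperature − upper T_pejus.
- **Survival** — two-parameter binomial log-logistic
  `P(survive|T) = 1 / (1 + exp(b (ln T − ln M50)))`, profile-likelihood CI
  for M50, and a likelihood-ratio test for a population effect.
- **Supporting pieces** — Q10 temperature coefficients, allometric
  mass adjustment (exponents 0.67 RMR / 0.58 MMR, 3.5 kg reference), organ
  indices (GSI, RVM, SSI, HSI) with the hematocrit < 20 % exclusion, and
  Beer–Lambert enzyme-activity conversion.

A seeded synthetic-data generator (`simulate_cohort()`) emulates the raw
inputs — flush/measure cycles, mono-exponential post-chase recovery with a
Q10-scaled resting rate, spontaneous overnight bursts, probe noise, and
log-logistic mortality — together with a ground-truth ledger, so the whole
pipeline is testable without any external data.

## Worked example

```r
library(thermalscope)

cfg <- run_config(seed = 42, min_measurements = 12,
                  simulate = list(temperatures = c(12, 18, 21, 24),
                                  n_per_temperature = 4, cycle_count = 20,
                                  populations = list(
                                    coastal  = list(m50 = 21,   slope = 25),
                                    interior = list(m50 = 23.6, slope = 25))),
                  log_level = "quiet")
res <- run_pipeline(cfg)

head(res$summaries[, c("fish_id", "test_temperature", "rmr", "mmr_overall",
                       "aas", "fas", "survived")], 5)
#>          fish_id test_temperature  rmr mmr_overall   aas  fas survived
#> 1 coastal_12_001               12 2.41        11.1  8.73 4.62     TRUE
#> 2 coastal_12_002               12 2.01        10.6  8.58 5.27     TRUE
#> 3 coastal_12_003               12 2.51        10.5  7.95 4.17     TRUE
#> 4 coastal_12_004               12 2.65        13.3 10.61 5.00     TRUE
#> 5 coastal_18_005               18 4.11        10.8  6.68 2.63     TRUE

res$survival$coastal
#> Two-parameter log-logistic survival fit
#>   M50 = 21.00 C (95% CI 19.41-22.52), slope b = 207.49, logLik = -2.773

res$tpc$coastal
#> Quadratic thermal performance curve
#>   AAS(T) = 0.4985 + 1.508 T + -0.06354 T^2
#>   Topt = 11.87 C, AAS_max = 9.451, upper T_pejus(80%) = 17.32 C
```

The per-fish table gives resting and maximum rates in mg O2 kg⁻¹ min⁻¹ and
the derived scopes; RMR roughly doubles from 12 to 18 °C (a Q10 near 2)
while MMR barely moves, which is what compresses scope at warm temperatures.
The survival fit recovers the generative M50 of 21 °C from only 16 fish per
population, and the thermal performance curve places the 80 % pejus limit
several degrees above the fitted optimum. All exclusions are accounted for
in `res$exclusions` (here one fish dropped for hematocrit < 20 %).

A thin command-line wrapper is installed at
`inst/scripts/run-pipeline.R`:

```sh
Rscript inst/scripts/run-pipeline.R --config my-run.yaml --seed 7 --out runs/run1
```

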