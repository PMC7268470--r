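# coldRR

Estimating the effect of a variable that was never measured: **coldRR**
augments a cancer-registry-style cohort with binary health behaviours
(smoking, drinking, exercise, obesity, ...) imputed from an *unrelated*
population survey, quantifies how much information the imputation carried,
and corrects the resulting relative risk of one-year mortality for the
misclassification the imputation introduces. It is aimed at
epidemiologists who want at least preliminary behaviour–survival estimates
from registry data when record linkage is impossible — no cases in common,
too few matching variables, or confidentiality constraints.

## The method in brief

1. **Random cold-deck imputation.** Registry cases (recipients) and survey
   respondents (donors) are stratified on six shared auxiliary variables
   (5-year age group, gender, marital status, race, state, calendar year).
   The donor pool for a case diagnosed in year *y*, age group *a* is the
   survey stratum from year *y − 5*, age group *a − 1* (behaviour five
   years pre-diagnosis). Two distinct donors are drawn without replacement
   per case; cases whose stratum runs out of donors are omitted and
   counted.

2. **Calibration.** With prevalence *p* and within-pair correlation *ρ*,
   the two imputed values agree "behaviour present" with probability
   *p² + p(1−p)ρ*: matches in excess of chance measure the information
   conveyed. *p̂* pools both imputed vectors; *ρ̂* is the phi coefficient
   between them; the excess-match count is *np̂(1−p̂)ρ̂*.

3. **Correction.** Non-differential misclassification attenuates the
   imputed-exposure relative risk *RRᵢ* toward 1. The true relative risk
   is estimated by

   *RR_T = 1 − (RRᵢ − 1) / [ (RRᵢ − 1) p̂ (1 − ρ̂) − ρ̂ ]*,

   applied to both the crude and the Cochran–Mantel–Haenszel age-adjusted
   *RRᵢ*. A negative *RR_T* is an impossible value; when more than 5% of
   repetitions are impossible the behaviour's imputation is labelled
   **failed**.

4. **Repetition.** The whole pipeline is repeated 100 times (derived
   per-repetition seeds, bit-reproducible); results are medians with
   empirical 2.5/97.5-percentile intervals.

A survival simulator (`simulate_survival()`) validates the estimator:
designate the first imputed value as truth, simulate death at a known
target RR while preserving the overall death rate, re-estimate from the
second imputed value, and check that the corrected RR recovers the target.

## Worked example

Validate the correction at the current-smoking calibration (27,835
recipients, prevalence 0.159, phi 0.071) for a null and a doubled risk,
with a one-year death rate of 0.54:

```r
library(coldRR)
res <- run_pair_validation(27835, p = 0.159, rho = 0.071, label = "smoking",
                           targets = c(1, 2), death_rate = 0.54,
                           repetitions = 100, seed = 1)
subset(res$summaries, estimand %in% c("simulated_rr", "rr_i", "rr_t"))
#>   target_rr     estimand median  lower upper impossible_count failed
#> 1         1         rr_i 0.9992 0.9652 1.031                0  FALSE
#> 2         2         rr_i 1.0599 1.0375 1.092                0  FALSE
#> 3         1         rr_t 0.9897 0.5462 1.459                0  FALSE
#> 4         2         rr_t 1.9716 1.6182 2.583                0  FALSE
#> 5         1 simulated_rr 0.9969 0.9644 1.032                0  FALSE
#> 6         2 simulated_rr 1.9955 1.9656 2.029                0  FALSE
```

Read the `target_rr = 2` rows bottom-up: the simulator achieved a true RR
of 1.9955; estimated on the imputed exposure it collapsed to 1.0599 —
barely distinguishable from the null, which is exactly what weak but
informative imputation does — and the correction recovered 1.97 with an
empirical 95% interval of 1.62–2.58. The null target passes through
undistorted (corrected median 0.99). For an information-starved behaviour
(say `p = 0.048`, `rho = 0.011`) the same call instead reports dozens of
impossible draws and `failed = TRUE`: the method refuses rather than
fabricates.

The full pipeline on tables runs through `run_study()` (real outcomes) and
`run_simulation_study()` (simulated outcomes), or from a shell via
`exec/coldrr synth|estimate|validate`, each writing a results table, a
per-repetition draws sidecar, and a reproducibility manifest.

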