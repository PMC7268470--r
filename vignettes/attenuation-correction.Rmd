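---
title: "Cold-deck imputation, calibration, and misclassification-corrected relative risks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cold-deck imputation, calibration, and misclassification-corrected relative risks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldRR)
```

## The problem

Cancer registries record demographics and survival but not pre-diagnosis
health behaviour, and for rare cancers there is usually no dataset that
could be record-linked to supply it. coldRR implements an algorithm for
this situation: behaviour is *fully imputed* into the registry cohort from
an unrelated population survey using random cold-deck imputation on shared
demographic strata, the information content of that imputation is
*calibrated* by imputing every case twice, and the attenuated association
between imputed behaviour and one-year mortality is *corrected* back to an
estimate of the true relative risk.

The two input tables share six auxiliary variables: 5-year age group,
gender, marital status, race, region (state), and calendar year. Because
behaviour can change around diagnosis, the donor pool for a case diagnosed
in year $y$ and age group $a$ is the survey stratum observed in year
$y - 5$ and age group $a - 1$: behaviour five years before diagnosis, with
the age group shifted one 5-year band down so the donors were the age the
case was at that time. Both offsets are configuration parameters
(`lag_years`, default 5 years; `age_group_shift`, default 1 group).

## Double cold-deck imputation

Within each (lag-shifted) stratum, two distinct donors are drawn uniformly
at random **without replacement** for every recipient: a donor serves at
most one recipient per behaviour per repetition. Recipients in a stratum
are processed in random order, so when the stratum's donors are exhausted
the omitted recipients are an exchangeable random subset. A recipient is
excluded (and counted) either because its stratum ran out of donor pairs
(`exhausted`) or because no donor stratum matches at all (`no_stratum`,
which includes cases already in the youngest age group, where the
one-group-down shift is undefined). Each behaviour uses its own
complete-case donor dataset, so a donor missing one behaviour still serves
for the others and a missing value is never imputed into a missing value.

## Calibration: how much information did the imputation carry?

Let $p$ be the prevalence of the behaviour and $\rho$ the correlation
between the two imputed values of one case. If the imputation carried no
information the probability that both imputed values are "behaviour
present" is the chance level $p^2$; informative imputation produces excess
matches, modelled as

$$P_{11} = p^2 + p(1-p)\rho .$$

From the paired values we estimate $\hat p$ by pooling both imputed
vectors and $\hat\rho$ as the phi coefficient (the Pearson correlation of
two 0/1 vectors), giving the expected excess-match count
$n\hat p(1-\hat p)\hat\rho$. When a margin of the 2x2 agreement table is
degenerate (plausible for very rare behaviours) phi is undefined; the
repetition is recorded as invalid rather than patched.

## Correction of the attenuated relative risk

Imputation misclassifies individuals non-differentially with respect to
outcome, which attenuates the imputed-exposure relative risk $RR_i$
toward 1. Assuming the behaviour prevalence is the same for donors and
cases within each stratum, the true relative risk is recovered as

$$RR_T \;=\; 1 - \frac{RR_i - 1}{(RR_i - 1)\,\hat p\,(1-\hat\rho) - \hat\rho},$$

whose exact algebraic inverse (`forward_attenuation()`) is
$RR_i = 1 + (RR_T-1)\hat\rho \,/\, [\,1 + (RR_T-1)\hat p(1-\hat\rho)\,]$.
Because $\hat\rho$ is small for cold-deck imputation, $RR_i$ differs from 1
only in the second decimal place even when $RR_T = 2$ — the correction is a
large extrapolation, which is why its stability must be tracked. When
$\hat\rho$ is too small relative to $(RR_i-1)\hat p$ the formula returns a
negative value — impossible for a relative risk — and the draw is flagged
rather than thrown. The same correction is applied to the crude RR and to
the Cochran–Mantel–Haenszel age-adjusted RR, using the overall (not
age-specific) calibration, consistent with the equal-prevalence premise of
the derivation.

Age is the adjustment variable because both one-year survival and
behaviour prevalence decline with age; the CMH pooled risk ratio
$\sum_k a_k n_{0k}/N_k \,/\, \sum_k b_k n_{1k}/N_k$ is computed by hand
(no installed package exposes the MH *risk* ratio; base R's
`mantelhaen.test()` is odds-ratio-based) and collapses to the crude RR for
a single stratum.

## The repetition engine

Because donors are drawn at random, every statistic varies between runs.
The whole algorithm is repeated `repetitions = 100` times per behaviour
(and per subgroup, when a subgroup column such as histology is present);
each repetition draws from an independently derived substream of the
master seed (`derive_seed()`), so results are bit-reproducible and
independent of execution order. Summaries report the median and the
empirical 2.5/97.5 percentiles. Quantiles interpolate linearly between
order statistics (`stats::quantile` type 6, so the 2.5th percentile of 100
draws interpolates between the 2nd and 3rd order statistics); no source we
rely on prescribes a particular rule, and with 100 draws the difference
between conventions is well inside Monte-Carlo noise.

Three kinds of defective draws are tracked separately:

* **impossible** — corrected $RR_T < 0$ or non-finite (the failure mode of
  the correction itself);
* **invalid** — undefined phi or undefined RR (zero cells); and
* **not possible** — the survival simulator cannot reach the target RR.

Impossible and invalid draws are excluded from medians and percentiles;
only impossible draws feed the *failed* rule: an imputation is labelled
failed when strictly more than `failure_threshold = 0.05` of the
non-invalid repetitions are impossible. Failed corrected-RR cells are
written as the sentinel token `"failed"`.

## The simulation validation design

There is no gold-standard cohort with measured pre-diagnosis behaviour, so
the estimator is validated on simulated survival: the first imputed value
is designated the *true* behaviour, death is simulated at a known target
relative risk, and the estimate is recomputed from the *second* imputed
value, which relates to the first exactly as it would to the unobserved
truth. Given target $RR$ and overall death rate $d$, risks are

$$R_0 = \frac{d}{1 + \hat p\,(RR-1)}, \qquad R_1 = RR \cdot R_0,$$

with $\hat p$ the empirical prevalence of the truth vector, so the overall
death rate and the expected risk ratio are preserved exactly; deaths are
independent Bernoulli draws (a stochastic mechanism, adopted as the
simplest design consistent with the stated constraints). When $R_1 > 1$
the target is unachievable and reported as "not possible" — with
$d = 0.54$ this happens at $RR = 2$ for prevalences at or below about
0.048, which is exactly where the two rare-behaviour scenarios sit.

The default death rate $d = 0.54$ was fixed from that same feasibility
pattern (a one-year death rate a little above one half, plausible for
oesophageal cancer, makes $RR = 2$ infeasible at $p \le 0.048$ but
feasible at $p = 0.100$); the correction medians are insensitive to $d$
because the baseline risk cancels in the risk ratio, and $d$ remains a
config parameter.

`run_pair_validation()` runs this harness with pairs drawn directly from
the exchangeable-pair joint at a known $(p, \rho)$ — the route used to
validate the estimator at the six reference calibrations in
`validation_scenarios()` (cohorts of about 27,700–27,850 recipients,
prevalences 0.034–0.737, phi 0.011–0.071, 100 repetitions; about one to
two seconds per scenario-target). `run_simulation_study()` runs the same
design through the full cold-deck machinery on donor/recipient tables.

## What the synthetic generator does and does not emulate

`generate_donor_pool()` / `generate_recipient_cohort()` reproduce the
*structure* the algorithm needs — strata with configurable sizes,
behaviour prevalences and item non-response (missingness independent of
the value) — and `generate_correlated_pairs()` reproduces the calibration
model exactly. They do not emulate survey sampling weights or design
effects, real registry age/stage distributions, behaviour trends over
calendar time, or confounding between behaviour and other mortality
predictors (simulated survival depends on the behaviour alone). Passing
validation therefore shows the estimator inverts the attenuation its own
model describes; on real data the correction additionally inherits
whatever confounding and differential non-response the auxiliary variables
fail to capture.

## Numerical and degenerate-input choices

* Zero cells in a 2x2 invalidate the repetition; no continuity
  corrections are applied anywhere.
* The impossibility test is exactly $RR_T < 0$, with non-finite values
  (zero denominator) also counted impossible.
* The failed rule is a strict inequality, so exactly 5% impossible does
  not fail.
* Which imputed value is "first" is the order drawn; the two are
  exchangeable by construction.
* Between repetitions the donor pool is fully restored: repetitions are
  independent replicates of one algorithm run, and "without replacement"
  binds within behaviour x repetition x stratum.
* Zero valid repetitions yield an all-sentinel summary row and a warning,
  not an error.

## Known limitations

The correction assumes equal behaviour prevalence between donors and
recipients within each stratum; systematic prevalence differences (e.g.
survey non-response correlated with behaviour) bias $RR_T$ in a way the
calibration cannot see. The empirical percentile intervals describe
repetition noise of the algorithm, not full sampling uncertainty. And the
approach is honest about its limits: when calibration information is weak
(rare behaviour, small phi) the failed rule fires and no estimate is
reported — that behaviour genuinely cannot be recovered from the given
auxiliary variables.
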