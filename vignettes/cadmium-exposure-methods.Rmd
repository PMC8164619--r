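---
title: "Methods: probabilistic dietary cadmium exposure from rice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic dietary cadmium exposure from rice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrice)
```

## The assessment problem

Chronic dietary cadmium exposure is assessed by propagating three sources of
population variability — the contaminant concentration in the food, the
amount of the food eaten per day, and consumer body weight — through a dose
equation, and comparing the resulting dose distribution to a health-based
reference dose. `cdrice` implements this for cadmium in rice, with the
practical constraint that national surveys are usually published as summary
tables rather than raw records.

For each Monte Carlo draw,

$$\mathrm{LADD} = \frac{C \times IR \times AF}{BW}\cdot\frac{ED}{AT},
\qquad \mathrm{HI} = \frac{\mathrm{LADD}}{\mathrm{RfD}},$$

where $C$ is the concentration in mg/kg fresh weight (numerically equal to
µg/g, so no unit conversion factor appears), $IR$ the daily intake in
g/day, $AF$ the absorption factor, $BW$ the body weight in kg, and $ED/AT$
the exposure-duration to averaging-time ratio. A hazard index above 1
flags potential non-carcinogenic concern.

The three stochastic inputs are sampled independently. The source tables
provide no correlation structure between concentration, intake and body
weight; independence is the conventional default and tends to be mildly
conservative for upper percentiles of the ratio.

## Input models

### Exposure factors from arithmetic moments

Intake and body weight are published per age–gender stratum as an
arithmetic mean $m$ and SD $s$ of a lognormal, plus an observed intake
range. The package fits the underlying normal parameters by the method of
moments,

$$\sigma^2 = \log\!\left(1 + (s/m)^2\right), \qquad
\mu = \log m - \sigma^2/2,$$

so that the untruncated model reproduces $m$ and $s$ exactly (the identity
$e^{\mu+\sigma^2/2}=m$ is enforced in tests to a relative tolerance of
1e-12). Moment fitting, not maximum likelihood, is the only option when raw
records are unavailable; it is also what the printed tables mean. The
published moments are interpreted as arithmetic moments on the natural
scale — reading, say, a mean of 83.6 g/day with SD 69.1 as log-scale
parameters would imply physically absurd intakes.

Sampling respects the published intake range by inverse-CDF restriction to
$[F(\mathrm{lower}), F(\mathrm{upper})]$. Rejection sampling would give the
same law, but the inverse-CDF form consumes a fixed number of uniforms per
draw, which keeps runs deterministic under a seed and immune to
infinite-loop pathologies for narrow intervals. An interval carrying less
than 1e-12 of probability mass is rejected as infeasible rather than
silently producing near-constant values. Truncation bounds are applied
*without* re-calibrating $\mu$ and $\sigma$: no re-calibration procedure is
published, and re-fitting would silently change the central tendency the
table states. The cost is a small downward bias in the realized mean of
truncated factors; `spec_mean()` computes the exact truncated mean so the
bias can be quantified (for the intake ranges packaged here it is a
fraction of a percent; tests measure it rather than assume it away).

### Left-censored concentrations

Samples below the limit of detection are recorded as zero — that is the
convention under which the survey's means were computed, so the model must
honor it. The concentration model is therefore a zero-inflated lognormal:
a point mass $p_0$ at zero and a lognormal positive part.

When raw records are available, $p_0$ is the observed non-detect fraction
and the positive part is moment-fitted to the detected values. When only a
summary row (mean $m$, SD $s$, maximum, detection rate $1-p_0$) is
available, `from_summary()` solves the mixture moment equations

$$m_+ = \frac{m}{1-p_0}, \qquad
E[X_+^2] = \frac{m^2+s^2}{1-p_0},$$

so that the *mixture* reproduces the published mean and SD, and truncates
the positive part at the published maximum (the survey offers no evidence
beyond it). If the implied positive-part variance is negative — possible
when a high zero fraction meets a small published SD — the positive part
collapses to a point mass with a warning; a published SD of zero likewise
gives a point mass, not an error.

One published inconsistency deserves note: the reported limit of
quantification (0.2 mg/kg) cannot be reconciled with an 89% detection rate
at a 0.04 mg/kg mean — censoring at 0.2 would censor nearly everything.
The packaged constants preserve the printed value as `loq_as_printed`, but
the working censor threshold defaults to 0.002 mg/kg, a value at which the
89% detection rate is achievable; it is configurable wherever it is used.

## The Monte Carlo engine

Each stratum is simulated with 100,000 draws by default — the scale at
which quantile noise is well below the two-decimal reporting precision
(relative Monte Carlo standard error of the median is about 0.5%).
Percentiles use the linear-interpolation order-statistic rule
(`stats::quantile` type 7) everywhere, chosen once and reused for both
survey summaries and simulation output; at this sample size the choice of
estimator is immaterial beyond the fourth decimal. HI percentiles are
obtained by dividing unrounded LADD percentiles by the RfD — division by a
positive constant commutes with order statistics, so the draw-wise and
percentile-level definitions agree exactly, and visible rounding artifacts
(an HI that does not equal the rounded LADD over the rounded RfD) are
avoided by rounding only at display time.

Reproducibility is stream-based: every stratum and every region draws from
an RNG substream whose seed is derived deterministically from the master
seed and the stratum/region *label* (a small polynomial hash, exact in
double precision on any platform). Keying by label rather than position
means permuting the input rows permutes the output rows without changing
any number, and adding a stratum never perturbs the others.

### Deterministic factors

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `af` | 1.0 | fraction | complete-absorption convention for ingested Cd; the ~6% gastrointestinal absorption figure is informational and deliberately not applied, keeping the assessment conservative |
| `ed`, `at` | 1, 1 | years | lifetime exposure averaged over a lifetime; only the ratio enters the dose |
| `rfd` | 0.36 | µg/kg bw/day | EFSA tolerable weekly intake of 2.5 µg/kg bw ÷ 7, displayed at two decimals; EPA water/food reference doses ship in the constants file as selectable alternatives |
| `iterations` | 100,000 | draws | quantile noise ≪ reporting precision; seconds of runtime |

`derive_daily_rfd()` keeps the unrounded weekly-to-daily conversion
(2.5/7 = 0.35714…) internally and rounds only the displayed value, which
is how a printed 0.36 arises.

## The synthetic survey generator

The generator's role is to rebuild sample-level records whose recomputed
summaries match a published regional table, so that record-level code paths
(reading, summarizing, compliance checks, model fitting) are exercised
end-to-end. Per region it:

1. fixes the non-detect count at `round((1 - detect_rate) * n)` — the
   detection rate is a count ratio, so it is matched by construction rather
   than left to binomial noise;
2. draws the detected values from the positive part of the moment-matched
   mixture by stratified inverse-CDF sampling (one jittered uniform per
   equal-probability stratum, randomly permuted), which pins the sample
   mean near its expectation even for regions with 32–40 samples and large
   SDs;
3. clips draws at the published regional maximum — one-pass calibration:
   clipping preserves more of the target mean than discarding tail mass,
   and guarantees the recomputed maximum never exceeds the published one;
4. censors draws below the working threshold to zero/non-detect, warning if
   that pushes the achieved detection rate more than 2 percentage points
   from target.

Sampling years are assigned uniformly over 2010–2018: per-region yearly
means are not published, so no temporal calibration is attempted, and the
yearly box-plot function should be read as machinery, not as a
reconstruction of the survey's time trend. The same caveat applies more
broadly: the generator reproduces the published summary *statistics*, not
unpublished features of real contamination data — no spatial structure, no
soil covariates, no within-region clustering. Tests passing on synthetic
surveys therefore validate the pipeline's statistical machinery, not any
claim about Taiwanese rice beyond the published summaries.

## Numerical and degenerate-input policy

* Zero-SD inputs are point masses, handled without special-casing errors.
* A point mass outside its truncation interval, an all-non-detect record
  set, and a truncation interval of negligible mass are errors with typed
  conditions (`cdrice_domain_error`, etc.).
* An empty record set cannot be summarized (error), but a compliance check
  on it returns zero exceedances with fraction 0.
* The pipeline validates percentile ordering and the HI = LADD/RfD identity
  before writing any file, and writes atomically (temp file + rename).

## Verification strategy and problem sizes

The test suite checks the engine against independent oracles: the fitted
lognormal's moments recovered by numerical integration of its density; the
closed-form lognormal-ratio distribution ($\ln \mathrm{LADD}$ normal with
$\mu_C+\mu_{IR}-\mu_{BW}$ and summed variances) when censoring and
truncation are disabled, matched within 3 Monte Carlo standard errors at
100,000 draws; sample-and-refit recovery of all 28 stratum parameters at
500,000 draws; and exact scaling laws (concentration scale and 1/RfD
factor out of every percentile when the random stream is held fixed).
These sizes keep the full suite under about ten seconds on one core while
leaving the statistical assertions with 3-sigma margins.

## Known limitations

* **Upper tails are model-sensitive.** Only the first two moments and the
  maximum of the concentration distribution are published; any
  heavier-tailed distribution with the same moments would raise P95 doses
  substantially while leaving P50 nearly unchanged. Central percentiles of
  this package's output are therefore comparable across refits;
  95th-percentile values should be read as model-conditional.
* **Near-ties are not resolvable at full precision.** Several strata's
  median doses differ by less than Monte Carlo noise (and print
  identically at two decimals); rankings among them are only meaningful at
  the reported precision.
* **Per-region detection rates are not published**; all regions default to
  the overall 89%, which slightly smooths regional contrasts in the zero
  fraction.
* Single-food assessment only: no aggregate diet, no carcinogenic
  slope-factor risk, no metal–metal interaction, and no separation of
  uncertainty from variability (one-dimensional Monte Carlo).
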