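---
title: "Poisson partition statistics for ddPCR and downstream infection surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poisson partition statistics for ddPCR and downstream infection surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddquant)
```

## The measurement model

Droplet digital PCR partitions a reaction into on the order of 10,000–20,000
nanolitre droplets, amplifies to end point in each droplet independently, and
reads a fluorescence amplitude per droplet. Target molecules distribute over
droplets approximately as a Poisson process, so with `k` positive droplets
out of `n` accepted, the mean copies per droplet is

$$\lambda = -\ln(1 - k/n),$$

and the absolute concentration of the 1x reaction is
$\lambda / V_d$ copies/µl, where $V_d$ is the effective droplet volume.
`ddquant` implements this chain (`lambda_from_counts()`,
`concentration()`), the exact Garwood confidence interval on the count,
droplet-count quality control, and the conversion of a reaction
concentration to an *infection load* in copies per nanogram of total DNA,

$$C_{ng} = C_{ddPCR} \times (V_r / V_s) / C_{DNA},$$

with reaction volume $V_r$ (default 22 µl), template volume $V_s$ (default
2 µl) and extract DNA concentration $C_{DNA}$ (ng/µl). The load scale is
what host–symbiont surveys model: a host is *infected* when its load
exceeds zero.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `droplet_volume_ul` | 0.00085 | µl | Effective partition volume of QX200-class readers. Not printed by instrument reports; 0.85 nl reproduces every printed (λ, copies/µl) pair in the packaged validation tables, so it is the calibration the vendor software itself used. Configurable per assay. |
| `min_droplets` | 10,000 | droplets | Wells below this accepted-droplet count are too imprecise; the QC rule is boundary-inclusive. |
| `ci_level` | 0.95 | — | Two-sided level of the Garwood interval. |
| `min_positive_droplets_lod` | 3 | droplets | A dilution level counts as detected only when *every* replicate has at least this many positives. |
| `reaction_volume_ul`, `sample_volume_ul` | 22, 2 | µl | Volume ratio used by the load conversion. |

### Numerical choices

* **Saturation**: `k = n` makes the estimator diverge; the package raises
  an error ("concentration above dynamic range") rather than returning
  infinity, so pipelines fail loudly.
* **`k = 0`** maps to exactly zero concentration and a Garwood lower bound
  of exactly zero.
* **Confidence intervals**: the exact (Garwood) interval computes
  chi-square bounds on the count, $\tfrac12\chi^2(\alpha/2; 2k)$ and
  $\tfrac12\chi^2(1-\alpha/2; 2k+2)$, and pushes each bound through the
  occupancy transform and the droplet volume. Vendor software prints its
  own unpublished interval; the two agree approximately, and printed vendor
  CIs are treated as references, not golden numbers. A normal approximation
  on the count scale is available via `quant_config(ci_method = "normal")`.
* **Classification tie-break**: a droplet is positive when its amplitude is
  *strictly* greater than the threshold, so a threshold placed on the
  ceiling of the negative cluster excludes it. Droplets in the "rain"
  region between clusters are classified by the threshold alone — no
  exclusion band.
* **Automatic thresholding** (`auto_threshold()`) is a convenience for a
  step usually done by eye: a deterministic 1-D 2-means (centres
  initialised at the pooled min and max) and a threshold at the midpoint of
  the two centres, which lands close to where an operator places the manual
  line. If the centre gap is under four pooled within-cluster standard
  deviations the function refuses ("no separation") and a manual threshold
  must be supplied. Real assays in the packaged tables used manual
  thresholds (13,033 and 11,309 amplitude units in the two experiments);
  no rule reproduces the manual placement exactly, and the package does
  not try.

## Assay validation

`run_validation_workflow()` bundles the validation battery:

* **Reproducibility**: `replicate_summary()` reports mean, SD, SE and %CV.
  Instrument-report group tables reproduce with the *population* (m) SD
  divisor while pairwise %CVs reproduce with the *sample* (m − 1) divisor;
  both are exposed and the tests pin each convention to its matching
  statistic.
* **Droplet-generation comparison**: an exact Wilcoxon rank-sum test
  (`rank_sum_test()`; full enumeration of rank assignments up to combined
  size 20, tie-splitting, normal approximation with continuity and tie
  correction beyond) plus the Hodges–Lehmann shift — the median of all
  pairwise differences, the only "median shift" definition that reproduces
  the reference 0.27 copies/µl for the packaged cartridge groups (a plain
  difference of medians gives 3.4).
* **Dynamic range**: `dilution_linearity()` fits OLS of concentration on
  relative quantity. The reference r² > 0.99 of the packaged series is a
  *linear-scale* fit (fold vs copies/µl, r² = 0.994); the log–log fit of
  the same wells gives r² = 0.965 and slope 0.89, mostly because
  low-count wells scatter multiplicatively. Both scales are exposed;
  `scale = "log10"` is the default because slope-1 on that scale is the
  natural invariant for a geometric series, but the acceptance tests check
  the linear-scale number the way the reference value was computed.
* **Limit of detection**: the most dilute level at which *all* QC-passing
  replicates have ≥ 3 positive droplets; the reported LOD concentration is
  the mean of that level's replicate concentrations. "At least three" is
  used (not "more than three"); the two readings agree on the packaged
  data, whose minimum passing count is 4. When no level passes, the result
  carries a `lod_reached = FALSE` flag instead of raising.
* **Primer efficiency**: `qpcr_efficiency()` maps a standard-curve slope
  `s < 0` to `(10^(-1/s) - 1) * 100` percent.

## Survey statistics and models

`prevalence()` computes per-group infection proportions with Wilson score
intervals — chosen because survey cells routinely sit at 0% or 100%, where
Wald intervals collapse, and survey reports rarely state an interval
method. `aggregation_index()` reports the mean, variance and
variance-to-mean ratio of infected-host loads (sample divisor by default;
the packaged summary table's printed mean/variance pairs make the golden
vmr check divisor-independent). Analyses of load use infected hosts only,
and the functions enforce that filter.

The regression stage mirrors standard practice for seasonal host surveys:
a binomial-logit model of infection status and a gaussian model of
log-transformed load (natural log; only loads > 0 enter), with population
and month dummy-coded against declared reference levels. Fitting is
delegated to `stats::glm` behind the `fit_glm()` contract; the surface the
package guarantees — and tests — is coefficients, standard errors and the
vcov, not solver internals.

Missing covariates are handled by chained-equations predictive mean
matching (`pmm_impute()`): each incomplete variable is regressed on the
other covariates, and each missing cell takes the observed value of a
donor sampled from the five nearest predicted means, for 50 sweeps per
imputation and five imputations (all configurable). Two design points
deserve note:

* The imputation model **conditions on the analysis outcome** (infection
  indicator and log1p load are appended to the predictor matrix
  automatically). Omitting the outcome attenuates the covariate–outcome
  coefficient in the pooled analysis — in our recovery simulations the
  imputed-length coefficient drifted to ~3 pooled SEs below truth without
  it, and sits well inside the band with it.
* The donor count (5) is the conventional PMM default; it is a package
  choice, not an inferred author setting.

Per-imputation fits are pooled with Rubin's rules (`rubin_pool()`): pooled
estimate = mean; total variance $T = \bar W + (1 + 1/m)B$; per-term
Barnard–Rubin degrees of freedom; per-term Wald t-tests. Pooled
model-comparison tests (multivariate Wald, likelihood-ratio pooling) are
out of scope — the package reports per-coefficient tests and leaves model
selection to the user. A wholly missing density month is completed by
`interpolate_density()`, linear on calendar month index (March = 3 …
November = 11) with no extrapolation past series boundaries; equal spacing
versus month-index spacing was an open choice, and month indices were
chosen because the flanking observations (August, November) are unevenly
spaced around October.

## What the synthetic generators emulate — and what they do not

`simulate_well()` draws per-droplet copy counts Poisson(λ), gives occupied
droplets amplitudes from a positive cluster N(16,788, 400²) and empty ones
from N(5,028, 300²) (cluster means are instrument-realistic; the SDs are
assumptions — real instruments do not publish them), and re-draws 2% of
droplets uniformly between the cluster means as rain. Positive amplitude is
independent of the droplet's exact copy number because end-point PCR
saturates. A counts-only fast path (`simulate_well_counts()`) draws
k ~ Binomial(n, 1 − e^{−λ}) directly for coverage studies.

The uniform-rain geometry implies ~half the rain falls above any
between-cluster threshold, so the expected auto-threshold classification
error is about 0.85% of n at the 2% default — within the 1% design target —
but grows proportionally with the rain fraction; at 5% rain no
between-cluster threshold can stay within 1%. The generator does not
emulate baseline drift, cluster skew, droplet-volume variation or
multi-channel chemistry.

`simulate_survey()` draws infection from a logistic model and infected-host
loads from a lognormal (continuous copies/ng; strongly aggregated,
variance-to-mean ≫ 1 for sdlog ≳ 0.7 — a negative binomial would also give
aggregation but is for integer counts). Default coefficients follow a
field-realistic complete-case survey fit (intercept 1.76; population offsets
−3.0/−1.8/−2.8; month offsets 0–0.7; length +0.001 per µm; density −0.0003
per ind/m²), with host densities drawn uniformly on 1,000–30,000 ind/m² —
realistic for dense spionid beds and necessary for the linear predictor to
span the reference 18.5–100% prevalence band rather than saturate.
Missingness is applied completely at random; informative missingness is
not simulated, so a green recovery test establishes correctness under
MCAR, not robustness to MNAR.

## What a green test establishes

The fixture-driven tests establish that the estimator chain reproduces the
packaged validation tables from raw droplet counts at printed precision
(three rows are pinned separately as vendor rounding). The property tests
establish distributional behaviour under the generators' stated world:
~95% CI coverage over 2,000 simulated wells at the validated assay's
undiluted concentration, pooled coefficient recovery within ±3 SE under
20% MCAR, and the classification error bound above. They do not establish
that any particular field survey's coefficient tables are reproducible —
surveys rarely distribute raw per-host data, and the package deliberately
does not attempt them.

## Known limitations

* Single-channel assays only; no duplex normalisation or copy-number
  ratios.
* The LOD rule is the replicate-threshold convention, not a probit/logistic
  detection model.
* Garwood intervals are conservative for very small k; coverage sits
  slightly above nominal there.
* `auto_threshold()` assumes exactly two amplitude clusters; heavy rain or
  baseline drift defeats it, by design loudly.
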