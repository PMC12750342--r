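---
title: "Deriving regional soil thresholds for Cd and As in paddy systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving regional soil thresholds for Cd and As in paddy systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paddythresh)
```

## The model and its assumptions

`paddythresh` operationalizes a two-track threshold system for Cd and As
in neutral-to-alkaline paddy soils of karst high-geochemical-background
regions, where total soil metal decouples from grain uptake.

**Track 1 — transfer-model inversion (safety threshold, ST).** Grain
concentration is modelled as log-linear in soil properties:

$$\lg(C_\mathrm{rice}) = c + \sum_j \beta_j\, t_j(x_j),$$

with $t_j = \lg$ for concentrations and oxide fractions and $t_j =
\mathrm{id}$ for pH and SOM. The assumptions are the usual OLS ones on the
log10 scale — linearity, homoscedastic Gaussian residuals, and predictors
measured without (relevant) error — plus strict positivity of every
concentration. Predictors are screened by Pearson correlation with
$\lg(C_\mathrm{rice})$ at $\alpha = 0.05$ (`screen_predictors()`); the
screen tests marginal association, matching how the regional models were
built, not partial effects. Collinearity is controlled by the variance
inflation factor $\mathrm{VIF}_j = 1/(1-R_j^2)$: while any VIF exceeds 5,
the available-form member (`A_*`) of the most correlated pair
($|r| > 0.7$) is dropped in favour of the soil total, since the total is
the regulated quantity; absent such a pair, the highest-VIF predictor goes
(`resolve_collinearity()`). The ST is the soil total at which the fitted
model, with pH at the bin's representative value (7 or 8) and all other
covariates at one study-wide set of means, predicts exactly the grain
limit MAC.

**Track 2 — sensitivity-distribution inversion (hazard threshold, HT).**
Per pH bin, the reciprocal bioconcentration factors $1/\mathrm{BCF} =
C_\mathrm{soil}/C_\mathrm{rice}$ are ranked into an empirical CDF and
fitted with the three-parameter logistic curve $y = a/(1+(x/x_0)^b)$.
Because cumulative probability rises with $x$, the fitted shape $b$ is
negative; the closed-form inverse $x = 10^{\lg(a/y-1)/b + \lg x_0}$ is
sign-agnostic. HT is the grain limit times the curve's 95th percentile:
$\mathrm{HT} = \mathrm{MAC} \times \mathrm{HC}_{95}$. The implicit
assumption is that the sampled sites' 1/BCF values represent the regional
variety-by-site sensitivity distribution within each bin.

BCF is treated throughout as the plain dimensionless ratio. Reporting
conventions sometimes attach a factor of 100; the regional benchmark
1/BCF values (order 50 for Cd, 200 for As) are only consistent with the
ratio convention, so that is what `compute_bcf()` stores.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `alpha` (screening) | 0.05 | — | conventional marginal-significance level |
| `vif_threshold` | 5 | — | severe-collinearity cutoff used regionally |
| `corr_threshold` | 0.7 | — | pair rule engages only for tightly coupled predictors |
| MAC (Cd, As) | 0.2, 0.5 | mg·kg⁻¹ | food-standard grain limits (bundled YAML) |
| representative pH | 7, 8 | — | bin midpoints fixed by the national standard's bins |
| covariate means | SOM 34.55 g·kg⁻¹; C-Fe 390, C-Mn 80, F-Fe 34450, F-Mn 1080, Am-Fe 4190, Am-Mn 970 mg·kg⁻¹ | | one study-wide set; `covariate_means(data)` recomputes from a survey |
| `protection` | 95 | % | protection percentile defining HC95 |
| `plotting_position` | hazen | — | `100(r-0.5)/n`; Weibull `100r/(n+1)` available since the convention is not standardized |
| `fix_a` | `TRUE` in `hazard_thresholds()` | — | see numerical choices |
| inversion bracket | lg x ∈ [−2, 4] | lg mg·kg⁻¹ | 0.01–10 000 mg·kg⁻¹ covers any plausible paddy soil |

The auxiliary relation `aux_relation()` (A-As = 0.721·S-T-As − 0.263,
R² = 0.55) lets a model that uses the available-As fraction be inverted
for the soil total: the substitution happens on the linear concentration
scale before the model's log10 is taken.

## What the synthetic generator emulates — and what it does not

No raw survey data are deposited, so `simulate_paired()` generates
datasets with the survey's documented structure: n = 125; pH a
two-component uniform mixture (74.4 % in 7.5–8.25, 25.6 % in 6.56–7.5);
SOM truncated normal (mean 34.55, range 9.53–70.30 g·kg⁻¹, SD 12 g·kg⁻¹ —
the SD is our choice, set so the stated range is well covered); soil
totals log-normal with arithmetic means 2.16 (Cd) and 60.18 (As) mg·kg⁻¹
and a spread of 0.5 log10 units (the survey reports no dispersion; 0.5 is
an assumption surfaced in `generator_config()`); six oxide fractions as
independent log-normals (SD 0.15 log10 units) mean-matched to the
regional means. Grain concentrations follow the reference transfer models
plus homoscedastic Gaussian noise on the log10 scale.

Calibrations made once and not revisited:

* **Cd noise SD 0.26.** Chosen so that refitting the generating
  specification at n = 116 returns an adjusted R² near 0.72, the fit
  quality of the regional Cd model (measured ≈ 0.73 across seeds).
* **As noise SD 0.02**, mirroring that element's much tighter regional
  fit (hold-out RMSE ≈ 0.02 log10 units).
* **Available fractions.** A-Cd is a multiplicative fraction of the total
  (ratio 0.5, 0.08 log10-units scatter), giving the tight total–available
  coupling that makes the collinearity rule bite. A-As follows the linear
  tie 0.721·x − 0.263 with noise **proportional to the signal**
  (cv = 0.35) rather than a constant SD sized to the relation's R²: under
  the log-normal total-As spread a constant SD large enough to push R²
  down to 0.55 drives roughly a third of the values negative, which is
  not a property of concentration data. Values still falling below 0.001
  mg·kg⁻¹ are floored with a warning (≈ 0.3 % of draws).

The generator does **not** emulate: spatial autocorrelation (no
coordinates), between-oxide correlation (independent draws; a correlated
survey would change VIF patterns), variety-specific uptake, heteroscedastic
measurement error, or censoring at detection limits. Passing tests on
synthetic data therefore demonstrate that the estimators recover known
generating structure under the stated noise model — not that the regional
models themselves are correct for any particular field.

## Numerical choices

* **ST inversion.** When the soil total appears in exactly one model term
  the closed form $\lg x^* = (\lg \mathrm{MAC} - \text{other terms})/\beta$
  is used; with an auxiliary substitution the equation is solved by
  `uniroot` on lg(x) over [−2, 4] at tolerance 1e−13. Both paths agree to
  1e−6 relative where both apply, and the round trip
  `predict(model, ST) = MAC` holds to 1e−10 on the log10 scale. If the
  bracket contains no sign change the error reports the function values on
  a grid so the user can see which way the curve runs.
* **SSD fitting.** Levenberg–Marquardt least squares
  (`minpack.lm::nlsLM`), initialized at a = 100, b = −2, x0 = median(x),
  maximum 500 iterations; non-convergence is an error carrying the last
  iterate and SSE. `hazard_thresholds()` fixes a = 100 by default: the
  points being fitted are an empirical CDF whose population asymptote is
  100 %, and a freely fitted a below the protection level would make the
  95th percentile undefined. Free-`a` fitting (`fix_a = FALSE`) is
  retained for curve exploration, and `derive_ht()` then refuses
  protection levels at or above the fitted asymptote rather than
  extrapolating.
* **Degenerate inputs.** Non-positive concentrations are rejected at
  validation with the offending site named; constant predictors are
  excluded from screening with a warning; perfect collinearity reports
  VIF = ∞ rather than erroring; ties in 1/BCF share average ranks, and
  both plotting positions keep probabilities strictly inside (0, 100).
* **Boundaries and ties.** A concentration exactly equal to a threshold
  counts as compliant (quadrant rules use strict `> 0` on the log ratio);
  quality class I is strict `<` the lower threshold and class II is `≤`
  the upper. Rates are reported to one decimal, rounding half away from
  zero. Samples with pH ≤ 6.5 fall outside both bins and are skipped from
  threshold workflows with a warning.
* **Reproducibility.** All randomness descends from one root seed through
  named per-stage substreams (soils, rice, split), so each stage is
  independently reproducible; package functions never disturb the
  caller's RNG state.

## Design choices where the design was open

* The screening statistic "0.89 > 0.7" motivating the available-Cd
  exclusion is read as the correlation coefficient: a *p*-value of 0.89
  would argue for, not against, keeping the predictor.
* Relative importance (`relative_importance()`) is an explicitly labelled
  surrogate — absolute standardized coefficients scaled to max = 100 % —
  because the normalized-importance algorithm of the statistical suite
  used regionally is not public. Ranks are comparable; exact percentages
  are not, and no test asserts them.
* The 95 % point is taken on the **fitted** curve via the exact inverse,
  not as the empirical 95th percentile: the curve is the regional
  sensitivity model, the sample its noisy realization.
* Covariate means are study-wide, not per-bin, matching how the regional
  STs were derived; `means = "from_data"` in `run_pipeline()` switches to
  the dataset's own means.
* The three-class assignment optionally demotes class III to II when the
  measured grain is compliant (`demote_by_grain`), reflecting
  crop co-monitoring practice; it is off by default.

## Problem sizes used by the test suite

Unit tests run on 12-site tiny fixtures and 116–125-site study-like
datasets; statistical recovery uses 200 replicates at n = 116 (binomial
tolerance on 95 % CI coverage); grid-search oracles use ~10⁴–10⁵
combinations; the end-to-end pipeline test runs the full 125-site
workflow. These sizes make the whole suite complete in well under a
minute on one CPU.

## Known limitations

* Recomputing STs from the published 3-decimal model coefficients gives
  ≈ 4.98 / 6.46 mg·kg⁻¹ (Cd, pH 7/8) and ≈ 96.1 / 97.5 (As) — within
  ±15 % of the published regional values (4.54 / 7.12 / 91.43 / 92.30)
  but not equal to them; the full-precision coefficients behind the
  published table are unavailable. Tests assert the ±15 % band.
* No uncertainty propagation: STs and HTs are point values (coefficient
  and curve-parameter uncertainty is not carried into the thresholds),
  matching the regulatory practice the package mirrors.
* Whether ST ≤ HT must hold is not asserted — it is not guaranteed by the
  two derivations, which use different information.
* The logistic form is the only SSD implemented; log-normal or Burr
  alternatives would need their own inverse algebra.
* Bin-level SSD fits with few sites (the neutral bin holds ~25 % of
  samples) inherit the usual small-sample instability of three-parameter
  curves; fixing the asymptote mitigates but does not remove it.
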