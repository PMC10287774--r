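---
title: "Converting loss-on-ignition SOM to soil organic carbon: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting loss-on-ignition SOM to soil organic carbon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mangroveoc)
```

## The model

Loss-on-ignition (LOI) measures soil organic matter (SOM) as the mass
fraction lost when a dried sample is combusted at 550 °C.  Organic
carbon (OC) is a roughly constant fraction of that organic matter, so a
conversion equation predicts OC from SOM.  Three functional forms occur
in the blue-carbon literature and are all supported:

* linear, `OC = m * SOM + b` — the workhorse; `m` is the OC:SOM ratio;
* quadratic, `OC = a2 * SOM^2 + a1 * SOM + a0` — captures the observed
  steepening of the relationship in high-SOM (peat-forming) soils;
* power, `OC = a * SOM^p` — used by a published global mangrove
  equation.

All built-in coefficients are stored on the *percent* scale (SOM and OC
in 0–100).  This matters only for intercepts: an intercept of 10 on the
percent scale means 10% OC at zero SOM, while the same soil described on
the fraction scale has an intercept of 0.10.  Slopes are identical under
both conventions.  One published saltmarsh quadratic was originally
expressed on the fraction scale; it is re-expressed on the percent scale
at load time (`a2` divided by 100, `a1` unchanged) so that a single
internal convention holds everywhere — mixing conventions is a known
source of order-of-magnitude intercept errors.  One literature equation
(Palau) publishes an intercept without a stated convention; it is stored
as percent, the convention of every other entry, and the assumption is
recorded in its provenance field.

A physically meaningful linear equation has `m` in (0, 1) — carbon
cannot exceed the organic matter containing it — and `b` near zero.
Non-zero intercepts are interpreted as procedural error: a positive
intercept arises when carbonate survives into the elemental-analyzer
measurement, a negative one when residual water is counted as SOM mass.
The registry self-checks these constraints at load time.

## Outlier screening

Screening happens in two stages, before any fitting.

**Ratio bounds.**  Samples with OC:SOM ≥ 1 or ≤ 0 are physically
impossible and are removed, with a reason code.  A sample with measured
OC but zero SOM has an undefined ratio; it is treated as an analysis
error and removed (`undefined_ratio`), because OC without organic matter
cannot occur.

**Modified Thompson tau.**  Within each region, the per-sample OC:SOM
ratios are passed through an iterative tau filter: with `n` points, the
point most deviant from the mean is removed if its deviation exceeds
`tau * SD`, where `tau = t * (n-1) / (sqrt(n) * sqrt(n-2+t^2))` and `t`
is the two-sided Student-t critical value at `alpha = 0.05` with `n-2`
degrees of freedom; the procedure repeats on the reduced set until no
point exceeds the threshold or fewer than three remain.  Ties on the
maximal deviation are broken by input order.  The variate is the ratio
(not OC or SOM separately) because the screening rationale is entirely
about the admissible ratio band; both the variate and `alpha` are
configurable.

A property worth knowing: applied to a *clean* Gaussian sample, the
iterative tau rule is not a no-op.  Once the sample maximum exceeds the
threshold the removal cascades, because deleting the extreme point
shrinks the SD and lowers the threshold; the self-consistent stopping
point for large `n` sits near 1.2–1.3 SD, so the filter trims roughly
10–20% of a large well-behaved sample (we verified this by simulation,
and the same behavior follows analytically from the variance of a
truncated normal).  This is inherent to the classical formulation at a
fixed `alpha`, not an implementation artifact.  Consequently the
screened synthetic datasets below lose on the order of a fifth of their
samples to the tau stage even though the generator produces no gross
outliers; the bounds stage removes nothing by construction.  Because the
trimming is symmetric in the residual, fitted slopes are essentially
unbiased (the parameter-recovery tests confirm coverage), but residual
variances and standard errors after screening are smaller than the
generating values.  Screening is idempotent: re-screening a screened
dataset changes nothing.

## Fitting

Linear and quadratic forms are ordinary least squares (`stats::lm`);
degenerate designs (zero predictor variance, collinearity, `n` below the
coefficient count + 1) are hard errors, never silent `NA`s.  The power
form is nonlinear least squares on the original scale
(`minpack.lm::nlsLM`), initialized from the log–log OLS estimate, with a
maximum of 200 iterations and relative tolerance 1e-8; if the optimizer
fails the log–log estimate is returned with `converged = FALSE` and a
warning.  R² for all forms is computed as `1 - SSE/SST` about the mean
of the response on the original scale — not on the log scale — so that
linear, quadratic and power fits are comparable; for the forced
zero-intercept quadratic the same centered definition is used rather
than the uncentered R² that regression-through-origin software sometimes
reports.

The cross-regional curve relating each region's conversion slope to its
mean SOM is fitted as a two-parameter power law `slope = a * SOM_bar^p`
with the same routine.  On the default synthetic system it recovers an
increasing, decelerating curve (`a > 0`, `0 < p < 1`, R² ≈ 0.8).  The
predicted slope for a new region implies a zero-intercept equation — an
assumption empirical fits rarely satisfy exactly — so the prediction is
documented as a rough guide, ranked last in the selection hierarchy.
A ±1 SE band is available via the delta method from the fit covariance.

## Residual validation

An equation is validated against a region by testing whether the
residuals (observed − modeled OC) are centered at zero.  A Shapiro–Wilk
test at `alpha = 0.05` gates the choice: normal-looking residuals go to
a one-sample t-test (central tendency reported as the mean), otherwise a
two-sided one-sample Wilcoxon signed-rank test (central tendency
reported as the median).  No transformation is attempted before the
gate — inventing an unspecified transform seemed worse than gating
directly, and the gate threshold is a configurable argument.  Wilcoxon
conventions: zero residuals are dropped (classical treatment), ties are
mid-ranked, the exact distribution is used for n ≤ 25 without ties and
the normal approximation with continuity correction otherwise.

Per-family performance is summarized by `AbsSum`, the sum over regions
of the absolute central tendencies, and `AbsMean = AbsSum / n_regions`;
the identity `AbsMean * n_regions = AbsSum` holds exactly and is tested.
No multiple-testing correction is applied across regions — the source
framework applies none — and the output notes this.

Group comparisons use the pooled-variance two-sample t-test for the
two sedimentary settings (so `df = n1 + n2 - 2`, and with two groups the
one-way ANOVA F equals t² exactly) and one-way ANOVA with Tukey HSD for
the six coastal environmental settings.  Compact letters are assigned by
an insert-and-absorb pass over the groups sorted by mean.  The
calibration of the gated residual test is itself tested: on true-null
Gaussian residuals its empirical type-I rate over 2,000 seeded
replicates must lie in [0.03, 0.07] at `alpha = 0.05`.

The latitudinal analysis bins samples into 10%-SOM increments, computes
regional mean OC:SOM within each bin, and regresses it on latitude; the
average slope over significant bins is reported with a delta-method SE.
Binning removes the confounding between latitude and regional mineral
(hence SOM) content.  Bins with fewer than three regions are skipped and
logged.

## Selection hierarchy and estimation

`select_equation()` walks the tiers regional → CES → sedimentary →
general → slope-from-mean-SOM and returns the first applicable
equation.  Adding context never demotes the tier.  A carbonate-lagoon
context is served by the carbonate open coast equation (the documented
substitution for that unsampled setting).  Within the general tier the
linear equation is the default and the quadratic is selectable.  The
slope-from-mean-SOM tier is only reachable when a slope curve fit is
supplied and higher tiers are unavailable or explicitly excluded, since
a general equation otherwise always applies.

`estimate_oc()` returns both the raw prediction and a clamped value:
several regional intercepts are strongly negative, so low-SOM inputs can
produce impossible negative OC; the clamp to zero is flagged per sample
and both values are retained.  For linear equations with published
standard errors the prediction SE is `sqrt(som^2 * se_m^2 + se_b^2)`;
this ignores the slope–intercept covariance, which published tables do
not report, and is flagged as such in the documentation.

Stocks integrate `(oc/100) * bulk_density * thickness` over depth
intervals and convert g cm⁻² to Mg ha⁻¹ with the exact factor 100.  The
accounting depth defaults to 100 cm; intervals straddling the limit are
pro-rated by the in-limit fraction of their length (a declared
convention), overlapping intervals are rejected, and the uncovered
fraction of the profile is reported rather than extrapolated.  Stock
computation is additive over depth partitions and homogeneous of degree
one in bulk density, both tested.

Sequential-LOI carbonate content uses the mass lost between 550 and
990 °C, multiplied by a stoichiometric factor converting evolved CO₂ to
CaCO₃.  The default factor is 100/44 (molar-mass basis); the alternative
1.36 (carbonate-ion basis) is selectable because sources differ on which
was used, and at zero second-step loss the choice is immaterial.
Drying-temperature metadata never alters any computation.

## The synthetic generator

`default_region_specs()` encodes one specification per study region:
true slope, intercept, sample count and target R² from the published
regional equations (sample counts sum to 1,246), CES and sedimentary
labels, and a latitude.  Regional mean SOM is printed in the source
framework only for the two extremes (9.9% and 69.2%); the other fifteen
means are package defaults — *not* authoritative values — chosen to
satisfy the published bin counts (ten regions below 30%, four between 30
and 50%, three above 50%), the north-to-south Florida SOM gradient, and
approximate inversion of the slope-vs-mean-SOM power curve.  SOM spreads
are likewise unpublished; `som_sd = clamp(0.35 * som_mean, 3, 15)` and
the residual noise is derived from the target R² as
`noise_sd = slope * som_sd * sqrt(1/R² - 1)`, so each region's fitted R²
lands near its published value.  Bulk density declines with SOM
(`1.6 * exp(-0.025 * som_mean)` g cm⁻³, ±12%), the standard pattern for
organic coastal soils.

Generation draws SOM from a truncated normal, OC as
`slope * SOM + intercept + N(0, noise_sd)` clipped inside
`(0.005 * SOM, 0.995 * SOM)` so that every sample survives the ratio
bounds, and tiles 10-cm depth intervals into cores.  An optional
`latitude_effect` shifts each region's true slope per degree of latitude
from a reference, which lets tests verify that the binned latitudinal
analysis recovers a known effect (−0.04 per degree).  Region substreams
are derived deterministically from the master seed, so datasets are
bit-reproducible.

What the generator does *not* emulate: downcore diagenetic trends,
spatial autocorrelation within sites, non-Gaussian residuals, carbonate
content covarying with setting, and gross outliers of the kind the
screening stages exist to catch.  Passing tests therefore demonstrate
that the pipeline recovers known structure from well-behaved data of the
study's size and shape — not that it is robust to every pathology of
real field datasets.

## Problem sizes and test design

The test suite generates all fixtures in code.  The heavier checks use:
100 random datasets for the OLS-vs-normal-equations oracle (1e-10
relative agreement), 1,000 random small lists (n ≤ 12) for the
tau-filter-vs-brute-force oracle, 500 replicates of n = 100 for slope
coverage (±3 SE in ≥ 99%), 2,000 replicates of n = 20 for the type-I
calibration of the residual test, and full 1,246-sample datasets for the
end-to-end pipeline checks.  These sizes give stable verdicts for the
properties tested while keeping the whole suite around ten seconds.

## Known limitations

* The tau filter's heavy trimming of large clean samples (above) means
  post-screening standard errors understate the generating noise; if
  that matters for an application, screen with a smaller `alpha` or skip
  the tau stage.
* Prediction SEs ignore coefficient covariance and all equation-choice
  uncertainty; they are lower bounds.
* CES labels are user-supplied; the package performs no spatial lookup
  of the global typology map.
* Literature equations are reproduced as printed, including three with
  unreported intercepts (evaluated as pure slopes) and one with an
  unreported sample count; where a printed table was internally
  ambiguous the resolution is recorded in the equation's provenance.
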