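---
title: "Methods: quasi-pipe allometry for tree leaf area, leaf mass and stand LAI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quasi-pipe allometry for tree leaf area, leaf mass and stand LAI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpipe)
```

## The problem and the model

The pipe model of tree form holds that the amount of foliage a tree carries
is approximately proportional to the stem cross-sectional area at the crown
base, $A_{CB}$ (m²) — the stem there is, to first order, a bundle of
"pipes" each serving a unit of leaf. $A_{CB}$ is an excellent predictor of
tree leaf area and leaf mass, but measuring it requires climbing to the
crown base, which rules it out for large inventories.

The quasi-pipe (qPipe) estimator replaces the climb with geometry. If the
stem between treetop and breast height (1.3 m) is treated as a paraboloid
of revolution with its apex at the treetop, cross-sectional area grows
linearly with distance from the tip, so

$$A_{CB\_Est} = A_{BH} \, R_{CROWN}, \qquad
  R_{CROWN} = \frac{H - h_{CB}}{H - 1.3},$$

where $A_{BH}$ is the breast-height area, $H$ total height and $h_{CB}$
crown-base height — all measurable from the ground. `estimate_acb()` and
`add_crown_metrics()` implement this. No regression coefficients are
involved: the estimator is pure geometry, which is what makes it portable
across stands that have no local allometry.

Leaf amount is then predicted from a power law on arithmetic scales,

$$Y = CF \times \mathrm{Elevation} \times X^{\mathrm{Slope}},$$

with $X$ either $A_{CB}$ (pipe) or $A_{CB\_Est}$ (qPipe), $Y$ leaf area
(LA, m², one-sided; projected for conifers) or leaf dry mass (LM, kg),
Elevation the response at $X = 1$ m², and $CF$ the bias correction for
back-transforming a natural-log regression (below). The package ships a
registry (`qpipe_registry()`) of population-level coefficients established
on a compiled dataset of 962 trees from 159 species across four plant
functional types (PFTs: evergreen/deciduous × conifer/broadleaf), spanning
tropical to boreal forests: pooled leaf-area equations (PFT adds nothing
for LA) and per-PFT leaf-mass equations (PFTs separate clearly for LM).

## Stem taper and when the estimator errs

Between breast height and treetop the relative stem profile is modelled as
$A = L^{2/X}$, with $L$ relative distance from the tip and $X$ the taper
exponent: a cone at $X=1$, paraboloid at $X=2$, cubic solid of revolution
at $X=3$. The qPipe estimator assumes $X = 2$; for a stem with true
exponent $X$ observed at relative crown length $l$ the error is exactly

$$\frac{A_{CB\_Est}}{A_{CB}} = l^{\,1 - 2/X},$$

an overestimate for tapered stems ($X<2$), exact at $X=2$, an
underestimate for cylindrical stems ($X>2$). `qpipe_relative_error()` and
`taper_diagnose()` expose this; `taper_exponent_from_observation()` inverts
the profile for trees whose $A_{CB}$ was measured, so a stand can be placed
against the cone/paraboloid/cubic reference curves
(`plot_taper_error()`). In mixed stands over- and underestimates cancel
partially — the log errors average to zero when $2/X$ is symmetric about 1
— which is why the estimator is more reliable for stand totals than for
single trees. Trees close to death tend to sit in the overestimated
region, which is why `estimate_stand()` drops trees flagged dead (and
zero-crown trees, whose leaf amount is zero but whose stem area is not)
before aggregating.

## Model II versus Model I regression

Two regression families are deliberately kept apart:

* **SMA (standardized major axis, Model II)** — `fit_sma()` — for
  *estimating* allometric slopes, because it treats residuals in both
  log-transformed variables symmetrically. The slope is
  $\mathrm{sign}(r)\, s_y / s_x$; its magnitude always weakly exceeds the
  OLS slope (equality only at $r^2 = 1$), and refitting with the axes
  swapped returns the reciprocal slope — both are enforced as tests.
  Confidence limits use the standard construction
  $b(\sqrt{B+1} \pm \sqrt{B})$, $B = F_{1-\alpha;1,n-2}(1-r^2)/(n-2)$.
  With a grouping factor (PFT), a likelihood-ratio test of a common slope
  is run: the statistic $-\sum_i (n_i - 2.5)\ln(1 - r_i^2)$, where $r_i$
  correlates each group's residual scores $y - bx$ with its fitted-axis
  scores $y + bx$, is minimised over the candidate common slope and
  referred to $\chi^2_{g-1}$. When slopes are homogeneous, elevations are
  compared pairwise by Wald tests at the common slope with Sidak-adjusted
  p-values, $1 - (1-p)^m$.
* **OLS / random-intercept mixed models (Model I)** — `fit_ols()`,
  `fit_random_intercept()` — for *prediction*. Species enters as a random
  intercept (a ln-scale Gaussian shift per species); candidate structures
  (with/without species, with/without PFT as a fixed effect) are compared
  by AIC in `fit_allometry()`, with non-converging candidates discarded
  and ties broken toward fewer parameters. Variance components are
  estimated by REML, but the AIC reported for selection comes from a full
  maximum-likelihood refit so that models with different fixed effects are
  comparable. OLS goes through `stats::lm` and the mixed model through
  `lme4::lmer`; the SMA machinery, being the inferential core here, is
  implemented in the package and validated against hand-computed moments
  and a brute-force profile of the common-slope statistic.

**Robust SMA.** To blunt the influence of stray points, the robust variant
estimates the bivariate location and scatter entering the slope formula by
Huber M-estimation: points are weighted by $\min(1, k/d)$ on standardized
distance $d$ from the centroid (weights squared for second moments,
$k = \sqrt{\chi^2_{2,0.95}}$), starting from medians/MADs and iterating to
a $10^{-8}$ change (max 50 iterations). The scatter consistency constant
cancels in the slope and correlation, so none is applied. Groups with
fewer than 5 points fall back to the standard fit with a warning. Robust
and standard slopes typically differ by well under 0.01 on clean data.

**Outlier filtering.** `grubbs_filter()` applies the two-sided Grubbs test
iteratively: remove the most extreme value while
$G = \max|v - \bar v| / s$ exceeds
$\frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}$ with
$t = t_{1-\alpha/(2n),\,n-2}$, stopping when nothing is significant or
fewer than 3 values remain. $\alpha$ defaults to 0.05 (two-sided), ties
break on first occurrence, and filtering is idempotent. In
`fit_allometry(grubbs = TRUE)` it is applied per PFT to residuals about a
provisional OLS line.

## Back-transformation bias and prediction intervals

A regression of $\ln Y$ on $\ln X$ back-transformed with `exp()` estimates
the *median* of $Y$; under lognormal residuals the mean is recovered by
multiplying with $CF = \exp(\hat\sigma^2/2)$, $\hat\sigma$ the ln-scale
residual sd (`correction_factor()`). The registry's printed CFs are
consistent with this form (e.g. CF 1.077 corresponds to
$\hat\sigma \approx 0.386$).

95% prediction intervals are carried in two closed forms on the ln scale,
with $u = \ln X$:

* quadratic: $\Delta PI(u) = c_0 + c_1 u + c_2 u^2$, used for the
  mixed-model equations, fitted by least squares to pointwise intervals
  (residual + between-species + fixed-effect variance, normal quantile)
  over the observed predictor range — the approximation stays within 1% of
  the pointwise values across the central 90% of that range;
* least-squares exact: $\Delta PI(u) = c_0 c_1 \sqrt{1 + 1/c_2 +
  (u - c_3)^2 / c_4}$ with $c_0$ the $t$ quantile, $c_1$ the residual SE,
  $c_2 = n$, $c_3 = \bar u$, $c_4 = \sum (u - \bar u)^2$ — the textbook
  OLS prediction interval, stored for the one registry equation fitted by
  plain least squares. The registry interprets both forms in $u = \ln X$;
  $c_2 = 57$ for that entry is its calibration sample size, which pins the
  interpretation down.

Bounds are $\exp(\ln \hat Y_{uncorr} \pm \Delta PI)$. Whether the printed
interval brackets the CF-corrected or uncorrected prediction is ambiguous
in the source material; the package centres the bounds on the uncorrected
(median-scale) prediction — the regression's natural scale — while
reporting the CF-corrected point estimate alongside, and
`predict_interval(cf_in_interval = TRUE)` moves the CF into the bounds for
users who read the convention the other way. Predictions outside an
equation's calibration range warn rather than fail, since large-scale
users will meet trees larger than any calibration tree; the shipped soft
range (10⁻⁵–1 m²) spans roughly a 4 mm to 1.1 m crown-base diameter.

## Stand aggregation and error propagation

`estimate_stand()` sums per-tree point estimates and divides by ground
area (LAI, m²/m², from leaf area; biomass, kg/m², from leaf mass).
Per-tree 95% intervals are propagated to the stand under independence
across trees. Three rules are implemented:

* **lognormal (default)** — each tree's interval is read as a lognormal
  ($\sigma_i = \ln(u_i/l_i)/2z$), arithmetic means and variances are
  summed, and a lognormal is matched to the total (Fenton–Wilkinson).
  Against a 50,000-draw Monte-Carlo simulation of a 30-tree stand the
  propagated half-widths agree within a few percent.
* **quadrature** — lower and upper arithmetic half-widths combined
  separately as $\sqrt{\sum \delta^2}$. This is the simplest reading of
  "propagation of errors", and for $n$ identical trees gives the
  closed-form $\sqrt n$ scaling. But back-transformed lognormal intervals
  are asymmetric in a way that does not add in quadrature: at ln-scale sds
  around 0.3–0.4 (what the global equations actually have) it overstates
  the upper and understates the lower Monte-Carlo percentile of the total
  by 15–20%. It is kept as an option, not the default — the default had to
  be the rule that survives its own simulation check.
* **log_quadrature** — delta-method combination of ln-scale half-widths,
  for users who propagate on the log scale.

Independence across trees is an approximation on two counts: trees of the
same species share a random-effect draw, and all trees share the fitted
coefficients. Neither covariance is recoverable from published
coefficients alone, so the propagated intervals are what a reader of the
registry could compute — documented here as a known limitation.

## The synthetic generator

`simulate_trees()` produces inventories with known ground truth, emulating
the structure the analyses assume: DBH lognormal (median 12 cm, ln-sd
0.6); height $1.3 + 25\,\mathrm{dbh}^{0.65}$ m with 10% lognormal scatter;
crown ratio Beta(5, 3); taper exponent lognormal centred on the paraboloid
($\ln X \sim N(\ln 2, 0.15)$); true $A_{CB} = A_{BH} l^{2/X}$; leaf area
$2400\,A_{CB}^{1.0}$ m² with ln-scale residual sd 0.30 and species
intercept sd 0.30; and tree-level LMA $= 0.10\,(H/10)^{0.25}$ kg m⁻², so
leaf mass is LMA-weighted leaf area. The LMA–height exponent is the
mechanism that makes leaf-mass slopes exceed leaf-area slopes (taller
trees carry denser foliage); setting it to zero makes the two slopes
exactly equal, and the default 0.25 reproduces the ~0.05–0.1 slope excess
seen in the global fits. Distribution choices are for positivity and
realistic skew; every parameter is overridable. One integer seed drives a
counter-based per-tree stream, so any subset of a dataset regenerates
identically.

What the generator does *not* emulate: measurement error in heights and
crown bases, within-species taper correlation, spatial structure,
competition, or crown damage (top breakage, epicormic turnover). Tests
passing on synthetic stands therefore demonstrate internal consistency of
the estimators and intervals, not field accuracy for atypical crowns.

## Numerical choices and problem sizes

Tolerances: robust-SMA and mixed-model iterations converge at $10^{-8}$;
AIC ties within $10^{-9}$ prefer fewer parameters; $r^2$ is clamped to
$[0,1]$ against floating-point overshoot; groups whose residual variance
vanishes at a candidate common slope contribute zero to the LR statistic
(they are evidence *for* that slope, and the objective is discontinuous
there, so those candidate slopes are evaluated explicitly). Degenerate
inputs — zero variance, fewer than 3 points per group, crown base at the
treetop (crown ratio 0 would put zero leaf amount on a log scale) — are
rejected with typed errors rather than propagated as NaN.

The test suite and the reproduction script run entirely on synthetic data
at sizes chosen to keep Monte-Carlo error well below the tolerances they
assert: 100 replicates of 400-tree datasets for coverage checks, 50
replicates of 500 trees for the slope-ordering claim, 50,000 draws for the
propagation oracle, 962 trees (the compiled dataset's size) for the
script's headline dataset.

## Known limitations

* The published supplementary dataset is not redistributable with the
  package; the reproduction of its record counts and robust SMA slopes
  runs only when a local copy is supplied
  (`options(qpipe.supplementary_file = ...)`).
* Registry calibration ranges are soft bounds, not the exact per-PFT data
  extents of the source figures.
* Random-slope models are out of scope (the selected global structures are
  intercept-only); so are height–diameter allometries, non-leaf biomass,
  and sapwood-area variants of the pipe model.
* Prediction for a named species does not use that species' random-effect
  offset — registry equations are population-level, and the printed
  intervals are taken as complete.
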