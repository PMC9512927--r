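---
title: "Compressed calibration for ICP-MS survey scans: model, uncertainty and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed calibration for ICP-MS survey scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(compcal)
library(dplyr)
```

## The problem

An ICP-MS run usually begins with a *survey scan* — a fast sweep over all
mass channels that records an intensity for every measurable element in
every sample — before the instrument dwells on a handful of pre-selected
analytes in precise peak-hopping mode. Only the pre-selected analytes get
real calibration; for everything else the vendor software offers at best a
semi-quantitative guess with no uncertainty attached, and that guess can be
off by orders of magnitude when no internal standard is used.

Yet the survey scan, together with the external-standard dilution series
that was measured in the same run anyway, contains enough information to
*quantify* every element present in the calibration standard mixture — with
an honest standard deviation — entirely post-measurement. That is what this
package implements, along with the downstream screening and time-series
summaries used when monitoring metal concentrations in bioleaching
leachates (column experiments with biostimulated or bioaugmented mine
residues, sampled as column effluent and pore water over several weeks).

## The calibration model

The external standards are a main multi-element mixture (element
concentrations $C_0$, µg/L) and a series of dilutions of it, with dilution
factors $d \in [0, 1]$ ($d = 1$ undiluted, $d = 0$ a blank). For each mass
channel the measured intensity is modelled as a straight line in the
dilution factor,

$$ I = b + s\,d + \varepsilon, \qquad \varepsilon \sim (0, \sigma^2), $$

with three channel-specific parameters: the **background** $b$ (cps),
absorbing blank-borne signal and part of any interference; the
**sensitivity** $s$ (cps per unit dilution factor); and the error SD
$\sigma$ (cps), treated as an unknown to be estimated, depending on the
element but *not* on the dilution factor. Using the dilution factor — not
each element's concentration — as the regressor means every channel shares
the same design vector, so the ordinary-least-squares closed forms

$$ \hat s = S_{dI}/S_{dd},\quad \hat b = \bar I - \hat s \bar d,\quad
   \hat\sigma^2 = \mathrm{RSS}/(n-2), $$
$$ \operatorname{var}(\hat s) = \hat\sigma^2/S_{dd},\quad
   \operatorname{var}(\hat b) = \hat\sigma^2\left(\tfrac1n + \bar d^2/S_{dd}\right),\quad
   \operatorname{cov}(\hat b, \hat s) = -\hat\sigma^2 \bar d/S_{dd} $$

can be evaluated for the whole intensity matrix in one vectorized pass
(`fit_calibrations()`); the per-channel loop (`vectorized = FALSE`) is
retained and tested to be bit-identical. $\hat\sigma^2$ uses the unbiased
$n-2$ denominator; the choice is isolated in one internal function so a
maximum-likelihood convention could be swapped in. Blanks are ordinary
calibration points — that is precisely how the background parameter absorbs
blank-borne interference. A fit needs at least 3 points and 2 distinct
dilution levels, so that $\hat\sigma$ is defined; a non-positive fitted
sensitivity is flagged and refused downstream rather than inverted.

## Inverse prediction and error propagation

For an assay intensity $I$ (the mean of $m$ replicates), the estimated
dilution equivalent and concentration are

$$ \hat r = (I - \hat b)/\hat s, \qquad \hat c = \hat r\, C_0 , $$

with first-order (delta-method) propagation treating $I$, and the pair
$(\hat b, \hat s)$, as independent:

$$ \operatorname{sd}(\hat r)^2 =
   \frac{\hat\sigma^2/m + \operatorname{var}(\hat b)
         + \hat r^2 \operatorname{var}(\hat s)
         + 2 \hat r \operatorname{cov}(\hat b,\hat s)}{\hat s^2}. $$

Design choices here, each the subject of a test:

* The sample intensity's own noise uses the channel's calibration-estimated
  $\sigma$ (there is no per-sample replicate SD in a survey scan).
* $C_0$ is treated as exact; certificate uncertainty of the stock CRMs is
  not propagated.
* Negative concentrations (intensity below the fitted background) are
  **reported unclamped** and flagged `below_background`, keeping downstream
  averages unbiased.
* $\hat r > 1$ extrapolates above the undiluted standard; such estimates
  are usable and merely flagged `extrapolated_above_standard`.
* Intervals are symmetric ($\hat c \pm k\,\mathrm{sd}$); Fieller-type
  intervals are out of scope.
* If a corrupted calibration file carries a covariance beyond the
  Cauchy–Schwarz bound the propagated variance can go negative; it is
  clamped to zero with a warning. (With a self-consistent fit the
  quadratic form is non-negative by construction.)

Time-averaged concentrations (`time_averaged()`, `quantify_pooled()`)
average the *intensities* first and invert once with the $\sigma^2/m$ term,
which for a linear model equals the average of per-sample concentrations
but with the correct, smaller standard deviation.

## Screening and cross-method validation

Comparing two measurement runs whose standards differ (two growth media in
the motivating study) proceeds in three steps (`screening_report()`):

1. only elements present in both runs' standards are kept
   (`cross_check_elements()`);
2. elements whose estimated SD is *in the range of* the estimated
   concentration are excluded (`significance_filter()`). The phrase is
   operationalised as $\mathrm{sd} \ge \rho\,|\hat c|$ with $\rho = 1$, or
   $\hat c \le 0$, decided at run level on the **median** of per-sample
   values; $\rho$ and the summariser are arguments because no numeric rule
   is canonical, and the median is robust to single-sample excursions;
3. where a precise peak-hopping concentration exists, the difference is
   divided by the compressed-calibration SD alone (the reference method is
   treated as exact) and compared with a critical value of $k = 3$
   standard deviations (`compare_methods()`).

## The synthetic-data generator

`simulate_design()` and `simulate_survey()` generate survey datasets with
known ground truth so that every stage can be scored without any external
download. The generator emulates the structure of the motivating study:

* a 9-element default panel (Mg, Si, Al, K, Mn, Fe, Cu, Zn, Se — the
  retained interfering components), extensible to 20 elements;
* a calibration series at dilution factors $\{1, 0.5, 0.1, 0.01, 0\}$ —
  a main calibration sample, subsequent dilutions and a blank, each
  measured once;
* the study layout: treatments BS/BA × effluent/pore water × 5 timestamps
  (20 assay samples per run), with smooth per-element time trends;
* per-channel Gaussian noise, constant across dilution levels —
  instantiating the model assumption that the error variance depends on
  the element but not on the dilution factor. The default noise SD is 1%
  of the channel sensitivity, i.e. survey-scan counting noise at high
  count rates, which puts the default scenario in the well-conditioned
  regime (concentration cv below 5%) used for the uncertainty checks;
* backgrounds drawn between 5% and 25% of the full-standard response —
  high, as typical of uncorrected survey scans — and at least five noise
  SDs above zero, so that flooring of negative noisy counts (applied for
  physical non-negativity, and counted in attribute `n_floored`) stays a
  rare event that does not bias the blank levels;
* sensitivities spanning $10^{3.5}$–$10^5$ cps per unit dilution factor
  and mixture concentrations of 50–500 µg/L;
* one element with true concentration exactly zero (to exercise the
  significance filter) and one exceeding the undiluted standard
  ($r^* > 1$, exercising the extrapolation flag);
* one deterministic noise substream per channel, so adding a channel never
  perturbs the draws of existing channels.

What the generator does **not** emulate: isobaric and polyatomic
interferences, detector dead time, drift within a run, Poisson (rather
than Gaussian) counting statistics, and matrix effects. Tests passing on
synthetic data therefore validate the *estimation machinery* — not the
absence of spectral interference in any particular real run. The noise
distribution is pluggable in principle (only `simulate_survey()` would
change).

## What the verification computes — and one honest caveat

The acceptance script (`scripts/acceptance.R`) and the test suite verify,
at fixed seeds and documented problem sizes (200 random designs; 2,000
coverage replicates; 500 screening replicates; 1,000 twin replicates; a
50-channel vectorization check):

* exact agreement of the closed forms with an independent OLS fit;
* noiseless end-to-end recovery of every true concentration to $10^{-9}$
  relative, and $\hat r = 1$ for the undiluted mixture itself;
* delta-method SDs within 10% of $10^6$-draw Monte-Carlo propagation in
  the well-conditioned regime;
* near-certain exclusion of a zero-concentration element by the
  significance filter, with strong signals never excluded;
* bit-identity of the vectorized and looped calibration paths.

The caveat concerns **nominal-normal interval coverage at the 5-point
design**. All delta-method variance terms scale with $\hat\sigma^2$, and
the prediction-error numerator is independent of the RSS, so the
standardized error $(\hat c - c)/\widehat{\mathrm{sd}}$ is *exactly*
Student-$t$ with $n - 2 = 3$ degrees of freedom. Consequently
$\hat c \pm 1.96\,\mathrm{sd}$ covers $2\,P(t_3 \le 1.96) - 1 \approx
85.5\%$ — not 95% — and $|z| \le 3$ holds with probability
$\approx 94.2\%$, not the $\approx 99.7\%$ a normal reference would give.
This is a property of *any* correct implementation at a 5-point
calibration, not an estimation defect: the module tests verify the exact
$t_3$ rates, and verify that nominal coverage is restored when the
calibration has enough points (df $\gtrsim 28$). Users who need calibrated
intervals at small calibration designs should multiply the reported SD by
$t_{n-2,0.975}/1.96$; the package reports the SD itself and leaves the
quantile choice to the user, as the downstream screening rules are defined
directly on the SD.

## Numerical conventions

* Internal unit µg/L (ppb); the CLI's `--unit ppm` scales by $10^{-3}$ on
  output, and the Concentrations File records its unit.
* CSV writers emit 17 significant digits and the readers parse through
  R's correctly-rounded `strtod`, so all three file kinds round trip
  bit-exactly.
* Sums are accumulated column-wise in a fixed order in both calibration
  paths (and divided by $n$ without the two-pass mean correction), which
  is what makes the vectorized and looped fits bit-identical rather than
  merely close.
* Mass-channel labels follow `<mass><Symbol>` ("27Al"); an embedded
  isotope table rejects unknown element symbols and warns on mass numbers
  that are not stable isotopes of their element.

## A short worked pipeline

```{r pipeline}
truth  <- simulate_design(n_elements = 9, seed = 7)
survey <- simulate_survey(truth, seed = 8)
calib  <- fit_calibrations(survey, truth$design)
glance(calib)

est <- quantify(split_survey(survey, truth$design)$assay, calib)
significance_filter(est)
```

The excluded element is the generator's zero-concentration trace element:
its estimated SD is in the range of its estimated concentration, which is
exactly the situation the screen is designed to catch.

## Known limitations

* No interference correction beyond what the background parameter absorbs;
  the method inherits the matrix-effect vulnerability of external
  calibration without an internal standard.
* The error model is homoscedastic per channel; intensity-proportional
  (shot-noise) variance functions and weighted fits are out of scope.
* Coverage of $\pm 1.96$-SD intervals is the $t_{n-2}$ rate, as discussed
  above.
* Peak-hopping uncertainties do not enter the 3-SD comparison; the
  reference method is treated as exact.
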