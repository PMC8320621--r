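---
title: "Methods: drop shape analysis and the surfactant inhibition bioassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drop shape analysis and the surfactant inhibition bioassay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdsurf)
```

This vignette documents the models, numerical methods, parameter choices and
interpretation decisions behind `cdsurf`. The package implements the analysis
pathway of a constrained drop surfactometer (CDS) bioassay for lung surfactant
inhibition: a ~10 µL surfactant drop sits on a sharp-edged pedestal, an
aerosolized chemical deposits onto it while the drop is cycled through
compression–expansion at breathing-like rates, and surface tension is read
continuously from the drop's shape. A functional film reaches very low surface
tension on each compression; an inhibited film does not.

## 1. Drop shape model (ADSA)

### Forward problem

For an axisymmetric drop in hydrostatic equilibrium, the Young–Laplace
equation reduces to an ODE system in arc length $s$ measured from the apex,
with turning angle $\phi$, horizontal radius $r$ and depth $z$ (measured from
the apex into the drop):

$$
\frac{d\phi}{ds} = \frac{2}{R_0} + \frac{\Delta\rho\, g}{\gamma} z -
\frac{\sin\phi}{r}, \qquad
\frac{dr}{ds} = \cos\phi, \qquad
\frac{dz}{ds} = \sin\phi,
$$

where $R_0$ is the apex radius of curvature, $\gamma$ the surface tension and
$\Delta\rho$ the density difference. Units are mm, mN/m and kg/m³ throughout;
in these units the capillary term is
$\Delta\rho\, g / \gamma \times 10^{-3}$ mm⁻². The dimensionless shape is
controlled by the Bond number $\beta = \Delta\rho\, g R_0^2 / \gamma$.

`integrate_drop_profile()` integrates this system with `deSolve::lsodar`
(adaptive, `rtol = 1e-10`, `atol = 1e-12`). Two numerical points:

* **Apex singularity.** $\sin\phi / r \to 1/R_0$ as $s \to 0$, so integration
  starts a short step off the apex using the series expansion
  $\phi = s/R_0$, $r = s - s^3/(6R_0^2)$, $z = s^2/(2R_0)$, and the apex row
  $(0,0,0)$ is prepended afterwards.
* **Termination by root-finding.** The contour of the constrained drop ends
  at the pedestal's knife edge; the solver stops at the first root of
  $r = r_\mathrm{ped}$. A second root function, $\phi = \pi$, catches the
  case where the drop closes up without ever reaching the pedestal radius
  (reported as a geometry error rather than a silent truncation).

A consequence worth stating because it is easy to get backwards: at *fixed
apex radius*, increasing $\Delta\rho$ makes the truncated contour *taller*
relative to its width (curvature grows with depth, so the profile curls
toward the axis sooner). The familiar "heavy sessile drops flatten" statement
holds at fixed volume, where the apex radius itself grows with Bond number.
The package tests pin the direction the equations imply at fixed $R_0$.

Surface area and volume come from surface-of-revolution quadrature
($2\pi \int r\, ds$ and $\pi \int r^2\, dz$, trapezoid rule) in
`profile_area_volume()`. At $\beta = 0$ these reproduce spherical-cap closed
forms to $10^{-5}$ relative accuracy.

### Inverse problem

`fit_surface_tension()` recovers $(\gamma, R_0)$ from an apex-aligned
observed contour by Nelder–Mead minimization (in $\log\gamma$, $\log R_0$) of
the mean squared distance from each observed point to the forward-integrated
profile. Design choices:

* **Point-to-segment metric.** Distances are measured to the polyline's
  *segments* (projection), not its vertices: a vertex-only metric carries a
  discretization bias of order the sampling step that dominates the error
  budget at the 0.1 % level.
* **Comparison-curve extent.** The forward curve used in the metric is
  integrated until its polar radius from the apex exceeds the observed point
  cloud by 2 % (or until $\phi = \pi$). Terminating instead at the maximum
  observed $r$ fails with noisy data: noise pushes $\max r$ past the drop's
  equatorial bulge, making the target unreachable and creating penalty cliffs
  in the objective.
* **Nearest-segment search.** The metric locates each observed point's
  nearest dense-contour vertex and projects onto the segments adjacent to it
  (a small window guards edge cases). This is exact for a smooth curve
  sampled far below its curvature scale and avoids materializing the full
  points-by-segments distance matrix.
* **Initialization.** $R_0$ from the parabolic apex approximation
  $z \approx r^2/(2R_0)$; $\gamma$ from a coarse Bond-number grid
  (0.02–20).
* **Two stages.** A search stage against a 400-point forward contour,
  then (optionally, `refine = TRUE`) a restart against an 8× denser contour.
  The refinement removes the polyline chord bias (order step²/8), which
  matters only for noiseless contours; with ≥1 µm coordinate noise the bias
  is below the noise floor and `refine = FALSE` is the economical choice.

At $\Delta\rho = 0$ the shape is spherical for every $\gamma$, so the fit
refuses to run (identifiability error) rather than returning an arbitrary
number.

### Validation study

`adsa_roundtrip_study()` freezes the self-validation conditions: a water-like
drop ($\Delta\rho = 1000$ kg/m³, $R_0 = 1$ mm), Bond numbers
$\{0.05, 0.2, 0.5, 1, 2\}$ via $\gamma = 9.81/\beta$, contour sampled every
0.75 µm of arc, and i.i.d. Gaussian coordinate noise of 1 µm. The pedestal is
placed at 97 % of each drop's equatorial radius because arc coverage toward
the equator dominates the surface-tension information in the contour
(a Cramér–Rao argument: the shape derivative with respect to $\gamma$ grows
with depth); constrained drops are in fact operated near maximum volume,
where the contour approaches the equatorial plane. Under these conditions the
fit recovers $\gamma$ to better than 0.1 % noiselessly and ~1.4 % mean
relative error with noise, across the Bond grid.

## 2. Film simulator

`simulate_trace()` generates surface tension/area traces for a cycling drop
exposed to a depositing aerosol. It is a phenomenological model of the
*trace*, not a molecular film model — its purpose is to exercise the analysis
pathway with known ground truth.

* Area protocol: $A(t) = A_0 \left(1 - \tfrac{a}{2} + \tfrac{a}{2}
  \cos 2\pi f t\right)$, defaults $A_0 = 18$ mm² (the surface area of a
  ~10 µL constrained drop), relative amplitude $a = 0.25$ (compression stays
  under the 30 % QC limit), $f = 20$ cycles/min, 10 frames/s.
* Deposited dose: $D(t) = J\, t / 60$ (flux $J$ in ng/cm²/min).
* Surface-tension floor (the minimum the film can reach at full compression)
  rises with dose along a saturating curve:
  $\gamma_\mathrm{floor}(t) = \gamma_{f0} + (\gamma_{f\infty} - \gamma_{f0})
  \frac{D}{D + D_{50}}$, defaults $\gamma_{f0} = 2$,
  $\gamma_{f\infty} = 25$ mN/m — an intact film compresses to ~2 mN/m, a
  fully inhibited one stalls well above the 10 mN/m inhibition threshold.
* Instantaneous tension interpolates between the floor and a maximum
  (default 40 mN/m, near the equilibrium tension of a compressed monolayer)
  with compression fraction $c(t)$: $\gamma(t) = \gamma_\mathrm{floor} +
  (\gamma_\mathrm{max} - \gamma_\mathrm{floor})(1 - c(t))^p$, plus optional
  Gaussian noise (default 0.3 mN/m, a realistic ADSA read noise).

What it does *not* emulate: adsorption/spreading kinetics, hysteresis between
compression and expansion limbs, film collapse, temperature dependence, or
aerosol losses. None of these affect what the analysis pathway is being
tested for (segmentation, QC, thresholding, dose arithmetic).

Because the floor crossing of the inhibition threshold has the closed form
$D^* = D_{50} (\mathrm{thr} - \gamma_{f0}) / (\gamma_{f\infty} -
\mathrm{thr})$, `floor_crossing_time()` provides an analytic ground truth for
onset times, used to verify dose estimates end to end.

## 3. Trace analysis and the assay's decision rules

The assay's published criteria leave some details open; the package fixes
them as follows (all configurable through `assay_criteria()`):

* **Cycle segmentation** (`segment_cycles()`): cycles run between successive
  area maxima (prominence-filtered peaks above the area midline, separated by
  at least half the dominant FFT period). A boundary sample that is a
  one-sided maximum counts, so a trace starting at full expansion loses no
  leading cycle. Ranges are half-open.
* **Per-cycle minimum surface tension** is read as the minimum *sample* of
  $\gamma$ within the cycle (no sub-sample interpolation): at 10 frames/s
  and 3 s cycles the sampling error is negligible against the 10 mN/m
  threshold.
* **Baseline = the first 5 complete cycles.** QC requires the lowest baseline
  minimum strictly below 5 mN/m and the *mean* baseline compression ratio
  strictly below 0.30; values exactly at a limit fail. Replicates failing QC
  are excluded from the chemical call (but their analyses are retained for
  audit).
* **Inhibition**: minimum surface tension ≥ 10 mN/m for ≥ 3 *consecutive*
  cycles; the onset cycle is the first cycle of the earliest qualifying run.
* **Chemical call**: majority rule over QC-passing replicates — inhibitory
  when at least half are inhibited; discordant sets are flagged. With zero
  QC-passing replicates there is *no call* (an error), not a negative.
* **Inhibitory dose**: flux × onset time (ng/cm²), total mass via the mean
  drop area; not estimable for highly volatile chemicals.

## 4. Two-scenario predictivity

`predictivity_report()` evaluates the binary in vitro call against two
references: GHS acute inhalation classification (categories 3–4 positive) and
clinical signs of respiratory toxicity in rats during exposure or up to 2 h
post-exposure (windows H0/H1/H2; later observations do not score). Raw sign
wordings map onto a six-term lexicon through an editable YAML synonym table
(`inst/extdata/sign_lexicon.yaml`); unmapped wordings are surfaced in the
report, never silently dropped. Metrics keep exact fractions alongside
two-decimal values rounded half-up (base R's `round()` rounds half to even);
zero-denominator metrics are reported as undefined with a note. Wilson score
intervals are available via `conf_level`.

`generate_outcome_dataset()` builds datasets whose 2×2 margins are exact by
construction, so metric code can be tested against hand-computable fractions;
`make_table1_fixture()` pins the 26-chemical benchmark margins (GHS scenario
10/5/8/3, clinical scenario 17/4/1/4).

```{r table1}
report <- predictivity_report(make_table1_fixture(seed = 1))
report$clinical$metrics[, c("metric", "fraction", "rounded")]
```
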