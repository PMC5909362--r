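---
title: "Methods: the average absorbed breast dose model and its calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the average absorbed breast dose model and its calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammodose)
```

## The dose model

Mammography quality assurance reports the average glandular dose (AGD), but
AGD cannot be computed from acquisition parameters alone: it requires the
measured half value layer and Monte-Carlo conversion factors looked up in
published tables. The quantity this package computes, the *average absorbed
breast dose* (2ABD), is a physically simpler index that needs only what the
unit itself records for every exposure.

The compressed breast is modelled as a homogeneous slab of water-equivalent
soft tissue of thickness $d$ (cm). The incident air kerma $k_{a,i}$ at its
upper surface attenuates exponentially with an effective energy absorption
coefficient $\mu_{en}$ (cm$^{-1}$), and 2ABD is the depth average:

$$
2ABD \;=\; \frac{1}{d}\int_0^d k_{a,i}\,e^{-\mu_{en}x}\,dx
      \;=\; \frac{k_{a,i}}{\mu_{en} d}\left(1 - e^{-\mu_{en} d}\right).
$$

The kerma itself is modelled from calibration constants. Over the tube
voltages used clinically (22–34 kVp) the output per unit tube load is
linear in kVp, so

$$
k_{a,i} \;=\; \frac{Y_{tb}}{Y_0}\,(\alpha\,kVp + \beta)\; mAs
        \left(\frac{FID}{FID-d}\right)^{2},
$$

where $\alpha,\beta$ are fitted on a reference tube whose yield at the
reference voltage (28 kVp by default) is $Y_0$, $Y_{tb}$ is the clinical
tube's yield at the same voltage (from routine quality controls), $FID$ is
the fixed focus-to-image distance and the last factor scales output from
the image plane to the breast entrance surface, a distance $d$ closer to
the focus. Both yields are defined in identical geometry, so only their
ratio enters.

Assumptions worth keeping in mind: the slab is homogeneous (no glandularity
or breast-density correction — by design, since density estimation is
itself a major source of AGD uncertainty), backscatter is excluded, and
whatever the compression paddle absorbs is folded into the calibration,
which was measured with the paddle in the beam.

## Calibration

Three procedures produce the constants, mirroring a physicist's bench
workflow:

* **Kerma line** (`fit_kerma_line`): ordinary least squares of
  $k_{a,i}/mAs$ against kVp on zero-thickness measurements. Replicate
  readings at the same (kVp, mAs) cell are averaged before fitting
  (`averaging = "replicates_first"`), the way repeated meter readings are
  normally treated; pooled fitting is available. The fit is unweighted —
  no per-point sigmas are assumed. Fit standard errors and the
  $\alpha$–$\beta$ covariance feed the uncertainty budget.
* **Attenuation** (`fit_attenuation`): $I(x) = I_0 e^{-\mu_{en}x}$ through
  0–5.5 cm of solid water. The default estimator is nonlinear least
  squares in intensity space (Levenberg–Marquardt, started from the
  log-linear closed form), which is the natural choice under additive
  detector noise; a log-space OLS mode is kept as a fast diagnostic. The
  two estimators coincide in the mean but individual noisy draws can
  disagree by more than their formal errors, because they weight the
  low-intensity deep points differently — this is why `r_squared` is
  always reported in intensity space.
* **Yields** (`tube_yield`): replicate mean of kerma/mAs at the reference
  kVp; the sample standard deviation is the yield sigma.

$\mu_{en}$ falls slowly with kVp (harder spectra penetrate better), but
over the clinical range the variation is small, so the default dose mode
uses the per-combination *average* coefficient; `mu_en_mode = "per_kvp"`
switches to linear interpolation in kVp (clamped at the table ends) when
the calibration carries a per-kVp table. The average's sigma is taken as
the larger of the spread of the per-kVp values and their mean fit sigma,
so neither source of uncertainty is understated — the exact rule behind
published per-combination sigmas is not standardised, and this choice is
documented rather than asserted as canonical.

The bundled calibration set (`default_calibrations()`) covers five
anode-filter combinations (Mo-Mo, Mo-Rh, Rh-Rh on a GE Senographe DS
reference tube; W-Rh, W-Ag on a Hologic Selenia Dimensions). A self-check
is worth knowing about: $\alpha\cdot 28 + \beta$ and the measured $Y_0$
estimate the same quantity by different routes. For the bundled constants
they agree to 0.7% (Mo-Mo) and 1.8% (Rh-Rh) but differ by 3.1% (W-Ag),
5.6% (Mo-Rh) and 6.8% (W-Rh) — `calibration_self_check()` reports the
discrepancy, and the dose model deliberately uses the *measured* $Y_0$ in
the yield ratio rather than the line value, because the two are distinct
measurements and the ratio $Y_{tb}/Y_0$ is what the derivation defines.

## Uncertainty

`propagate_2abd()` uses the first-order delta method with analytic partial
derivatives with respect to the eight inputs $\alpha, \beta, Y_0, Y_{tb},
kVp, d, FID, \mu_{en}$, summed in quadrature, with an optional
$\alpha$–$\beta$ covariance cross-term (off by default; fitted slope and
intercept are anticorrelated, so including it shrinks the total).
Because the model is a product of terms, every partial is the dose times a
logarithmic sensitivity, and the absolute sigma scales linearly with the
dose. `finite_difference_check()` rebuilds all partials by central
differences (relative step $10^{-5}$) and is asserted against the analytic
forms in the tests at $10^{-4}$.

Default budget: thickness $\sigma_d = 0.5$ cm (the tolerance quoted in
device technical manuals — thickness is by far the dominant term for thin
breasts), calibration and yield sigmas from the fits, and kVp, mAs and FID
treated as exact set-points. With these defaults the relative 2ABD
uncertainty across the bundled reference-unit audit cohort comes out at
10–15%. That is below the 17–33% band quoted in audit practice for this
index; reproducing that band would require per-input sigmas (notably for
kVp and $Y_{tb}$) that are not published, so the band check in the test
suite is a plausibility probe and is expected to flag the difference
rather than be forced to pass by inflating sigmas.

Reference AGD values carry the conventional flat 20% relative sigma
(`agd_sigma()`); no coverage factor is applied anywhere — all reported
uncertainties are 1$\sigma$.

## Reference AGD and comparison

`dance_agd()` ($k_{a,i}\,g\,c\,s$) and `wu_agd()` ($k_{a,i}\,D_{gN}$)
evaluate the two table-based reference formalisms. The published
coefficient tables are third-party material and are *not* shipped; the
package defines the grid contract instead: rectangular (HVL, thickness)
grids, bilinear interpolation, exact at nodes, out-of-grid queries error
unless clamping is explicitly enabled (then they clamp to the edge with a
warning). The Dance $c$ factor is stratified by age group (40–49 / 50–64,
a glandularity proxy); ages outside both ranges map to the nearest group
with a warning, and an explicit glandularity overrides age when the table
is glandularity-binned. `compare_doses()` augments a dose report with both
AGDs and an overlap flag, $|2ABD - AGD| \le \sigma_{2ABD} + \sigma_{AGD}$.
Small synthetic example grids (clearly named `synthetic_*`) ship only so
the machinery can be exercised end-to-end.

## Synthetic data

The generators in `generate_kerma_calibration()`,
`generate_attenuation_series()` and `generate_exam_cohort()` emulate the
calibration bench and a clinical audit: kVp 22–34 and mAs 10–100 grids
with five replicates per cell, transmission series over 0–5.5 cm, and
cohorts spanning kVp 25–30, mAs 18–114, thickness 2–7 cm. Measurement
noise defaults to 1% multiplicative Gaussian — the repeatability scale of
solid-state dosemeters, consistent with the ~1% relative spread of the
bundled yield replicates — with a resampling guard keeping intensities
positive. Everything is deterministic given its seed.

What passing on synthetic data shows — and what it does not: the
generators draw from the *same* linear and exponential forms the fitters
assume, so recovery tests validate the estimation and propagation
machinery, not the physical adequacy of those forms. Spectral hardening
with depth, scatter, heel effect and detector energy response are all
outside the generating model; on real measurements they are absorbed into
the fitted effective constants, which is precisely why the constants are
effective rather than fundamental quantities.

## Numerical choices

* The attenuation factor $(1-e^{-u})/u$ switches to the series
  $1 - u/2 + u^2/6$ below $u = 10^{-6}$, avoiding cancellation; both
  branches agree to $1.6\times10^{-11}$ at the switch and the truncation
  error of the series there is $\sim u^3/24 \approx 4\times10^{-20}$.
* $d = 0$ returns 2ABD $= k_{a,i}$ exactly (thin-breast limit), and
  $d \ge FID$ is a hard geometric error.
* kVp outside the calibrated range warns and proceeds: the linearity claim
  is only validated inside 22–34 kVp, and extrapolation is the user's
  informed choice.
* Presentation rounding (0.1 mGy, the precision of clinical dose tables)
  is applied only at serialization; machine-readable output keeps full
  precision.
* Per-exam failures in batch workflows never abort the batch; errors are
  collected per row (audit runs must degrade gracefully).

## Problem sizes in the test suite

Stochastic checks use 100 seeded attenuation series (12 depths each) and
200 seeded kerma-line designs (13 kVp levels × 3 replicates), with 50-seed
properties for estimator agreement and a 20 000-draw Monte-Carlo
cross-check of the delta method. These sizes put Monte-Carlo error well
below the asserted tolerances while keeping the whole suite in the
tens-of-seconds range.

## Known limitations

* No breast-density/glandularity correction inside 2ABD — a deliberate
  modelling decision, not an omission; the index trades that refinement
  for being computable from recorded parameters alone.
* W-anode validation against the reference audit cohort is limited because
  the Hologic unit's FID is not part of the bundled registry; its exams
  are ingested but error at dose computation until the user registers the
  device.
* DICOM support is header-only, explicit VR little endian, top-level
  elements: enough for the exposure attributes mammography units write,
  not a general DICOM implementation. Files with other transfer syntaxes
  are rejected with a clear error.
* HVL is an input, never computed; s-factors are flat per-combination
  scalars.
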