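---
title: "Quality control of hyperspectral aquatic reflectance: methods and design"
author: "gloriaqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control of hyperspectral aquatic reflectance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gloriaqc)
```

## The problem

Remote sensing reflectance, \(R_{rs}(\lambda) = L_w(\lambda)/E_s(\lambda)\)
(sr\(^{-1}\)), is the central quantity of optical water-quality remote
sensing: the water-leaving radiance just above the surface normalized by
the above-water downwelling irradiance. Community collections of in situ
\(R_{rs}\) from lakes, estuaries, rivers and coastal waters are assembled
from dozens of instruments, viewing setups and processing chains, and a
minority of spectra carry characteristic measurement artifacts:

* **high-frequency noise** at the spectral extremes, where detector
  sensitivity and signal are both low;
* **additive baseline shifts** (up or down), typically from over- or
  under-subtraction of surface-reflected sky light ("glint");
* a residual **oxygen A-band feature near 762 nm**, the imprint of
  atmospheric absorption that survives when the radiance and irradiance
  channels are imperfectly intercalibrated;
* spurious **negative slopes in the ultraviolet--blue**, typically from
  suboptimal diffuse sky radiance correction;
* spectral shapes that are simply **atypical for natural waters**,
  captured statistically by the QWIP score.

`gloriaqc` implements the procedural screening pipeline for such
collections in the GLORIA multi-file CSV layout: each spectrum receives a
set of binary flags (1 = issue detected, 0 = clean, empty = not
determinable from the available wavelength range), and the data are kept,
not deleted — flags advise the user, they never censor.

## Data model

Spectra live on an integer 1 nm wavelength grid within 350–900 nm.
A `SpectraSet` (an extension of `SummarizedExperiment`) holds one
radiometric quantity for many samples: wavelengths in rows, samples in
columns, `NA` for wavelengths an instrument did not cover. Some archived
spectra legitimately span only 400–750 nm; every flag whose window is not
fully covered (every integer wavelength present and non-missing) returns
`NA` rather than a guess. No operation extrapolates.

## Reflectance assembly

Two assembly routes are provided. When water-leaving radiance was measured
directly, \(R_{rs} = L_w/E_s\) pointwise, with non-positive \(E_s\)
mapped to missing under a warning. When the upwelling radiance was
measured above the surface at an angle (\(L_t\)), it contains reflected
sky light, and \(R_{rs} = (L_t - \rho\,L_{sky})/E_s\) with the
conventional flat-sea surface reflectance factor \(\rho = 0.028\)
(configurable). Wind- or geometry-dependent \(\rho\) models and in-water
profile extrapolation are out of scope; the glint-corrected route is a
convenience for working with component tables and takes no part in the
flag suite.

## The flag suite

Four flags operate on the **standardized** spectrum — centred to zero
mean and scaled to unit sample standard deviation (denominator
\(n - 1\)) over its full non-missing extent — which makes them invariant
to the enormous dynamic range of \(R_{rs}\) magnitudes across water
types:

| Flag | Test | Threshold |
|------|------|-----------|
| `Noisy_red` | RMSE of a 4th-order polynomial fit, 750–900 nm | > 0.2 |
| `Noisy_blue` | RMSE of a 4th-order polynomial fit, 350–400 nm | > 0.15 |
| `Oxygen_signal` | oxygen peak height (below) | > 0.1 |
| `Negative_uv_slope` | slope of a line fit, 350–420 nm | < −0.005 nm\(^{-1}\) |

All thresholds are strict inequalities, exactly as distributed. RMSE uses
denominator \(n\) (the number of fitted points), not \(n - p\): the
metric is the plain root-mean-square of residuals. Fits are ordinary
least squares on a centred wavelength axis (for conditioning of the
quartic basis); windows are inclusive on both bounds.

Standardization over the full spectrum rather than per window is a
deliberate choice: the windowed tests are defined against "the
standardized spectrum", and a single standardization keeps the four flags
mutually consistent. A constant (zero-variance) spectrum cannot be
standardized; all four flags then return `NA`.

`Baseline_shift` is different: it works on the **raw** values in
sr\(^{-1}\), because two of its criteria are inherently absolute — the
sign of \(R_{rs}\) and a slope threshold printed in sr\(^{-1}\)
nm\(^{-1}\). A spectrum is *shifted up* when its minimum exceeds 60% of
its median (computed over the full non-missing extent; a healthy spectrum
has near-zero ultraviolet or near-infrared values far below its median).
It is *shifted down* when at least 20 values are negative (counted over
whatever extent exists) and either the 765–900 nm line slope is below
\(-8.75\times10^{-7}\) sr\(^{-1}\) nm\(^{-1}\) with more than half of
that window negative, or more than 70% of that window is negative, or at
least 20 negative values fall within 350–450 nm. The flag is `NA` only
when neither branch is determinable (non-positive median and no covered
down-shift window).

`QWIP_fail` flags spectra whose QWIP score (below) exceeds 0.2 in
magnitude. `Suspect` is an expert-elicitation label carried through from
an existing flag file; it is never computed. `Flagged` aggregates: 1 if
any component (including `Suspect`) is 1; 0 if none is 1 and at least one
is determinable; `NA` only if every component is `NA` — an undeterminable
component never asserts presence.

## Ancillary metrics

**Oxygen peak height.** The standardized spectrum is compared against a
local linear baseline anchored at 750 and 780 nm, the ordinates being the
medians of the standardized values over 745–755 and 775–785 nm. The
height is the maximum absolute deviation from that line within a search
window near the A-band. Two details are under-determined by the method's
published description and were fixed here once: the anchor abscissae are
the midpoints of the median windows (the symmetric choice), and the
search window is 759–766 nm inclusive — wide enough to bracket the band,
clear of both anchor windows — and is exposed as an argument for anyone
wishing to match other conventions.

**AVW** (apparent visible wavelength) is the reflectance-weighted
harmonic mean wavelength over 400–700 nm,
\(\sum R_{rs}(\lambda) / \sum (R_{rs}(\lambda)/\lambda)\), on the 1 nm
grid. **NDI** is the normalized difference
\((R_{rs}(665) - R_{rs}(492)) / (R_{rs}(665) + R_{rs}(492))\) read at the
exact grid wavelengths. The **QWIP score** is NDI minus the value a
4th-order polynomial in AVW predicts; the coefficients are transcribed
from the QWIP publication (Dierssen et al. 2022, Frontiers in Remote
Sensing 3:869611) and exposed via `qwipCoefficients()`. All three are
invariant to positive scaling of the spectrum.

**Chromaticity.** Tristimulus integration of \(R_{rs}\) against the CIE
1931 2° observer over 400–700 nm. The observer functions are evaluated
from the published multi-lobe piecewise-Gaussian analytic representation
(Wyman, Sloan & Shirley 2013, JCGT 2(2)), and each is normalized to unit
sum over the window (equal-energy normalization), so a spectrally flat
spectrum lands exactly on the white point (1/3, 1/3). The hue angle is
measured at the white point. Chromaticity here supports qualitative color
typing — sector of the diagram, hue ordering — not colorimetric-grade
rendering.

**Optical water typing** is nearest-centroid classification against
user-supplied centroid spectra (e.g., the 13 inland/coastal types of
Spyrakos et al. 2018), by spectral angle on area-normalized spectra by
default (correlation and Euclidean alternatives provided), with ties
resolved to the lowest class index. The classifier is pluggable because
no single assignment rule is canonical for these typologies; centroids
are data, not constants of this package.

## Water-quality screening

Chlorophyll a, TSS, a\(_{CDOM}\)(440) and Secchi depth span four to six
orders of magnitude across waters and are approximately log-normal, so
the outlier screen works on log10-transformed values (a raw-value mode is
available), stratified by the contributed `Water_type` classification.
Entries further than `k = 3` sample standard deviations from their group
mean are flagged for re-evaluation. Non-positive values cannot be
log-transformed and are reported as data errors, excluded from group
statistics. Groups smaller than 2, or with zero dispersion, yield `NA`.

One property deserves emphasis: in small groups an extreme outlier
inflates the sample standard deviation it is judged against. In a group
of ten with nine identical values, even a six-orders-of-magnitude outlier
reaches only \(z \approx 2.85\) and passes a \(k = 3\) screen. The screen
is therefore trustworthy for the group sizes of a large collection
(dozens to hundreds per water type) and deliberately conservative below
that; the test suite freezes both sides of this behaviour.

## The synthetic generator

The generator exists so that every flag and metric can be validated
end-to-end without downloading the archive. It emulates the archive's
format and failure modes, not its radiative-transfer physics.

**Base spectra** are smooth, strictly positive shapes on the full
350–900 nm grid: an ultraviolet shoulder, a main visible peak drawn from
450–620 nm (magnitude 0.002–0.02 sr\(^{-1}\) log-uniform, width
50–85 nm), a broad secondary red component, a sigmoid near-infrared
roll-off and a positive floor. Every candidate is self-checked against
the five procedural flags *with margin* (fit RMSEs at most half their
thresholds, oxygen height ≤ 0.05, UV slope ≥ −0.0025, minimum/median
≤ 0.45) and redrawn on failure, so the injected artifact alone controls
the expected outcome.

**Artifacts** are sized decisively — far enough from each threshold that
the expected flag is provable from the construction; near-threshold
amplitudes are refused with an error, because threshold tests are
implementation-sensitive exactly where this package must not be. The
noise artifacts use a bounded alternating-sign waveform (±10% amplitude
jitter) rather than Gaussian noise: alternating deviations are nearly
orthogonal to a 4th-order polynomial (an amplitude of \(s\) yields a
window RMSE of ≈ \(0.85s\) to \(s\)), and the alternation guarantees at
most every other point can go negative, which provably keeps every
negative-count branch of the baseline test off. Red noise is injected
over 790–900 nm only, clear of the oxygen-band support. Baseline offsets
and the UV tilt are additive in raw units and therefore provably
invisible to the standardization-based flags. Ground truth covers the
five procedural flags; `QWIP_fail` is computed but not asserted, because
additive artifacts couple to AVW and NDI in ways that are not decidable
by construction.

**Metadata** follow the distributed layout: water types drawn uniformly
over the six optical classes, water-body types at the archive's
lake-dominated proportions, and water-quality values drawn log-normally
with water-type-specific parameters, truncated at ±2 true standard
deviations. Planted outliers sit at exactly 4 true standard deviations,
at most one per water-type group and variable, so the outlier's own
inflation of the sample standard deviation stays bounded and a \(k = 3\)
screen recovers all of them at the default scale.

**Scale.** The default configuration — and the scale at which the
end-to-end suite runs — is 500 spectra with an artifact mix of 50% clean
and 10% of each artifact class, seed 20230216. At this scale the flag
suite reproduces the construction ground truth with 100% agreement and
the screen recovers every planted outlier; a full round trip takes a few
seconds. What passing proves is that the decision logic implements its
definitions exactly — thresholds, windows, units, missing-data semantics.
What it cannot prove is performance on real measurement error: real
noise is not alternating, real glint residuals are not constant offsets,
and real spectra carry several small defects at once. Near-threshold
behaviour on real data is governed by the archive itself, which is why
the archive validation entry point exists.

## Archive validation

`validateArchive()` points at a locally downloaded copy of the
distribution, recomputes the dataset cardinalities (spectra, water
bodies, lake share, samples with complete above-water radiometry), reruns
the full flag suite with the distributed `Suspect` column, and reports
recomputed and distributed per-flag counts side by side with their
differences. Exact count reproduction depends on conventions the
distribution's description leaves open (standardization extent, the
oxygen search window width, the negative-count extent for short spectra);
this package's choices are recorded above, and the discrepancy report
identifies which flags disagree so each choice can be audited against the
archived code.

## Numerical choices and degenerate inputs

* Polynomial fits: OLS via `stats::lm` on a centred raw-power basis;
  residual orthogonality is property-tested.
* RMSE denominator \(n\); sample standard deviation denominator
  \(n - 1\); medians are the standard sample medians.
* All flag thresholds strict; ties in water-type assignment impossible by
  construction; ties in OWT distance resolve to the lowest class index.
* Zero variance, uncovered windows, non-positive AVW denominators,
  zero NDI denominators: `NA`, never an error, inside the flag suite.
* CSV output prints up to 10 significant digits, which round-trips
  single-precision source data losslessly; missing values are empty
  cells.

## Limitations

* The `Suspect` flag cannot be computed — it encodes expert judgment —
  and is only carried through from existing files.
* The 3C-model reconstruction used for uncertainty analysis of
  above-water measurements is an external algorithm and out of scope.
* Chromaticity uses an analytic observer approximation adequate for
  color typing, not for colorimetric standards work.
* The synthetic generator validates decision logic, not retrieval
  accuracy on natural spectra; its artifacts are idealized by design.
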