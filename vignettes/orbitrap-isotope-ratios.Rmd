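---
title: "Ion-count isotope ratios from Orbitrap S/N: model, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ion-count isotope ratios from Orbitrap S/N: model, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbiso)
```

## The measurement problem

Orbitrap detectors do not count ions; they report, per centroid peak, a
signal intensity S and a baseline noise estimate N. For ratio work the
quantity that carries the statistics is the number of ions behind each peak,
because a ratio of two Poisson-counted populations has a hard precision
floor set by those counts. `orbiso` implements the standard conversion

$$\text{ion count} = \frac{S}{N}\, c\, \sqrt{\frac{R_n}{r}}\ \mu$$

where $c$ is an empirical calibration constant, $r$ the resolution setting
of the acquisition, $R_n = 240{,}000$ the reference resolution at which
$c = 3$ was calibrated (with $c = 4.4$ selectable for small organic acids),
and $\mu$ the number of co-added microscans. Because both isotopologues of
an analyte are acquired in the same scan under identical settings, every
factor except S/N cancels in the ratio:

$$^{13}R = \frac{S_{13}/N_{13}}{S_{12}/N_{12}}$$

This cancellation is load-bearing: the package never claims absolute ion
numbers (the constant $c$ is unverifiable downstream), only ratios and
their counting statistics. `ion_count_series()` enforces the identity
exactly — a property test asserts agreement between the S/N ratio and the
ion-count ratio to 1e-12 across random model constants.

## Delta values and drift correction

Delta values are reported against an in-run reference:
$\delta^{13}\mathrm{C} = (R_{sample}/R_{STD} - 1)\times 1000$ ‰. The
supported acquisition design is bracketed alternation — the canonical
template is seven blocks, standards at odd positions (1, 3, 5, 7), samples
at even positions (2, 4, 6). Instead of simple bracketing, an unweighted
ordinary least-squares line through the standard-block mean ratios versus
block position predicts the reference ratio at each sample block
(`drift_fit()`, `predict_reference()`). The final δ¹³C is the arithmetic
mean of the sample-block deltas; their n−1 standard deviation is the
reproducibility error (undefined, not zero, with a single sample block).

Two design choices here were genuinely open:

- **Regressor.** Block index and block mean acquisition time are both
  defensible; drift is physical in time, so time is the default whenever
  block start times are known (`t0` on the acquisition), with index as the
  fallback. For equally spaced blocks the two are affine-equivalent and
  give identical deltas, which a test asserts.
- **Weighting.** The canonical design has four standard points; weighted
  regression with four points is noise-chasing, so the fit is unweighted.

With exact linear drift the correction is exact (tested in the noise-free
case), and removing a common linear-in-position factor leaves δ unchanged
to first order up to 1% drift amplitude.

## Aggregation and error statistics

The per-acquisition aggregate ratio is the **ratio of summed ion counts**
over retained scans. Count-weighting is the minimum-variance estimator for
Poisson data and is robust to scans with few ions; the unweighted mean of
per-scan ratios is reported alongside (`ratio_scan_mean`) since neither
choice is canonical in the field. The acquisition error is the relative
standard error of the *per-scan* ratio series,
$1000\, \mathrm{sd}(R)/(\bar R \sqrt n)$ ‰ — per-scan rather than
block-sub-mean, documented as such.

The shot-noise limit uses the standard two-Poisson form
$1000\sqrt{1/\Sigma N_{13} + 1/\Sigma N_{12}}$ ‰. This formula is adopted
from counting statistics (it is not derivable from the processing chain
itself) and the quotient acquisition error / shot-noise limit is the
package's central health metric: ≈1 means the measurement is
statistics-limited; persistently >1 indicates excess variance from
suppression, AGC loss or space charge.

## Filtering rules

- **Time window.** Direct-infusion runs include a solvent front and a final
  flush; the default cull keeps the closed interval 2–8 min. Closedness is
  a choice ("between 2 and 8 min" does not state openness); boundary scans
  are included because silent exclusion is the more surprising behavior.
  The window is fully configurable since run lengths vary.
- **Peak matching.** Nearest-by-m/z within tolerance, default 5 ppm
  (per-target overridable in ppm or Da; no tolerance is stated by the
  upstream method, 5 ppm is a conventional high-resolution choice). Absence
  of a match is a value (`no_match` mask), not an error.
- **Outlier rejection.** Single pass, median ± k·1.4826·MAD on the
  per-scan ratio, default k = 5, requiring ≥5 usable scans. The rule is a
  design decision (outlier rejection is named upstream but unspecified);
  it is switchable (`k = Inf`) and the degenerate MAD = 0 case falls back
  to exact-median retention with a warning rather than rejecting
  everything.
- **Injection-time ceiling.** Scans within 0.1 ms of the IT ceiling
  (default 100 ms) are *flagged*, not dropped — at the ceiling the AGC loop
  is open and the scan is diagnostic of starvation; dropping is an explicit
  option.

## Diagnostics

TIC×IT approximates the charge delivered per fill and should sit at the AGC
target under control. Scans are classified `controlled` within
[0.7, 1.3]×target (thresholds are heuristic decisions, configurable),
`sub_target` below or at the IT ceiling, `over_target` above.
`detect_interference()` hunts undeclared ions inside the isolation window,
clusters them at the match tolerance (direct-infusion centroids are
stable), and scales them against the analyte selected-ion current — not the
TIC — with warn/fail thresholds of 1%/10%. The 10% threshold is an
empirical heuristic from a carbonate-contaminant case and may not
generalize across species; it is configurable and documented as such.

## The simulator: what it emulates, and what a green test proves

`sim_config()`/`simulate_acquisition()` generate scans from mechanisms, not
from instrument constants:

- **AGC feedback**: IT = agc_target / total flux, clamped to a floor
  (0.1 ms) and ceiling (100 ms). Total flux too low → ceiling, sub-target
  loads; too high → floor binds and charge overshoots the target.
- **Poisson ion statistics**: per-species counts are Poisson in F·IT·μ,
  split heavy/light binomially at p = R/(1+R).
- **Electrospray suppression**: flux × exp(−k·total concentration),
  default k = 0.05 /µM. Exponential form is a modeling choice; with the
  default analyte flux of 3.125e8 ions·s⁻¹·µM⁻¹ it reproduces the
  injection-time span of roughly 32 ms at 0.1 µM to 0.8 ms at 50 µM that
  motivates the AGC diagnostics.
- **Drift**: ratio × (1 + drift_rate·t), linear in sequence time.
- **Space charge**: ratio × (1 − β·max(0, Q/target − 1)) — linear in
  excess charge, the simplest monotone form consistent with a "slight but
  systematic" high-load bias; direction and monotonicity are the only
  claims made.
- **Spray noise** (`spray_noise_cv`): lognormal scan-to-scan flux
  fluctuation. AGC absorbs it mid-range; at the ceiling it passes into the
  counts and at the floor it modulates the space-charge bias — which is
  what makes acquisition error U-shaped across concentration when β > 0.
- **Variance inflation**: lognormal per-scan ratio noise sized so ratio
  variance is inflated by the configured factor over shot noise
  (phenomenological stand-in for any unmodeled excess noise).

Defaults mirror the stated acquisition conditions: AGC target 1e6, IT
ceiling 100 ms, resolution 60,000, two microscans, 600 scans at 1 s. The
analyte geometry in `sim_preset()` is a deprotonated C11 acid (m/z
175.0765/176.0798, true ¹³R 0.1214).

What the generator does **not** emulate: peak shapes and centroiding error,
mass drift (centroids sit exactly at the species m/z), vendor noise
estimation (noise is a flat floor), coalescence, chromatography, and real
ESI chemistry. A green zero-enrichment test therefore establishes that the
*processing chain* is unbiased and statistics-limited under the modeled
mechanisms — it says nothing about a physical instrument's constants, and
the headline experimental numbers of any real acquisition (specific
acquisition errors, specific IT values) are deliberately out of reach.

## Numerical and interface choices

- m/z values are never rounded internally; comparisons to printed
  references round to 3 decimals. The computed one-¹³C ion of C11H12O2 is
  176.0798, which rounds to 176.080 against a printed measured centroid of
  176.079 — the package reports the computation, not the print.
- Atomic masses are a versioned built-in table (CODATA/AME-derived, ≥6
  decimals); electron mass 0.00054858 Da is included with the sign of the
  charge (anions gain, cations lose).
- Scan tables are flat UTF-8 CSV (one row per scan/peak, metadata repeated)
  — diff-able and language-neutral; mzML import fills the missing per-peak
  noise by a constant or an in-scan percentile (default p10) and flags the
  acquisition `noise_approximate` because the ion-count model presumes the
  vendor noise estimate.
- CLI configs are JSON rather than YAML: the deployment environment
  guarantees a JSON parser but no YAML parser, and the config surface is
  flat enough that the format is immaterial. Precedence is CLI flag >
  config > default. Identical config + seed gives byte-identical outputs.
- Simulation seeds are mandatory; the global RNG stream is saved and
  restored around simulation so library calls do not perturb user code.

## Known limitations

- Only two-isotopologue (one heavy substitution) ratios are first-class;
  multi-isotope fine structure is out of scope.
- δ values are relative to the in-run standard only; no anchoring to
  international reference scales.
- The mzML reader targets centroided MS1 spectra with 32/64-bit float
  arrays (zlib or none); exotic encodings are not supported.
- The suppression, space-charge and spray-noise forms are phenomenological;
  they reproduce directions and shapes, not instrument-specific magnitudes.
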