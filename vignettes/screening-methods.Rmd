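---
title: "Screening veterinary antibiotics from SERS spectra with MCR-ALS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening veterinary antibiotics from SERS spectra with MCR-ALS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersmcr)
```

## The screening problem

Surface-enhanced Raman spectroscopy (SERS) on silver nanorod substrates
amplifies the vibrational fingerprint of trace analytes enough to see
veterinary antibiotics — enrofloxacin, oxytetracycline, neomycin — at ppm
levels in water. In pig urine the same bands drown in the autofluorescence
and organic-band background of the matrix, and single spectra become
uninformative below very high concentrations. The remedy is chemometric:
pool many spectra and factorize the data matrix

$$D \approx C\,S + E, \qquad C \ge 0,\; S \ge 0,$$

where the rows of $S$ are component spectra (analyte, fluorescence,
substrate background, matrix bands) and the rows of $C$ are per-sample
contributions. This package implements the whole analysis: a seeded
synthetic spectrum generator standing in for real measurements, the
multivariate curve resolution solver by alternating non-negative least
squares (MCR-ALS), reference-guided component assignment, characteristic
peak calling, and limit-of-detection (LOD) / maximum-residue-limit (MRL)
reporting.

## The synthetic data generator

The generator is first-class, tested code; it defines the experimental conditions
under which everything else is validated.

A spectrum is simulated as

```
response_coeff * response_factor * g(conc) * reference
  + fluorescence (broad Gaussians, per-sample log-normal amplitude jitter)
  + organics comb (medium-width bands, one shared per-sample scale factor)
  + matrix bands (urea region, substrate carbon bands)
  + linear baseline + i.i.d. Gaussian channel noise
```

with `g(c) = c / (1 + c / c_sat)` a Langmuir-saturating response
(`c_sat = 2000` ppm, so the 10,000 ppm spiking level sits in the
supra-linear regime). Reference spectra are sums of Lorentzian bands
(fwhm 12 cm⁻¹, a typical solid-state linewidth) on a 400–1800 cm⁻¹ grid in
2 cm⁻¹ steps, normalized to unit maximum. Band positions follow the published standard spectra of the three drugs: enrofloxacin 752, 803, 835, 1252,
1390, 1552, 1624 cm⁻¹ (identified by 1390/1624; 1387 is a literature alias
of the 1390 band), oxytetracycline 803, 835, 1170, 1254, 1315, 1620 cm⁻¹
(identified by 1315/1620), neomycin's single dominant band at 977 cm⁻¹.
Relative amplitudes are not printed anywhere, so the package fixes a
prominence ordering: primary identification band 1.0, secondary 0.95
(slightly below 1 so the dominant band is unambiguous even after sampling
on the 2 cm⁻¹ grid), other bands 0.5, and the 803/835 cm⁻¹ bands shared by
enrofloxacin and oxytetracycline 0.3.

Three packaged designs (`scenario_design()`) emulate the platform's measurement campaigns:

* **Water dilution** — ten blanks, ten concentrations (0.01–100 ppm) with
  four replicates each, nine standard spectra: 59 spectra in total. Only the total is fixed;
  the split is the package's own design, chosen to give the
  blank-based detection null a reasonable sample size.
* **Spiked urine** — 10, 20, 50, 100, 10,000 ppm with 50 replicates per
  level (250 spiked spectra) plus ten control-urine blanks and four
  standards.
* **In vivo** — control (13), day 1 (20), day 7 (20): 53 spectra. Day 7
  carries a 3× effective analyte level (consecutive dosing) and a doubled
  urea-region band at 1000 cm⁻¹.

Determinism is strict: per-spectrum seeds derive from the design seed and
the row index, so a design reproduces its dataset byte-for-byte.

### Calibration of the matrix models

The platform's detection limits are empirical instrument results; they
cannot be derived from first principles. The matrix models are therefore
calibrated once so that the *procedures* reproduce the empirical limits,
and then frozen; all regression tests run against these constants.

* **Water**: channel noise 0.02 a.u., response 0.4 a.u./ppm for
  enrofloxacin, with per-analyte response factors 0.12 (oxytetracycline)
  and 0.0023625 (neomycin). The nominal identification-band
  signal-to-noise ratio at the empirical water LODs is then 10
  (enrofloxacin, 0.5 ppm), ≈4.8 (oxytetracycline, 2 ppm) and 4.5
  (neomycin, 100 ppm), and 2 at 0.1 ppm of enrofloxacin — the single-spectrum
  call threshold (SNR ≥ 3) is crossed between 0.1 and 0.5 ppm. The margins
  look generous, but they are consumed by the mechanics of the measurement:
  the peak height is a maximum over a ±8 cm⁻¹ window (a positive-biased,
  unit-spread statistic), the noise is a MAD estimate, the univariate rule
  demands *every* replicate, and the unmixing null costs three blank
  standard deviations. Tighter calibrations flip LODs to neighbouring
  dilution steps on a large fraction of seeds.
* **Urine**: channel noise 0.05 a.u., response 0.02 a.u./ppm, two strong
  fluorescence humps (8 and 5 a.u., log-normal jitter), and an organics
  comb — ten medium-width bands that rise and fall together with one
  per-sample organic-load factor. The comb is the masking mechanism: its
  residual survives stiff baseline subtraction and inflates the robust
  noise floor, so single-spectrum identification fails up to 100 ppm and
  only the saturating 10,000 ppm level shows bands; at the same time the
  comb is exactly rank one, so the pooled factorization separates it
  cleanly and recovers 10 ppm.

What the generator does *not* emulate: heteroscedastic (shot-noise)
behaviour, wavenumber miscalibration and peak shifts between samples,
substrate-to-substrate enhancement drift beyond a scalar amplitude, and
real urine chemistry (the organics comb is a stand-in pattern, not a urine
library). Passing tests therefore demonstrate that the *algorithms* behave
as described under the stated statistical structure, not that the platform
would achieve these limits on new real-world samples.

## Preprocessing

`subtract_baseline()` implements asymmetric least squares: minimize
$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2$ with
$w_i = p$ above the baseline and $1-p$ below (defaults
$\lambda = 10^5$, $p = 0.01$). Two practical details matter:

* An asymmetric baseline runs along the *lower envelope* of the noise
  band, leaving the residual a positive pedestal of random depth;
  `preprocess_dataset(center_offset = TRUE)` removes the per-spectrum
  median. Peak calling measures heights from the median of the signal-free
  region for the same reason.
* The smoother is not exactly idempotent: compact (Gaussian-like) bands
  re-subtract by well under 1 % RMS, but Lorentzian tails and medium-width
  organics structure keep being shaved by a few percent on re-application.

Negative residuals are clipped only where a non-negative data matrix is
required; despiking (`despike_median()`) is available but off by default.

## The solver

`nnls_solve()` is a from-scratch Lawson–Hanson active-set solver on the
normal equations, with two accelerations for the batched use inside ALS:
all right-hand sides first receive the unconstrained solution from a single
factorization (feasible columns are done), and passive-set Cholesky factors
are cached per pattern within a call. Rank-deficient passive sets fall back
to a tiny ridge and flag the result. The unit tests compare it against an
exhaustive active-set enumeration oracle.

`mcr_fit()` alternates exact constrained half-steps (`C` given `S`, `S`
given `C`) and records the lack of fit
$100\,\lVert D - CS\rVert_F / \lVert D\rVert_F$ after every iteration;
because each half-step is an exact minimizer, the sequence is
non-increasing. Convergence is declared when the relative change drops
below `tol` (default $10^{-6}$; the solver default of 500 iterations is
plenty for small problems, while the packaged pooled-urine runs use 2000
because they need roughly 900–1700). The scale ambiguity is fixed by
normalizing each spectral row to unit maximum and folding the factor into
`C`. Initialization seeds any supplied reference spectra and fills the
remaining components by SIMPLISMA-style pure-variable selection on the
residual left after deflating the references, so free components start as
background rather than analyte clones. Seeded components are re-estimated
during the iterations; `ref_weight > 0` adds a soft prior (a ridge pulling
the seeded row toward its reference, scaled by the component's contribution
norm). The prior is off by default — it changes the objective, so the plain
lack-of-fit is then only empirically monotone — and is used by the packaged
in-vivo configuration, where the deliberately small four-component model
underfits the urine background rank and would otherwise let the seeded
component drift off the analyte.

Rotational ambiguity is not explored (no band boundaries); the solver
returns a single solution.

## Detection

**Peak calling** (`call_peaks()`): for each identification band, locate the
local maximum within ±8 cm⁻¹, measure its height above the median of the
signal-free region, and divide by the MAD of that region. Channels within
30 cm⁻¹ of any reference band — and of the platform's known background
bands (urea 1000, substrate 1050/1450 cm⁻¹) — are excluded from the noise
region. A band is found at SNR ≥ 3; an analyte is identified when *all*
its identification bands are found (the single 977 cm⁻¹ band suffices for
neomycin). The thresholds put a number on what an analyst would otherwise judge by
eye.

**Univariate LOD** (`lod_univariate()`): lowest tested concentration whose
replicate detection fraction reaches the rule (default: all replicates).

**Unmixing LOD** (`lod_mcr()`): fit the pooled *raw* spectra. Raw matters:
every background structure (offset, slope, fluorescence, organics, matrix
bands) is non-negative and exactly low-rank in raw form, which is precisely
what a component model can absorb, whereas baseline subtraction is a
nonlinear operation that scatters background energy across many directions.
The analyte component is assigned by cosine similarity to the reference
(threshold 0.7; recovered components typically score > 0.99).

The per-sample analyte intensity is the assigned contribution column after
a *blank-calibrated leakage correction* (`analyte_intensity()`). A bilinear
factorization is rotation-ambiguous exactly along (background overlap ×
analyte): the solver may park part of a background's overlap with the
analyte bands inside the analyte component, where it rises and falls with
the background level. The blanks identify this leakage. Each sample's
background factor levels are estimated by least squares on the analyte-free
channels; the blank contributions are regressed on those factors; the
fitted leakage is subtracted from every sample. Blanks then centre at zero,
and the detection cut is the blank mean plus three
degrees-of-freedom-corrected residual standard deviations. The LOD rule is
the same all-replicate rule as the univariate route. Under the packaged
models this pipeline reproduces the empirical limits — 0.1 ppm in water
(down from 0.5 ppm per-spectrum) and 10 ppm in spiked urine — across the
large majority of seeds; occasional rotation-unlucky fits can shift the
spiked-urine result to a neighbouring level.

**Trend, ordering and screening**: `concentration_trend()` reports
per-level mean intensities and their Spearman rank correlation with the
nominal concentrations (ties via average ranks); `compare_conditions()`
checks the in-vivo ordering day 7 > day 1 > control, flags conditions
closer than two standard errors as not separable, and tests the control
against its own mean + 3 SD cut; `screen_samples()` converts intensities to
estimated concentrations by inverting the saturating response through a
calibration slope fitted to the level means and calls a sample *positive*
at ≥ 1.5× MRL (default MRL 100 ppm for all three drugs), *negative* below
1.25× MRL, and *indeterminate* in the guard band between — the band keeps
measurement dispersion at the MRL itself from flipping compliant samples.

## Numerical choices and degenerate inputs

* NNLS tolerances scale with the Gram diagonal; rank deficiency falls back
  to a ridge of `1e-10 * mean(diag)` and is flagged.
* Non-finite spectra, negative concentrations, non-monotone grids, unknown
  configuration keys and out-of-grid peak windows are rejected with named
  errors; non-convergence returns a result with `converged = FALSE` rather
  than failing.
* All-blank pools and unassigned components report "not reached" with a
  diagnostic instead of a numeric LOD.
* Ties in component matching go to the lower component index; equal
  concentrations in trend analysis use average ranks.

## Problem sizes

The packaged scenario sizes (59 / 264 / 53 spectra on 701 channels) are the
study's own scale, and every regression test runs them directly; a full
three-scenario pipeline pass completes in well under a minute per scenario
on a single core.

## Known limitations

* The empirical LOD regressions are fixture-calibrated: they validate the
  procedures under the packaged noise model, not the instrument.
* The leakage-corrected intensity requires blanks; without them the raw
  contribution column is returned, which is vulnerable to rotational
  ambiguity.
* The spiked-urine unmixing LOD is stochastic at its margin: roughly one
  seed in ten lands a rotation where the corrected blank spread is inflated
  and the reported LOD moves one level up.
* Quantitative concentration prediction (a calibration curve in ppm) is out
  of scope; `screen_samples()` only classifies against the MRL.
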