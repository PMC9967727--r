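# sersmcr

Screening veterinary antibiotic residues — enrofloxacin, oxytetracycline
and neomycin — from surface-enhanced Raman spectra (SERS) of water and pig
urine samples.

On a silver nanorod SERS substrate the vibrational bands of these drugs are
visible at ppm levels in water, but in urine they drown in autofluorescence
and organic matrix bands. The package implements the full chemometric
screening analysis around that problem:

* a seeded **synthetic spectrum generator** emulating the platform's measurement campaigns
  (water dilution series, spiked urine, in-vivo control/day-1/day-7 urine),
* spectrum containers, two-column CSV I/O and asymmetric-least-squares
  **baseline correction**,
* a from-scratch **MCR-ALS solver** — multivariate curve resolution by
  alternating non-negative least squares, factorizing the pooled spectra
  matrix as `D ≈ C Sᵀ + E` with `C, S ≥ 0` — with reference-seeded
  initialization, SIMPLISMA-style pure-variable selection and cosine
  component assignment,
* **detection**: characteristic-peak calling (SNR ≥ 3 at the
  identification bands, e.g. 1390/1624 cm⁻¹ for enrofloxacin), univariate
  and unmixing-based limit-of-detection (LOD) determination against a
  blank null (mean + 3 SD), concentration trends, condition ordering and
  maximum-residue-limit (MRL, 100 ppm) screening calls,
* a **pipeline** (`run_scenario()`, `cmd_simulate()`, `cmd_run()`) plus a
  thin command-line wrapper in `inst/cli/sersmcr.R`.

## Worked example

Simulate the water dilution series (ten blanks, 0.01–100 ppm at four
replicates, nine standards — 59 spectra) and determine the enrofloxacin
LOD both per spectrum and by pooled unmixing:

```r
library(sersmcr)
refs <- antibiotic_references()

ds <- generate_dataset(scenario_design("water_dilution", seed = 1))
ds
#> <spectral_dataset> 59 spectra x 701 channels (400..1800 cm-1)
#>   conditions:  blank (10), c0.01 (4), c0.1 (4), c0.5 (4), c1 (4), c10 (4), ...

lod_univariate(ds, refs$enrofloxacin)
#> <lod_result> enrofloxacin (univariate)
#>  concentration_ppm detection_fraction
#>              1e-02                  0
#>              1e-01                  0
#>              5e-01                  1
#>              ...                  ...
#>   LOD: 0.5 ppm

lod_mcr(ds, refs)
#> <lod_result> enrofloxacin (mcr)
#>  concentration_ppm detection_fraction
#>              1e-02                  0
#>              1e-01                  1
#>              ...                  ...
#>   LOD: 0.1 ppm
```

Per spectrum, the lowest concentration at which both identification bands
still clear the SNR-3 threshold in every replicate is 0.5 ppm. Pooling all
59 spectra, fitting the six-component model and testing each sample's
blank-corrected analyte contribution against the blank null pushes the
limit down to 0.1 ppm; the extracted component matches the enrofloxacin
reference with cosine similarity 0.99999. The spiked-urine scenario
(`scenario_design("spiked_urine")`) reproduces the 10 ppm screening limit
in urine the same way, and the in-vivo scenario orders day-7 > day-1 >
control intensities.

Scenario-level runs:

```r
report <- run_scenario(run_config("spiked_urine", seed = 1))
report
#> <run_report> spiked_urine (seed 1, 6 components, converged)
#>   unmixing LOD:   10 ppm
#>   trend: Spearman rho = 1.000
```

or from a shell:

```sh
Rscript inst/cli/sersmcr.R run --scenario water_dilution --seed 1 --out out/
```

See the methods vignette (`vignettes/screening-methods.Rmd`) for the model,
the calibration of the synthetic matrix models, and the detection
estimator.

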