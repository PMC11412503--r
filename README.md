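# musclet2

T2-distribution biomarkers for muscle MRI in dystrophic mice.

Quantitative T2 mapping sees dystrophic muscle pathology — edema,
inflammation and necrosis all raise the transverse relaxation time — but
the mean muscle T2 is a poor biomarker: lesions occupy a minority of
voxels, so bulk averaging hides them. The informative signal is the
*shape* of the muscle T2 histogram. `musclet2` implements that measurement
as a tested pipeline:

* **Voxelwise monoexponential fitting** of multi-echo spin-echo stacks,
  `S(TE) = S0 · exp(−TE/T2)`, by vectorized bounded Levenberg–Marquardt
  (log-linear initialization, T2 ∈ [1, 1000] ms, bound-hits flagged
  invalid), with a log-linear alternative.
* **Histogram-shape biomarkers** on the 1%-tail-trimmed muscle T2 sample:
  interdecile range `IDR = P90 − P10` (spread / tail magnitude), Pearson
  mode skewness `(mean − mode)/sd` with the mode from a Gaussian KDE
  (Silverman bandwidth), and D'Agostino's K² normality test.
* **Cohort statistics**: Bland–Altman test–retest analysis with minimum
  detectable change (`MDC = 1.96 · sd_diff`), linear regression of a
  membrane-leak (dye-uptake) assay on the imaging metrics, severity
  stratification in the (skew, IDR) plane, and serpentine group balancing
  with a-priori exclusion of extremes.
* **A synthetic ground-truth phantom generator**: hindlimb-like multi-echo
  stacks with healthy muscle (25 ms), diffuse mild lesions (35 ms) and
  focal high-T2 lesions (65 ms) whose areal fractions scale with a
  severity dial, non-muscle confounders (bone, fat rim, bladder), Rician
  noise at a stated first-echo SNR, exact lesion-burden bookkeeping, and
  shared-anatomy test–retest pairs. Every stage of the pipeline is
  validated against it.
* **NIfTI I/O** (minimal self-contained NIfTI-1 reader/writer with JSON
  sidecars for echo times and provenance; bit-exact float64 round trips).

## Worked example

```r
library(musclet2)

acq <- acq_params(matrix_size = c(64, 64), n_slices = 2)   # reduced matrix
ph  <- make_phantom(phantom_spec(seed = 42, severity = 0.6), acq)
map <- fit_map(ph$stack, muscle_mask(ph$truth$mask_true))
summarize_t2(map)
#> T2 distribution: n = 1912 (of 1952 raw)
#>   mean 30.46 ms, sd 10.00 ms, mode 25.48 ms (KDE bw 1.44)
#>   IDR 11.64 ms, Pearson mode skew 0.498
#>   D'Agostino K2 = 1011.1, p = 2.8e-220
ph$truth$lesion_burden
#> [1] 0.311
```

Read: at severity 0.6, 31% of muscle voxels carry elevated T2. The mode
stays near healthy muscle (25 ms) while the mean is pulled up 5 ms — a
positive Pearson skew of 0.50 — and the IDR (11.6 ms) is roughly six times
that of a healthy animal (≈1.9 ms), while the K² test confirms the
distribution is nowhere near Gaussian. A healthy phantom (`severity = 0`)
gives IDR ≈ 1.9 ms and skew ≈ 0; these two numbers stratify the disease
spectrum.

## Analysis workflow

The numbered scripts under `analysis/` run the full study-scale analysis
over the package (each writes tables under `results/`, images under
`scratch/`):

1. `01_simulate_cohort.R` — 36-animal cohort (13 WT, 20 mdxB10, 3 mdxD2).
2. `02_fit_metrics.R` — maps + biomarkers per animal; histogram panel with
   the (failing) Gaussian overlay.
3. `03_stratify.R` — skew-vs-IDR stratification, genotype summaries,
   rank-balanced treatment groups.
4. `04_repeatability.R` — test–retest Bland–Altman and MDC for both
   biomarkers.
5. `05_dye_correlation.R` — dye-surrogate regressions on burden, IDR and
   skew.

## Acceptance script

`scripts/acceptance.R` re-runs the installed package end to end from
scratch: it simulates mild and severe subjects and analyzes them through
the auto-masked pipeline, measures a simulated dye-validation cohort and
its regression, and runs shared-anatomy test–retest pairs through
Bland–Altman, then writes its JSON output:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette
(`vignettes/t2-distribution-biomarkers.Rmd`) documents the signal model,
every default and convention (percentile type, KDE bandwidth, noise model,
MDC formula), what the phantom does and does not emulate, and the known
limitations. Function-level documentation is in the roxygen comments in
`R/`.
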