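# tumortract

Tumor-associated diffusion MRI tractography for glioblastoma, with the
downstream analyses that turn tractograms into prognostic and biological
read-outs — and synthetic generators that make the whole chain testable
without patient data.

Diffusion-weighted MRI resolves the orientation structure of white matter;
around a glioblastoma, coherent "projecting" tracts extend outward from
the tumor mass and may mark routes of microscopic invasion. This package
implements that analysis end to end for researchers in quantitative
neuro-oncology imaging:

* **phantom** — multi-tensor DWI simulation (`phantom_spec()`,
  `simulate_dwi()`) with Rician noise, acquisition presets
  (`human64`: b = 1000 s/mm², 64 directions; `mouse512`: b = 1200 s/mm²,
  512 directions), plus survival-cohort (`simulate_cohort()`) and RNA-seq
  count (`simulate_counts()`) generators with recorded truth.
* **recon** — log-linear tensor fit with FA/MD/AD maps
  (`fit_tensor()`, `tensor_metrics()`), and a generalized q-space
  orientation function with multi-peak extraction and quantitative
  anisotropy (`reconstruct_sdf()`, `extract_peaks()`):
  ψ(û) = Σᵢ Sᵢ · sinc(r · √(6·D₀·bᵢ) · ⟨gᵢ, û⟩).
* **tracking** — deterministic bidirectional Euler streamlining over the
  tri-linearly interpolated peak field (`track_streamline()`,
  `track_all()`), step 0.3 mm, 45° angular threshold, 0–300 mm window.
* **tumortract** — tumor-ROI tract selection (`select_tumor_tracts()`),
  core/shell/projecting classification (`classify_tracts()`), tract
  metrics incl. mean (projecting) tract length and MDF/QuickBundles-style
  projecting-bundle counts (`tract_metrics()`, `count_bundles()`).
* **survstats** — OLS survival regression, Welch t-tests, type-7 quartile
  stratification, Kaplan–Meier curves, and k-sample log-rank tests
  (`survival_by_quartile()` and friends).
* **transcriptome** — CPM filtering, sample clustering, limma-voom
  differential expression with BH FDR and a 2-fold call threshold, and
  exact hypergeometric over-representation of user gene sets
  (`cpm_filter()`, `voom_de()`, `de_call()`, `ora_fisher()`).

File formats: NIfTI-1 volumes (via RNifti), FSL `bvals`/`bvecs`, TrackVis
TRK and MRtrix TCK tractograms, CSV/TSV tables, GMT gene sets.

## Worked example

Three fiber bundles pierce a spherical "tumor" and extend 25 mm beyond it;
the full pipeline — simulate (64 directions, b = 1000 s/mm², SNR 30),
reconstruct, track, select, classify, count — recovers them:

```r
library(tumortract)

res <- run_phantom_pipeline(k_bundles = 3, preset = "human64",
                            snr = 30, seed = 7)
res$metrics
#> tract_metrics: mean TL 79.1 mm; mean projecting TL 79.3 mm; 3 bundles; tumor 11.56 cm^3
#> classes
#>       core      shell projecting
#>          2          0        763
```

The three constructed bundles are counted exactly, essentially every
tumor-intersecting streamline is classified as projecting, and the
11.6 cm³ sphere volume is recovered from the ROI mask. Downstream, a
simulated 66-subject cohort whose hazard rises with mean projecting tract
length shows the expected outcome association, and a simulated count
matrix with 2-fold tract-group effects yields a differential-expression
call set:

```r
co <- simulate_cohort(66, seed = 7)
sv <- survival_by_quartile(co, "mean_projecting_tract_length")
sv$logrank
#> log-rank chi2 = 16.17 (df 3), p = 0.0010
sv$ols$beta
#> -7.77           # days of survival per mm of projecting tract length

cm  <- simulate_counts(3000, de_fraction = 0.15, fold_change = 2,
                       dispersion = 0.05, seed = 7)
de  <- voom_de(cpm_filter(cm, min_cpm = 1, min_samples = 2))
nrow(de_call(de, fc_threshold = 2, q_threshold = 0.05))
#> 79              # genes past the 2-fold / q < 0.05 thresholds
```

A thin command-line wrapper over the same functions is installed with the
package (`inst/scripts/tumortract.R`); see `--help` for the
`simulate`, `pipeline`, `survstats` and `de` subcommands.

## The methods vignette

`vignettes/tumortract-methods.Rmd` documents the signal model, the
reconstruction and tracking mathematics, the classification and bundle
counting rules, the statistical conventions (quantile type, t-test flavor,
FDR control), the adaptive QA threshold used by the end-to-end pipeline,
and what the synthetic generators do and do not emulate.
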