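# benmapr

Voxel-wise **brain entropy (BEN)** mapping and multi-scanner conjunction
analysis for BOLD fMRI, in R.

## The problem

Task activation and static connectivity analyses summarize *where* and *how
strongly* brain regions respond, but say little about the temporal character
of the signal itself. Brain entropy quantifies the moment-to-moment
irregularity of the BOLD time series at each voxel with **sample entropy**:

```
SampEn(m, r) = -ln(A / B)
```

where `B` counts pairs of length-`m` templates of the series whose Chebyshev
distance is at most `r`, `A` counts the same for length-`(m+1)` templates,
self-matches are excluded, and both counts share the template index range
`1..N-m` so that `A <= B` and `SampEn >= 0`. The tolerance is
`r = 0.6 * SD` of each voxel's series and the template ("window") length is
`m = 3`; low entropy means regular, predictable dynamics, high entropy means
rich, irregular dynamics.

The scientific use case is a within-subject, multi-scanner design: the same
participants are scanned on several MRI platforms under four 8-minute mental
states (rest, sad memory, rumination, distraction), and condition effects on
BEN are only trusted where they replicate — voxel-wise paired t-tests per
scanner (two-sided, uncorrected `p < 0.05`), then a **sign-consistent
conjunction** across all scanners, restricted to voxels showing task-vs-rest
changes, followed by ROI extraction and individual-level paired t-tests
(`df = n - 1`).

`benmapr` implements that whole chain:

- **synthetic cohorts** (`cohort_spec()`, `generate_cohort()`,
  `write_cohort()`): multi-scanner, multi-condition 4D NIfTI runs with
  known ground-truth regional entropy differences (AR(1) temporal
  regularity as the complexity knob), emitted motion/WM/CSF nuisance
  tables, and per-scanner offset/gain/noise perturbations — fully seeded;
- **preprocessing** (`preprocess_run()`): discard first 4 volumes, regress
  out 6 motion parameters + WM + CSF (no global signal regression),
  zero-phase 0.01–0.1 Hz bandpass, 6 mm FWHM Gaussian smoothing;
- **BEN mapping** (`ben_map()`, `ben_map_analysis()`): an exact
  template-counting sample-entropy kernel in C++ (`m = 3`,
  `r = 0.6 * SD`), trilinear resampling to the 3 mm analysis grid, 10 mm
  FWHM post-smoothing;
- **group statistics** (`paired_t_map()`, `t_to_z()`, `conjunction()`,
  `restrict_to_task_mask()`, `label_rois()`, `roi_mean_table()`,
  `roi_paired_tests()`);
- **orchestration** (`run_pipeline()`, `validate_manifest()`): one call
  from cohort to contrast maps, overlap masks, ROI tables, recovery
  metrics, figures and a provenance log; plus a thin CLI
  (`inst/scripts/benpipe.R`) with `simulate` and `run-all` subcommands.

## Worked example

```r
library(benmapr)

# entropy falls as temporal regularity rises
sample_entropy(generate_voxel_series(0,   1, 236, seed = 1))  # 1.0691
sample_entropy(generate_voxel_series(0.9, 1, 236, seed = 1))  # 0.4806

# an 8-subject, 3-scanner synthetic cohort with planted regional effects
spec <- cohort_spec(n_subjects = 8, seed = 42)
res  <- run_pipeline(spec, run_config())
res$recovery
#>   region                  contrast expected_sign n_planted recall false_sign_rate
#> 1  VCish         rumination_vs_sad            -1       196  0.985               0
#> 2 PCCish        distraction_vs_sad            -1       196  1.000               0
#> 3  VCish rumination_vs_distraction            -1       196  0.990               0
#> 4 PCCish rumination_vs_distraction             1       196  0.995               0

res$roi_tests[["rumination_vs_distraction"]]
#>      scanner          roi_label n df      t         p flagged
#> 1    IPCASGE   roi_x5_y5_z4_neg 8  7 -25.17 3.990e-08   FALSE
#> 2    IPCASGE roi_x13_y11_z5_pos 8  7  34.72 4.267e-09   FALSE
#> 3      PKUGE   roi_x5_y5_z4_neg 8  7 -12.26 5.496e-06   FALSE
#> 4      PKUGE roi_x13_y11_z5_pos 8  7  25.00 4.185e-08   FALSE
#> 5 PKUSIEMENS   roi_x5_y5_z4_neg 8  7 -30.49 1.054e-08   FALSE
#> 6 PKUSIEMENS roi_x13_y11_z5_pos 8  7  20.18 1.838e-07   FALSE
```

Reading the output: every planted effect is recovered with the correct sign
in ≥ 98% of its voxels and no wrong-sign voxels elsewhere. The ROI table
shows the individual-level replication structure — in the
rumination-vs-distraction contrast the posterior ROI (`..._pos`) has
*higher* entropy under rumination on every scanner, the visual ROI
(`..._neg`) lower, all at `p < 1e-5` despite only 8 subjects (the planted
synthetic effects are deliberately strong).

From a shell, the same analysis over on-disk NIfTI data:

```sh
Rscript inst/scripts/benpipe.R simulate --seed 1 --subjects 8 --out cohort/
Rscript inst/scripts/benpipe.R run-all --manifest cohort/manifest.tsv --out results/
```

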