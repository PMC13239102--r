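---
title: "Brain entropy mapping: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain entropy mapping: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(benmapr)
```

## What this package computes

Brain entropy (BEN) analysis asks how *irregular* the BOLD signal is at each
voxel, rather than how strongly it responds to a task. The statistic is
sample entropy,

$$\mathrm{SampEn}(m, r) = -\ln\frac{A}{B},$$

with $B$ the number of unordered pairs of length-$m$ templates of the voxel
series whose Chebyshev (maximum-component) distance is at most $r$, and $A$
the analogous count for length-$(m+1)$ templates. Both counts use template
start indices $1..N-m$, so every length-$m$ template has a length-$(m+1)$
extension; self-matches are excluded. Two consequences are built in rather
than incidental:

* $A \le B$ always (a length-$(m+1)$ match implies its length-$m$ prefix
  match), so the value is non-negative;
* for a constant series $r = 0.6\,\mathrm{SD} = 0$ and all templates match
  at both lengths, giving exactly $-\ln 1 = 0$.

Degenerate series ($A = 0$ or $B = 0$, possible for short or pathological
inputs) are flagged `NA` and excluded from all downstream statistics —
clipping them to a finite value would bias group maps. The tolerance uses
the *population* SD (`ddof = 0`) of the analyzed series; because both the
templates and $r$ scale together, SampEn is exactly invariant under
$x \mapsto a x + b$, $a \ne 0$, which also makes the question of whether SD
is computed before or after any internal demeaning immaterial.

"Window length" is interpreted as the template (embedding) length $m$; no
sliding sub-window segmentation of the run is performed.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `m` | 3 | samples | template length; standard BEN practice for ~240-frame runs |
| `r_frac` | 0.6 | fraction of series SD | match tolerance; same convention as the established BEN toolbox |
| `n_discard` | 4 | volumes | T1 saturation; leaves 236 of 240 frames at TR 2 s |
| `band` | 0.01–0.1 | Hz | slow BOLD fluctuation band; must stay below Nyquist 0.25 Hz |
| `fwhm_pre_mm` | 6 | mm | pre-entropy spatial smoothing of the 4D data |
| `target_voxel_mm` | 3 | mm | analysis grid for group statistics |
| `fwhm_post_mm` | 10 | mm | post-entropy smoothing of the BEN map |
| `alpha` | 0.05 | — | two-sided uncorrected voxel threshold |

The preprocessing order is fixed — discard, nuisance regression, bandpass,
smoothing — and recorded in each run's provenance. Entropy is computed on
the native preprocessed grid, then resampled to 3 mm, then smoothed at
10 mm, in that order.

### Filter realization

Only the passband (0.01–0.1 Hz) is scientifically fixed; the filter
realization is a package choice. We apply the squared magnitude response of
an order-4 Butterworth bandpass in the frequency domain — the gain a
forward–backward (zero-phase) Butterworth pass would have — because it (a)
has *exactly* zero phase, so entropy is not biased by phase distortion, (b)
removes DC entirely, and (c) applies to all voxels of a run in a single
FFT, which matters when a cohort contains ~500 runs. The testable contract
is the gain itself: ≥ 0.9 amplitude retention at 0.05 Hz, ≤ 0.1 at 0.2 Hz,
zero phase shift in the passband. A time-domain `filtfilt` realization
would satisfy the same contract; results differ only in edge handling of
finite series.

### Nuisance regression

Exactly eight regressors are used as provided — six motion parameters, mean
WM and mean CSF signals — plus an intercept (kept on by default so residual
means are ~0, stabilizing the $r = 0.6\,\mathrm{SD}$ scaling). No
derivatives or expansions, and no global signal regression. A
rank-deficient design errors with the names of the collinear columns;
all-zero columns are treated as absent so that a zeroed motion file reduces
cleanly to intercept-only centering.

### Smoothing

Separable Gaussian convolution with $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$
expressed per axis in voxel units (anisotropic voxels supported), boundary
mode "nearest", kernel truncated at $4\sigma$. Entropy maps are smoothed
mask-aware: `NA` voxels are excluded and the kernel renormalized over valid
neighbours, so missing voxels do not bleed zeros into the map.

## Group model

Per scanner and contrast, a voxel-wise paired t-test on the per-subject
difference maps: $t = \bar d / (s_d/\sqrt n)$ with sample SD (`ddof = 1`),
two-sided p from Student-t with $df = n-1$. Subjects missing at a voxel are
dropped pairwise with a per-voxel df adjustment. Zero-variance differences
follow an explicit rule — $t = 0, p = 1$ when the mean difference is also
zero, a $\pm\infty$ sentinel (flagged) otherwise — so degenerate synthetic
inputs cannot crash the pipeline. z-maps are computed through
tail-symmetric survival functions in log space, keeping $|z|$ finite to
$|t| \approx 40$ and $\mathrm{sign}(z) = \mathrm{sign}(t)$ exactly.

Replication across platforms is enforced by a sign-consistent conjunction:
a voxel survives only when significant with the same direction on *all*
scanners. Under independent nulls at two-sided $\alpha = 0.05$ on three
scanners the surviving fraction is $2 \times 0.025^3 = 3.125\times10^{-5}$,
which the test suite verifies empirically. Two open choices were resolved
as follows and are design decisions of this package, not assertions about
the original experimental scripts:

* **Task-vs-rest restriction.** Each task condition is contrasted with rest
  per scanner, conjuncted across scanners, and the three task overlaps are
  merged by a sign-consistent union (conflicting signs cancel to zero).
  Condition contrasts are then restricted to this composite mask.
* **Sign consistency in the conjunction** (rather than mere bilateral
  significance), because the replication logic and the bidirectional
  warm/cool rendering of overlap maps only make sense for direction-
  consistent effects.

No multiple-comparison correction is applied by default, matching the
exploratory voxel-wise protocol; `run_config(p_adjust = "fdr")` enables a
Benjamini–Hochberg variant as an extension.

ROIs are 26-connected components of the restricted overlap mask, named by
the coordinate of their peak mean $|z|$; per-subject mean BEN over each ROI
feeds scalar paired t-tests per scanner — the individual-level replication
check.

## The synthetic cohort

The generator emulates the *structure* of a three-scanner, four-condition
within-subject experiment: 41 subjects × 3 scanners × 4 conditions, 240
frames at TR 2 s on a 16×16×8 grid of 3 mm voxels (a desk-scale grid that
preserves the >200-frame temporal regime of real runs).

The single complexity knob is the AR(1) coefficient $\phi$: voxels inside a
planted region follow $x_t = \phi x_{t-1} + e_t$ (unit marginal variance),
background voxels are white noise, and sample entropy decreases
monotonically in $\phi$ — a one-parameter, analytically characterized
control. Each run is contaminated by a linear mixture of its own emitted
nuisance signals (motion as smoothed random walks; WM/CSF as low-frequency
sinusoids plus noise), perturbed per scanner by an additive offset, a
multiplicative gain and a noise-SD factor, and overlaid with white
measurement noise (SD 0.5 in signal units). Everything is seeded per run,
so cohorts are bit-identical under a fixed spec and runs can be generated
in any order or streamed.

Default planted effects (AR coefficients per condition):

| region | rest | sad | rumination | distraction | encodes |
|---|---|---|---|---|---|
| VCish | 0.1 | 0.1 | 0.8 | 0.1 | entropy drop under rumination (visual-cortex-like) |
| PCCish | 0.8 | 0.1 | 0.1 | 0.8 | entropy higher under rumination than distraction; lower under distraction than sad (posterior-DMN-like) |

The $\phi$ contrast of 0.1 vs 0.8 and the noise SD were fixed once from a
pre-build Monte-Carlo calibration of the post-preprocessing entropy
separation (mean SampEn ≈ 0.565 vs 0.468, per-series SD ≈ 0.035 after the
discard + bandpass chain), i.e. a strong but not degenerate per-voxel
effect. No published effect size exists for regional BEN differences in
this design; these are tooling choices for testability, not estimates of
the real effect.

**What passing tests show — and don't.** Recovery of planted effects shows
the pipeline's statistics and bookkeeping are correct under a known model.
The generator deliberately omits hemodynamic response structure, spatial
autocorrelation beyond the applied smoothing, motion *artifacts* (only
motion *regressors*), scanner drift nonstationarity, and MR physics.
Passing recovery therefore validates the machinery, not the empirical claim
that any real mental state modulates entropy.

### Recovery metrics

`recovery_metrics()` reports, per planted (region, contrast) effect, the
recall (fraction of planted voxels carrying the expected sign in the
restricted overlap) and a false-sign rate. Because 10 mm post-smoothing
*necessarily* spreads true signal a few voxels past a region boundary with
the correct sign, a detection outside all planted regions is counted as
false only when its sign cannot be explained by a nearby planted effect:
each region indicator is smoothed with the post-entropy kernel, and voxels
where some region's weight exceeds 1% "expect" the sign of the dominant
such region; everywhere else any detection is false. Wrong-sign detections
are always false.

## Numerical choices

* Sample-entropy counts are integer template counts in C++; the R brute
  force oracle in the test suite reproduces them *exactly* (same $r$
  formula, independent counting path).
* Trilinear resampling uses cell-centered voxel coordinates with edge
  clamping; a grid resampled onto itself is returned untouched, constants
  stay constant, and linear ramps are interpolated exactly in the interior.
* Per-run seeds are derived deterministically from the cohort seed and the
  (subject, scanner, condition) index, all below $2^{31}$.
* Problem sizes in the test suite: the full-cohort recovery check runs the
  complete 41 × 3 × 4 cohort (492 runs, 236 analyzed frames each) through
  preprocessing, entropy mapping and statistics; oracle-equivalence checks
  use 1,000+ random series across $N \in \{20, 64, 236\}$; the conjunction
  null calibration uses $10^6$ voxels.

## Limitations

* Spatial alignment is out of scope: runs are assumed on a common grid
  (synthetic data is generated aligned; real data must be normalized with
  external tooling before entering the pipeline). Only rigid-grid
  resampling is provided, no nonlinear warps.
* Slice-timing correction, realignment estimation and tissue segmentation
  are likewise delegated to standard external preprocessors.
* Single-scale sample entropy only; no multiscale, approximate or
  permutation entropy variants.
* No cluster-extent, permutation or TFCE inference; the uncorrected
  voxel-wise threshold plus cross-scanner conjunction is the inferential
  device, and it controls false positives only in the conjunction sense.
* In-memory provenance records the full generating spec and seed rather
  than a content hash; file-based inputs are hashed with MD5.
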