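---
title: "Linking band-limited EEG power to BOLD in resting-state networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking band-limited EEG power to BOLD in resting-state networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandbold)
```

## The scientific question

Hemodynamic fluctuations of resting-state networks such as the default
mode network (DMN) are believed to track band-limited electrophysiological
power, with the alpha rhythm (8–13 Hz) playing a dominant role at rest.
Testing this requires a long chain of signal processing: EEG recorded
inside the MR scanner must be cleaned of gradient, ballistocardiogram
(BCG), ocular and myogenic artifacts; cleaned sensor data are projected
into source space; band-limited power time-courses are computed on a voxel
grid; a network is detected from the power by temporal ICA; the network's
power time-course, convolved with a canonical hemodynamic response
function (HRF), is correlated voxelwise with the simultaneously acquired
BOLD series; and group inference with false-discovery-rate control yields
maps whose overlap with the fMRI-defined network quantifies spectral
specificity.

`bandbold` implements this chain end to end and, because real
simultaneous EEG–fMRI recordings of this kind are rarely shared, ships a
synthetic generator with known ground truth so that every stage — and the
chain as a whole — is testable.

## The generative model

A study is a cohort of subjects sharing a head model and a network
layout. For subject $s$:

* **Sources.** Network $k$ is a smooth nonnegative blob $a_{kv}$ on the
  gray-matter voxels. Voxel activity is
  $x_v(t) = \sum_k a_{kv}\, e_k(t)\, c_k(t) + b_v(t)$, where $e_k$ is a
  slow envelope (rectified low-pass Gaussian noise, cutoff 0.1 Hz — the
  timescale of resting-state fluctuations), $c_k$ is band-pass Gaussian
  noise in the network's assigned band, and $b_v$ is an independent
  $1/f$ background per voxel. Dipole orientations are fixed per voxel.
* **Sensors.** A leadfield built from the closed-form potential of a
  current dipole in an infinite homogeneous conductor maps sources to an
  upper-hemisphere sensor shell; the leadfield is average-referenced.
  This is a deliberate stand-in for realistic volume conduction: exact
  for its own geometry and sufficient to exercise a linear inverse.
* **Artifacts.** The contaminated recording adds (i) a gradient artifact,
  exactly periodic at the slice rate and locked to TR onsets; (ii) a BCG
  pulse train locked to jittered cardiac markers with slow amplitude
  drift; (iii) blink transients weighted to frontal sensors; (iv)
  20–70 Hz EMG bursts weighted to rim sensors. Amplitudes are multiples
  of the clean RMS (defaults 50, 5, 3, 2).
* **BOLD.** Voxel $v$'s series is
  $\sum_k a_{kv}\,(h \ast e_k)(t_j) + \text{drift} + \text{noise}$ at
  $t_j = j\,\mathrm{TR}$, where $h$ is the canonical double-gamma HRF.
  With all noise off, an in-network voxel correlates exactly 1 with the
  HRF-convolved envelope — the relationship the analysis is asked to
  recover.

### Generator choices worth knowing

* The $1/f$ background flattens below 0.5 Hz. EEG amplifiers are
  AC-coupled; without the knee the record is dominated by unbounded
  drift that no real acquisition shows, and that drift (rather than the
  artifacts under study) dominates every residual metric.
* The BCG pulse rides on a 3.5 Hz carrier under a 0.13 s envelope:
  ballistocardiographic deflections are slow. EMG is band-limited to
  20–70 Hz, the range in which muscle activity contaminates EEG.
* Bands are half-open $[f_{lo}, f_{hi})$ (13 Hz belongs to beta, 8 Hz to
  alpha; gamma closes at 80 Hz inclusive), and band power is evaluated at
  integer frequencies. A carrier's passband therefore ends 0.5 Hz below
  its upper edge so that, after windowing, its energy stays inside its
  own band's bins; a nominally "alpha" carrier must not leak into beta's
  first bin, or the planted ground truth itself is not band-limited.
* The network layout is drawn from the study seed, not the subject seed:
  a cohort shares network anatomy, as in template-based group analysis.
* Gray matter is the upper portion of the grid — the part of the volume
  under the sensor array, standing in for cortex under a head net. With
  sensors only on an upper shell, sources far below are electrically
  near-invisible, as deep sources are in practice.

### What the generator does *not* emulate

Realistic tissue conductivities and FEM volume conduction; physiological
BOLD noise beyond polynomial drift and white noise; eyes-open/closed
state changes; scanner file dialects. Passing the end-to-end tests shows
that the chain recovers planted band-specific coupling through realistic
artifact levels and a linear forward model — not that it would produce
identical numbers on any particular scanner's data.

## The analysis chain

**Cleaning.** Gradient: per channel, epochs on TR markers have the
sliding average of `n_avg_epochs` neighbors subtracted (AAS), then the
top `n_obs_pcs` principal components of the residual epochs removed
(optimal basis set). BCG: epochs from −0.2 to +0.6 s around R peaks have
the top `n_obs_pcs` PCs of the epoch matrix fitted and subtracted.
Bad channels are flagged when their mean absolute 1–80 Hz correlation
with the array is a low outlier or their noise-band variance a high
outlier (robust median ± 3·1.4826·MAD rule; the noise band is 200–250 Hz
when the sampling rate allows, otherwise 0.4–0.5 × Nyquist with a
warning), then interpolated from the four nearest good channels.
After a zero-phase 4th-order Butterworth band-pass (1–80 Hz), FastICA
components are classified as artifact if correlated with the EOG or EMG
reference (|r| > 0.3), dissimilar from a $1/f^\beta$ spectrum (fit
correlation over 2–40 Hz below 0.5), or of excess kurtosis above 10; the
recording is rebuilt from the remaining components and average-referenced.

**Source power.** The eLORETA weights are iterated to convergence
(tolerance $10^{-6}$); regularization adds `alpha_reg` (default 0.05)
times the mean sensor-space eigenvalue to the diagonal. The noise
covariance is the identity (the design has no empty-room data). Band
power uses a 2 s Hamming window with 50% overlap — one frame per second,
the first centered at 1 s — with orientation powers summed per voxel.

**Networks.** Temporal ICA runs on the voxels × time power matrix per
band; spatial ICA on the volumes × voxels BOLD matrix. Model order comes
from the Wax–Kailath MDL criterion, bounded by the data rank and by the
configurable cap `k_max`. The cap exists because MDL assumes many more
observations than variables; with the short desk-scale records used here
(~120 frames against ~100 voxels) the spread of noise eigenvalues
inflates the estimate, and planted-envelope recovery degrades measurably
when the decomposition over-splits (the default cap of 5 recovered the
envelope best across diagnostic runs; at full experimental scale MDL's
own estimate is far below any reasonable cap). Components are
sign-normalized so loadings have positive skewness — compact activations
come out positive — which makes template matching reproducible. The
network of interest is the component whose map correlates best with the
template (ties go to the lower index); for synthetic runs the template
is the ground-truth map, for real data any NIfTI map on the grid.

**Coupling and inference.** The selected IC time-course (or the averaged
occipital-channel alpha power, for the sensor-level variant) is convolved
with the canonical double-gamma HRF (delays 6/16 s, dispersions 1 s,
ratio 6, length 32 s, peak-normalized), and correlated per voxel with
BOLD linearly upsampled to 1 Hz; the first 32 s are excluded as
convolution burn-in, correlations are clipped below |r| = 1 and
Fisher-transformed. Group maps are one-sample one-sided t-tests per
gray-matter voxel; significance uses Benjamini–Yekutieli FDR at
q = 0.05, corrected over voxels for the fMRI and sensor maps and over
voxels × bands jointly for the network maps. Spectral specificity is
tabulated as the Pearson correlation (CC) of each band's group t-map with
the fMRI group map over gray matter, and the Dice coefficient (DC) of
their positive significance masks (a z > 1.96 binarization is available
via `binarize_rule`).

## Numerical conventions and degenerate inputs

* Correlation with a zero-variance series is defined as 0 (with a
  warning where it matters); a zero-variance regressor is an error.
* A voxel with zero variance across subjects takes the degenerate t-test
  limit: p = 0 if its mean lies strictly in the tested direction, else 1.
* Dice of two empty masks is defined as 0 with a warning.
* FastICA restarts a non-converging component up to 10 times, switching
  to damped (stabilized) updates after half the iteration budget; failure
  after all restarts is an error naming the component.
* All generators and analyses are pure functions of (configuration,
  seed); per-subject seeds are the master seed plus 1000 × subject index.

## Problem sizes

Generator defaults are desk-scale: 32 sensors, a 6 × 6 × 6 grid at 6 mm
(216 voxels), 300 s at 250 Hz, TR 2 s. Repeated end-to-end studies (the
spectral-specificity benchmark: 10 master seeds × 10 subjects) use
`small_study_config()` — 120 s, 200 Hz, a 5 × 5 × 5 grid — chosen so a
full group analysis runs in about a minute. These sizes are the package's
stated study conditions; a full-scale experiment (256 channels, 1 kHz,
10 min) is configurable but not the default.

## Worked example

```{r example, eval = FALSE}
cf <- small_study_config()   # 10 subjects, master seed 1
group <- run_group(cf)
round(group$table, 2)
#>    Full Delta Theta Alpha  Beta Gamma
#> CC 0.52   0.4  0.28  0.64 -0.32  0.12
#> DC 0.86   0.0  0.00  0.84  0.00  0.00
write_group_results(group, "results/demo")
```

The alpha column dominating both rows — with the full band, which
contains alpha, close behind — is the expected signature when the planted
carrier is an alpha rhythm.

## Known limitations

The dipole leadfield ignores tissue boundaries, so absolute source
amplitudes are not physiologic; desk-scale records give noisier subject
correlation maps than 10-minute acquisitions, which is why group masks,
not subject maps, carry the inference; and MDL-selected orders at these
sizes depend on the `k_max` guard described above. The BCG remover is a
fixed-basis OBS, deliberately simpler than adaptive variants: its epoch
window and component count are configurable, and the cleaning benchmark
reports what it achieves on the standard fixture.
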