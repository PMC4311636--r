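---
title: "Models, pipeline and design choices in nfengine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, pipeline and design choices in nfengine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfengine)
```

`nfengine` is a client-server engine for real-time fMRI neurofeedback: a
TCP/IP protocol server over isolated session workspaces, a per-volume
processing pipeline with plug-in hooks, four shipped feedback plug-ins, a
synthetic session simulator, and a reference terminal client. This vignette
documents the models it computes, the parameters that matter, the numerical
choices, and what the simulator does and does not emulate.

## Sessions, commands, and the concurrency contract

A *session* is an isolated in-memory workspace holding one experiment's
configuration, per-command statuses, and per-volume feedback and motion
stores. Long-running commands (`PREPROC`, `PIPELINE`, `FEEDBACK`, `GLM`,
`FEATURESELECTION`, `TRAIN`) move through `IDLE → RUNNING → DONE|FAILED`;
their `NB`-prefixed twins return as soon as the work is scheduled, and
frontends poll `SESSION/<COMMAND>` for completion and `SESSION/TEST` /
`SESSION/GRAPHPARS` for per-volume values. The contract the package
guarantees — and what its tests assert — is behavioural: queries answer
promptly while work runs, from any connection bound to the session. The
mechanism is a cooperative event loop: every long-running command is broken
into bounded steps (one directory poll, one volume, one ≤ 50 ms delay
slice) interleaved with socket servicing in a single R process. This was a
deliberate design choice over OS threads: it keeps the engine dependency-free
and deterministic, at the cost that one pathological step (e.g. motion
estimation on a very large grid) bounds query latency by its own duration.
At the default 32 × 32 × 16 geometry a volume step takes well under a
second.

Two details of the reply grammar are package-defined, since only the command
vocabulary is standard: every request receives a status line
(`OK`/`ERROR <reason>`/`NOT_READY`), payload lines, and a blank-line
terminator; `READCONFIG <n_bytes>` frames its configuration payload by byte
count. Blocking `TEST`/`GRAPHPARS` wait server-side until the requested
volume is stored (bounded by `poll_timeout_s`); the `SESSION/` forms never
block.

## Study configuration

The configuration dialect is one `key=value` per line, `#` comments, block
design as repeated `design=CONDITION:start-end` entries (1-based, closed,
disjoint, jointly covering `1..n_volumes`), masks as repeated `roi_mask=`
entries. Key fields, with defaults:

| key | default | meaning |
|---|---|---|
| `n_volumes`, `tr_seconds` | —, 2 | run length and repetition time (s) |
| `baseline_condition` | first design condition | blocks defining the PSC baseline |
| `sliding_window_L` | min(30, n) | connectivity window length (scans) |
| `feature_fraction_p` | 1 | fraction of voxels kept by feature selection |
| `smoothing_fwhm_mm` | 0 | Gaussian smoothing FWHM (mm) |
| `motion_correction` | on | rigid-body correction per volume |
| `hrf` | on | convolve GLM boxcars with the canonical HRF |
| `poll_timeout_s` | 10 | arrival/waiter timeout (s) |
| `debug_delay_s` | 0 | artificial per-command delay, for latency testing |

Volume files are expected as `<prefix><index, zero-padded>.nii` (1-based);
arrival is detected when a file's size is stable across two polls ≥ 50 ms
apart, so partially written files are never read.

## The processing pipeline

Per volume: the `Volume` hook fires, the file is read, rigid-body motion is
estimated against the run reference (volume 1, or a configured reference)
and applied, Gaussian smoothing follows, motion parameters are stored, the
`PostProc` hook fires, and — in feedback runs — the `Test` hook computes the
(class, value) pair, which is stored in the session. `Finalization` runs on
completion *and* on failure. Re-running `PREPROC` resets all per-run state,
making restarts idempotent.

One ordering choice was genuinely open: whether smoothing precedes the
feedback hooks. Here smoothing (and motion correction) precede all
`PostProc`/`Test` hooks, so every plug-in sees the same preprocessed data
the GLM sees.

**Motion correction.** The 6-parameter rigid transform (translations in mm,
rotations in degrees about the grid centroid, `Rz·Ry·Rx` convention, voxel
centers at integer coordinates) minimizes the mean squared intensity
difference to the reference after trilinear resampling. The optimizer is
derivative-free Nelder-Mead from the zero transform: a coarse stage on a
stride-2 subsample, then full-resolution refinement; the objective is
restricted to the grid's central region (4-voxel border excluded) so the
cost surface stays smooth under small transforms. This is deterministic
given its inputs. Measured on smooth synthetic volumes with injected
transforms (|t| ≤ 2 voxels, |r| ≤ 3°), median recovery errors are well
below 0.1 voxel and 0.5°. The reported `rms` is the root-mean-square
intensity residual at the optimum; a constant (degenerate) volume yields a
flagged identity estimate rather than an error.

**Smoothing.** Separable Gaussian with σ = FWHM/(2√(2 ln 2)) converted
per-axis to voxels, truncated at 3σ, renormalized over the in-grid support
at edges. Renormalization preserves constant fields exactly (and hence ROI
means of flat signals); total intensity of a signal is conserved exactly
only when its smoothed support stays ≥ 2 kernel radii from the boundary.

**GLM.** Ordinary least squares per voxel on [per-task-condition boxcar
(optionally convolved with the canonical double-gamma HRF: gamma densities
with shape 6 and 16 at unit rate, undershoot ratio 1/6, unit peak),
intercept, centered linear drift], with
`t = c'β / sqrt(σ̂² c'(X'X)⁻¹c)`, `σ̂²` on `n − p` degrees of freedom. The
HRF shape is the field-standard default; nothing in the engine depends on
it beyond the design matrix. Zero-residual series get `t = 0` rather than
0/0. Rank-deficient designs error, naming the collinear columns.

**Feature selection.** The `ceiling(p·N)` in-mask voxels of highest
statistic; ties at the threshold break deterministically by lowest linear
voxel index.

## The four plug-ins

**libROI / libMotor.** Fractional percent signal change against the most
recently *completed* baseline block. The baseline is rolling: when a
baseline block finishes, its per-volume ROI means replace the previous
baseline estimate — and this update happens *before* that final volume's
own feedback is computed, so only volumes strictly inside the first
baseline block have undefined feedback. Two resolutions worth noting:
(i) the defining ratio carries no factor 100, so the engine reports a
fraction (0.02, not 2.0) and leaves display scaling to frontends; (ii) a
feedback run must store a pair for *every* volume, so volumes whose
feedback is undefined (before the first baseline completes) are stored as
(condition label, `NA`) rather than omitted. `libMotor` is the identical
computation on two masks (left/right motor cortex in its intended use),
returning both values in mask order. MNI-to-subject mask transformation is
out of scope by design: masks must already live on the functional grid, and
preprocessing validates exactly that.

**libConnectivity.** Pearson correlation of the two ROI-mean series over
exactly the last `L` scans. Until the window holds `L` entries the plug-in
reports not-ready rather than a partial-window estimate — the statistic is
defined over exactly `L` scans, and early short-window values would be
noisier than the contract suggests. Zero variance in a window is an error,
not a 0. Its `Train` hook (`buildROIs`) refines the two masks from a
completed localizer run in the same session: per-mask GLM t map, then
top-`p` voxel selection.

**libBrainDecoding.** Linear two-class SVM on z-scaled concatenated voxel
vectors (per-feature scaling fitted on the training set). Training delegates
the quadratic program to libSVM (e1071) — the engine owns scaling,
hyperplane extraction (`w = Σ αᵢyᵢxᵢ`, `b = −ρ`), sign canonicalization
(positive projection ⇔ first class), and serialization to versioned JSON
for reuse in later decoding sessions. Where the data are separable a hard
margin is used (the solver is run at a large penalty and kept if it
separates); otherwise a soft margin with cost 1 — a documented default, not
a tuned value. Feedback is the raw projection `x'w + b`: it is not
normalized by ‖w‖ (an optional flag provides the geometric distance), and
its discretization into display figures is left to frontends. The reported
class is the sign of the projection mapped back to the design's condition
labels.

## The simulator

`simConfig()`/`generateSession()` produce a complete session on disk:
configuration, spherical ROI masks, ground-truth manifest, and volumes with
signal

`base(x) · (1 + Σ_r psc_r a_r(t) + drift·(t−1)) + latent + noise`,

where `base` is a static smooth texture (default 10% contrast, 9 mm
smoothness — enough structure for registration to grip), `a_r(t)` the
condition boxcar (HRF convolution optional and off by default so plateau
arithmetic stays exact), `noise` i.i.d. Gaussian per voxel per volume
(default 1% of the 1000-unit baseline), and `latent` a shared fluctuation
`amp·(√ρ·z_t + √(1−ρ)·ε_rt)` added uniformly within each of two ROIs so
their mean series correlate at `ρ` in expectation. Defaults — 32 × 32 × 16
grid of 3 mm voxels, 60 volumes in alternating 15-volume baseline/task
blocks, 2% task activation — describe a small but realistic block-design
run and are the conditions under which the package's recovery properties
are stated. Because multiplying `base` by the activation factor cancels in
the PSC ratio, a noise-free session reproduces the requested PSC to
floating-point accuracy, which is what the closed-form tests rely on.

Simulated sessions contain no head motion unless a `motion_schedule` is
given, so generated configurations disable engine motion correction by
default (the engine's own default is on); `streamVolumes()` paces arrivals
and uses write-to-temp-then-rename so watchers never see partial files.

What the simulator does *not* emulate — temporally autocorrelated noise,
physiological confounds, EPI artifacts, field inhomogeneity, slice timing —
bounds what passing tests show about real data: they verify the engine's
computations and contracts, not robustness to scanner physics.

## Numerical and protocol edge choices

* Session ids are short random alphanumeric tokens; an explicit id argument
  on a query overrides the connection's binding, so a second frontend (e.g.
  quality control) can attach with just the token.
* A session-scoped command on a connection that never sent `NEWSESSION`
  lazily binds a default session — the synchronous single-connection flow
  needs no session management.
* `ERROR` replies never mutate session state beyond marking the command
  `FAILED`; repeated `SESSION/*` queries are idempotent.
* Feedback values are serialized at full precision (17 significant digits);
  `NA` is transmitted literally.
* Test-suite and acceptance problem sizes (tiny 6 × 6 × 3 oracle grids, the
  default 60-volume session, 10⁴ simulated voxels for the type-I check, 20
  motion trials) were chosen as the smallest sizes at which the measured
  quantities are stable.

## Known limitations

Single-process cooperative concurrency (see above); no TLS or
authentication; no persistence of sessions across restarts; masks must be
supplied on the functional grid (no MNI registration, skull stripping or
segmentation); two-class decoding and two-ROI connectivity only; no
slice-timing or distortion correction. These mirror the package's scope:
the engine, protocol, plug-ins and simulator — not a full fMRI
preprocessing stack.
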