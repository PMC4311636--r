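# nfengine

A client-server engine for real-time fMRI neurofeedback studies, with a
synthetic scanner-session simulator so that every processing path can be
exercised and verified without a scanner.

In closed-loop neurofeedback, a participant in the scanner receives a
continuously updated signal derived from their own ongoing brain activity —
a thermometer bar tracking motor-cortex BOLD change, an avatar hand that
moves when the decoded brain state says so. The software burden is
substantial: volumes must be picked up the moment the scanner exports them,
motion-corrected, smoothed, and reduced to a feedback value within a
repetition time, while the stimulus-presentation frontend (possibly on a
different machine and platform) keeps querying for values without ever
freezing. `nfengine` implements this as three separated parts:

* an **engine**: a TCP/IP server owning isolated *session* workspaces and a
  real-time pipeline (directory watching, rigid-body motion correction,
  Gaussian smoothing, GLM, feature selection),
* **plug-ins**: feedback computations called through six lifecycle hooks
  (`Train`, `Test`, `Initialization`, `Finalization`, `Volume`, `PostProc`);
  four ship with the package,
* a **frontend**: any client speaking the line-based command protocol; a
  reference terminal client with a thermometer display is included.

## Feedback pipelines

**ROI percent signal change** (`libROI`, and the two-ROI `libMotor`): for
the current volume's ROI mean and the per-volume means `ROI_k` of the `B`
volumes of the previous baseline block,

    feedback = (ROI_curr − m) / m,   m = (1/B) Σ_{k=1..B} ROI_k

reported as a fraction (0.02 ≙ 2% signal change).

**Sliding-window connectivity** (`libConnectivity`): the Pearson correlation
ρ(ROI1, ROI2) over exactly the last `L` scans' ROI means, emitted once the
window is full. ROIs can first be refined from a functional localizer: a GLM
(task boxcar convolved with a canonical double-gamma HRF, plus intercept and
drift) yields a t map, and the top fraction `p` of in-mask voxels is kept.

**SVM brain decoding** (`libBrainDecoding`): training volumes are
concatenated to voxel vectors, z-scaled, and a linear two-class
maximum-margin classifier (libSVM via e1071) is fit. Feedback for a new
volume is its signed projection on the discriminating hyperplane,
`x'w + b`; the class boundary is the value zero.

## Protocol

Newline-terminated commands, each answered by `OK` / `ERROR <reason>` /
`NOT_READY` plus payload lines: `NEWSESSION`, `ENDSESSION`, `READCONFIG`,
`PLUGIN`, `PREPROC`, `PIPELINE`, `FEEDBACK`, `GLM`, `FEATURESELECTION`,
`TRAIN`, `TEST`, `GRAPHPARS`, and session queries
(`SESSION/PREPROC`, `SESSION/FEEDBACK`, `SESSION/TEST`,
`SESSION/GRAPHPARS`). Every command has a non-blocking `NB` twin that
returns immediately after scheduling; progress is observed by polling the
`SESSION/*` queries, which respond while the work runs — including from a
second connection bound to the same session.

## Worked example

Generate a 12-volume synthetic session (3 mm grid, 1% noise, 2% activation
in a spherical ROI), serve an engine, stream the volumes in "real time", and
run the reference client (scripts live in `exec/` of the installed package):

```sh
Rscript exec/simulate.R generate --config sim.yaml --out cli_session
Rscript exec/engine.R serve --port 47113 &
Rscript exec/simulate.R stream --dir cli_session --interval 0.05 &
Rscript exec/client.R run --host 127.0.0.1 --port 47113 \
    --config cli_session/study_params.txt --plugin libROI --mode nb
```

which prints, per volume, the thermometer gauge, feedback value and class:

```
vol   6 [#                                       ] 0.0007533 (class 1)
vol   7 [###################                     ] 0.01904 (class 2)
vol   8 [#####################                   ] 0.02101 (class 2)
vol   9 [###################                     ] 0.01912 (class 2)
vol  12 [#################                       ] 0.01735 (class 2)
final status: DONE (12 volumes)
```

Volumes 7–12 belong to the task block: the recovered signal change
fluctuates around the simulated 2% (0.019–0.021). Volume 6 is the last
baseline volume, whose feedback is computed against its own just-completed
block and so sits near zero. Class labels are the design condition of each
scan (1 = baseline, 2 = task).

The same run can be driven from R:

```r
library(nfengine)
gt <- generateSession(simConfig(n_volumes = 12), "session_dir")
streamVolumes("session_dir", 0)
h <- launchEngine()
rep <- runSession(h$host, h$port, gt$params_path, plugin = "libROI", mode = "nb")
rep$results
stopEngine(h)
```

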