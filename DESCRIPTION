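Package: nfengine
Title: Real-Time fMRI Neurofeedback Engine with a Client-Server Protocol
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A client-server engine for real-time fMRI neurofeedback
    experiments. A TCP/IP server executes a documented command protocol with
    synchronous and non-blocking dispatch over isolated session workspaces; a
    real-time pipeline watches an input directory for incoming single-volume
    NIfTI files, applies rigid-body motion correction and Gaussian smoothing,
    and invokes plug-in hooks at defined time points. Four feedback plug-ins
    are shipped: region-of-interest percent signal change, a dual-ROI motor
    variant, sliding-window functional connectivity, and linear SVM brain
    decoding. General linear model fitting and top-fraction voxel feature
    selection support functional localizers. A synthetic scanner-session
    simulator with known ground truth and a terminal reference client make
    every path testable end-to-end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    e1071,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
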