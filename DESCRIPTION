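Package: cppErp
Title: Decision-Locked EEG Analysis of the Centro-Parietal Positivity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the centro-parietal positivity (CPP), a slow
    EEG potential whose build-up rate tracks decision formation. The package
    simulates continuous multichannel EEG with a ground-truth
    accumulation-to-bound CPP component and shifted-lognormal decision times,
    and implements the full decision-aligned analysis chain: mastoid
    rereferencing, anti-aliased downsampling, cue- and response-locked
    epoching, baseline correction, Gaussian smoothing, decision-time trial
    exclusion, robust variance-based trial flagging, electrode-cluster ERPs,
    decision-time percentile binning and ERP images, pre-decision slope
    regression with a start/end window sweep, two-level (participant, group)
    inference with Cohen's d, and cluster-based permutation tests along the
    time axis with an exhaustive-enumeration oracle for small samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
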