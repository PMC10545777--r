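Package: opfiber
Title: Joint Operant-Behavior and Fiber-Photometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for merging operant-behavior session logs with fiber
    photometry recordings. Parses integer-coded (Imetronic-style) and
    generic column-per-event behavioral files, derives scheduled and
    unscheduled intervals (light periods, post-injection time-outs) by
    rule, processes dual-channel photometry signals into isosbestic-
    corrected dF/F or Z-difference traces, detects calcium or
    neurotransmitter transients by windowed MAD double-thresholding,
    and runs batched perievent analysis (baseline Z and robust-Z
    renormalization, AUC, peak statistics) across multiple sessions.
    A seeded synthetic-data generator emulates fixed-ratio
    self-administration sessions and matched photometry recordings with
    known ground truth, so the entire pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    pracma
Suggests:
    rhdf5,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
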