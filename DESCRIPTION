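Package: nanotiming
Title: Dynamic Single-Cell Profiling of Effector-Tumor Interactions in
    Nanowell Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of time-lapse imaging microscopy in nanowell grids
    (TIMING) assays of CAR T cell-tumor cell interactions. Simulates
    ground-truthed nanowell chips (time-lapse tracks, rendered image
    stacks, endpoint cytokine-capture bead readouts), segments and links
    rendered frames into object tracks, detects effector-target
    conjugations and computes killing kinetics (t_Seek, t_Contact,
    t_Death), annotates effector function (killing, serial killing,
    IFN-gamma secretion), quantifies directional migration in and out of
    contact, analyses single-cell qPCR panels for migration-associated
    differential expression, and stratifies clinical cohorts by
    immunohistochemistry H score with Kaplan-Meier and log-rank
    progression-free-survival analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
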