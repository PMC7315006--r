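Package: pursuitkin
Title: Kinematics of Cuttlefish Visual Attack on Moving Prey
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of markerless pose-estimation output for
    predator-prey pursuit experiments in which a cuttlefish attacks a
    shrimp target moving along a one-dimensional rail. Provides readers
    and writers for the DeepLabCut CSV dialect, likelihood-gated track
    cleaning with linear interpolation, per-frame angular and
    translational kinematics (visual attack angle, eye angles, tentacular
    strike angles, club angles, horizontal speeds, mantle-length
    normalised distances), segmentation of attention episodes and
    tentacular strikes, the accompanying nonparametric rank statistics
    (Wilcoxon matched-pairs signed-rank and Mann-Whitney U with exact
    enumeration at small samples), and a ground-truthed pursuit simulator
    that emulates the rig so every pipeline stage can be validated
    against known parameters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
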