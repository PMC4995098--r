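Package: proximap
Title: Cortical Population Maps Evoked by Visual and Prosthetic Retinal
    Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for intrinsic optical-imaging recordings of
    primary visual cortex responding to visual stimuli and to sub-retinal
    micro-electrode-array stimulation.  Converts multi-frame trial stacks
    into blank-normalized z-score and fractional-change maps, extracts
    thresholded activation regions and their equivalent-ellipse descriptors,
    builds retinotopic polar maps and cortical-magnification and size-tuning
    fits, fits Naka-Rushton intensity-response functions with their 10-90%
    operational range, implements a two-source model of retinal activation
    (isotropic diffusion plus axons-en-passant shadow cone) with a
    retino-cortical transform, and tests the radial organization of
    elongated activations around the optic-disk representation with a
    Monte-Carlo null.  A synthetic-data generator emulating the recordings
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
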