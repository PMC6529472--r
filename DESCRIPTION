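Package: mechpheno
Title: Mechanical Phenotyping of Growth-Factor-Stimulated Cancer Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for quantifying growth-factor-induced changes in
    the mechanical phenotype of cancer cells: optical-stretcher
    creep-and-recovery strain curves with bootstrap confidence bands and
    maximum-strain rigidity statistics, 2D single-cell migration speed and
    penalized directional persistence, 3D collagen-invasion quantification
    from nucleus spot detection in confocal-like stacks, and expression
    time-course analysis (fold changes, Gaussian-process smoothing,
    differential calls, hypergeometric gene-set enrichment). A synthetic-data
    module generates instrument-like inputs with planted ground truth so the
    whole pipeline can be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
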