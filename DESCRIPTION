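Package: confinemetry
Title: Quantitative Analysis of T-Cell Confinement Experiments on
    Antigen-Presenting Bilayer Mimics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for mechanical cell-confinement
    experiments on supported lipid bilayer (SLB) bio-interfaces.
    Provides a synthetic-data generator with ground truth for every
    acquisition type (single-molecule TIRF movies, dual-excitation
    Fura-2 calcium stacks, membrane-stained z-stacks, two-channel
    immunofluorescence images, membrane deflection profiles), and the
    downstream quantification: single-molecule localization, density
    estimation by brightness normalization, trajectory linking and
    diffusion analysis; Fura-2 sum/ratio construction, cell
    segmentation, tracking and pre/post-confinement window statistics;
    mean-squared-displacement motility fits (diffusion plus directed
    motion) with bootstrap uncertainties; nucleus/cell immunostain
    quantification; elastic-membrane deflection fitting, arc-length
    engineering strain and pressure linearity; and the statistical
    layer (Welch tests, Games-Howell post hoc comparisons, notched
    boxplot summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    EBImage,
    pracma,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
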