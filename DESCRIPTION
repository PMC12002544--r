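Package: LesionShells
Title: Multi-Parametric Quantitative MRI Analysis of Lesions, Perilesional
    Shells and Normal-Appearing Brain Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multi-parametric quantitative MRI analysis of focal
    and diffuse white-matter pathology in multiple sclerosis. Builds volumes
    of interest from 3D lesion masks and tissue-probability maps (per-lesion
    connected components, one-voxel erosion, two-voxel perilesional shells,
    concentric one-voxel shells via spherical structuring elements, and
    normal-appearing white/grey matter), extracts biomarker means at lesion,
    subject and group level, and runs the nonparametric statistical battery
    (Mann-Whitney U, Wilcoxon signed-rank, Benjamini-Hochberg FDR control).
    Includes a fully synthetic multi-subject phantom generator with known
    ground truth for validation and calibration studies, plus table/figure
    data exports and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'stats.R'
    'morphology.R'
    'voi-geometry.R'
    'extraction.R'
    'phantom.R'
    'pipeline.R'
    'reporting.R'
    'cli.R'
    'volume-io.R'
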