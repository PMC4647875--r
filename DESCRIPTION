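Package: hypoxica
Title: Decomposition of Tumour R2* Time Series into Systemic and
    Tumour-Specific Oxygenation Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates spontaneous fluctuations in voxel-wise tumour R2*
    (BOLD MRI) time series into systemic and tumour-specific sources of
    oxygenation variation, using a concurrently recorded systemic arterial
    oxygen-saturation trace. Implements PCA dimensionality reduction with
    scree-shoulder eigenvector selection, spatial independent component
    analysis (X = M S), component classification by O2sat correlation,
    dominant-frequency and z-thresholded spatial-cluster criteria,
    class-wise reconstruction and voxel thresholding, frequency-domain
    summaries, exact small-sample nonparametric tests, a seeded synthetic
    phantom generator with ground-truth labels, and quantification of
    fluorescence coverage on histology sections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    ica,
    igraph,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    EBImage,
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
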