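Package: sgcquant
Title: Quantification of Anti-Satellite-Glia-Cell IgG Binding from
    Immunofluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based quantification of serum IgG binding to satellite
    glia cells (SGCs) and sensory neurons, and the downstream patient
    stratification analysis used in fibromyalgia autoantibody studies.
    Provides an experiment-wide intensity threshold (mean + 8 SD of the
    pooled pixel population), per-cell suprathreshold area and integrated
    density inside externally supplied or baseline-segmented cell masks,
    positivity calling, per-sample summaries (percent IgG-positive SGCs,
    mean integrated density), dorsal-root-ganglion tissue object
    classification (SGC, neuronal soma, axon, other) with
    background-normalized intensity and slide-weighted donor averaging,
    pressure-pain-threshold and conditioned-pain-modulation scores,
    rank-based and parametric group comparisons with Dunn and Tukey post
    hoc tests, significance-masked Spearman correlation matrices, k-means
    severity clustering, paired donor tests, ELISA plate-effect
    correction, and a synthetic-data module that generates fluorescence
    images, tissue sections, and phenotyped cohorts with full ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
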