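Package: casync
Title: Spontaneous Activity Analysis for Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spontaneous neuronal activity recorded with
    two-photon calcium imaging of genetically encoded indicators (GCaMP6f).
    Provides robust baseline correction of dF/F traces, calcium transient
    detection, estimation of the unitary (single-spike) calcium kernel by
    fitting a difference-of-exponentials alpha function, exact model-based
    spike deconvolution, segmentation of population activity into alternating
    high/low states from the bimodal activity density, detection of
    significant synchrony peaks against a circular-shift surrogate null, and
    nonparametric group statistics (Kruskal-Wallis with Dunn-Holm post hoc,
    Welch's ANOVA). Includes a ground-truthed synthetic population simulator
    with presets emulating sham and amyloid-pathology activity regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
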