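Package: thyrovasc
Title: Quantitative Regional Vascularity Analysis of Thyroid Nodule Doppler Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies thyroid nodule vascularity on colour Doppler ultrasound
    still images. Partitions a nodule region of interest into central and
    peripheral regions by an offsetting principle (default offset 22% of the
    maximum inscribed distance), counts colour (Doppler-signal) pixels to form
    regional vascularity indices (VI), classifies nodules by the ratio
    vascularity index (RVI, peripheral VI over central VI), applies rule-based
    EU TIRADS grey-scale categorisation with configurable cut-offs, and
    evaluates sole and combined classifiers with exact binomial confidence
    intervals, single-operating-point AUROC, McNemar, Cochran Q, Cohen's kappa
    and related tests. Includes a synthetic Doppler phantom and cohort
    generator with exact colour-pixel ground truth so the whole pipeline is
    testable without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    png,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
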