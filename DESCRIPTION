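Package: rnacap
Title: Candidate RNA-Binding Protein Scoring for Oligonucleotide-Capture
    Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for RNA antisense-capture / mass-spectrometry
    experiments that identify proteins associated with specific mRNAs.
    Implements control-referenced spectral-count enrichment scoring with
    explicit zero-handling and strict exclusion, selection and highlight
    thresholds; delta-delta-Cq quantification of mRNA capture efficiency and
    specificity with standard-curve diagnostics; polysome-gradient fraction
    distributions and pooled translational-state summaries; and a
    negative-binomial synthetic-data generator with planted ground truth for
    end-to-end benchmarking of candidate detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
VignetteBuilder: knitr
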