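Package: coldribo
Title: Ribosome Complex Quantification and Riboproteome Analysis for Cold
    Acclimation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of plant ribosome biogenesis during cold
    acclimation. Implements sucrose density gradient absorbance-trace
    quantification (blank subtraction, valley-based peak segmentation,
    trapezoidal integration, log2 fold changes of ribosome complex
    abundances, inter-complex correlation, KCl-sensitivity of monosomes),
    compositional analysis of fraction-wise label-free quantification (LFQ)
    riboproteomes of non-translating 40S and 60S fractions (fraction
    identity assignment from ribosomal-protein class sums and pre-60S
    markers, normalization to ribosomal-protein reference sums,
    abundance-maximum filtering, presence/absence and fold-change calling,
    shared-change selection across paired experiments), and transcriptome
    statistics (quantile normalization, probe collapsing, Welch tests,
    two-factor ANOVA, parametric gene set enrichment with
    Benjamini-Hochberg FDR, and a constitutive-change screen). A synthetic
    data generator with planted ground truth makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    pracma,
    car,
    fgsea,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
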