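Package: laxipair
Title: Paired-Comparison Scaling of Facial Skin Laxity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying facial skin laxity from balanced
    two-alternative forced-choice (2-AFC) consumer perception experiments.
    Implements the binomial-approximation evaluator sample-size formula,
    balanced group/pair/presentation design with position swapping, logit
    quantification of pooled pair choices with boundary corrections,
    ridge-penalized Bradley-Terry scaling into a Facial Skin Laxity Index
    (FSLI), collinearity-screened support-vector regression linking the
    index to noninvasive skin physiological parameters with leave-one-out
    validation, and normality-gated paired pre/post efficacy tests. A
    synthetic-data generator reproduces the statistical structure of such
    studies so the whole pipeline is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
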