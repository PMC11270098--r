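Package: dshapr
Title: Deep SHAP Attribution and Expert-Benchmark Validation for EHR Mortality Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for explaining deep visit-sequence mortality models built on
    electronic-health-record diagnosis codes. Implements a from-scratch deep
    attribution engine (DeepLIFT-rescale multipliers with an exact Shapley
    enumeration oracle), aggregation of unit-level attributions into
    diagnosis-code-level current and historical impacts, high/low impact
    segmentation, and importance statistics (count-high, count-low, high-ratio,
    low-ratio, importance) benchmarked against ordinal expert annotations.
    Includes a synthetic in-hospital-cardiac-arrest cohort generator with
    controllable diagnosis prevalences, code-mortality effects and within-visit
    comorbidity co-occurrence, so the whole pipeline runs without restricted
    claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
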