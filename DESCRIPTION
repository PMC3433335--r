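Package: npascore
Title: Network Perturbation Amplitude Scoring of Causal Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies treatment-induced perturbation of biological
    processes described by signed causal network models ("HYPs": an
    upstream entity plus the signed set of downstream genes it regulates)
    from per-gene differential expression statistics. Implements the four
    Network Perturbation Amplitude scoring algorithms (Strength, Geometric
    Perturbation Index, Measured Abundance Signal Score, Expected
    Perturbation Index), companion Uncertainty statistics (analytic
    t-intervals with Welch-Satterthwaite effective degrees of freedom, and
    parametric bias-corrected percentile bootstrap intervals) and a
    cadre-matched permutation Specificity test, together with construction
    of an aggregated HYP from a causally consistent signed network, probe
    set collapsing rules, and a synthetic-data generator with known true
    perturbation amplitude for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'hyp.R'
    'network.R'
    'contrast.R'
    'scoring.R'
    'stats.R'
    'specificity.R'
    'synthetic.R'
    'cli.R'
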