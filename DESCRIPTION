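Package: parrot
Title: Prediction of Condition-Specific Enzyme Allocation in
    Protein-Constrained Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based prediction of per-enzyme abundance
    allocation for an alternative growth condition by minimizing the
    distance to a reference condition's allocation inside a
    protein-constrained metabolic model (the PARROT family of linear and
    quadratic programs). Includes import of GECKO-dialect SBML and a
    native toy-model format, integration and flexibilization of
    quantitative proteomics, norm-minimal baseline construction,
    parsimonious-FBA benchmarks and a kcat null model, an evaluation
    stack (log10 Pearson, root-median-square error, pairwise Wilcoxon
    with Bonferroni correction, lambda sweeps), and a seeded generator
    of toy protein-constrained models with planted allocations for
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    boot,
    quadprog,
    jsonlite,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: python3 with numpy and scipy (independent
    optimization oracle used by the test suite)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
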