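Package: metsel
Title: Multi-Trait Genotype-Ideotype Distance Selection for Multi-Environment Maize Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Mixed-model analysis of multi-environment plant breeding trials run
    under contrasting soil-moisture regimes (optimal, managed drought, managed
    waterlogging), and multi-trait genotype selection with the
    genotype-ideotype distance index (MGIDI).  Variance components are
    estimated per trait and regime by EM-REML with genotype,
    genotype-by-environment and incomplete-block random effects; the package
    reports genotypic-mean heritability, selection accuracy, likelihood-ratio
    tests and BLUP-based genotype means, genetic correlations among traits,
    and the full MGIDI chain (0-100 rescaling, exploratory factor analysis
    with varimax rotation, factor scores, ideotype distance, selection,
    per-factor strengths and weaknesses, and selection gains).  A synthetic
    alpha-lattice trial generator with factor-structured genetic correlations
    makes every stage testable without field data, and field helpers compute
    growing degree days and moisture-standardized grain yield.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
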