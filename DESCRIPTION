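Package: wmama
Title: Ancestral Paternal Age, Mutation Load and Fitness in Multi-Generation Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the fitness consequences of advanced paternal
    age accumulated over several ancestral generations. Implements the weighted
    mean age of male ancestors (WMAMA), a relatedness-weighted summary of the
    ages at which a proband's father, grandfathers and great-grandfathers
    fathered the proband's lineage; pedigree file input/output, validation and
    male-lineage traversal; cohort construction under demographic eligibility
    filters; a deterministic mutational-load calculus linking deleterious
    mutation rates and selection coefficients to per-generation fitness
    reduction; a forward-time simulator of monogamous pedigrees in which
    paternal-age-dependent de novo mutations are transmitted with Mendelian
    halving and penalize survival and marriage; and maximum-likelihood
    regression analyses of four fitness components (survival to 15, adult
    longevity, marriage, lifetime breeding success) with cluster-robust and
    permutation inference, discrete-time hazard modelling, AIC-based
    interaction screening, and translation of fitted coefficients into
    predicted outcome declines between ancestral ages 30 and 40.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    readr,
    rlang,
    sandwich,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
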