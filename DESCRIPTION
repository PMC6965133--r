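Package: asvdecon
Title: Control-Informed Decontamination and Maternal-Source Analysis of
    16S rRNA ASV Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Removes probable reagent and environmental contaminants from
    low-biomass 16S rRNA amplicon sequence variant (ASV) count tables using
    a per-sample-group dual criterion on prevalence and mean relative
    abundance versus instrument and field negative controls. Includes
    taxonomy-based prefiltering, read-depth sample exclusion, dam-foal
    ASV-sharing and Venn-partition analyses, Shannon diversity, a
    nonparametric test battery (Kruskal-Wallis and Friedman omnibus tests
    with Nemenyi all-pairs post-hoc procedures, Mann-Whitney, Spearman),
    and a synthetic-data generator that emulates a mare-foal neonatal
    microbiota study design with known contamination ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    jsonlite,
    yaml,
    generics,
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
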