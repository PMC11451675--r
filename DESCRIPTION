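Package: parGWAS
Title: Cross-Ancestry Population Attributable Risk from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the population attributable risk (PAR) of common
    disease-associated variants from per-ancestry genome-wide association
    study (GWAS) summary statistics. Provides risk-allele harmonization
    (protective effects are allele-flipped and their frequencies
    complemented), nominal-significance filtering and per-locus lead-variant
    selection with user-declared proxy substitution, Levin's attributable
    risk formula on risk allele frequency and odds ratio, single-causal
    variant fine-mapping with Wakefield approximate Bayes factors, dense
    cross-ancestry ranking and universal/population-enriched locus
    classification, bubble-plot visualisation, and a case-control summary
    statistics simulator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
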