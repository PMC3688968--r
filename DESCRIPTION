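Package: interolog
Title: Cross-Species Protein Interaction Transfer with Random-Forest Confidence Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transfers protein-protein interactions between species over scored
    ortholog mappings (interolog transfer) and scores each transferred
    interaction with a Random-Forest-Filter trained on a rich feature set:
    Resnik GO semantic similarities, network neighborhood overlap, ortholog
    quality scores, sequence, token, domain and pathway similarities,
    phylogenetic and transitive-orthology features. Includes readers for
    tab-separated interaction and ortholog tables, OBO ontologies and Newick
    trees, precision/relative-recall evaluation with Davis-Goadrich AUPRC and
    rank-based AUROC, Information-Gain feature ranking, and a synthetic
    multi-species world generator with planted interaction conservation for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
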