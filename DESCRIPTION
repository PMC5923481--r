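Package: repchimera
Title: Detection of Chimeric Two-Domain Replication Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect chimeric (recombinant) two-domain replication
    proteins such as the Reps of circular Rep-encoding single-stranded (CRESS)
    DNA viruses. The full-length protein alignment is split into the N-terminal
    HUH endonuclease and C-terminal superfamily 3 helicase domains at the
    Walker A motif; domain co-evolution is then scored two complementary ways,
    a hit-set overlap ("connectedness") statistic from all-against-all
    similarity searches, and per-leaf incongruence between the two domain
    phylogenies. Sequences whose domains evolve incongruently are purged and
    supported monophyletic groups are recovered from the purged full-length
    tree. A synthetic-data generator produces two-domain protein families with
    planted domain swaps so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
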