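Package: coexscreen
Title: Cross-Cohort Seed-Gene Co-Expression Consensus Screening
Version: 0.1.0
Authors@R:
    person("Seville", "Bioinformatics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for screening many expression cohorts for genes
    co-expressed with a single seed gene and for building a cross-cohort
    consensus of the hits. Each cohort is correlated gene-by-gene against
    the seed, significant genes are split by correlation sign, per-group
    recurrence cutoffs select genes that replicate across a group's
    cohorts, and recurrent lists are intersected across condition groups
    with full Venn region decomposition. Also provides hypergeometric
    fold-enrichment scoring against user-supplied gene-set collections,
    seed-high/low stratified differential testing, and a synthetic
    multi-cohort generator with planted co-expression modules for
    end-to-end validation of the screen.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
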