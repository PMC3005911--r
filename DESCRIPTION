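Package: aaflux
Title: Parsimony-Polarized Amino Acid Substitutions in Gene Family
    Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts per-family protein multiple alignments and rooted
    gene trees into a relational database of parsimony-polarized amino
    acid substitutions, and computes genome-wide descriptors of protein
    evolution: per-amino-acid flux (net relative gain D), substitution
    radicality (absolute polarity change and exchangeability), Ka/Ks
    partitioned by gene-duplication status, and asymmetry tests between
    the two clades descending from each duplication with false discovery
    rate and Bonferroni control. Duplications are inferred by LCA
    reconciliation of gene trees against a species tree; substitutions
    are polarized by analysis of most-parsimonious reconstructions
    (Fitch parsimony) with explicit unambiguous/ambiguous bookkeeping.
    Includes a sequence-evolution simulator with known duplication
    histories and a ground-truth event log for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    DBI,
    RSQLite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
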