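Package: dynasel
Title: Selection and Turnover Analysis for Dynamically Evolving Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Codon-aware McDonald-Kreitman tests on population samples of
    protein-coding alignments, including minor-allele-frequency filtering,
    outgroup polarization of fixed differences, per-domain analysis,
    neutrality indices and the associated contingency statistics; gene-set
    association tests linking evolutionary attributes (positive selection,
    conservation) to phenotype categories such as essentiality; gene age and
    loss inference from ortholog presence/absence on a dated species tree
    under Dollo parsimony; construction of concatenated per-repeat-type
    expression references from RepeatMasker annotations; and a synthetic-data
    generator that plants substitutions and polymorphisms with a ground-truth
    ledger so every stage of the analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
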