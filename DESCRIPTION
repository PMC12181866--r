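Package: varconcord
Title: Concordance of Variant Annotations and Its Impact on ACMG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking the concordance of clinical variant
    annotations across annotation tools. Reads ClinVar-style VCFs and the
    output dialects of common annotators (SnpEff ANN, VEP CSQ, ANNOVAR
    multianno tables) into a common model; curates variants with the usual
    stringent filters (indel size, review stars, significance, molecular
    consequence); normalizes consequence vocabularies onto Sequence Ontology
    terms with most-severe prioritization; parses and compares HGVS coding
    and protein descriptions, recognizing equivalent but non-preferred
    syntax (one- vs three-letter amino acids, Ter/X/*, dup vs ins, 3' rule
    shifting against a transcript); aggregates match fractions, mismatch
    causes, and three-way Venn partitions; evaluates a modified ACMG/AMP
    2015 rule-combining engine with automated PVS1 from loss-of-function
    calls; and quantifies how discordant annotations flip PVS1 and the final
    five-tier classification. A ground-truthed simulator generates variants,
    corrupted per-tool annotations, and evidence features so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
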