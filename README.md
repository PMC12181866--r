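# varconcord

Clinical variant interpretation leans on three things that different
annotation tools routinely disagree about: which transcript a variant is
described on, how its HGVS coding/protein name is spelled, and which
Sequence Ontology (SO) consequence it is assigned. The disagreements are
not cosmetic — the loss-of-function (LoF) category drives the
heaviest-weighted ACMG/AMP criterion (PVS1), so a variant called
`stop_gained` by one tool and `missense_variant` by another can come out
of an automated classifier as Likely pathogenic or as VUS depending on
which annotation you believed.

`varconcord` is an R toolkit for quantifying exactly that, aimed at people
who benchmark or maintain clinical annotation pipelines. It provides:

* **Dialect readers** for ClinVar-style VCF INFO (`CLNSIG`, `CLNREVSTAT`,
  `MC`), SnpEff `ANN`, VEP `CSQ` (header-driven field order, `%3D`
  decoding) and ANNOVAR multianno tables, all landing in one flat
  annotation model, plus writers that round-trip each dialect.
* **Curation** reproducing the usual stringent test-set filters — indels
  under 50 bp, review status ≥ 2 stars, no VUS/conflicting records, no
  mitochondrial variants, molecular consequence present and unambiguous —
  with first-failing-filter attribution, and VCF-style allele
  normalization (parsimony + left alignment).
* **SO normalization**: per-tool vocabularies (`stopgain`,
  `frameshift deletion`, ...) mapped to canonical SO terms, a strict
  severity order for most-severe prioritization, and the ACMG-facing
  functional categories LoF / Missense / ProteinLengthChange /
  Synonymous / Other.
* **An HGVS engine**: parser for coding and protein descriptions
  (intron offsets, UTR positions, one- and three-letter amino acids,
  `Ter`/`X`/`*`, short and long frameshifts, repeat `unit[N]` tokens),
  protein canonicalization (`p.Q480X` → `p.Gln480Ter`,
  `p.Val17Val` → `p.Val17=`), edit application to a transcript sequence,
  3′-rule shifting with dup-over-ins preference, and a three-level
  comparator (`strict` string identity, `canonical` notation rules,
  `full` sequence-aware equivalence).
* **Concordance accounting**: per-tool match fractions with
  mismatch-cause breakdowns (missing annotation / position-or-type /
  non-preferred syntax / unknown), stratification, and three-way Venn
  partitions over (variant, transcript, value) tuples.
* **A modified ACMG/AMP 2015 engine**: PVS1 fired directly from the LoF
  category, PP3 suppressed under PVS1, CADD thresholds 25.3 / 22.7 and
  SpliceAI 0.5 for PP3/BP4, PP5/BP6 strength scaled by review stars,
  cohort/phasing criteria excluded, and the published rule-combining
  table producing B / LB / VUS / LP / P.
* **Delta analysis**: PVS1 loss/gain from category discordance, and
  reclassification direction (upgraded / unchanged / downgraded) when the
  same evidence is re-combined under each tool's category.
* **A ground-truthed simulator** that generates variants on synthetic
  transcript windows with planted repeat runs, emits a ClinVar-style
  reference plus three per-tool corrupted annotation sets (missingness,
  transcript unavailability, non-preferred-syntax substitution, version
  stripping, consequence confusion), and carries exact closed-form
  expectations for every pipeline metric.

## A worked example

Simulate a 300-variant benchmark, push it through the full comparison, and
look at the headline tables:

```r
library(varconcord)

sim <- simulate_dataset(sim_config(n_variants = 300, seed = 42))
res <- compare_annotations(sim$reference, sim$tool_annotations,
                           sim$transcripts)
rep <- concordance_report(res, sim$tool_annotations)
print(rep$fractions, digits = 3)
#>   metric    tool   n fraction fraction_strict
#> 1  hgvsc annovar 300    0.867           0.843
#> 2  hgvsc  snpeff 300    0.963           0.950
#> 3  hgvsc     vep 300    0.980           0.973
#> 4  hgvsp annovar 178    0.888           0.742
#> 5  hgvsp  snpeff 178    0.972           0.860
#> 6  hgvsp     vep 178    0.978           0.938
#> 7 impact annovar 300    0.863           0.863
#> 8 impact  snpeff 300    0.953           0.953
#> 9 impact     vep 300    0.977           0.977
```

`fraction` treats recognized equivalent syntax as a match; under
`fraction_strict` only byte-identical strings count, so the gap between
the two columns is the non-preferred-syntax burden (largest for the
protein column, where one-letter codes, `X`-for-`Ter` and short
frameshifts are common). `n` is the number of comparable reference
entries — missing tool annotations stay in the denominator and count
against the tool.

Equivalence is sequence-aware when a transcript is available:

```r
compare_hgvs("c.5824_5825insC", "c.5824dup",
             tm = transcript_model("toy",
                                   paste0(strrep("G", 5822), "TC", "AAA")),
             level = "full")
#>      verdict         cause detail
#> 1 equivalent non_preferred
```

And the ACMG engine shows why the LoF category matters:

```r
out <- classify_acmg(list(functional_category = "LoF", cadd = 33.1,
                          spliceai_max = NA, clinvar_class = "P",
                          stars = 2))
out$class
#> [1] "LP"
out$applied
#>   criterion    strength  direction
#> 1      PVS1 very_strong pathogenic
#> 2       PP5    moderate pathogenic
```

Re-run `classify_acmg` with `functional_category = "Missense"` (the same
variant as a discordant tool saw it) and the class drops to VUS: a
downgrade caused purely by annotation disagreement. `reclassify_delta()`
does this systematically and `summarize_deltas()` tabulates the
direction counts.

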