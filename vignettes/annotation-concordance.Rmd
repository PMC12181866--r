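---
title: "Measuring annotation concordance and its ACMG consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring annotation concordance and its ACMG consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varconcord)
```

## The problem and the pipeline

A clinical variant reaches an interpretation through a chain of
representational choices: which transcript it is described on, how its
HGVS coding (`c.`) and protein (`p.`) names are written, and which
Sequence Ontology (SO) consequence term it receives. Annotation tools
make these choices differently, and automated ACMG/AMP classification is
sensitive to them — most acutely through PVS1, the very-strong pathogenic
criterion triggered by the loss-of-function (LoF) category (frameshift,
splice donor, splice acceptor, nonsense).

`varconcord` measures this sensitivity as a pipeline with well-separated
stages: read each tool's output dialect into one annotation model; curate
the reference set; normalize consequence vocabularies; judge HGVS
equivalence; aggregate concordance; classify under a modified 2015 ACMG
rule set; and difference the classifications. Every stage is exercised by
a ground-truthed simulator, so the package's correctness claims rest on
recovering known answers rather than on fixtures.

## Curation

The reference set is curated the way clinical concordance test sets
usually are. Records pass, in order: indel size (length difference at
most `max_indel_len = 49` bases, i.e. indels of 50 bp and larger are
excluded as structural), review stars (`min_stars = 2`), significance
class (VUS, conflicting and other assertions excluded), chromosome
(mitochondrial variants excluded, since their transcripts and ACMG rules
differ), molecular-consequence presence, and MC uniqueness per transcript
(multi-term records are ambiguous for category assignment and are
dropped rather than guessed at). Exclusions are attributed to the first
failing filter; the retained set is identical under any filter order, and
the attribution order is fixed so summaries are reproducible.

Allele normalization trims shared suffix then prefix (keeping one base
each side, VCF-style) and left-aligns indels against a reference context
when one is supplied. The 50 bp rule is applied after normalization and
reads "indel length" as `max(len(ref), len(alt)) - 1`, the usual
small-variant/SV boundary. De-duplication is by exact
(chrom, pos, ref, alt) after normalization, keeping the first record.

## SO normalization and severity

Each tool's raw vocabulary is mapped to a single canonical term set by a
synonym table shipped as editable TSVs (`inst/extdata/so_synonyms.tsv`,
`so_severity.tsv`); canonical terms pass through unchanged for every
tool, unknown terms map to an explicit `"unmapped"` sentinel and are
counted, never dropped. The severity order is the published Ensembl/VEP
consequence ranking — a strict total order, so most-severe selection
needs no tie-break rule. Both files are data, not code, precisely so a
different ranking or synonym set can be slotted in without touching the
package.

Two mapping decisions are worth calling out. `start_lost` sits in the
ProteinLengthChange category (with the inframe indels and stop-loss), not
in LoF, although some classifiers treat initiator-codon loss as LoF; the
category lists here follow the ACMG-facing grouping where PVS1 is
reserved for frameshift/splice-site/nonsense. Second, the ClinVar MC term
`inframe_indel` is folded into canonical `inframe_deletion`: both land in
ProteinLengthChange, and keeping the canonical vocabulary strictly
Ensembl's buys a clean severity order at the cost of not distinguishing
the two in reports.

## HGVS equivalence

The comparator judges a query against a reference at three levels:

* `strict` — byte identity after whitespace removal.
* `canonical` — notation-level rules that need no sequence: one- vs
  three-letter amino-acid codes, `Ter`/`X`/`*` stops, `p.Val17=` vs
  `p.Val17Val`, short-form frameshifts (`p.Arg1942fs` matches any
  `p.Arg1942XxxfsTerN`, because the short form withholds information
  rather than contradicting it; two *long* forms that disagree in the
  new residue or the stop offset are position/type mismatches), and
  dup-vs-ins when the insertion site is immediately 3′ of the duplicated
  interval *and* both alleles are spelled out.
* `full` — additionally sequence-aware, given a transcript model:
  descriptions are normalized by maximal 3′ shifting (`shift3()`), with
  insertions that complete a repeat rewritten as duplications, and
  compared as normal forms; if that is inconclusive both descriptions are
  applied to the sequence (`apply_edit()`) and the edited sequences
  compared. `apply_edit` is also the package's independent oracle: two
  descriptions denote the same variant iff they edit the transcript into
  the same string.

Missing queries are verdict `missing` (cause `missing_na`) and stay in
every denominator — a tool that says nothing is wrong, not excused.
Unparseable queries are `mismatch`/`unknown`, the residual cause class.
Equivalent-but-not-exact verdicts all carry cause `non_preferred`: the
pair denotes one variant spelled two ways, and which side deviates from
the preferred spelling is reported in `detail` rather than split into
separate causes. Accession comparison is version-blind by default because
ANNOVAR output carries no transcript versions; a versionless accession
never contradicts a versioned one even under strict comparison.

Repeat notation (`c.53AGC[23]`) parses but never judges equivalent below
`full`: rewriting repeat counts into dup/ins coordinates without a
sequence invites false equivalences, and repeat notation's place in the
HGVS preference hierarchy is genuinely unsettled.

Protein-level comparison is notation-level only (`canonical`), even when
a transcript is supplied: recomputing a frameshift's downstream protein
consequence from cDNA would need CDS translation machinery that is out of
scope here, and none of the package's accounting requires it.

## The ACMG engine

Criteria are evaluated from per-variant evidence with the modifications
an automated platform needs to run unattended:

| knob | default | why |
|---|---|---|
| PVS1 | fires iff category = LoF | the automation under study |
| PP3 | CADD ≥ 25.3 or SpliceAI ≥ 0.5; suppressed under PVS1 | avoids double-counting the LoF call |
| BP4 | CADD < 22.7 and no splice signal | calibrated benign computational band |
| PP5 | P/LP assertion; moderate at 2★, very strong at ≥3★ | reputable-source evidence scaled by review confidence |
| BP6 | B/LB assertion; strong at 2★, very strong at ≥3★ | benign counterpart |
| PM4 | category = ProteinLengthChange | stop-loss/inframe length change |
| BP7 | category = Synonymous and no splice signal | silent with no predicted splice impact |
| disabled | PS4, PM3, PP4, BP2, BP5 | need cohort, phasing or gene–disease data |

CADD is on the PHRED-like scale; SpliceAI thresholds are delta-score
maxima in [0, 1]; stars are ClinVar review tiers 0–4. Thresholds are
inclusive at the pathogenic bound (≥ 25.3, ≥ 0.5) and exclusive at the
benign bound (< 22.7), and boundary behaviour is pinned by tests at
±1e−9. All other criteria (PS1, PM2, ...) are pass-through input flags:
no hidden evaluators are invented for evidence the package cannot
actually compute.

Combination implements the published 2015 table over strength counts,
pathogenic and benign sides independently; both sides met, or neither,
yields VUS. Two combinations the 2015 table never anticipated need local
decisions: a *second* pathogenic very-strong (possible once PP5 is
promoted at ≥3 stars) is weighed as a strong — so two very-strongs
classify Pathogenic, mirroring how the table weighs 1 VS + 1 S — and one
*benign* very-strong (BP6 at ≥3 stars) suffices for Benign, mirroring the
pathogenic side's weighting; both are configurable. A lone very-strong
criterion with no supporting evidence remains VUS, exactly as the table
is written — this engine deliberately does not adopt the later
recommendation of treating PVS1 alone as Likely pathogenic.

The engine is verified by exhaustive enumeration: all 4,096 subsets of a
12-criterion pool (twice — default strengths and star-promoted
strengths) against an independently written transcription of the table.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` draws, per variant: a significance class from the
composition of a curated two-star clinical set (23.3% P, 3.7% LP, 34.7%
B, 38.4% LB); a consequence term from a class-conditional mix in which
the P/LP mass is far richer in LoF and indel consequences than the B/LB
mass; a synthetic transcript window of 60–300 nt with a planted
homopolymer run of 6–9 bases (so 3′ shifting, dup/ins preference and
left/right placement are really exercised — the run boundary is guarded
so the planted run is maximal); a preferred HGVSc generated from an
actual edit on that window (indels are planted inside the run, so a
shifted non-preferred spelling always exists for them); a formulaic
preferred HGVSp; review stars (90/9/1% for 2/3/4★); class-conditional
CADD (normal, mean 30 sd 4 for P/LP truth, mean 12 sd 5 for B/LB,
truncated at 0 — arbitrary but chosen to exercise both the PP3 and BP4
thresholds); and SpliceAI high (0.6–1) only for splice-site truth.

Each "tool" then corrupts independently through labelled channels:
missingness (no annotation), transcript unavailability (the annotation
lands on a different accession, which version-blind matching correctly
scores as missing), non-preferred-syntax substitution (drawn uniformly
from the known equivalent-form set: one-letter codes, `X`-for-`Ter`,
`Val17Val`, short frameshift, left-shifted placement, ins-for-dup),
consequence confusion to a designated neighbouring term, and — for the
ANNOVAR-style tool — version stripping. The default per-tool rates
(missing 8/2/1%, non-preferred 15/10/5%, transcript-absent 5/2/1%,
confusion 2/1.5/1% for the ANNOVAR/SnpEff/VEP-style tools) encode the
qualitative ordering seen in real benchmarks — the versionless,
oldest-transcript-set tool worst, VEP best — at rates large enough to
measure at n = 2,000. The confusion neighbour map keeps one within-LoF
edge (nonsense confused to frameshift), so category-preserving term swaps
occur alongside PVS1-losing ones, as they do in real output.

Two deliberate simplifications keep every metric in closed form
(`expected_metrics()`): corruption channels are orthogonal (confusion
never rewrites the HGVS strings; non-preferred substitution never touches
the term), and HGVSp truth is generated formulaically per term rather
than by translating the synthetic cDNA. Consequently passing the
end-to-end recovery tests shows the pipeline measures what the generator
planted — parsing, matching, equivalence resolution, category accounting
and the PVS1/classification deltas are correct — but says nothing about
biological realism of the joint (HGVSc, HGVSp) distribution, about
genomic-to-cDNA projection across exons (single-window transcripts only),
or about real tools' correlated failure modes.

## Numerical and degenerate-input choices

Probability vectors are validated to sum to 1 within 1e−9. Fractions are
reported to 4 decimals and percentages to 2. Strata with empty
denominators are absent from reports, not zero. `match_fraction` refuses
an empty reference outright. Unknown stratum labels group under
`"other"`. The simulator is deterministic given (config, seed), including
byte-identical files. Test problem sizes — 1,000-case HGVS fuzz, 4,096 ×
2 ACMG subsets, a 3 × 3 corruption grid at n = 2,000 with five seeds —
were chosen as the smallest sizes at which binomial 3-standard-deviation
recovery bands are meaningfully tight.

## Known limitations

Genomic (`g.`) descriptions are carried but not normalized beyond allele
normalization; there is no liftover and no GRCh37 support. Inversions and
`ext` semantics parse and apply but get no special equivalence handling.
The ANNOVAR reader targets the tab-delimited multianno layout (its VCF
output mode differs) and takes the table's coordinates as given. Repeat
`[N]` notation is recognized but never canonicalized. The engine's
pass-through criteria mean classification deltas reflect only what the
consequence change moves (PVS1, PM4, BP7, PP3/BP4 interplay), which is
the quantity of interest here, not a complete clinical classifier.
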