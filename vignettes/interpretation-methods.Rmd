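---
title: "Methods: rule-based interpretation of cancer gene variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based interpretation of cancer gene variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoboard)
```

## Overview

`oncoboard` separates cancer variant interpretation into an allele-centric
layer (is this change functionally relevant at all?) and a context-dependent
layer (what does it mean for this patient?). This vignette documents the
model behind each rule, the tunable parameters with their defaults and
rationale, the numerical and design choices made where several readings were
defensible, what the synthetic fixtures do and do not emulate, and the known
limitations.

## Variant normalization

All accepted syntaxes — VCF records, genomic (`g.`), cDNA (`c.`, with
intronic offsets) and protein (`p.`) HGVS-style expressions — are reduced to
one canonical representation per allele:

- alleles are trimmed of shared prefix/suffix context;
- pure insertions/deletions are **left-aligned on the genome** (VCF
  convention), which defines the `variant_key` used by all lookups;
- the same indel is **3'-shifted along the transcript strand** before cDNA
  naming, matching HGVS convention. The two shifts serve different masters on
  purpose: lookup keys must match VCF-normalized score and frequency tables,
  names must match how curators write variants.

Protein-level inputs (`p.V600E`) are resolved to a nucleotide change by a
deterministic scan of the codon for the first single-base substitution
producing the target amino acid; expressions with no single-base realization
are rejected with instructions to supply a nucleotide-level form. Exact-change
knowledge entries authored at protein level are matched at protein level, so
alleles curated as `p.V600E` in one source and `c.1799T>A` in another share a
key either way.

Coordinates are 1-based and closed throughout; protein positions are 1-based
amino acids. Classification always uses the gene's designated canonical
transcript: one call per variant.

## Consequence model

Coding effects are computed by editing the spliced transcript sequence and
re-translating from the CDS start through the 3' UTR. Consequently frameshift
premature termination codons (PTCs) are found by conceptual translation, not
heuristics; when no downstream stop exists before the transcript end, the
frameshift start codon stands in as the effective truncation point (the
lesion removes at least everything downstream of it).

Splice classification uses intronic distance to the nearest exon boundary:
positions ±1–2 are canonical sites, ±3–8 the splice region. Only canonical
sites ever satisfy the PVS1-style rule below; splice-region variants never
do. Deletions straddling an exon/intron boundary, and insertions landing
exactly on one, are treated as canonical-site disruptions.

**NMD (50-nt rule).** A PTC is predicted to trigger nonsense-mediated decay
when the *first base of the stop codon* lies strictly more than 50 nt
upstream of the last exon–exon junction of a multi-exon transcript, measured
in spliced-transcript coordinates on the *mutant* transcript (junction
positions downstream of an indel are shifted by its length). Single-exon
transcripts and last-exon PTCs always escape. Measuring from the first stop
base keeps the stated 30-nt-escape / 60-nt-trigger behavior unambiguous.

**Truncated fraction.** For PTC variants,
`(protein_length − ptc_codon + 1) / protein_length`; for canonical splice
disruptions, the fraction of the coding sequence downstream of the affected
junction. The >10% rule is a strict inequality: losing exactly the final 10%
of the protein does not fire it.

## The classification cascade

Pre-filter first: common polymorphisms (max population AF ≥ 1%, `≥` by
design so a threshold set at an observed frequency includes it) and
synonymous variants are labelled functionally neutral up front and excluded
from the relevant/unknown accounting. These assumed-neutral calls need a tier
for bookkeeping: common polymorphisms carry tier A (their evidence *is* the
population knowledge bases) and silent variants tier B (a biological
assumption), both at strength "strong". The pre-filter outranks everything —
a common polymorphism with a deleterious computational score stays neutral.

Then strict precedence A > B > C; the first conclusive verdict wins and later
tiers are never consulted:

| Tier | Rule | Strength |
|---|---|---|
| A | usable assertions agree: functional | very strong |
| A | usable assertions agree: neutral | very strong |
| B | canonical splice disruption (TSG) | very strong (PVS1) |
| B | NMD-triggering PTC (TSG) | very strong (PVS1) |
| B | truncation within a critical region (TSG) | strong (PVS1_Strong) |
| B | truncation of > 10% of the protein (TSG) | strong (PVS1_Strong) |
| C | significant mutation hotspot (p < 0.05) | strong |
| C | missense in TSG, CADD Phred > 30 / < 10 | strong |

Anything else is *unknown relevance*. Criteria codes are cumulative within a
tier (a critical-region truncation that also removes >10% carries both
PVS1_Strong codes) but strength is the maximum, with PVS1 outranking
PVS1_Strong.

Design choices worth stating explicitly:

- **Evidence B is restricted to tumor-suppressor and dual-mechanism genes.**
  There is no bona fide null-variant argument for activation; activating
  calls require curated assertions or hotspot evidence.
- **Conflicting usable assertions are inconclusive**, not tie-broken: the
  cascade proceeds to tier B with a `CONFLICT` flag surfaced in the report.
- **Hotspots are checked before CADD** within tier C, and CADD applies to
  missense variants in tumor suppressors only; there is no in-frame-indel
  CADD rule. Hotspot records are class-specific (missense vs in-frame indel).
- **Tier-A strength** is "very strong" for every usable-assertion verdict,
  with the matched record count surfaced so reviewers can weigh single-record
  calls; sources do not carry an explicit cross-source strength precedence.
- **Boundaries**: CADD thresholds are strict (`> 30`, `< 10`; exactly 30 or
  10 stays unknown); hotspot significance is strict (`p < 0.05`; exactly 0.05
  is not significant); the truncation rule is strict (`> 0.10`).
- **Critical regions** are inferred as the prefix interval `[1, L*]` where
  `L*` is the most C-terminal curated truncating loss-of-function position
  for the gene: a downstream PTC at or before a position already known to
  destroy function is deemed disruptive. The inference grows monotonically as
  curated knowledge accumulates and is unioned with any curated region on the
  gene record. This concrete rule is this package's own choice among several
  defensible refinements.
- **Allele-centricity is enforced structurally**: the cascade's inputs simply
  do not include cancer type, VAF, origin or zygosity, and a property test
  permutes them to confirm no effect.
- Functional-entity matching (e.g. "oncogenic mutations") is defined against
  the engine's own calls and therefore applies only to the biomarker layer;
  entity-style *assertions* cannot feed evidence A without circularity, so
  class-level knowledge is expressed as category assertions instead.

All thresholds — CADD 30/10, hotspot alpha 0.05, truncation 0.10, common-AF
0.01, rating minimums per source, the germline VAF windows, TMB cut-offs, the
NMD distance and the ESCAT matrix — live in `interpretation_config()` and are
overridable from the run-configuration file.

## Actionability layer

Biomarkers match by exact change, category predicate (consequence class, exon,
protein interval) or functional entity. The patient-vs-biomarker cancer-type
relation is resolved on a rooted ontology DAG: `same`, `patient_is_subtype`
(the biomarker's type is an ancestor of the patient's), or `other` — the
reverse direction deliberately counts as `other`, since evidence for a broad
disease does not automatically transfer to a sibling subtype. Off-tumor-type
matches are retained but flagged; they can only reach the lower tiers.

ESCAT tiers come from a configurable matrix over (evidence level × relation).
Defaults: approved/guideline evidence in the matching disease (or a subtype)
is tier I; investigational clinical evidence in the matching disease tier II;
clinical evidence in other tumor types, retrospective series and case reports
tier III; preclinical evidence tier IV. Cells the scale does not pin down
(approved × other-type, retrospective × matching) default to III, consistent
with off-label/weaker-evidence usage; case-report-only biomarkers at III is
the deliberate house modification. The matrix is monotone by construction and
a test sweeps the full domain.

Trial rules are ALL/ANY/NONE combinator trees over gene-alteration predicates
(loss/gain/switch-of-function mutations, amplifications, deletions) and
signature predicates (categorical TMB or numeric thresholds). Mutation
predicates require a functionally relevant call of the right direction whose
tier meets the rule's evidence floor — default tiers A and B only, so
computational-only calls never match a trial unless a rule carries an explicit
per-gene override (the mechanism for emerging biomarkers in less characterized
genes). `NONE` evaluates absence over the whole profile, which is what the
"high TMB without a DNA-repair explanation" arm needs. Firing rules are
ordered by their integer priority; the six fixture arms map printed order to
priorities 1–6. TMB categories default to low < 6 ≤ intermediate < 20 ≤ high
mut/Mb, a common panel convention, and are configurable. Resistance-
association biomarkers are reported but never drive recommendations.

Germline alerts fire for panel genes only, for loss-of-function calls at
tiers A or B only (never C — counseling referral requires curated or bona
fide evidence), with MUTYH restricted to homozygous or compound-heterozygous
carriers (two distinct qualifying germline variants in the gene count as
compound heterozygosity). With paired calling the recorded origin is
authoritative; in tumor-only mode a variant is germline-plausible when its
VAF falls in `[0.40, 0.60] ∪ [0.90, 1.00]` (configurable — the windows are a
convention, not a published constant), and such alerts carry an explicit
`inferred_vaf` origin marker rather than silently equal status. A missing VAF
in tumor-only mode yields an `indeterminate`-basis alert rather than
suppression. The converse case matters clinically: a true germline variant at
low tumor VAF (e.g. 0.12) is *missed* by tumor-only inference — the fixtures
plant exactly this scenario, and the cohort truth records it as a known miss
rather than an alert.

## Synthetic fixtures

The generators produce, from a seed: gene/transcript models (anchor genes
with realistic protein lengths, strand mix, 1–28 exons, forced structural
features — a junction at a known cDNA position, an exon spanning a known
window, long NMD-escaping last exons, fixed codons at famous residues, one
single-exon gene); knowledge tables planted so that every cascade branch,
every ESCAT cell, conflicting and sub-threshold assertion pairs, and boundary
values (Phred exactly 30/10, hotspot p exactly 0.05, AF exactly 0.01,
truncation exactly 0.10) are all reachable; and a patient cohort whose first
twenty members are engineered scenarios (one per trial arm including the
NONE-condition arm, MUTYH mono- and biallelic carriers, tumor-only
inferred-origin and missed-low-VAF germline cases) with the remainder drawn
randomly from the planted library. Every generated variant carries exactly
one truth record, and generation is a pure function of the seed
(hash-identical files on regeneration).

What the fixtures do **not** emulate: real cohort allele-frequency spectra,
gene-level mutation rates, or clinical covariates; real genome sequence (the
contigs are codon-consistent but arbitrary); licensed knowledge-base content.
Passing tests therefore demonstrate that the rules are implemented exactly
and deterministically — not that the thresholds are well calibrated on real
tumors, which depends on knowledge-base snapshots and benchmarking outside
this package's scope.

## Problem sizes and numerical choices

The test suite exercises the cascade against an independently coded flat
decision table over its full ~3,400-combination feature grid, the NMD rule
against a brute-force positional oracle on 1,200 random (transcript, PTC)
pairs, ontology relations against an igraph reachability oracle on 500 random
pairs over a 200-node random DAG, and an end-to-end 500-patient synthetic
cohort (the same size the acceptance script uses) with 100% planted-truth
recovery and byte-identical reruns modulo timestamps. These sizes were chosen
so the full suite completes in a few minutes on one CPU while still covering
every branch; all are trivially scalable through the generator arguments.

Degenerate inputs are defined: an empty variant set yields a valid report
with three empty tables; a variant outside every transcript, an unparseable
expression or an unknown gene is rejected naming the offending token; a
malformed VCF line aborts the whole run before any report is written (exit
code 3 from the CLI), and schema violations in resource files name the file,
line and field (exit code 2).

## Known limitations

- HGVS support is deliberately a well-tested subset (substitutions, del, ins,
  dup, delins, intronic offsets); no inversions, extensions, or uncertain
  ranges.
- One canonical transcript per gene; no multi-transcript reconciliation.
- Protein-level inputs requiring multi-base codon changes are rejected rather
  than guessed.
- The splice rule models canonical-site disruption as loss of the downstream
  junction's contribution; it does not model exon skipping vs intron
  retention explicitly.
- Copy-number events, structural variants and signatures are consumed as
  profile attributes for trial matching only; calling them is out of scope.
- No liftover: inputs must match the assembly of the transcript models.
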