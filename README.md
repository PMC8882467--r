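# oncoboard

Rule-based clinical interpretation of cancer gene variants, at desk scale.

Molecular tumor boards face two distinct questions about every variant found
in a tumor sequencing panel. First, the *allele-centric* question: does this
specific change disrupt (or activate) the wild-type function of the gene,
regardless of who carries it? Second, the *context-dependent* question: given
this patient's tumor type, the variant's origin and everything else in the
profile, what can be done about it? `oncoboard` implements both layers as an
explicit, configurable rule engine for single-nucleotide variants and small
indels, together with deterministic synthetic fixtures so the whole pipeline
runs and is testable with no external downloads or licensed database exports.

The package is written for bioinformaticians building or evaluating clinical
decision support for precision oncology: every rule is a documented function
over tidy data frames, and every threshold lives in one configuration object.

## The classification cascade

Variants are first normalized to one canonical representation (VCF records,
genomic/cDNA/protein HGVS-style text all converge; indels are left-aligned on
the genome and 3'-shifted on the transcript for naming). After a pre-filter
that sets aside assumed-neutral variants (silent changes away from splice
sites, common polymorphisms at max population AF >= 1%), each variant passes
through three evidence tiers with strict precedence — the first conclusive
verdict wins:

- **A — curated knowledge.** Assertions aggregated across knowledge bases
  (exact-change, or category-level such as "in-frame deletions in exon 19"),
  after source-native rating filters (ClinVar-style >= 2 stars, CIViC-style
  >= 3 stars). Pathogenicity and drug-response assertions both map onto the
  same functional axis; conflicting usable assertions are inconclusive and
  fall through with a `CONFLICT` flag.
- **B — bona fide biological assumptions** (tumor suppressors only), the
  ACMG PVS1 family: canonical (±1/2) splice-site disruption or a premature
  termination codon predicted to trigger nonsense-mediated decay (50-nt
  last-junction rule) count as *very strong* (PVS1); truncation inside a
  critical protein region, or of more than 10% of the protein, counts as
  *strong* (PVS1_Strong). Critical regions are refined from the curated
  truncating loss-of-function variants already in the knowledge layer.
- **C — computational metrics.** Statistically significant mutation hotspots
  (p < 0.05, missense and in-frame indel classes kept separate), then CADD
  Phred scores for missense variants in tumor suppressors: > 30 functionally
  relevant, < 10 neutral, anything between stays unknown.

Everything that survives unclassified is reported as *unknown relevance* —
in practice the largest class, which is the honest answer.

The context-dependent layer then matches classified variants against a
biomarker catalog (exact / category / functional-entity match kinds, the
latter driven by the engine's own calls), resolves the patient-vs-biomarker
cancer-type relation through an ontology DAG, assigns ESCAT tiers I–IV from a
configurable (evidence level × disease match) matrix, evaluates boolean
clinical-trial eligibility rules (ALL/ANY/NONE combinator trees with per-gene
evidence floors and priorities), and issues germline counseling alerts for a
34-gene panel (tier A/B loss-of-function only; MUTYH only when biallelic).

## Worked example

```r
library(oncoboard)

fx <- generate_fixture_bundle(n_patients = 20, seed = 1)   # synthetic resources

calls <- normalize_variants(
  c("BRCA1:c.5468-1G>A", "BRAF:p.V600E", "KRAS:c.35G>A"), fx$db) |>
  classify_variants(fx$db, fx$kb)

tidy(calls)[, c("gene_symbol", "protein_change", "label",
                "evidence_tier", "criteria_codes")]
#> # A tibble: 3 × 5
#>   gene_symbol protein_change label                 evidence_tier criteria_codes
#>   <chr>       <chr>          <chr>                 <chr>         <chr>
#> 1 BRCA1       ""             functionally_relevant A             KB_MATCH
#> 2 BRAF        p.V600E        functionally_relevant A             KB_MATCH
#> 3 KRAS        p.G12D         functionally_relevant C             HOTSPOT
```

The BRCA1 splice variant is relevant on curated evidence (tier A); V600E on
aggregated knowledge-base assertions; the KRAS change only via hotspot
membership (tier C) — which is why, under the default evidence floors, it
would match biomarkers but not trial arms requiring well-curated or bona fide
evidence.

A whole patient:

```r
i <- 2   # an engineered fixture patient carrying a BRCA1 nonsense variant
meta <- read_patient_profile(fx$inputs$profile[i])
raw  <- read_variants_vcf(fx$inputs$vcf[i], fx$db)
report <- interpret_patient(raw, meta, fx$db, fx$kb)
report
#> <patient_report> P0002 (breast_carcinoma)
#>   variants: 1 relevant / 0 unknown / 0 neutral
#>   trial recommendations: 1; germline alerts: 0
report$trial_recommendations
#> # A tibble: 1 × 3
#>   trial_id arm_id priority
#>   <chr>    <chr>     <int>
#> 1 BoB      1A            1
```

The NMD-triggering BRCA1 nonsense variant is classified relevant/loss-of-
function at tier B (`PVS1_NMD`) and satisfies the fixture trial arm that asks
for BRCA1/2 loss-of-function mutations. Reports serialize to structured JSON
(`write_report()`), identical across reruns except for the timestamp.

A thin command-line wrapper ships in `inst/cli/oncoboard.R` with
`interpret`, `cohort` and `validate-resources` subcommands (exit codes:
0 ok, 2 validation failure, 3 integrity failure).

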