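---
title: "Five-tier CNV interpretation: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Five-tier CNV interpretation: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chromosomal microarrays report dozens of copy-number variants (CNVs) per
patient, almost all of which are benign population polymorphisms. Clinical
interpretation assigns each call one of five ACMG-style tiers — benign,
likely benign, variant of uncertain significance (VUS), likely pathogenic,
pathogenic — by weighing its size and gene content against catalogues of
variants seen in unaffected populations and in affected patients. In admixed
or under-represented populations an extra complication appears: variants
that are genuinely polymorphic locally may be rare or absent from the
international benign catalogues, so a cohort-frequency step is needed to
demote recurrent local variants that the catalogues would otherwise leave in
the uncertain tiers.

`cnvtier` implements this workflow end to end: sample QC gating, per-call
inclusion filtering, overlap-based evidence gathering, an ordered five-tier
rule engine, recurrence-based reclassification, and cohort summaries —
plus a seeded synthetic-cohort generator with per-call ground truth so every
stage is testable without patient data.

```{r, eval = FALSE}
library(cnvtier)
cfg <- simulation_config(seed = 1)
tracks <- simulate_tracks(cfg)
cohort <- simulate_cohort(cfg, tracks)
report <- verify_recovery(cohort, tracks)
report$recovery_pct   # 100 on an unambiguous cohort
```

## Coordinates

Internally every interval is 0-based half-open, so `length = end - start`
with no off-by-one arithmetic; all exchange formats (call tables, track
TSVs, reports) use 1-based inclusive coordinates as array-analysis exports
and genome browsers do, and BED input is taken as already half-open. The
round trip display → internal → display is the identity, and lengths are
convention-independent. Only autosomes ("1".."22" after stripping a "chr"
prefix) enter the analysis; the sex chromosomes are rejected by the
inclusion filter, not the parser.

## Sample QC and call inclusion

QC is sample-level: a failing array removes all of its calls. The
thresholds are the manufacturer-recommended cutoffs, all inclusive:

| metric | SNP6 | CytoScan 750K / HD | meaning |
|---|---|---|---|
| MAPD | ≤ 0.35 | ≤ 0.25 | probe-to-probe log-ratio noise |
| SNPQC | — | ≥ 15 (≥ 12 if MAPD and waviness pass) | genotyping quality |
| waviness SD | — | ≤ 0.12 | long-range signal waves |

The relaxed SNPQC floor applies only when both other metrics pass. The
source wording attaches a similar parenthetical to waviness SD itself; we
read waviness ≤ 0.12 as mandatory, because a relaxation with no stated
fallback value is not actionable. A required metric that is absent fails
with an explicit `*_absent` reason.

Surviving calls must be autosomal, covered by ≥ 50 probes, and ≥ 200 kb
(gains) or ≥ 150 kb (losses); the lower floor for losses reflects the
greater phenotypic impact of deletions. Thresholds are inclusive, matching
the printed operators ("minimum size of 200 kb" means 200,000 bp passes).
An optional exclusion track drops calls over loci already known to be
causative in the cohort (e.g. 18p/18q/22q11.2 deletions) so they do not
swamp the counts; exclusion regions are type-matched — a deletion region
removes only losses — with an `any` escape hatch, so a reciprocal
duplication at the same locus is not silently discarded. The attrition
report attributes each removal to its first failing reason in the fixed
order sample QC → autosome → probes → size → exclusion, so the per-reason
counts partition the removals exactly.

## The overlap grammar

All evidence is computed from pairwise interval overlaps with two
fractions: the *query fraction* (overlap / CNV length) and the *reference
fraction* (overlap / track-record length).

* **Benign support**: a benign-population record contributes iff it has the
  same type (deletion vs duplication), covers *more than* 50% of the call
  (strict, "more than 50% overlap in size and location"), and its own
  non-overlapping segment does not exceed 50% of its length (reference
  fraction ≥ 0.5, non-strict). Support is the sum of per-record unaffected
  carrier counts over contributing records. Whether "at least three
  unaffected individuals" should count records, studies or carriers is not
  decidable from the wording; summing the per-record carrier counts is the
  default because the benign-track schema carries them, and a record
  lacking the column defaults to 1 so the choice degrades gracefully to
  record counting.
* **Gene content**: a gene counts as contained at ≥ 1 bp of overlap (the
  permissive literal reading of "genes within"; configurable through
  `min_gene_overlap_bp`), and the OMIM flag is true iff any contained gene
  is OMIM-annotated.
* **Affected matches and syndrome regions** use the same strict > 50% query
  coverage, type-matched, for consistency across the grammar.

The engine is checked against a brute-force per-base set-intersection
oracle on random interval pairs, and the interval index is required to
return exactly what a linear scan returns.

## The rule engine

Rules are tested in a fixed order; the first satisfied rule assigns the
tier, and the trail of tested rules is recorded per call
(`B-DGV50; P-SIZE; …`) so every label is auditable.

1. `B-DGV50` — benign: benign support ≥ 3.
2. `P-SIZE` — pathogenic: length strictly > 3 Mb.
3. `P-SYND` — pathogenic: matching-type syndrome-region hit.
4. `P-CONS` — pathogenic: OMIM genes + an affected match curated as
   consistently correlated with phenotype.
5. `LP-DBCONS` — likely pathogenic: OMIM genes + matches all
   consistent/reported but none consistent at the call level.
6. `V-1`/`V-2`/`V-3` — VUS: non-OMIM genes with a match; OMIM genes with
   no match; OMIM genes with an uncertain match.
7. `LB` — likely benign: no genes or only non-OMIM genes, and no match.
8. `V-FALLBACK` — VUS for anything else (e.g. a match over a gene-free
   call).

Two orderings are genuinely open in the source material and are committed
here in one function for easy revision. *Benign first* is forced by the
data: benign CNVs above 3 Mb (and above 5 Mb) exist in the published
cross-tabulation, so population support must dominate the size rule.
*Pathogenic before VUS* follows the triage intent of the published
flowchart. A call with both consistent and uncertain matches takes
`P-CONS` (first match wins); the curation judgements themselves live in the
input data, which is also where the source put the human subjectivity.
Consistently, the 3 Mb boundary belongs to the 1–3 Mb size bin: a CNV of
exactly 3 Mb is not pathogenic by size and must not appear in the 3–5 Mb
pathogenic row.

The engine is total and monotone: every evidence combination gets exactly
one tier; removing an affected match or the OMIM flag never increases the
tier, and adding benign support never increases it. A 96-row exhaustive
decision table (hand-derived, frozen as a fixture) pins the whole surface.

## Recurrence and reclassification

Same-type calls are grouped by single-linkage clustering with a link at
≥ 50% reciprocal overlap (both fractions, non-strict). The source groups
recurrent CNVs "within a certain genomic region" without stating a rule;
50% reciprocal is the field's convention and matches the classifier's
overlap grammar. The threshold is configurable. Each region's carrier
frequency is distinct carrier samples over the number of analyzed arrays
(a sample carrying two members counts once; zero-call samples stay in the
denominator).

Regions at frequency ≥ 2% have their likely-benign and VUS members
reclassified to benign, with the original tier preserved so the
pre-reclassification view stays computable; pathogenic and likely
pathogenic members are never touched. The comparison is ≥ 2% (the Methods
wording) rather than strictly more than 2% (the Results wording); where
the two disagree the Methods operator wins. Reclassification is idempotent
and conserves counts. Clustering is cohort-wide by default; the published
per-platform consistency discussion suggests per-platform grouping as an
alternative, available simply by running the stage per platform subset.

## Cohort summaries

The cross-tabulation counts calls per tier × size bin × type with margins;
percentages are column-wise (each type × size-bin column against its own
total) and rounded half away from zero to one decimal. The reference
tabulation this is checked against truncates some of its printed
percentages instead of rounding (e.g. 25/1504 prints as 1.6% where
rounding gives 1.7%); the implementation rounds consistently and the
acceptance tests allow one printed-decimal step for exactly those cells.
Mean calls per patient divide by all analyzed arrays, including arrays
with zero surviving calls. Mean sizes are arithmetic means in bp, reported
in kb.

## What the generator emulates — and what it does not

`simulation_config()` defaults are the emulated study conditions: 268
arrays split 59/54/155 across SNP6/750K/HD; Poisson per-sample call counts
with means 12.6/2.9/3.9; overall 80.3% gains; log-normal sizes (log-scale
SD 1) with the background model calibrated numerically so its truncated
mean hits ~704 kb for gains and ~1.0 Mb for losses within
[inclusion minimum, 25 Mb]; the overall tier mix
92.9/1.6/2.6/0.2/2.7%; and four recurrent gain regions at 97.8%
(14q32.33, benign), 32.1% (22q11.22, benign), 9.7% (1p36.32, VUS) and
6.7% (1q21.1, likely benign) of arrays, at hg19-like coordinates.

Because the injected recurrent calls are all benign/LB/VUS gains, the
generator back-computes the gain fraction and tier mix of the
*non-recurrent* background so the overall cohort matches the targets
above. Recurrent members replace rather than add to a sample's Poisson
budget, keeping per-platform means calibrated; when a sample's Poisson
draw is smaller than its carrier count the total is the carrier count, a
small upward bias (~0.2 calls on the 750K platform) well inside sampling
noise at these cohort sizes. The realized overall mean sizes are emergent:
the fixed-size recurrent loci and the 2.9 Mb ceiling on non-benign
background calls pull the per-type means a few percent off the background
targets.

Each call's evidence is private by construction: background calls are laid
out disjointly along the autosomes (with a 200 kb margin and the recurrent
loci ± 2 Mb reserved), and each call gets exactly the track records its
intended tier requires — so every intended tier is reachable by exactly
one rule, and a pipeline run must recover 100% of intended labels at any
seed. A spike of below-threshold calls (10% of the expected included
count; half size-failing, half probe-failing) exercises the inclusion
filter. One shared random stream is split hierarchically by stage, so the
whole output is fixed by the seed and adding draws to one stage never
perturbs another.

Passing on such cohorts demonstrates that the rule engine, overlap
grammar, clustering and bookkeeping are correct — not that the tiers are
clinically right on real data. Real cohorts have overlapping calls with
conflicting evidence, fuzzy breakpoints, segmental-duplication artifacts,
sex chromosomes and real curation disagreements, none of which the
generator produces; the generator reproduces the per-platform call-count
differences without modeling their cause (probe content).

## Numerical choices and degenerate inputs

* Truncated log-normal sampling uses the inverse-CDF on a bounded uniform,
  so no rejection loop and exact determinism under seed; the `meanlog`
  calibration solves for the truncated mean with `uniroot`.
* Ties in rounding are broken away from zero with a 1e-9 guard against
  binary representation of decimal halves.
* Empty tracks, empty call sets, and zero-count crosstab columns are all
  valid (vacuous) inputs; a copy-number state of exactly 2 is a row error,
  as are inverted intervals and unknown platforms, each reported with its
  line number.
* Problem sizes: unit tests run 80-array cohorts; the acceptance suite
  runs the full 268-array conditions (~1,500 included calls), a 10,000-pair
  overlap oracle, and ten 50-call clustering oracles.

## Known limitations

* The point-based ACMG scoring update (Riggs et al. 2020), inheritance and
  trio evidence, mosaicism, and dosage-sensitivity maps are out of scope.
* Benign support may double-count individuals shared between overlapping
  benign-track records; no cross-record de-duplication is attempted.
* No statistical test is run on the per-platform call-count difference;
  the published comparison names none.
* Liftover between genome builds and proprietary binary array formats are
  not handled; the column-mapping dialect is the compatibility mechanism
  for export-format drift.
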