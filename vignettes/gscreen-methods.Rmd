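---
title: "gscreen: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gscreen: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gscreen)
```

# Scope

`gscreen` re-implements, as tested reusable code, the inference chain used
to screen advanced-cancer cohorts for pathogenic germline variants: a
four-stage filter cascade, a simplified five-class pathogenicity engine,
paired tumor LOH / second-hit / reversion analysis, pathway burden
tabulation, an expression-signature HRD/PARPi classifier, and clinical
categorization. Alignment, variant calling, annotation (consequence
prediction), array normalization and SNP-array LOH confirmation are out of
scope: the package consumes called, annotated variants and a normalized
log-scale expression matrix.

# The filter cascade

Four independent predicates applied in sequence, each recorded in a
`FilterTrace`:

| stage       | rule                                            | boundary semantics |
|-------------|--------------------------------------------------|--------------------|
| quality     | keep `call_quality >= 20` and `depth >= 10`      | 20 and 10 kept     |
| population  | keep `pop_af <= 0.01` or established pathogenic common | 0.01 kept    |
| consequence | keep coding non-synonymous; splice sites with abs(offset) <= 2 | offset ±2 kept |
| vaf         | keep `vaf > 0.20`                                | 0.20 rejected      |

Boundary semantics mirror the quoted inequalities of the source procedure
exactly ("< 20", "> 1%", "> 20%"). Two readings were genuinely open and
are resolved as follows:

* **Quality AND/OR.** The source wording ("call quality < 20 and read
  depth < 10; were disregarded") is ambiguous between rejecting on either
  failure or only on both. We reject when *either* fails — the
  conservative QC reading, and the one a calling pipeline's own filters
  use.
* **Missing population frequency** is treated as 0: absence from every
  population database is precisely the informative rare-variant case the
  cascade targets. `known_pathogenic_common` is consumed as a curation
  fact, never computed.

Because the predicates touch disjoint fields, the final kept set is
invariant under any permutation of the stages and the cascade is
idempotent; both are asserted as property tests.

# Pathogenicity classification

The original classification is expert manual curation with in-silico
tools and locus databases. The engine here is an explicit, documented
simplification chosen to be deterministic and testable while remaining
faithful to the observed composition of reportable variants (over 90% are
loss-of-function types):

1. a supplied curated assertion (class 1–5) wins outright — this channel
   absorbs the role of splice/missense predictors and expert databases;
2. loss-of-function consequences (frameshift, nonsense, start-loss,
   splice ±2 bp) in a panel gene: class 5 when `pop_af` is 0 or missing,
   class 4 otherwise. *The 4-vs-5 grading by population frequency is a
   stand-in: the source does not state how it graded likely pathogenic
   versus pathogenic for LoF variants.*
3. missense without curation: class 3 (VUS); anything else: class 3.

Only classes 4–5 are reportable. For recessive-inheritance genes a
heterozygous singleton never counts toward carrier status; homozygotes
count, and two or more reportable variants in one gene count when their
pairwise phase is TRANS or UNKNOWN. UNKNOWN is treated inclusively
because the screening question is for *potential* compound heterozygotes;
a CIS pair sits on one allele and is excluded.

# Tumor integration

* **Heterozygosity check**: blood VAF < 0.65 (0.65 itself fails).
* **LOH**: tumor VAF > 0.65, strict; the threshold is applied to the raw
  tumor VAF with **no purity correction** — biopsies contaminated with
  normal tissue therefore under-call LOH, which is the documented and
  tested behaviour (sensitivity is purity-monotone).
* **Reversion**: somatic indel in CIS with a germline frameshift and
  summed net indel length ≡ 0 (mod 3). UNKNOWN phase never calls a
  reversion (conservative), while it does count for a somatic second hit
  (the source reports second hits whose allelic location could not be
  resolved). The rule is symmetric in which indel is labelled germline.
* **Precedence** per germline variant: REVERSION, else SOMATIC_SECOND_HIT,
  else LOH, else NONE; two somatic hits on OPPOSITE_ALLELES additionally
  set a `biallelic_somatic` flag rather than a competing category.
* **Evaluable semantics**: LOH fractions are computed over variants with
  an observed tumor VAF; missing tumor samples enter neither numerator
  nor denominator and are reported as `no_tumor`, never as "no LOH". The
  source does not state its denominator convention; this choice is
  documented for users.

# Pathway burden

Each reportable variant counts once, by its own gene's pathway — the
denominator is the variant count, not the carrier count (a patient with
variants in two pathways contributes to both). Fanconi anemia genes are a
labelled sub-group of homologous recombination: they keep their FANCONI
label in distribution tables and count as HR in HR-fraction summaries.
Per-cancer-type carrier fractions flag types with **more than 10**
patients for the ranked view (strictly greater: a 12-patient type is in,
a 10-patient type is out).

# HRD / PARPi expression classifier

Two-stage procedure per signature: (1) restrict the matrix to the
signature genes and hierarchically cluster samples (average linkage,
Euclidean distance on log-scale values — the source names neither;
these are the common defaults for array data), cutting at k = 2;
(2) label the cluster with the **lower** mean signature expression
DEFICIENT — the signatures are framed as down-regulation of repair
capacity — with an explicit override because the source is silent; exact
centroid ties label everything NORMAL with a warning. (3) Train
k-nearest-neighbours (default k = 5, odd, ≤ n−1) on the labels;
prediction is the majority vote, the vote fraction is the confidence
(≥ 0.5 by construction), and predictive value is estimated by
leave-one-out cross-validation since the source states no protocol.
Distance ties are broken by training-sample order, so results are
deterministic and permutation-equivariant.

The source legend names both a "KNN based classifier" and a "K-means
based classifier"; KNN is implemented (it is the name used twice,
including in the methods text), K-means is noted as an unimplemented
alternative. The published signature gene lists are not reproduced in the
source: the package ships synthetic placeholder lists
(`synthetic_signature_genes()`, symbols `SIGHRD001`…) purely so the
machinery is testable, and real lists are supplied as plain text via
`read_signature_genes()`. Missing expression values are rejected at
ingestion, not imputed: post-RMA array matrices have none.

Consequently the published predictive values (96% HRD / 95% PARPi on 534
real tumors) are **not** reproduced here — the expression data would have
to be downloaded and the unpublished lists obtained. The acceptance
surface is property-based instead: leave-one-out predictive value ≥ 0.95
at planted effect size 3 (n = 100), chance-level agreement at effect
size 0, and accuracy non-decreasing in effect size.

# Clinical categorization

Group 1: established (gene, cancer type) association, including
reduced-penetrance alleles. Group 2: emerging association, or tumor
two-hit evidence (LOH or somatic second hit) without a known association,
or the gene's pathway explicitly flagged as over-represented for that
cancer type. Group 3: otherwise. The over-representation trigger is a
configuration table, not auto-detected, because the source applied it
judgmentally (its example: Fanconi genes in mesothelioma); likewise the
EMERGING associations ship only as worked-example defaults. Treatment
suggestions are restricted to PARPi (*BRCA1/2*, class 4/5) and
immunotherapy (MMR genes, class 4/5), de-duplicated per patient.
Return-of-results is recommended for ACMG-return-list genes, or
Group 1/2 findings with family history, and vetoed for alleles flagged
moderate-risk. Family history is a per-patient boolean; pedigrees are out
of scope.

# The synthetic cohort generator

`simulate_cohort()` generates the *stated world* of the analysis — the
conditions the source reports — not a tunable realism dial:

| parameter | default | origin |
|---|---|---|
| `n_patients` | 636 | cohort size |
| `cancer_type_weights` | printed per-type proportions | cohort table |
| `carrier_fraction` | 0.178 | reported carrier rate |
| `mean_depth` | 50 reads | stated 50–100× coverage aim (lower end) |
| `loh_fraction` | 0.27 | reported LOH rate in HR genes |
| `second_hit_fraction` | 6/113 | six second-hit patients |
| `reversion_fraction` | 1/113 | one reversion case |
| `recessive_het_rate` | 16/636 | reported recessive-het carriers |
| `tumor_purity_range` | [0.4, 0.9] | realistic biopsy purity span |
| `common_benign_rate` | 2/patient | enough decoys to exercise every filter |
| `expression_effect_size` | 3 | separation giving near-perfect recovery |

Blood VAFs of planted heterozygous variants are binomial draws around 0.5
at the call's depth, rejection-sampled into the open interval
(0.20, 0.65): the observed world is a cohort in which *every* germline
blood VAF fell below the 65% heterozygosity bound, so planted calls
honour it by construction. Tumor VAFs under LOH have expectation
`purity + (1 − purity)/2` (loss of the wild-type allele in the tumor
fraction, heterozygous normal remainder). Decoy variants each violate
exactly one named filter — quality, depth, population frequency,
synonymous consequence, or low VAF — so the truth table can assert the
rejection stage of every decoy. The noise model is binomial read sampling
only: no substitution errors, no subclonal structure beyond a single
purity scalar, no read-level data, and exactly one pathogenic variant per
carrier (the few real multi-variant patients are covered by direct unit
tests). Per-gene priors follow the printed top-gene counts and are flat
beyond them. A green test on this generator therefore establishes that
the *inference rules* recover planted structure — not that the generator
resembles any particular patient population.

`simulate_expression()` shifts signature genes down by `effect_size`
(units of the within-group SD, 1) in the deficient group on a log-scale
baseline of 8, with exchangeable noise genes; hidden labels are returned
for recovery testing. All generators derive sub-seeds deterministically
from one integer seed and are byte-reproducible.

# Numerical conventions and degenerate inputs

* Printed percentages round **half away from zero** at report time
  (113/636 → 17.8); VAFs and fractions are carried in [0, 1] throughout.
* VCF positions are 1-based and preserved exactly; multi-allelic records
  split per alternate allele with AD-derived VAFs; records lacking depth
  are skipped with a counted warning; malformed records error with their
  line number. `pop_af` is a single pre-aggregated maximum across
  population databases — aggregation is the caller's duty.
* Empty inputs flow through: zero-patient simulations, empty cohort
  summaries and empty report tables are valid outputs, and undefined
  fractions (empty denominators) are NA, never 0.
* The packaged printed-cohort fixture reconciles an internal
  inconsistency of the source tables: per-type carrier counts sum to 109
  while the printed total is 113. Every per-type count referenced by a
  printed fraction is kept verbatim; the four unallocated carriers are
  assigned to types no printed fraction references. A second
  inconsistency (cervical cancer "28%" in the narrative vs 1/18 in the
  table) is resolved by computing from counts; nothing hard-codes the
  narrative value.

# Known limitations

* The 168-gene panel is a reconstruction and should be replaced for real
  use; inheritance modes beyond *MUTYH*/*NTHL1* recessivity are not
  modelled.
* Classification is rule-based; it will mis-grade variants whose
  pathogenicity rests on evidence outside the LoF rule and the curation
  channel.
* Phase is consumed as data; no read-backed phasing.
* No purity estimation or correction; LOH sensitivity degrades at low
  purity by design.
* The expression classifier's accuracy claims are synthetic-surface
  properties, not reproductions of the published figures.
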