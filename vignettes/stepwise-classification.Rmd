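---
title: "Stepwise WTS classification of ALL: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise WTS classification of ALL: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtsALL)
```

# The problem

Acute lymphoblastic leukemia is genetically heterogeneous: four WHO
entities are defined by specific fusion transcripts (BCR-ABL1,
KMT2A-rearranged, ETV6-RUNX1, TCF3-PBX1), two by abnormal chromosome number
(high hyperdiploidy, low hypodiploidy/near-triploidy), and the provisional
BCR-ABL1-like (Ph-like) entity by a kinase-activated expression signature in
the absence of the fusion itself. A whole-transcriptome sequencing run
contains evidence for all of these at once. `wtsALL` organizes that evidence
into a strict decision cascade — pairing QC, lineage, entity fusions, ploidy
groups, Ph-like signature, residual 'other' — in which stronger evidence
always precedes weaker: a detected entity fusion can never be overridden by
an expression-derived call, and every decision is appended to a per-sample
evidence chain.

This vignette documents the model behind each stage, the tunables and their
defaults, the generative model of the synthetic cohorts, and the numerical
and design choices that were genuinely open.

# Stage models and parameters

## Pairing QC (genotype concordance)

Diploid genotypes are banded from variant allele frequencies: VAF < 0.1 is
homozygous reference, 0.1–0.9 heterozygous, > 0.9 homozygous alternate;
sites under `minDepth = 5` reads are missing. The wide het band absorbs
allelic expression imbalance, which is common on the RNA side. The
concordance score counts identical alleles per SNP (for alt-allele dosages
$a, b$ the multiset intersection has size $2 - |a - b|$) over twice the
number of SNPs callable in both assays — alleles, not genotype identity, so
a het-vs-hom-alt mismatch still contributes one matching allele.

A pairing is flagged when the best score falls below `flagThreshold = 0.8`,
when the best match is tied, or when a same-named WGS profile exists but
scores below the threshold. The last clause is what catches a swap: the
swapped-in donor may match some WTS profile almost perfectly, so the *best*
score alone would look clean; it is the divergence of the *nominal* partner
that marks the accident. Flagged samples are excluded from all later stages
(`keepUnpaired = TRUE` overrides).

## Expression normalization and lineage

Genes are kept when any sample reaches `minTotal = 2` counts. Scaling
factors are trimmed-mean-of-M-values via edgeR (trims 0.3/0.05, reference =
sample whose upper-quartile/library ratio is closest to the cohort mean,
factors anchored to geometric mean 1). Log2 CPM uses a fixed prior count of
0.5 per sample: $\log_2\!\big((c + 0.5)/(N f + 1) \cdot 10^6\big)$. The
fixed prior keeps the transform monotone and finite at zero; its cost is a
small rescaling artifact at low counts (about 0.035 log2 for a count of 10
under a 2x library change, under 0.01 from count 50).

Lineage is nearest-marker-centroid on cohort z-scores over five B and five
T markers; the margin (B minus T mean z) is reported so ambiguous samples
are visible, and exact ties default to BCP with a warning. CD10 (MME) and
CD1A are exposed as maturation marker values only — maturation subtyping
from bulk expression is unreliable and deliberately out of scope.

## Consensus fusion calling

Caller tables are harmonized to a common schema; breakend-style records
reported with both strands "−" are flipped back to annotated 5'→3'
orientation. Consensus groups calls per sample and gene pair, merging
breakpoint clusters within `bpTolerance = 10` bp (RNA coordinates), and
requires `minCallers = 2` of 3. WGS confirmation demands an SV record with
both breakends within `confirmWindow = 1e5` bp of the RNA breakpoints: the
window must exceed intron-scale DNA-vs-RNA breakpoint offsets (the generator
plants up to ±20 kb) yet stay below gene-neighborhood scale. Control
filtering matches by gene pair, not breakpoint (recurrent artifacts wander
in coordinates), and uses any-caller control calls — the stricter reading.

Read-through categorization requires same chromosome, same strand,
collinear order, and either a spanning WGS deletion segment or membership in
the curated indicator table (MTAP-ANRIL → CDKN2A/B, RCBTB2-LPAR6 → RB1,
DLEU2-SPRYD7 → MIR15A/16-1, P2RY8-CRLF2 → PAR1); transcription-induced
chimeras without genomic support are not classified. Entity assignment
honors wildcards (KMT2A-\*) and the clinical priority BCR-ABL1 > KMT2A-r >
ETV6-RUNX1 > TCF3-PBX1; conflicting entities in one sample are recorded.
Comparison tables round half up to integer percent, the convention of
printed clinical tables.

## Ploidy groups from expression dosage

Per-gene log2 ratios are sample log2 CPM minus the per-gene median of the
control cohort (genes with reference median below `referenceFloor = 1` log2
CPM are uninformative and dropped), winsorized at ±3. Two centering steps
deal with the compositional nature of CPM: ratios are median-centered per
sample at the gene level, and the 22 per-chromosome aggregates (10% trimmed
means) are re-centered by their median. The second step matters: in an
aneuploid sample the gene-level median sits between the neutral and gained
components of the ratio distribution, which would push neutral chromosomes
past the loss threshold; the median *chromosome* is neutral as long as fewer
than half the autosomes are aberrant, so it is the robust anchor.
Chromosome-level centering is skipped when fewer than five chromosomes carry
data, so single-chromosome inputs remain interpretable. A consequence is
that genuinely near-haploid or near-triploid genomes (most chromosomes
aberrant in the same direction) are outside the method's reach — a known
limitation it shares with any relative-dosage approach.

States use a symmetric threshold (gain > 0.15, loss < −0.15; only the gain
direction is conventionally printed, but the loss rules are only evaluable
with the symmetric reading) and a strict weight rule (> 15 supporting
genes). The rule engine is a pure function of the 22-state vector: > 3
changes selects a candidate; hypodiploid is evaluated first (≥ 5 losses or
joint loss of chromosomes 3, 7, 13, 17 — read as a conjunction), then
hyperdiploid (≥ 2 gains among 4, 6, 10, 14, 17, 18, 21); both firing
resolves to hypodiploid with a conflict note, neither leaves a
candidate-unresolved note. iAMP21 is never called from dosage — the
chromosome-level resolution is too coarse — and surfaces only as an
expression advisory flag (DYRK1A and CHAF1B cohort z-scores both > 2).

## Ph-like classification

Signature genes are ranked by absolute difference of group medians
(BCR-ABL1-positive vs -negative), ties broken by gene id. References store
per-gene medians of both groups; cohort sizes are metadata and do not weight
the distance. Classification is plain Euclidean distance on log2 CPM —
without per-gene re-standardization, so genes with larger separations
legitimately contribute more; optional z-scoring was considered and rejected
as a silent change to the published procedure. A sample is phlike on a panel
when strictly closer to the positive median; ties are conservatively
non-phlike. With two panels (defaults 26 and 38 genes, 17 shared), the final
call requires agreement; discordant samples are reported, not dropped.

# The synthetic cohort generator

The generator is first-class, tested code: it renders every input the
pipeline consumes from a planted truth, under the study conditions the
pipeline was designed for.

* **Gene universe.** ~1100 synthetic genes on a 1 Mb grid over 22 autosomes
  (no sex chromosomes; the dosage method covers autosomes only), all on the
  "+" strand so read-through collinearity reduces to coordinate adjacency.
  Real marker and fusion-partner names are reserved at fixed slots with the
  indicator pairs adjacent (MTAP, CDKN2A, ANRIL consecutive on 9, etc.).
  Baselines are log-normal (meanlog log 150, sdlog 1); markers get a fixed
  moderate baseline, CRLF2 a low one so its bimodal shift is visible.
* **Genotypes and SNP profiles.** 50 common SNPs (MAF 0.2–0.5),
  Hardy-Weinberg genotypes. WGS depth is Poisson with mean 90 (a standard
  genome coverage); WTS depth is log-normal (meanlog log 20, sdlog 1.2), so
  roughly an eighth of sites fall under the 5-read filter and the filter is
  exercised naturally. Alternate reads are Binomial(depth, p) with p from
  dosage and a 0.002 error rate. Mix-ups swap whole WGS profiles and are
  recorded in a provenance table; `plantSwap()` plants one deterministically.
* **Counts.** Negative binomial with variance $\mu + 0.1\mu^2$ (a standard
  bulk RNA-seq overdispersion), mean = baseline x library factor
  (log-normal, sd 0.15) x $2^{0.9\,\log_2(\mathrm{cn}/2)}$ x shifts. The
  0.9 dosage transmission emulates non-tumor cell dilution. Shifts: +3 log2
  on lineage markers, +1.5 log2 on the signature panel union for BCR-ABL1
  *and* Ph-like samples (both carry the kinase-activated state — that is
  what makes the reference construction meaningful), +5 log2 CRLF2 in
  Ph-like samples, +2.5 log2 DYRK1A/CHAF1B in optional iAMP21 plants.
* **Hyperdiploid genomes** gain 3–6 chromosomes from the typical set plus
  up to 2 others (cn 3, occasionally cn 4 on 21); **hypodiploid genomes**
  lose chromosomes 3, 7, 13, 17 plus 2–5 others (cn 1). Both satisfy the
  rule-engine invariants by construction, which the property tests assert.
* **Fusion callers.** Three callers emit each true fusion independently at
  sensitivity 0.9 with ≤ 2 bp RNA jitter; the third caller emulates a
  breakend dialect (flipped orientation). Read-throughs from planted
  deletions are emitted only by the two RNA-centric callers. False positives
  are Poisson (1/sample/caller) random gene pairs with no WGS counterpart;
  recurrent artifact pairs are injected into patients and controls alike.
* **WGS tables.** True fusions become breakend records with ±20 kb jitter
  (intron-scale DNA-vs-RNA offset, deliberately below the 100 kb
  confirmation window); deletions become deletion SVs plus CNV segments.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: GC and length biases, batch effects, isoform
structure, subclonal heterogeneity and contamination fractions, caller
error modes correlated between callers, DUX4/IGH-type fusions that real
callers miss for mappability reasons, and the published signature gene
identities (panels are synthetic stand-ins; the published lists live in
supplementary material and are config inputs in practice).

# Problem sizes and determinism

Every stochastic stage draws from a deterministic seed derived from the
configuration seed, so a fixed configuration is byte-identical across runs,
and each rendered product is reproducible independently of call order. The
test and acceptance workloads use desk-scale cohorts chosen to make their
statistical assertions well-powered: 50 WTS/WGS pairs for pairing recovery;
10 cohorts of 80 patients + 64 controls with ≥ 80 genes per chromosome for
ploidy recovery; 40 positive / 65 negative reference samples and 60 test
samples for the Ph-like classifier; 1000 planted fusions for the consensus
recovery rate (theory $3p^2(1-p) + p^3$ at $p = 0.9$); and the exhaustive
$3^{10}$ pattern space of a 10-chromosome toy genome for rule-engine
equivalence against an independently coded oracle.

# Known limitations

* Ploidy calls degrade gracefully but inevitably as dosage transmission
  (blast fraction) falls; at zero transmission no candidates are produced.
* Near-haploid genomes and iAMP21 are out of reach of chromosome-level
  dosage; the latter is covered by an advisory expression flag only.
* Maturation subtyping within lineages, differential expression, fusion
  rescue for DUX4/IGH, and contamination estimation are non-goals.
* The pairing stage detects mix-ups, not partial contamination; a
  contaminated sample lowers its concordance but the score is not a
  contamination fraction estimate.
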