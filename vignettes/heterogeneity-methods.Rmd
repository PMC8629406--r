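---
title: "Methods: multi-region heterogeneity analysis and the clonal simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region heterogeneity analysis and the clonal simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonehet)
```

## Scope and data model

`clonehet` analyzes somatic variant calls from multi-biopsy targeted
deep-sequencing of epithelial ovarian cancer (EOC) cohorts: several
biopsies per patient from the ovary and synchronous abdominal lesions at
primary surgery, relapse biopsies after chemotherapy, and one matched
blood per patient.  The unit of information is a *call* — one variant in
one sample, with depth, variant-supporting reads, and allelic fraction
(AF = variant reads / total reads, kept internally as a fraction in
[0, 1] and printed as a percent with two decimals).  A *locus* is
identified by chromosome, position, reference and alternate allele.
Because "same locus" can be read as "same site" or "same variant", both
keys are implemented (`locus_key`); the allele-aware key is the default,
since it cannot manufacture concordance out of two different
substitutions at one position.  The looser site key is a configuration
switch for users who prefer the permissive reading.

## Somatic filtering

A tumor call passes when

* depth ≥ `min_depth` (default 200; "minimum coverage of 200-fold" is
  read as inclusive),
* AF > `min_af` (default 0.01; "> 1%" is read as strict), and
* the locus is not germline: the matched blood shows AF >
  `germline_max_af_in_blood` (default 0.02) at blood depth ≥
  `germline_min_blood_depth` (default 50).

The 2% blood cutoff is a conventional matched-normal threshold, far below
the 50% expectation for a heterozygous germline variant but above
sequencing noise at panel depth; it is a package choice, exposed in
`filter_config()`.  When the blood is covered below 50× at a locus,
germline status is genuinely unresolvable; the call is retained, flagged
`blood_low_coverage`, and a warning is raised, rather than silently
dropped or silently kept.  Each rejection carries exactly one reason,
assigned in the fixed order germline → depth → AF (then any user-supplied
predicates), so audit summaries do not depend on evaluation order.
Missing matched blood is an error: the design is tumor/normal-paired, and
without a normal the germline subtraction would be fiction.

Two callers' outputs (e.g. a Bayesian SNV caller and a heuristic
indel-capable caller) are harmonized by `merge_callers()`.  The default
is the union, keeping single-caller calls with provenance tags — at
~2500× amplicon depth sensitivity is the binding constraint and consensus
can be recovered by post-filtering on the tags.  When both callers report
a locus, counts are taken from the deeper caller (ties to the first
argument), which keeps the merged record internally consistent.

## Sharing partitions and the category table

Three partitions operate at different scopes, all over primary-surgery
samples:

* *shared* (cohort scope): the locus occurs in ≥ 1 ovary sample and ≥ 1
  synchronous (non-ovary) lesion, not necessarily of the same patient;
* *concordant* (patient scope): the locus occurs in the patient's ovary
  and ≥ 1 of the same patient's synchronous lesions;
* *private*: everything else confined to one biopsy.

Two edge cases are deliberately not forced into the binary: loci in
several synchronous lesions but no ovary sample get their own label
(`synchronous_recurrent`), and loci in two ovary samples of a bilateral
patient but no synchronous lesion are labelled private (to the ovary
compartment).  Collapsing either into "concordant" would inflate
concordance percentages; the partition
{concordant, private, synchronous_recurrent} stays exhaustive and
mutually exclusive, which the tests assert.

The category table counts *distinct variants* in a 3 × 4 layout
(ovary-exclusive, synchronous-exclusive, shared × the four effect
classes).  Shared loci are counted once cohort-wide; exclusive loci are
deduplicated within a patient's compartment but counted again when an
independent patient carries the same variant.  Whether a published table
deduplicates across patients is usually unstated; this per-patient
counting is the documented choice here, and
`expand_category_counts()` makes any count table checkable against the
counting logic by expanding it into a minimal realizing cohort.

Effect classes are non-synonymous, synonymous, indel (< 50 bp; larger
length changes are out of panel scope and raise an error) and VUS.  With
codon annotation, synonymy is decided by translating reference and
alternate codons; without annotation an SNV is a VUS — the package
deliberately bundles no annotation database, and accepts an explicit
effect column so annotated VCFs and simulator output flow through the
same path.

## Allelic-fraction clustering and patient phylogenies

The AF matrix is samples × loci with 0 where a sample has no call.  Zero
is treated as evidence of absence, not missingness: after matched-normal
filtering at ~2500×, a locus without a call at > 1% AF is very unlikely
to be present, so no imputation is attempted.  Synonymous loci are
excluded by default, following the convention of dropping translationally
silent variants from heterogeneity analyses.

Clustering is agglomerative (`stats::hclust`) with Euclidean distance and
average linkage by default — no specific choice is canonical for AF
matrices, so the package picks the most common pair and exposes both
knobs.  Rows are sorted lexicographically by sample id before clustering
so that distance ties break deterministically.  The flat cut at k = 2
reports the ovary-vs-synchronous branch structure that multi-region EOC
cohorts display.

Per-patient trees are neighbor-joining (`ape::nj`) on pairwise AF
distances, rooted on an unrelated control — a profile (cell-line-like)
with no shared somatic history, whose AF vector is orthogonal to every
biopsy, so the root edge is "no common ancestry".  NJ is used because it
is deterministic, handles non-ultrametric data (biopsies differ in
mutation counts), and is exact on additive matrices: under the package's
clonal model, Manhattan distance on noiseless AF vectors *is* additive
(each edge contributes 0.5 × its mutation count), so NJ provably recovers
the true lineage there, and the test suite checks exact recovery on
random additive matrices (6–10 taxa).  Euclidean distance is the default
for consistency with the clustering stage; Manhattan is the right choice
when tree accuracy against a clonal ground truth matters, and is what the
recovery experiments use.  Negative NJ branch lengths (a finite-sample
artifact) are clamped to zero with the deficit moved to the sister
branch, preserving path lengths through the parent node where possible.
Locus universe for trees is per-patient by default; a cohort-wide
universe (all loci called anywhere, zeros elsewhere) is available, since
published tree analyses sometimes use a fixed panel-wide locus set whose
composition cannot be reconstructed from text.

Leaf-pair similarity scores each cherry of a tree: over a locus universe,
*concordant* = called in both samples, *private* = called in exactly one,
*wild-type* = called in neither.  The universe is all loci somatic in ≥ 1
sample of that patient — published similarity tables rarely define the
wild-type denominator, and this choice is the smallest set that makes the
three classes a well-defined partition summing to 100%.  Indels are
included alongside SNVs by default (toggleable), as nothing in the
similarity definition is substitution-specific.

## Substitution spectra

Single-base substitutions are folded onto the pyrimidine-referenced
strand (G>A ≡ C>T), the standard convention in mutational-signature work,
giving six classes.  "Spectra are comparable before and after
chemotherapy" is operationalized as a chi-squared homogeneity test on the
6 × 2 class × stage table, dropping classes absent from both arms and
adjusting the degrees of freedom; identical spectra give statistic 0 and
p = 1 exactly.  Pooled cohort-level comparison is the default; per-patient
spectra are available.  Trinucleotide-context (96-class) signatures are
out of scope.

## The simulator: what it emulates, and what it does not

`simulate_patient()` draws a branched subclone tree: a founder (trunk)
edge, optionally one clade per anatomical site group (so lesions of a
site share clade mutations — the structure that makes real cohorts
cluster by site), one dominant subclone per biopsy, and relapse subclones
descending from the dominant subclone of *one* primary lesion (the
pre-existing-resistant-clone model; the alternative `"none"` detaches
relapses from any primary).  Mutations land on edges with genes sampled
proportionally to coding length, effects from configurable proportions,
and substitution classes from a C>T-dominant spectrum.  Sequencing is a
heterozygous diploid model: expected AF = purity × cancer-cell-fraction ×
0.5; depth is negative-binomial (overdispersed, as amplicon panels are);
variant reads are binomial with an error floor of error/3 per
non-reference base; blood carries the germline heterozygotes at AF ≈ 0.5.

Key defaults and why: mean depth 2500× and NB size 20 (deep amplicon
sequencing with realistic overdispersion; the depth calibration test
checks the mean within 2% over 10⁴ draws); purity 0.8 (snap-frozen
surgical biopsies); error 10⁻³/base (post-filter substitution error of
short-read chemistry); 6 trunk mutations against ~10 clade-private and
~20 lesion-private mutations (Poisson means), putting per-biopsy burden
in the tens and the trunk fraction in the few-percent range — the regime
where concordance is small and private mutations dominate, as observed in
multi-region EOC panels; effect proportions 37/9/4/50%
(non-synonymous/synonymous/indel/VUS), the mix of a 1131-variant EOC
panel cohort; 30 germline heterozygotes and 25 error-candidate sites per
sample to exercise the germline and AF filters.  The 19-patient default
cohort layout reproduces a realistic sampling design: 71 tumor biopsies —
21 ovary (two bilateral patients), 24 synchronous, 24 second-surgery and
2 third-surgery relapses — plus 19 bloods and one unrelated control.

Not simulated: copy-number change and LOH (AF would need a
copy-number-aware expectation; the analyses here use AF only
metrically/ordinally, and adding CN would introduce unidentifiable
parameters), subclonal mixtures beyond a single dominant-fraction knob,
read-level artifacts (strand bias, mapping error), tumor contamination of
the blood, and chemotherapy-specific mutational processes (the default
relapse spectrum equals the primary spectrum, so the spectrum test's null
is true by construction unless the user configures an enrichment).
Passing recovery tests on this generator therefore demonstrates that the
*pipeline logic* is correct under its stated model — not that the model
captures every failure mode of real FFPE/frozen-tissue sequencing.

## Numerical and determinism choices

* Percent formatting rounds to two decimals only at the reporting edge;
  internal fractions are double precision.
* Newick round trips preserve branch lengths to 10⁻⁶ and quote labels
  containing metacharacters.
* All randomness flows from one integer seed; `simulate_cohort()` and
  `run_pipeline()` are byte-identical under a fixed seed (manifest
  included — it records seed, config hash and row counts, never
  timestamps).
* Degenerate inputs fail loudly: empty locus universes (undefined
  percentages), zero loci after synonymous exclusion, < 3 taxa for NJ,
  missing blood, malformed records with their line number.

## Problem sizes

The shipped validation uses desk-scale sizes chosen to make every
distributional claim testable in seconds: 100 random additive matrices of
6–10 taxa for NJ recovery; 1000 random call sets for filter monotonicity;
50 replicate single-patient cohorts (five biopsies each, ~150 mutations)
at 2500× for sensitivity, trunk-fraction concordance (mean absolute error
≤ 2 percentage points), relapse attachment (≥ 80%) and site separation
(≥ 90%); 100 replicate spectrum pairs (200 SNVs per arm) for test
calibration.  The same machinery scales to cohort sizes in the hundreds
of biopsies without design changes.

## Known limitations

* Pathway-level comparison uses a two-proportion chi-squared test per
  pathway without multiplicity correction across pathways; with 11
  pathways, users comparing many cohorts should apply `p.adjust`.
* The concordant/shared definitions are call-presence-based; a variant
  missed in one biopsy purely by sampling (low purity, low CCF) counts as
  private.  At the default depth and filter settings this misclassification
  is rare (the recovery experiment bounds it), but it grows as purity
  drops toward the filter boundary.
* The unrelated-control root is required for tree building; cohorts
  without a control sample get clustering and similarity but no rooted
  trees.
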