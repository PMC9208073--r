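---
title: "Methods: downstream WES analysis of metastatic ccRCC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream WES analysis of metastatic ccRCC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccrccwes)
```

# Scope and model

`ccrccwes` implements the downstream analysis of paired tumour/normal
whole-exome sequencing for metastatic clear cell renal cell carcinoma
(ccRCC) cohorts: tumour purity estimation, purity-aware somatic variant
filtering and tumour mutational burden (TMB), copy-number calling by
circular binary segmentation (CBS) with cytoband-level cohort recurrence,
clonality-based multi-sample phylogenies, and therapy-naive versus
pretreated contrasts. A synthetic-cohort generator with full ground truth
makes every stage testable offline.

Everything rests on one admixture model. A specimen with tumour purity
$p$ mixes tumour cells (local copy number $C$, mutation multiplicity $m$)
with diploid normal cells, so at a mutated locus the expected variant
allele frequency (VAF) is

$$\mathrm{E}[\mathrm{VAF}] \;=\; \frac{c\,p\,m}{p\,C + 2(1-p)},$$

with $c$ the cancer-cell fraction ("clonality") of the mutation. Coverage
behaves analogously: the expected tumour/normal depth ratio at a locus of
copy number $C$ is $(pC + 2(1-p))/2$. The package inverts this model three
ways: corrected VAF (`correct_vaf`, setting $c=m=1$ and rescaling to a pure
tumour), clonality (`compute_clonality`, solving for $c$), and the
log2-ratio correction $r' = (r - (1-p))/p$ used for copy-number calls.

# Purity estimation

At a germline heterozygous SNP overlying a one-copy (hemizygous) loss, the
tumour allelic fraction moves from $1/2$ to $1/(2-p)$ if the retained
allele is the alternate, or $(1-p)/(2-p)$ otherwise. Folding
$b = \max(f, 1-f)$ makes both cases share the expectation $1/(2-p)$, so

$$\hat p = 2 - \frac{1}{\mathrm{median}(b)},$$

clamped to $(0.05, 1]$, with a percentile bootstrap (200 resamples) for the
interval. The estimator consumes SNPs that are heterozygous in the normal
(normal fraction in $[0.4, 0.6]$, both depths $\ge 20$) and that overlie
*candidate* one-copy-loss segments found by a first segmentation pass run
at purity 1.

Two guards make this robust to imperfect candidates. First, the pooled
candidate SNPs must show allelic imbalance at all: the standardised
deviation $z = |f - 1/2|\big/\sqrt{1/(4\,d)}$ (depth $d$) is half-normal
under neutrality, and a one-sided rank test of the pooled $z$ against the
half-normal median (0.674) must reject, otherwise the sample is analysed
uncorrected at purity 1 with a loud `fallback_neutral` flag. We prefer
abstention to a fabricated estimate: an underestimated purity inflates
every downstream correction. Second, individual candidate segments whose
mean imbalance sits closer to the neutral expectation than to the
loss level implied by the pooled estimate are discarded (two refinement
iterations); they are almost always segmentation false positives, and
pooling them drags $\hat p$ toward zero. Fragmented candidates with fewer
than three SNPs are pruned per SNP only in the clear-separation regime
($\delta \ge 3$, where misclassification is rare), because per-SNP
selection at weak separation would bias the folded median upward.

On simulated samples with 334 SNPs at depth 100 — the assay scale of the
study conditions — the estimator's mean absolute error over true purities
0.2–0.9 is about 0.02 (acceptance suite), with fallbacks concentrated at
purity $\le 0.3$ where an arm-level loss shifts raw log2 by less than one
noise standard deviation. That regime is a genuine identifiability limit
of coverage-guided candidate discovery, not a numerical artefact, which is
why the recovery grid feeds the estimator the sample's true loss segments
as candidates and reports the fallback rate separately.

# Somatic variant filtering and TMB

Filtering applies the published rules with this reason precedence:
present in the matched normal, synonymous, fewer than 10 total tumour
reads at the locus, corrected VAF below 10%. A variant failing only the
VAF rule is rescued when COSMIC reports it at least 10 times, its
corrected VAF exceeds 5% and its normal VAF is below 1%. "Present in the
normal" is made operational as at least 2 alternate reads *and* normal VAF
$\ge 2\%$ — the source rules name no threshold, and at depth ~100 this
keeps the germline false-drop rate of true somatic variants near 2%.
The 10-read rule is read as total aligned tumour reads, not alternate
reads, since the VAF thresholds already police alternate support.

TMB is kept non-synonymous mutations (one per event; an indel counts once)
divided by megabases of covered capture regions, where covered means
passing the coverage filter below. Indel fraction is indels over all kept
variants.

# Copy-number analysis

Capture regions are excluded only when *both* tumour and normal have fewer
than 100 reads (the conjunctive reading; a disjunctive switch is in the
config). Read counts are normalised to each sample's total, the
tumour/normal ratio is log2-transformed, and the profile is segmented per
chromosome by CBS: the arc maximising a two-sample $t$-like statistic
against its complement is split off when a seeded permutation test (1000
permutations, early-stopped) gives $p < 0.01$, recursively, with a minimum
segment width of 3 regions and a post-hoc merge of adjacent segments whose
means differ by less than 0.1. The implementation is in C++ (as the
field's CBS implementations are) and is cross-checked in the tests against
an exhaustive single-split oracle written independently in R.

Purity correction is applied to the *segment means*, not to per-region
values, before classification. The admixture inversion is nonlinear, and
applying it to noisy per-region ratios puts a downward Jensen bias of
roughly $-\mathrm{var}(r)/(2\ln 2\, p^2)$ on every neutral region — at
$\hat p \approx 0.2$ and exome-level noise that is $\sim -0.5$, enough to
mislabel the whole genome as lost. Averaging within segments first removes
the bias while still placing the published thresholds on the pure-tumour
scale: segment means above 1 are amplified, above 0.5 gained, below −0.5
lost, below −1 deleted.

Segments are annotated with the cytobands they overlap; a sample whose
altered fraction exceeds 0.5 is flagged for manual review (ploidy shifts
and normalisation failures masquerade as genome-wide change), without any
automatic correction. CNA burden is the fraction of retained autosomal
basepairs in non-neutral segments; sex chromosomes are excluded from
burden and purity estimation by default because a single-copy male X
violates the diploid baseline. Cohort recurrence counts patients (not
samples) with a loss/deletion — or gain/amplification — overlapping each
cytoband.

# Phylogenies

For each patient with at least two samples, a variant is *present* in a
sample when its clonality there is at least 0.25 — above the binomial
noise floor at depth 100 and purity 0.4 — and it passed the somatic
filters in at least one sample of the patient. Variants are grouped by
identical presence pattern; a laminar (pairwise nested-or-disjoint) family
of patterns assembles into the unique perfect phylogeny rooted at the
germline, each pattern contributing one edge whose length is its variant
count. Conflicting patterns are resolved greedily by discarding the
lowest-count offender, with discards logged; no bootstrap or test is
attached, matching the qualitative intent of the original analysis.
Samples are leaves; internal nodes are unobserved ancestors.

A locus is treated as *missing data* in a sample only when its overlying
corrected segment mean is at or below −2 (copy number near zero, physical
absence). Using the looser "deletion" call class (log2 < −1) here marks
one-copy losses — where the variant is still observable — as missing
whenever the purity estimate errs modestly, and that corrupted truncal
patterns in both directions during development. Missing entries resolve
to the most frequent complete pattern compatible with the observed ones.

# Cohort statistics

Gene frequencies are patient-level proportions (a patient counts once per
gene). Contrasts between therapy-naive and pretreated samples use the
Mann–Whitney U test: exact when the smaller group has at most 8
observations and no ties, otherwise the normal approximation with tie and
continuity corrections (delegated to `stats::wilcox.test`; the tests carry
an independent enumeration oracle). Benjamini–Hochberg correction is
applied across the per-gene VAF family; TMB, indel fraction and CNA burden
are single-test families. The unit of analysis is the sample for
VAF/TMB/burden and the patient for frequencies; patients with samples in
both treatment groups appear in both, as in the source cohort design.

# The synthetic cohort generator

`emit_cohort()` draws, per patient, a clonal tree over 1–4 samples by
recursive random bipartition (truncal, branch and private SNV counts are
Poisson with means 50, 15 and 10), truncal driver mutations from a gene
panel whose probabilities equal the published per-patient mutation
frequencies (SETD2 0.62, PBRM1 0.57, APC 0.43, VHL 0.36, KDM5C 0.31,
HIF1A 0.24, RBM10 0.21, FBXW7 0.19, TRAK1 0.16, EGFR 0.09), and truncal
arm-scale copy-number events with probabilities equal to the published
recurrence counts over 44 patients (3p25/9p21/14q25/6p21/13q14 losses at
36, 30, 17, 18 and 23 of 44; 5q gain at 21 of 44). A VHL-pathway trunk
rule adds a VHL mutation when neither a VHL mutation nor a 3p loss was
drawn (probability 0.9), mirroring the near-universal truncal VHL
inactivation in ccRCC. Defaults: 44 patients, 13 of them multi-sample
(2–4 samples, totalling ~68), purity uniform on 0.2–0.9, mean depth 100
(the platform's reference coverage), negative-binomial coverage with size
100 (log2-ratio noise SD ≈ 0.29 per region, mid-range for exome capture),
normal-sample error rate 0.2% (so the <1%-normal-VAF rescue arm is
exercised), about 4 low-clonality private SNVs and 5 germline-leak
variants per sample, and a 38/68 pretreated fraction. The synthetic exome
is deliberately reduced — 23 chromosomes × 6 cytobands × 10 regions of
500 bp — so a full cohort analysis runs in seconds; TMB values are
therefore on a synthetic scale (small denominator), which is immaterial to
the rank-based contrasts.

What the generator does *not* emulate: GC and mappability waves,
replication-timing coverage structure, subclonal copy number, mutational
signatures, multi-allelic sites, and sample swaps. Passing recovery tests
therefore demonstrates correctness of the algorithms under the stated
model, not robustness to every artefact of real capture data.

# Numerical choices and degenerate inputs

Constant profiles yield one segment per chromosome (zero variance guards
the arc statistic); chromosomes shorter than twice the minimum width are
never split; the corrected ratio is floored at 0.01 so homozygous
deletions stay finite; a permutation alpha below $1/(n_\mathrm{perm}+1)$
can never accept a split. Karyotypic order (1–22, X, Y) is a total order
and sorting is idempotent; chromosome names are accepted with or without
the `chr` prefix. All randomness flows through R's RNG (the C++
permutation loop uses `unif_rand`), so a fixed seed makes the whole
pipeline byte-identical, which the acceptance suite asserts on the full
44-patient cohort.

Problem sizes in the test and acceptance runs — a 160-draw purity grid,
ten 200-region step profiles at 1000 permutations, 50 simulated
multi-sample patients, 2000 null rank tests, and two full 44-patient
cohort analyses — were chosen so the entire suite completes in a couple of
minutes while keeping Monte-Carlo margins comfortable.

# Known limitations

Purity below ~0.3 is frequently flagged rather than estimated, and
single-sample detection of one-copy arm losses degrades steeply below
purity 0.4; recurrence counts on low-purity cohorts are attenuated
accordingly (the package reports what it detects and never imputes).
Multiplicity is fixed at 1 except where a segment's VAF demands promotion;
allele-specific copy number and subclonal deconvolution are out of scope.
The greedy conflict resolution in tree building is not maximum parsimony;
with the study's SNV counts per edge the two coincide in practice, but
heavily conflicting presence matrices (e.g. from contaminated samples)
would deserve a dedicated method.
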