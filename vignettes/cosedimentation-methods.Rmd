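---
title: "Co-sedimentation profiling: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-sedimentation profiling: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosedim)
library(dplyr)
```

## The measurement model

A density-gradient fractionation experiment yields, for every RNA (and, via
mass spectrometry, many proteins), a vector of abundances across ordered
sucrose fractions. We treat each entity's vector as a *sedimentation profile*:
after dividing by the row total, it is a probability distribution over the
gradient, and two entities that occupy the same subcellular microenvironment
should have similar distributions regardless of how highly they are expressed.
All shape comparisons in the package are therefore Pearson correlations of
profiles, and all clustering operates on correlation distance `1 − r`.

Two structural facts about these experiments shape the data model. First, edge
fractions often lack usable material, so profiles carry explicit physical
fraction numbers (RNA typically spans fractions 3–24 of a 24-fraction
gradient, protein 3–19); every cross-kind operation — RNA versus protein,
RNA versus RBP peptide — is computed on the intersection of fraction numbers.
Second, abundances are relative within a fraction (TPM, normalized peptide
signal), so only profile *shape* is meaningful; absolute level enters a single
statistic, the weighted count, which deliberately uses raw values.

## Normalization

"Relative expression" is defined as row-sum-to-one over the fractions present.
We chose sum-to-one over max-scaling or z-scoring because it makes profiles
comparable as distributions and makes peak enrichment directly interpretable:
a normalized value of `k / n_fractions` at a fraction is a `k`-fold enrichment
over the uniform baseline, which is the natural reading for gradients whose
compartments concentrate material only ~2–4-fold. Max-scaling is available as
an option (`method = "max"`) but is not the default because it couples the
whole profile to a single noisy maximum. Rows whose raw total falls below an
expression floor (`min_total`, default 1 summed TPM for RNA, 0 for curated
protein tables) are dropped, never zero-padded: a zero-padded pseudo-profile
would correlate spuriously with everything flat. Missing cells at load are
imputed as 0 with a warning — in TPM tables an absent entry means "not
detected" — while negative values are rejected outright.

The fraction-by-fraction correlation heatmap is computed on `log2(TPM + 1)` of
raw values by default: raw abundances span orders of magnitude, and a handful
of very highly expressed genes would otherwise dominate every inter-fraction
correlation. This is configurable (`log2_transform`).

## Co-sedimentation clustering

Agglomerative hierarchical clustering with correlation distance and average
linkage, cut at height 0.3, is the default. Correlation distance matches the
scientific intent (clusters of RNAs whose normalized profiles are highly
correlated); average linkage with a 0.3 cut keeps within-cluster profile
correlations roughly above 0.7 without forcing a cluster count. Both the
metric/linkage pair and the cut are exposed because no single choice is
canonical for this assay. Cluster labels are assigned by decreasing size
(cluster 1 is the largest, ties broken by first occurrence), which makes
reports stable under row reordering; merge ties inside the tree are resolved
by `stats::hclust`'s deterministic ordering. The downstream size filter
(default: keep clusters with ≥ 20 genes) exists because set enrichment on
very small clusters is uninformative.

## Enrichment statistics

Cluster-level enrichment is the one-sided Fisher exact test — the
hypergeometric tail `P(X ≥ k)` for `k` of `n` query genes hitting a `K`-gene
set in an `N`-gene universe — with Bonferroni correction over the sets tested
and fold enrichment `k/(nK/N)`. The universe is the set of genes that survived
the expression floor and entered clustering, not the whole genome: the
question is always "more than expected among the genes in this gradient".

For correlation-ranked lists we report the minimum hypergeometric (min-HG)
score: the smallest tail p over all prefixes of the ranked list, with the
optimizing prefix length. This scan is *anti-conservative* across prefixes —
we do not compute the exact min-HG null (a dynamic program we consider out of
scope) — so the score is reported as a raw min-HG tail with BH FDR across
sets, and documented as an approximation.

## Gradient statistics

The weighted count `Σ_{i=x}^{y} i·n_i` summarizes how dense an entity
sediments; it uses raw abundances because its comparison target is a raw
total-abundance reference (e.g. ribosome-footprint TPM). Scatter comparisons
are done on `log2(v+1)` by default. Off-diagonal structure is quantified by
signed orthogonal (total-least-squares) residuals from the principal axis
rather than ordinary regression residuals, because neither axis is an
error-free predictor; the sign convention (positive = heavier than the axis
predicts) is fixed and documented so "this compartment sediments lighter than
its ribosome load predicts" is a one-sided test on residual sign.

RNA–protein coupling is the per-gene correlation between normalized RNA and
protein profiles over shared fractions. The percentile annotation rate
(default: top and bottom 20% by correlation) breaks ties at the boundary by
lexicographic gene id, making the selection deterministic. Within-cluster
protein coherence is the median of all pairwise protein correlations; for
clusters above 200 members the member set is first down-sampled to 200 under
a fixed seed (the exact median over all pairs is kept for every realistic
cluster size). Its null is built by reassigning protein profiles to clusters
via uniform random permutations of protein ids, recomputing per-cluster
medians per permutation, and pooling; the observed-versus-null comparison is a
one-sided rank-sum test. The permutation seed and count are recorded in the
result and in every written artifact.

## RBP-target prediction and hexamer statistics

An RBP's normalized peptide profile is correlated with every RNA profile (and
with cluster mean profiles) over shared fractions; RNAs strictly above the
correlation threshold (default 0.85) form the predicted target set. Raising
the threshold can only shrink this set, which the tests assert as an
invariant.

Hexamer enrichment counts *every overlapping occurrence* of each of the 4096
6-mers — the standard k-mer convention, and the one under which a clean
sequence of length `L` contributes exactly `L − 5` counts, an invariant
asserted per sequence. Windows containing `N` are skipped. The score is the
log2 ratio of pseudocount-smoothed frequencies normalized by total counts, so
a difference in total foreground/background sequence cannot masquerade as
motif enrichment; with matched pseudocounts the score is exactly antisymmetric
under foreground/background swap. Counting per-gene presence/absence instead
of occurrences is a documented alternative we did not adopt. Conservation
rates accept a generic per-base boolean mask (serialized as 0-based half-open
intervals); an occurrence counts as conserved only if all six positions are
marked.

CLIP density is binding sites per unit expression, with the expression summary
defaulting to mean TPM across the gradient (configurable). Default correlation
bins are `(-1, 0]`, `(0, 0.85]`, `(0.85, 1]`: anti/uncorrelated background,
intermediate, and the target-call region.

## The isoform ΔΨ screen

An isoform is analyzable only if its Ψ confidence-interval width is strictly
below 0.2 in *every* fraction; one bad fraction disqualifies it, and events
left with a single isoform are dropped (no usage contrast remains). ΔΨ is the
maximum-minus-minimum of Ψ across fractions, taken per isoform and maximized
over the event's isoforms — for two-isoform events the isoforms' Ψ values are
complementary, so every reasonable reading of "maximum usage difference across
the gradient" coincides; for events with more isoforms our per-isoform-span
convention is one defensible choice and is documented as such. Class
boundaries are `strong` (ΔΨ > 0.5) and `moderate` (0.25 < ΔΨ ≤ 0.5); a value
sitting exactly on a cut falls to the lower class, a convention we fixed
because strict inequalities on both sides would leave the cut points
unassigned. Conservation comparisons between classes are one-sided rank-sum
tests (regulated more conserved) with BH adjustment across the two
comparisons.

Throughout the package, rank-sum tests use exact p-values whenever the sample
permits and mid-rank normal approximation under ties; the fully degenerate
case (every value identical in both groups) returns p = 1 by convention since
no rank information exists.

## The synthetic gradient generator

The generator emits every input the pipeline consumes, together with the
ground truth that produced it, so recovery can be measured rather than
eyeballed. It emulates:

- **24 collected fractions**, RNA usable in 3–24, protein in 3–19.
- **K = 6 compartments** of 150 genes each by default. Sedimentation kernels
  are a light-edge exponential decay, four interior truncated Gaussians
  (sd 2.5 fractions, centers evenly spaced), and a dense-edge exponential
  rise — the shape variety seen in real gradients, spaced so that no two
  kernels correlate above ~0.5 (compartments are genuinely distinct) and peak
  enrichment of compartment mean profiles over uniform stays in the 2–4-fold
  band.
- **Gene profiles** are `scale × ((1−α)·uniform + α·kernel) × ε` with mixing
  α = 0.9, per-gene log-normal scales (median 20 summed TPM, log-sd 1), and
  log-normal multiplicative noise ε with σ = 0.2 — abundance data are positive
  and heavy-tailed, so additive Gaussian noise would be the wrong model.
  50 background genes draw independent random kernels and belong to no
  compartment.
- **RNA–protein coupling**: genes flagged secreted (probability 0.8 in the
  secretory compartment, 0.1 elsewhere — overall ≈ 20%) get proteins sharing
  their RNA kernel; all other proteins use the fraction-reversed kernel. One
  mechanism thus produces the three observations the analysis should recover:
  a negative-median RNA–protein correlation histogram, a secreted-gene excess
  among the most-correlated genes, and within-cluster protein coherence that
  beats a shuffled null.
- **Five RBP peptide profiles** tracking compartments 1–5; the one tracking
  the secretory compartment has the hexamer `TGCATG` planted into 60% of its
  target genes' UTRs (i.i.d. ACGT background, 150–500 nt), with planted motif
  bases fully conserved against a Bernoulli(0.5) background mask. CLIP counts
  are Poisson with a rate multiplier that ramps smoothly with the gene's
  kernel correlation to the RBP, reaching 3× on true targets — so target
  status drives a 3-fold site-rate excess while partially correlated genes
  sit in between, as binding data do.
- **50 isoform events** (strong/moderate/non-regulated = 15/15/20) whose
  tracked isoform's Ψ ramps linearly across the gradient by a class-specific
  span, with spans leaving margins around the 0.25/0.5 boundaries so small
  estimation noise (σ = 0.01 per fraction) cannot flip a label; 10% of events
  receive one wide-CI isoform to exercise the confidence filter; per-event
  conservation scores are unit-normal with class shifts +1/+0.7/0.

Every sub-generator draws from its own RNG stream derived from the master
seed, so adding one output never perturbs another, and identical configs give
byte-identical outputs.

**What the generator does not emulate** — and hence what passing tests do not
show about real data: real UTR composition and motif co-occurrence structure,
isoform-level quantification error correlated across fractions, batch and
replicate variation between gradients, genes belonging to multiple
compartments, and RBPs binding targets across several compartments. Recovery
metrics here validate the statistical machinery under the stated model; they
are not estimates of real-data sensitivity.

## Problem sizes and numerical choices

The default study conditions (950 genes, 400 proteins, 5 RBPs, 50 events, 100
permutations, 200 power replicates) run the full pipeline in well under a
minute, which we consider the right scale for a validation suite; all sizes
are configuration fields. Normalization tolerances are 1e-9 on row sums;
oracle comparisons in the tests are at 1e-12. Degenerate inputs are errors,
not silent NaNs: constant profiles cannot be correlated, empty queries cannot
be enriched, and single-fraction events have no gradient span.

```{r example}
sim <- simulate_gradient(simulation_config(seed = 1))
norm <- normalize_profiles(sim$rna)
cl <- cluster_profiles(norm)
glance(cl)
truth_metrics(sim, clusters = cl)$ari
```

## Known limitations

The min-HG p-value is anti-conservative across prefixes (no exact
multiple-threshold correction). The hexamer background model is i.i.d.;
real 3′ UTRs have dinucleotide structure that inflates some k-mer ratios.
Cluster-count outcomes depend on the cut height and are data-dependent — we
expose the knob rather than chase a particular number of clusters. The
pipeline predicts association from co-sedimentation; co-sedimentation is
consistent with, but never proof of, physical interaction or shared
localization.
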