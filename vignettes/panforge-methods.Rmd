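---
title: "panforge: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panforge: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panforge)
```

panforge implements a complete comparative pan-genome workflow — ortholog
clustering, partition analysis, dual phylogenies, selection-pressure
estimation, gene-family gain/loss inference, horizontal-transfer detection
and gene-cluster synteny — together with a seeded synthetic-data generator
that plants a known truth for every stage. This vignette explains the models
and their assumptions, the parameters that matter, the numerical choices, and
what validation on synthetic data does and does not establish.

## The synthetic-data generator

The generator emulates a clonal bacterial genome collection related by a
species tree, with gene content shaped by vertical descent, family gain and
loss, and occasional horizontal acquisition.

**Species tree.** `simulateSpeciesTree()` draws a pure-birth (Yule) tree with
the requested number of extant leaves. The tree is ultrametric and binary;
its depth is set by the birth rate (about `log(n)` time units at rate 1).

**Gene content.** `simulateGeneContent()` plants three family strata: a core
set present in every genome, root accessory families, and families gained
along branches. Gains arrive as a Poisson process with intensity `gain_rate`
per unit branch length; a loss-prone family survives a branch of length *t*
with probability `exp(-loss_rate * t)`. Core families are exempt from loss:
the observational definition of "core" (present in every sampled genome)
needs a planted, guaranteed-non-empty truth to validate against, so the core
stratum is core *by construction* while accessory families may incidentally
survive everywhere. Gains on terminal branches yield strain-specific
families. Horizontal acquisitions are planted as singleton families on
terminal branches at `hgt_rate` expected events per genome, each with a
recorded donor drawn from a Vibrio-dominated pool of outgroup genera.

**Sequences.** Every family receives a random root CDS (first codon fixed at
ATG, all codons drawn from the 61 sense codons) evolved along the tree under
a Goldman–Yang-style codon model: substitutions between single-nucleotide
neighbor codons at relative rate κ for transitions, multiplied by ω for
nonsynonymous changes, uniform codon frequencies, and the matrix scaled to
one expected substitution per codon per unit branch length. No indels are
simulated, which removes the multiple-alignment stage from the pipeline while
preserving the input contract of every estimator. The `divergence_scale`
parameter (default 0.1) multiplies species-tree branch lengths before
sequence evolution, so sequence divergence can be set independently of tree
shape; the default gives roughly 0.2–0.4 substitutions per codon between
distant leaves — high enough that families are visibly diverged, low enough
that homology is unambiguous.

**Similarity tables.** `simulateOrthologHits()` computes percent identity
from the actual simulated proteins for all within-family pairs, converts it
to a BLAST-like bit score (about two bits per identical residue) and a
Karlin–Altschul-style E-value, and adds a low rate of spurious weak
cross-family hits. Spurious hits are drawn only among genes that also carry
genuine homology signal: a spurious hit joining two otherwise hitless
singletons would create a two-node component that *no* graph clustering can
distinguish from a real two-gene family, so that unresolvable regime is
deliberately not simulated (and is a known failure mode on real data).
`simulateHitTable()` builds taxon-labelled best-hit profiles for transfer
detection: vertical genes get strong self and close-group hits with sparse
weak distal hits, implanted transfers get distal-dominated profiles whose top
distal hit carries the recorded donor.

**What passing on this generator shows.** That the estimators recover the
parameters of their own generating model at realistic sizes, and that the
pipeline's bookkeeping (partitioning, counting, ordering) is exact. It does
not show robustness to indels and alignment error, rate heterogeneity across
sites or lineages, annotation noise, contamination, or taxon sampling biases
in real databases.

## Ortholog clustering

Hits are filtered at E ≤ 10⁻⁵ (the standard cutoff for this workflow) with
self-hits dropped; edge weight is −log₁₀E capped at 200 (for E = 0) and
averaged over reciprocal directions. Percent identity is deliberately *not*
used as a clustering filter — only the E-value cutoff is applied. A
species-mean weight normalization (as in OrthoMCL proper) is not performed;
the plain −log₁₀E graph is simpler and recovers planted families exactly in
the tested regimes.

MCL runs on a sparse column-stochastic matrix with self-loops set to each
node's maximum incident weight (loops stabilize the iteration on small
cliques). Defaults: inflation 1.5, expansion 2, pruning threshold 10⁻⁵,
convergence tolerance 10⁻⁶ on the maximum entry change, at most 200
iterations (non-convergence is an error, never silently accepted). Clusters
are the connected components of the converged matrix. Families are classified
core / accessory / specific by the number of genomes represented; unclustered
genes become their own specific singleton families, so the clustering always
partitions the full gene universe.

## Pan-genome structure and openness

Accumulation curves average over 100 random genome orderings (a single
ordering, as some studies plot, is a special case; permutation averaging is
the field-standard stabilization). Heaps' law is fitted by least squares on
`log pan(n) = log κ + γ log n`; an exact power-law input is reproduced to
machine precision. The openness verdict uses γ > 0.05 rather than γ > 0: a
genuinely closed pan-genome estimated from finitely many permutations
produces small positive exponents, and 0.05 leaves room for that noise.

One behavior worth knowing: openness verdicts conflate *unbounded growth*
with *unsaturated sampling*. A collection with zero gain but heavy loss has
bounded total gene content, yet each added genome reveals previously unseen
root families, the curve keeps rising across 20–25 genomes, and the Heaps fit
honestly calls it open (γ ≈ 0.07–0.13 at loss rate 0.5). The package's
closed-pan-genome validation scenario therefore uses zero gain with mild
residual loss (0.05 per family per unit branch length) — the regime where
"closed" is actually identifiable from an accumulation curve at this scale.

Annotation profiling (CAZyme classes, GO slims, COG letters) consumes
externally produced gene→label tables; a family carries a label if at least
one member does, and is counted once per distinct label. Computing the
annotations themselves is out of scope.

## Phylogenies

The single-copy supermatrix tree concatenates per-family alignments
(provenance kept as a partition attribute), filters columns by gap fraction
(> 0.5 removed) and conservation (majority character < 0.5 removed), computes
p- or Poisson-corrected distances, and builds a neighbor-joining tree;
bootstrap support resamples columns with replacement and annotates each
internal edge with the percentage of replicates containing its bipartition.
NJ stands in for full maximum-likelihood inference: the validation questions
here are about topology recovery (NJ is consistent on additive distances,
verified against least-squares enumeration), not likelihood scores, and the
same choice keeps the presence/absence tree method consistent. Negative NJ
branch lengths arising from noisy distances are clamped to zero. The
gene-content tree uses Manhattan distances between 0/1 family profiles
(equal to Hamming counts on binary vectors) and the same NJ engine. Trees
are compared by Robinson–Foulds bipartition distance; both trees are left
unrooted (no outgroup is assumed).

## Selection pressure

**NG86 counting.** Synonymous sites per codon are the fraction of the three
alternative nucleotides at each position producing a synonymous change, with
changes that create stop codons counted as nonsynonymous opportunities;
differences between codons differing at several positions are averaged with
equal weight over substitution orders, excluding pathways that pass through a
stop codon (if every pathway is blocked, stop steps count as nonsynonymous).
Both proportions get the Jukes–Cantor correction `d = −(3/4)·ln(1 − 4p/3)`,
with p ≥ 3/4 reported as saturation rather than extrapolated. When dS = 0, ω
is reported as *undefined* (NA) — not 0 or infinity — so that category
summaries are not polluted by fake signals.

**M0 maximum likelihood.** The single-ratio codon model uses the same
GY94-style rate matrix as the simulator with uniform codon frequencies
(F-equal rather than F3×4; the estimator then matches the generating model
exactly, and frequency estimation is orthogonal to the questions tested).
The likelihood is computed by pruning over pattern-compressed alignment
columns with per-pattern rescaling; ω, κ and all branch lengths are
optimized on log scale by L-BFGS-B within [10⁻⁴, 20], [0.05, 50] and
[10⁻⁶, 20] respectively, restarted from ω ∈ {0.1, 1.0, 2.0} with the
highest-likelihood solution kept. dN and dS are derived from the fitted tree
length by partitioning the expected substitutions per codon into synonymous
and nonsynonymous flux, with site proportions taken from the mutational
(ω = 1) matrix. An all-identical alignment short-circuits to zero branch
lengths and undefined ω.

NG86 carries the classic downward bias on data generated with transition
bias (κ = 2): transitions are disproportionately synonymous, so the
unweighted site counts understate synonymous opportunity and ω̂ lands about
0.1–0.2 low near neutrality. The M0 fit models κ and is the estimator used
for quantitative recovery claims; NG86 remains the fast counting
cross-check, its hand-derivable worked example anchoring the test suite.
Site-class models (M7/M8) and their likelihood-ratio tests are out of scope,
a recorded limitation.

## Gene-family gain and loss

Family sizes evolve under the standard birth–death size-transition law with
a single symmetric rate λ; with α = λt/(1+λt), the s→c transition
probability is the closed-form sum given in `?bdTransition`, valid for
α < 1/2 (λt < 1; longer branches are an error, not an extrapolation). Size 0
is absorbing. Transition rows are renormalized after truncation at
`size_cap = 2·max(observed) + 10`, which bounds truncation error cheaply.
The root prior is uniform on 1..size_cap — a family observed in the
collection is assumed to have existed at the ancestor, matching the
most-recent-common-ancestor framing of the analysis. The global λ maximizes
the summed pruning log-likelihood over a bounded interval; ancestral sizes
are the joint max-probability assignment (Viterbi over the same lattice)
with ties broken toward the smaller size change, a parsimony-flavored
deterministic rule. Family significance is Monte-Carlo: the p-value is the
fraction of ≥ 1000 null families (root resampled from the prior, evolved
under λ̂) whose likelihood is at most the observed one; ties make the
p-value mildly conservative, and calibration is verified (fraction below
0.05 equals 0.05 ± 0.02 on null data). Per-branch rate variation and
annotation-error corrections are not modeled.

## Horizontal-transfer detection

Each gene's retained hits (identity ≥ 50 %, E ≤ 10⁻⁵, best 500 by bit
score, deduplicated by query–subject pair) are partitioned into self, close
and distal taxa, normalized by the gene's best bit score and summed per
group. Two identity thresholds are exposed because the upstream workflow
uses both: 50 % for best-hit screening (the default here) and 90 % for a
strict re-run (`strict = TRUE`). Cutoffs come from the score distributions:
the first local minimum of a Gaussian KDE (Silverman bandwidth) between the
two largest modes, accepted only if the valley dips below half the smaller
mode — wiggles of a unimodal density must not produce a cutoff mid-
distribution. When no separated secondary mode exists the data carry no
transfer signal and the cutoffs are set so nothing is flagged (close 0,
distal ∞), which is what keeps the false-positive rate on transfer-free data
at zero; an explicit quantile method (close q25, distal q75) is available
when the user prefers fixed quantiles over the conservative default. A gene
is called transferred when its close score falls below the close cutoff
while its distal score reaches the distal cutoff; the donor is the taxon of
its best distal hit. Mobile-element screening against plasmid/IS/phage
databases requires external resources and is replaced by an annotation-table
hook; tree-reconciliation transfer inference is out of scope.

## Synteny of the metal-reduction cluster

The reference locus is the seven-gene order *mtrD–mtrE–mtrF–omcA–mtrC–mtrA–
mtrB* with the *feoA–feoB* ferrous-iron operon as flank. Labels are mapped to
families through the reference genome's genes (collisions — two labels in one
family — are an error, not silently merged). Within each genome the locus is
read along the contig run containing the most cluster genes, tolerating up to
`max_gap_genes = 5` intervening non-cluster genes between consecutive members
(gene insertions are common and should not break the locus). Copy numbers are
counted genome-wide, so dispersed extra copies are visible; a genome is
*complete* only when every label has a copy and all labels sit in that single
run. Reverse-complementing a contig reverses the read-out order and flips
strands but changes no copy number or completeness call. The four-genome
benchmark (`simulateClusterFixture()`) plants the canonical fates — complete,
mtrDEF-less, omcA-duplicated with a split locus, absent — and the profiler
reproduces the planted truth exactly.

## Problem sizes used in validation

The shipped validation suite uses: 24 genomes with 200 core + 300 root
accessory families for clustering recovery; 100-permutation accumulation
curves; 50 random 4–8-leaf trees for NJ consistency; 2000-codon, 4-taxon
alignments with 20 replicates per ω ∈ {0.1, 0.5, 1.0} for M0 recovery;
300 families on an 8-leaf tree for λ recovery and 400 for p-value
calibration (1000 null draws); ~500 genes with 10 % implants for transfer
recovery. These sizes keep each property statistically meaningful while the
whole suite runs in minutes on one core.

## Known limitations

* No indel evolution or alignment uncertainty; column filtering exists but is
  exercised only by constructed cases.
* Uniform codon frequencies throughout; F3×4 or empirical frequencies are not
  implemented.
* Single global λ for gain/loss; no per-branch or per-category rates.
* Transfer detection is profile-based only; phylogenetic reconciliation
  methods will disagree on ancient or within-clade transfers.
* The openness verdict is a curve-shape statistic, not a statement about the
  true gene-content process (see the closed-pan-genome discussion above).
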