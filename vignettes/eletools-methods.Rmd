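---
title: "Annotating transcribed enhancer-like elements from CAGE data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating transcribed enhancer-like elements from CAGE data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`eletools` annotates transcribed enhancer-like elements (ELEs) from
stranded CAGE 5′-end count data in a multi-subgenome (polyploid) genome
and characterizes them: tissue specificity, transposable-element (TE)
origin, target-gene links, LTR insertion ages, and cross-subgenome
homology. All genomic coordinates are 0-based half-open everywhere
inside the package; conversion to and from 1-based inclusive coordinates
happens only at the GFF3 boundary. CTSS tables are strand-specific: a
`+` and a `-` record at the same position are distinct observations.
Every on-disk output passes a deterministic sort (chromosome, start,
end, strand) so repeated runs diff cleanly.

# Tag clustering

Counts are normalized per sample to reads per million (RPM). For each
tissue, replicate RPM is averaged per position and positions at or above
`ctss_rpm_threshold` (default 0.5 RPM) are partitioned into maximal runs
in which consecutive retained positions lie at most `max_dist` (default
20 bp) apart; sub-threshold positions never seed, join or bridge
clusters. The two defaults are the conventional distance-clustering
settings of CAGE tag-cluster callers; both are configurable.

A tissue-level cluster is kept only when at least
`min_supporting_samples` (default 2) replicates each contribute at least
one read at a retained position inside the cluster. We interpret
"supported by at least two samples" as *within-tissue replicates*, and
count support at the CTSS level rather than requiring an independent
per-replicate cluster call: this is robust to replicate-depth
differences and is the weaker (more permissive) of the two readings.

Tissue cluster sets are merged by strict ≥ 1 bp same-strand overlap into
union intervals. Bookended (adjacent) clusters are *not* merged: under
half-open coordinates adjacency is a zero-width intersection and merging
it would make the merge sensitive to how a run was split. The merge is
idempotent and invariant to tissue order. The dominant position is the
position with the highest all-sample pooled RPM (leftmost on ties), and
clusters wider than 10 bp are *broad*, all others *sharp* (strict at
10).

Signal positions that never enter a kept cluster are grouped by the same
distance rule into *weak* clusters. These are the rescue pool for the
chromatin-state stage: "weak" covers both failure modes (insufficient
replicate support and sub-threshold signal).

# Chromatin-state model

Per-track bin counts over 500-bp tiles are binarized by a Poisson
upper-tail rule: a bin is 1 iff `P(X ≥ count | λ = track mean) < 1e-4`,
the convention of binarized chromatin segmentation. The hidden Markov
model has independent Bernoulli emissions per track (product form),
first-order transitions, and is fit by Baum–Welch with scaled
forward–backward recursions. The per-iteration log-likelihood is
asserted non-decreasing (within 1e-8); emissions are floored at 1e-6
during M-steps to keep the likelihood finite. Several random restarts
(seed-derived sub-seeds) are run and the best final log-likelihood wins,
ties by restart index, so a fit is a pure function of `(data, seed)`.

Decoding is posterior argmax per bin (ties toward the lower state
index); Viterbi is available behind `method = "viterbi"`. Posterior
decoding was preferred because the rescue rule is applied bin-by-bin and
smoother marginal calls behave better at state boundaries than the
single jointly-best path.

State labels are arbitrary across fits, so the TSS-active state is
identified *functionally*: the state maximizing the product of emission
probabilities on the CAGE, H3K4me3 and H3K9ac tracks. Any track set
containing these three names is accepted. On data where both gene
promoters and ELEs are planted, two states may fit this profile (they
differ in elongation-track context); the functional rule then picks one
deterministically, which is sufficient for rescue because rescue is
additionally gene-linked. A weak cluster is rescued as a low-confidence
gene TSS when its dominant position falls in a TSS-active bin *and* it
lies in a gene's 5′UTR, 500-bp upstream window, or gene body, on the
gene's strand.

The pipeline default fits 10 states with 2 restarts and 100 iterations
on roughly 12,000 bins × 6 tracks; the model-recovery tests use 2–3
state planted chains of 10,000–12,000 bins, where parameters are
recovered within ±0.05 after state matching. Fitting 15 states is
supported and only changes runtime.

# TSS annotation

Categories are assigned in fixed precedence and form an exhaustive
partition of the input clusters:

1. *gene_tss* — a confident cluster overlapping a gene's 5′UTR or the
   strand-aware `[TSS − 500, TSS)` window, on the gene's strand. CAGE is
   stranded and a gene TSS is sense transcription, so antisense clusters
   at promoters are deliberately not gene-assigned. Multi-gene ambiguity
   resolves to the nearest annotated TSS from the cluster's dominant
   position, then lexically smallest gene id.
2. *ele_tss* — a confident cluster more than 3 kb (strict) from every
   gene model, overlapping at least one H3K4me3 or H3K9ac peak (≥ 1 bp,
   any strand). Distance is interval-to-interval.
3. *lc_gene_tss* — a weak cluster passing the chromatin-state rescue.
4. *intergenic_other* — intergenic without a qualifying mark. Weak
   clusters that fail rescue flow through the same intergenic/proximal
   rules but are never promoted to ELEs: ELE calling requires a
   confident cluster.
5. *proximal_unclassified* — within 3 kb of a gene but not
   gene-assigned. The source workflow leaves these clusters' fate
   unstated; an explicit label keeps the partition exhaustive instead of
   silently dropping them.

# ELE–gene linking

Candidate pairs are all (ELE, gene) combinations within 2 Mb on one
chromosome, with distance measured dominant-position to annotated TSS
(both are points in this framework). A gene's regulatory potential is
`RP = Σᵢ 2^(−dᵢ/d₀)`, `d₀ = 100 kb`, over ELEs within `20·d₀`. The
"top 50% RP" eligibility threshold is the median RP over genes having at
least one contributing ELE — not over all genome genes and not over
pairs; this is the reading under which the threshold depends only on the
linked gene population, and it is configurable (`rp_quantile`).
Correlation is per (ELE, gene) pair, Pearson, across all tissue ×
replicate samples of CAGE RPM (gene expression is the CAGE RPM of the
gene's own TSS clusters, not RNA-seq). A zero-variance vector has no
defined correlation and fails the filter. A pair is predicted iff
*r* > 0.5 strictly and its gene is RP-eligible.

Tissue specificity uses the τ index over per-tissue mean RPM,
`τ = Σ(1 − xᵢ/x_max)/(n−1)`, with `τ ≥ 0.8` calling a feature specific
to its maximal tissue, expressed features below it ubiquitous, all-zero
rows silent. The source analysis never states its specificity criterion;
τ is the field-standard choice and 0.8 its customary stringency.

# TE analysis and LTR dating

An ELE is TE-embedded iff its dominant position lies inside a TE copy;
nested copies resolve to the innermost (shortest) element. Family and
subfamily enrichment tests each group's copies for ELE-bearing status
against all other TE copies (the whole-genome TE complement as
background); tissue-bias enrichment tests group membership against
tissue-specific status with all ELEs as background. Both use the
two-tailed Fisher exact test under the conventional rule (sum of tables
with point probability not exceeding the observed), with BH adjustment
across groups; raw p values are also reported. The odds ratio reported
is the sample estimate `ad/bc` with 0/0 undefined and x/0 infinite.

LTR pairs are aligned globally (match +1, mismatch −2, gap of length L
costs 5 + L) via Biostrings; columns with gaps or N are excluded before
the Kimura two-parameter distance
`d = −½ ln(1−2P−Q) − ¼ ln(1−2Q)` (P transitions, Q transversions per
comparable site). When a log argument is non-positive the distance is
saturated and reported as such rather than extrapolated. Insertion time
is `time = distance/(μ·2·100)` with distance in percent — the ·100 is
the percent-to-fraction conversion of distance-matrix output, so
equivalently `time = d/(2μ)`: both LTRs were identical at insertion and
each diverges at μ per site per generation (default 1.3×10⁻⁸; one
generation per year converts to years).

PWM scanning is a log₂-odds scan of both strands. The hit threshold is
the smallest score with background p ≤ 1e-4, computed by exact
convolution of the per-column score distributions on a 1e-3 lattice.
Short motifs whose *maximal* score cannot reach that p fall back to
exact-consensus matches (only the maximal score hits); a constant score
distribution (e.g. a uniform PWM) stays uninformative and never hits.
Group comparisons normalize occurrences by group size (per-TSS
normalization) and test per-sequence counts with a two-tailed Welch
t-test; two degenerate zero-variance groups yield p = 1 when equal and
p = 0 with an infinite statistic when separated.

# Subgenome homology

Collinear anchors are obtained from a supplied homoeolog mapping by
longest-increasing-subsequence chaining per chromosome pair (strictly
increasing in both subgenomes, chains of ≥ 3 kept). This replaces a
full synteny engine: at this scale, with homoeolog relations given, LIS
chaining is deterministic, dependency-free and exact for the planted
structure. Regions between consecutive anchors are syntenic blocks.

For each ELE inside a block, the query is its TSS plus 200 bp
downstream on the ELE strand; it is Smith–Waterman aligned (same scoring
as above) against both strands of the counterpart block, and the best
score S is converted to a Karlin–Altschul E-value `E = K·m·n·e^(−λS)`.
λ is solved exactly from `Σ pᵢpⱼ e^(λ sᵢⱼ) = 1` for the ungapped +1/−2
scheme under a uniform background (λ ≈ 1.333); K is calibrated once per
scoring scheme by Gumbel moment matching on fixed-seed random alignments
and cached. Applying ungapped statistics to gapped scores is an
approximation (it slightly understates E for gapped optima); with the
E ≤ 0.01 cutoff the observed false-hit rate on random 201-bp queries
against multi-kb blocks stays below 5%, while genuine homologs score
far beyond the threshold. Hits are classified active when the homologous
locus overlaps an H3K4me3 or H3K9ac peak in the counterpart subgenome —
the same mark set that defines ELEs, pooled over tissues (the source
procedure does not state a tissue restriction; a per-tissue peak list
can be supplied instead). An ELE with an active homolog in neither other
subgenome is subgenome-specific, in exactly one shared, in both common.

# The synthetic study system

The generator emulates the structure the analysis is designed to detect,
at desk scale: three 2-Mb subgenomes (A/B/D) with 60 genes each in
shared homoeologous order (90% collinear; the rest locally swapped to
exercise chaining); four TE subfamilies of which the Gypsy subfamily
RLG_famc7.3 is expanded only in subgenome A (40 copies vs 2 and 2); 60%
of its copies host an ELE at the copy's 5′ edge, transcribed only in
spike; a smaller Copia subfamily hosts root-biased ELEs; and five
homoeologous non-TE ELE groups are planted at identical positions with
identical 600-bp cores in all three subgenomes, active in all tissues.
Full-length LTR elements carry 5′/3′ LTR pairs diverged by a per-element
draw from [0.01, 0.06] substitutions per site under a K2P-symmetric
process with a 2:1 transition:transversion ratio — the dating model is
therefore correctly specified, and model-mismatch behaviour is exercised
separately by the saturation tests.

CAGE output: sharp gene TSSs place all tag mass within 10 bp (peaked
weights), broad TSSs spread uniformly over a per-gene 20–60 bp width;
ELEs emit bidirectionally from their 5′ edge, reflecting the
edge-initiation of eRNAs; replicates are independent Poisson draws
around tissue means; background noise is Poisson at 1e-5 per bp per
strand. Expressed gene promoters and active ELEs receive H3K4me3/H3K9ac
peaks and promoter-profile bin counts (CAGE/marks/open/nascent over a
Poisson(1) background); gene bodies receive elongation signal; TE bodies
are CG/CHG hyper-methylated (90%) except hypo-methylated windows around
planted ELEs (10%). About 8% of genes emit only a two-tag
single-replicate signal (rescue candidates) and 10% are silent.

Free parameters with no stated counterpart in the source system — gene
tag means (60 per sample), ELE tag means (30 per strand), the
"common"-ELE tissue profiles — are the generator's own choices,
documented here and fixed. Common-group profiles are a permuted two-fold
ladder (8/16/32/64 RPM): planted ELE–target pairs must be genuinely
correlated for the linking stage's correlation filter to be a fair test,
and a near-flat profile would make the planted correlation
noise-dominated (its τ ≈ 0.7 stays below the specificity cutoff).
Each planted ELE's true target is the nearest untaken active gene, which
inherits the ELE's expression profile (scaled 1.5× for common groups,
tissue-biased for TE ELEs).

What passing tests do and do not show: the generator uses uniform random
background sequence, exact TE consensus copies at 2% divergence,
noiseless peak placement and a correctly specified substitution model.
Recovery of the planted structure therefore validates the *logic and
numerics* of the pipeline — thresholds, formulas, classifications — not
its robustness to mappability artifacts, peak-caller noise, diverged
homoeologous sequence, or rate variation in real data.

# Numerical choices and degenerate inputs

* Quantile type 1 (inverted ECDF) for the RP threshold, so "top 50%"
  includes the median gene exactly.
* Dominant-position, multi-gene, nearest-TSS and enrichment-ranking
  ties all break deterministically (leftmost position, lexical id,
  descending odds ratio after rounding p to 12 significant digits).
* `fisher_exact_2x2(0,0,0,0)` returns p = 1 with an undefined odds
  ratio; single-member groups are tested, with appropriately wide
  uncertainty, rather than skipped.
* HMM likelihoods of impossible observations are exact −∞ (not a large
  negative number); EM errors out on impossible data rather than
  silently renormalizing.
* The K2P estimator returns a saturation sentinel instead of a distance
  when `1−2P−Q ≤ 0` or `1−2Q ≤ 0`.
* All simulations draw from a private RNG stream and restore the
  caller's `.Random.seed`.

Problem sizes used by the test suite and the acceptance script — 2-Mb
subgenomes, 10,000–12,000-bin HMM chains, 200 LTR pairs, exhaustive
Fisher enumeration over row sums ≤ 12 plus randomized checks to margins
of 30, alignment-oracle strings to 12 bp — are the package's validation
scale, chosen so the full suite runs on a laptop in minutes.

# Known limitations

* The HMM assumes track independence given the state; correlated tracks
  (e.g. H3K4me3/H3K9ac) can inflate state confidence.
* Karlin–Altschul parameters for gapped local alignment are
  approximated by the ungapped solution with a calibrated K.
* The homology search is block-restricted by design; ELEs outside any
  collinear block are reported as such, not searched genome-wide.
* Gene expression for linking is CAGE RPM at the gene's TSS clusters;
  genes whose TSS yields no cluster cannot be linked.
* Tissue specificity is a hard τ threshold; borderline profiles flip
  labels under resampling.
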