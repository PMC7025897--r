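---
title: "Methods and design notes for svpatterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for svpatterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpatterns)
```

This vignette records the models behind `svpatterns`, the parameters that
matter, and the design decisions taken where the methodology was genuinely
open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## Coordinates and breakends

All internal coordinates are 0-based with half-open intervals; a breakend is
a single base position plus a side: `left` means the retained/joined
sequence lies at coordinates at or below the position, `right` at or above.
BEDPE strand `+`/`-` maps to `left`/`right`; VCF 4.2 bracket notation maps
via the four ALT forms and converts 1-based to 0-based losslessly (a
round-trip property test covers both directions). The side vocabulary
replaces strand symbols internally because `+`/`-` conventions differ
subtly across SV callers.

Junctions store their two breakends in canonical order (chromosome rank,
then position), so orientation classes are well defined: `DEL-like`
(left at the lower coordinate), `TD-like` (right at the lower), `head-head`
and `tail-tail` inversions, and `interchromosomal`.

## Clustering model

Junction breakpoints are grouped under an explicit null: with `n` breakends
callable over `G` bp, nearest-neighbour distances under uniform placement
follow `P(D <= d) = 1 - exp(-lambda d)`, `lambda = n/G`. Two breakends link
when that probability is below `p_merge`; clusters are connected components
of proximity links plus the always-present link between a junction's own
two breakends; footprints are maximal proximity-linked runs per chromosome.

Key choices:

* **Intra-junction exclusion.** The distance between a junction's own two
  breakends never contributes a proximity link, so a 5-Mb simple deletion
  is a single cluster with two single-breakend footprints rather than a
  spuriously "clustered" event. This is also how the dependence of
  clustering on the event-size distribution is absorbed: the merge decision
  sees only between-junction distances.
* **Defaults.** `p_merge = 1e-3`; callable size defaults to 0.9 of the
  genome length (roughly the uniquely mappable fraction of a human
  reference), overridable wherever it appears.
* **Determinism.** Links are evaluated over position-sorted breakends; the
  result is a partition, so agglomeration order cannot change it.

The exact statistic used by large published cohort analyses of this kind is
typically more elaborate (orientation- and size-aware); the Poisson
nearest-neighbour null is this package's documented stand-in and is
isolated in `cluster_model()` / `cluster_junctions()` so it can be swapped
without touching anything downstream. Calibration is checked empirically:
200 uniform junctions per 100-Mb genome over 100 replicates produce
multi-junction clusters at a rate consistent with `p_merge` (binomial
test in the suite).

Pre-filters applied before clustering: removal of redundant
segment-bypassing junctions (a junction whose two breakends are reproduced,
within 50 bp and with matching sides, by a path of two or more other
junctions traversing CN segments end-to-end); removal of short inverted
junctions (span < 5 kb) with no total-CN step of at least 0.5 copies within
10 kb — the signature of fold-back artefacts without read support; and
annotation of mutually overlapping balanced breakpoints versus candidate
very short templated insertions (100 bp scale).

Cluster refinement: a multi-junction cluster splits when every member is
independently a CN-consistent simple deletion or tandem duplication with
pairwise non-overlapping interiors (two unrelated deletions that happen to
share a neighbourhood); clusters with overlapping footprints merge.

## Copy-number context and classification

Total copy number is real-valued consensus data, so flatness is defined as
|step| < 0.5 copies and interval gains are length-weighted modal values of
`round(total_cn - background)`. The background is the coverage-weighted
mode of half-integer-rounded CN — rearrangement patterns are read relative
to the chromosome background the tumour actually has.

The decision cascade runs: single-junction rules (orientation + CN);
two-junction pattern keys (reciprocal inversion/translocation and the three
local 2-jump structures — dup/inverted-triplication/dup, inverted
duplications, deletion plus inverted duplication — matched as canonical
pattern keys against programmatically constructed prototypes, which buys
mirror- and relabeling-invariance for free); templated-insertion path
search; local and local–distant rules (1 Mb locality threshold, matching
the tight footprints such clusters show); chromoplexy (three or more
junctions, every breakend CN-flat, at least two chromosomes); a
deliberately coarse chromothripsis flag (>= 10 junctions and >= 10
oscillation switches between two CN states on one chromosome — full
chromothripsis characterization is out of scope); otherwise
complex/unclassified. Missing CN coverage downgrades to
complex/unclassified with a flag rather than erroring.

**Templated insertions.** The segment graph carries elementary intervals
between consecutive cluster breakends with their CN gains. A candidate
template is a gained elementary interval flanked by a `(start, right)`
breakend of one junction and an `(end, left)` breakend of another; a
templated-insertion event is a simple alternating walk using every cluster
junction once. Topology: both free ends on one chromosome with the
inter-end segment gained is a **cycle** (the host segment is rereplicated);
with the segment lost or absent, a **bridge**; free ends on two different
chromosomes at unbalanced CN transitions, a **chain**. Ties among valid
walks are broken deterministically (ordered start junctions and templates);
the first complete walk is reported.

Every reported path is **replayed**: `replay_path()` reconstructs the
derivative chromosome and emits the junctions and CN gains it implies, and
`path_replay_consistent()` requires exact agreement with the observed
cluster. The simulator emits events by the same construction, so the replay
oracle is shared between the two modules and closes the loop: simulation
-> classification -> replay -> identity.

## The configuration library

Enumeration works on an abstract alphabet: each reference chromosome is a
string of atomic segments and every cut falls at an interior segment
boundary, because two cut placements are equivalent exactly when they
induce the same segment partition. Cuts at telomeres are excluded — they
produce junction-free terminal events invisible to junction-based
observation (a documented, deliberate gap: a telomeric inversion pattern is
likewise not enumerated; fold-backs are recognized by classification rules
instead). Operations are DEL/TD/INV between two cuts, balanced and
unbalanced translocations, and whole-chromosome gain/loss. The default
substrate is two chromosomes of 3 and 2 atoms; the shipped depth is 3 with
a refusal guard above 5 (the state space grows combinatorially).

A derivative genome reduces to observable evidence — deduplicated junctions
between reference boundaries plus per-atom copy number — and then to a
**pattern key**: per-chromosome breakend side strings and compressed runs
of relative CN (capped at ±3) for each inter-breakend interval and flank,
plus junction wiring. The key is canonicalized by minimizing the
serialization over chromosome-group permutations and the global mirror
image. Observed clusters serialize through the same intermediate, with
breakend positions within 100 bp collapsing to one locus so that, e.g., a
reciprocal translocation's two overlapping breakpoints align with the
enumerator's shared-boundary cuts.

Correctness is checked two ways: an independently coded naive enumerator
(pure recursion over operation sequences, no state deduplication) must
agree with the BFS library at depth 2 on both the key set and minimal
sequence lengths; and every depth-3 sequence outcome must be present in the
depth-3 library (the naive recursion covers all sequences exhaustively —
the toy alphabet keeps this in the thousands of states).

## Genome properties

The genome is tiled into 1-kb pixels (the final partial bin counts once; on
hg19 autosomes plus X this yields exactly 3,036,315 pixels, which the suite
asserts). Tracks are coverage-weighted means per pixel with missing pixels
flagged.

The association test picks one side of each junction at random (seeded) to
reduce dependence between observations, pools observed positions with
uniform random positions drawn from non-missing pixels, rank-transforms
jointly to [0, 1] with mid-ranks, and compares observed against random
quantiles with a one-sided two-sample Kolmogorov–Smirnov statistic — the
larger of the two directions, reported signed (negative = enriched at low
property values), with the asymptotic one-sided p. Comparing against the
random sample's quantiles rather than the exact uniform keeps constant
tracks non-significant (all quantiles tie at 0.5 in both groups) and makes
no difference asymptotically otherwise. How ties and direction were handled
in the original cohort analyses is not stated anywhere we could follow;
these are this package's documented conventions. Across a suite of (class,
track) pairs, Benjamini–Yekutieli correction is applied with significance
reported at q < 0.01; random positions default to 10^4 per test in the
shipped configuration (a parameter — cohort-scale analyses would use 10^6).

Partner permutation enrichment preserves every breakend's position and side
and re-pairs breakends uniformly at random within the sample (1,000
permutations by default), reporting fold change and z against the permuted
distribution. Footprint connectivity reuses the identical machinery with
footprint side-pattern types as labels. Permutations are within-sample to
preserve per-genome breakpoint density.

The microhomology fit models log10(count + 1) against homology length with
three straight lines — NHEJ below `b1`, MMEJ on `[b1, b2)`, SSA at and
above `b2` — and grid-searches integer changepoints (`b1` in 1..8, `b2` in
8..15, matching the 2–7 bp microhomology scale of MMEJ and the 10–30 bp
scale of single-strand annealing). Ties keep the smallest changepoints;
single-point regimes get slope 0 through the point.

## Signatures

The default catalogue has 31 mutually exclusive categories. Deletions and
tandem duplications occupy 11 of them: deletion sizes {<50 kb, 50–500 kb,
>500 kb}; tandem duplications the same three sizes crossed with
early/late replication timing; plus one fragile-site category for each.
(The natural reading "timing split only for the two smaller TD bins" yields
10, not the 11 this scheme is described as having; crossing all three TD
size bins with timing is the arithmetic that actually reaches 11 and is
what this package implements.) The early/late split is at the median of the
supplied timing track over non-missing pixels — with three terciles the
middle band has no category of its own, so the operational split is binary.
Remaining categories: reciprocal inversions split at 500 kb, unbalanced and
reciprocal translocations, chromoplexy, fold-back inversions (with a
translocation-adjacent subtype), templated-insertion cycles/bridges/chains
split at 100 kb of total template span, the three 2-jump subtypes, local
n-jumps, local–distant clusters, the chromothripsis flag, and
complex/unclassified. A cohort-frequency filter (off by default, 50 at
study scale) folds rare non-core categories into the remainder.

**NMF.** KL-divergence (Poisson) objective with multiplicative updates,
30 seeded restarts per rank by default. For each rank K, stability is the
mean cosine of restart signatures matched (exact assignment up to K = 7,
greedy above) to the best-likelihood restart. Rank selection takes the
largest K that is both stable (stability >= 0.95) and still improving
reconstruction substantially (>= 20% KL drop over the next-smaller rank,
with rank 1 as the closed-form baseline for the first K). If no rank
qualifies, the report is flagged as having no stable multi-signature
solution; if the rank-1 baseline already reconstructs the data, the
smallest rank is returned with collinear signatures and a warning. The
0.95 and 20% constants are numerical conventions chosen once for this
selection rule. Signature rows are renormalized to sum to one with
exposures rescaled compensatingly.

**HDP backend.** A compact direct-assignment Gibbs sampler over a two-level
Dirichlet-process mixture of categoricals (patients as groups), alpha = 1,
gamma = 1, and a Dirichlet(0.2) prior on spectra. The reported K counts
dishes holding at least 2% of events (transient crumb dishes are a normal
feature of the sampler, not signatures); spectra and exposures are
posterior means over samples at the modal K, cosine-matched to handle label
switching, with 95% posterior intervals per cell; split-R-hat on K above
1.2 flags non-convergence. Single-site samplers of this kind mix slowly
between merge/split modes, so chain counts and iteration numbers should be
increased for anything beyond exploratory use — NMF is the primary backend,
and the two are reported by the paper trail of this methodology to behave
comparably.

Driver association fits, per gene group and signature, a linear model of
exposure on binary gene status (pathogenic germline plus somatic, pooled
over group members) with histology indicators as covariates, two-sided
tests on the gene coefficient and Benjamini–Hochberg correction across all
pairs (the looser BH rather than BY is a documented, switchable choice —
only "correction for multiple hypothesis testing" is specified for this
analysis in the source methodology). Genes mutated in fewer than 3
patients are skipped with a note.

## The simulator

Every simulated event is constructed as an explicit derivative and emits
exactly the junctions and CN deltas that derivative implies — internal
consistency is by construction, shared with the replay oracle. The toy
build (three 50-Mb chromosomes) keeps full pipelines in seconds; an
hg19-scaled build is available.

What the defaults emulate: per-class Poisson event counts; two-mode
log-normal size distributions for deletions and tandem duplications (modes
near 10 kb and 200 kb); replication-timing placement bias (deletions
toward late-, tandem duplications and unbalanced translocations toward
early-replicating DNA, via a smooth 10-Mb-period surrogate track);
truncated Gaussian CN noise (sd 0.1 copies); and cohorts with Gamma
exposures over planted signatures and Poisson category counts.
Templated-insertion templates and 2-jump segments default to the
sub-kilobase mode of the template size spectrum. That choice is
deliberate: it keeps intra-cluster breakend spacings inside the
proximity-null merge radius at realistic per-genome event counts, so the
clustering model itself can assemble these events — and it corresponds to
the small-template mode that is prominent in real data. Terminal-loss
events (unbalanced translocations, chain ends) place their breakpoints
within ~600 kb of a telomere and reserve the lost tail, so their CN effect
cannot contaminate other events.

What the simulator does **not** emulate: breakpoint-calling uncertainty
(positions are exact), caller-specific artefacts, subclonality (all events
are clonal), overlapping/nested events (placement is non-overlapping by
construction, with retries and a saturation error), microhomology
sequence content, and the large-template mode of templated insertions.
Passing the recovery tests therefore demonstrates correctness of the
pattern logic on clean, well-separated events — not robustness to caller
noise or to overlapping rearrangement histories.

## Problem sizes used by the shipped checks

The test suite and acceptance script run: a 500-event single-genome
recovery (all 13 simulable classes, truth-grouped clusters so the
classifier is measured independently of the clustering step, whose own
calibration is checked separately); 100 uniform-genome clustering
replicates; 200 null association suites of 20 tests at 10^4 random
positions; 100 Poisson-noise microhomology replicates; a 200-patient
3-signature cohort with 10 NMF seeds and a split-half check; and a
300-patient driver-association cohort with 40 null replicates. These sizes
were chosen as the smallest at which the corresponding statistical checks
have adequate power.

## Known limitations

* The clustering null ignores junction orientation and per-chromosome
  breakend density; it is a documented stand-in isolated behind one
  function.
* Pattern keys collapse same-locus breakends by side order; pathological
  clusters with multiple identical (position, side) breakends may not be
  fully canonical.
* The enumeration alphabet bounds expressible patterns (3 + 2 atoms by
  default); deeper or wider enumeration is a parameter but grows quickly.
* Chromothripsis is flagged coarsely, never characterized.
* The HDP backend is exploratory-grade; its mixing is the limiting factor.
* Local background for CN rules is the per-sample modal CN, not a
  per-chromosome estimate; heavily aneuploid genomes would benefit from
  the latter.
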