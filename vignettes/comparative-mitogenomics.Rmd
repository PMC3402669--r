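---
title: "Comparative mitogenomics with mitocomp: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## The problem

Complete mitochondrial genomes of closely related bovids — the European
bison (wisent), the American bison, the yak and domestic cattle — differ
at only a few percent of sites. At that divergence the informative
quantities are not trees searched over thousands of taxa but a careful
bookkeeping of individual mutations: which taxa share each substitution
or indel, which branch of a small, well-established topology each
mutation falls on, how fast the molecular clock ticks once a fossil
date anchors one node, and whether apparent runs of adjacent
substitutions are really one mutational event. `mitocomp` implements
that bookkeeping as a tested pipeline, together with the distance and
likelihood machinery needed around it and a seeded simulator that
provides ground truth for every step.

## Pipeline model

**Variant cataloguing.** All events are polarised against a designated
root sequence — for the bovid system, the *Bos taurus* bovine reference
sequence used as an "artificial root". A column where a taxon differs
from the root base yields one substitution event per distinct alternate
allele, with the set of carrying taxa attached; maximal runs of gap
columns become single insertion or deletion events, left-normalised in
homopolymer context so coordinates do not depend on the aligner's gap
placement. An IUPAC ambiguity code compatible with the root base is
treated as missing, not as a carrier, to avoid inflating counts.

**Micro-reorganization merging.** Aligners render a single complex
mutation (e.g. a rearranged oligonucleotide) as a run of adjacent
substitutions. Runs of at least `min_components = 3` events with an
*identical carrier set* and inter-event gaps of at most `max_gap = 2` bp
are merged into one `micro_reorganization` event. The defaults are
deliberately conservative: the canonical worked example is eight
contiguous substitutions at reference positions 1472–1479 carried by one
taxon, which merge into a single event. Both parameters are exposed, and
both raw and merged tallies are reported, since published mutation
counts rarely state which convention they use.

**Sharing patterns and branch mapping.** Each event's pattern is the
subset of the focal taxa among its carriers. A pattern that forms a
clade on the fixed rooted topology maps to the branch above that
clade's ancestor (parsimony: the derived state arose once, on the
subtending branch); singleton patterns map to terminal branches
("unique" mutations); non-clade patterns are homoplasies and are
reported separately as unresolved rather than forced onto a branch.

**Difference islands.** In a two-genome comparison, events cluster into
islands. An island is a maximal run of at least `min_events = 4` events
with consecutive gaps of at most `max_island_gap = 60` bp. The
published material names islands without defining them, so these
defaults were tuned once on the described island structure (a 20-event
island across ~223 bp, a 4-event island across 50 bp) and are flagged
as heuristic; both knobs are configurable.

**Coding effects.** Substitutions in protein-coding regions are
translated under the vertebrate mitochondrial code (translation
table 2) and labelled synonymous/nonsynonymous with the residue change;
coding indels of length not divisible by three are frameshifts and the
novel residue stretch up to the next stop is reported; rRNA/tRNA hits
are `rna_gene`; everything else is `intergenic`. Note that an A→G
substitution can never produce an Ala→Ile change under any genetic
code; where published residue pairs conflict with the code table, the
package reports the code-table truth.

## Distances

The headline "percent divergence" numbers of this literature are
interpreted as substitution-only p-distances with pairwise deletion of
gap and ambiguity columns; indels are counted separately by the event
catalogue. This is the convention of the era's standard tools, but
because published percentages rarely say whether pairwise or complete
deletion was used, both modes are exposed and the site count actually
compared is always reported alongside.

Model-based distances use the Tamura–Nei (1993) closed form, which
separates the two transition classes (A↔G, C↔T) from transversions,
with pooled empirical base frequencies (pooling keeps the estimator
symmetric in the two sequences) and gamma rate variation of shape
`alpha`. The default `alpha = 0.1` mirrors the analysis convention this
pipeline reproduces and is overridable per run; `alpha = Inf` gives the
uncorrected distance. Saturated configurations (non-positive logarithm
arguments) return an explicit `inestimable` status, never a silent
`NaN`. Standard errors come from resampling alignment columns with
replacement to the original length (default 1,000 replicates, seeded).

## Likelihood, clock test, branch support

The likelihood engine is Felsenstein pruning over unique site patterns
under GTR+Γ. Rate variation uses 4 discrete gamma categories with
category rates equal to the means of equiprobable quantile bins — the
de facto standard of the tools this pipeline emulates. Base frequencies
are empirical counts from the alignment, matching common usage of the
era's tools; exchangeabilities and the gamma shape are optimized when
requested.
Transition matrices come from eigen-decomposition of the reversible
rate matrix via symmetrization; entries are clamped at zero with
tolerance 1e-12 against round-off. Gaps and ambiguity codes are
partial missing data (all compatible bases get likelihood 1).

Branch lengths are optimized by cyclic bracketed scalar search
(tolerance 1e-8 per branch, sweeps until the log-likelihood improves by
less than 1e-6, maximum 100 sweeps, non-decreasing by construction).
On a rooted tree the two root-incident branches are only jointly
identifiable under a reversible model; recovery checks therefore
compare their sum.

The molecular-clock test compares free branch lengths (2n−3 effective
parameters) with an ultrametric parameterisation by node heights
(n−1 parameters, root height log-transformed, every other height a
logistic fraction of its parent's), giving a likelihood-ratio
statistic referred to χ² with n−2 degrees of freedom. At the simulated
study scale the empirical size of the nominal 5% test sits within a
few percent of nominal (the acceptance suite measures it over 200
1-kb replicates, a problem size chosen to exercise the asymptotics at
desk scale).

aLRT branch support compares the fitted tree with the better of the
two nearest-neighbour-interchange rearrangements of each internal
branch (branch lengths re-optimized), with support 1−p under the
½χ²₀+½χ²₁ mixture. On a rooted tree the branch incident to the root
has no NNI information — its rearrangements merely re-root the tree —
so its support is reported as ~0 and should be read as "root placement
untested", matching the behaviour of unrooted-tree tools.

The harmonic-mean utilities (`harmonic_mean_loglik`, `bayes_factor`,
`read_trace`) operate on externally produced posterior log-likelihood
traces in log-space (log-sum-exp); no relaxed-clock MCMC is
re-implemented here, deliberately.

## Chronology

`calibrate_rate` converts the substitution depth of a fossil-dated
node into substitutions/site/year. Node depth is the *mean* root-to-tip
path length over the node's descendants — mean, not maximum or
minimum, because the calibration presumes rate constancy, under which
every tip is an equally valid realisation. A pairwise alternative
(mean cross-split patristic distance / 2) is provided and labelled,
since published point dates are often reproducible only under one of
the two conventions. `date_nodes` divides each node's mean depth by
the rate; parent-younger-than-child inversions caused by rate
heterogeneity are flagged per node, never silently adjusted. No
uncertainty is propagated onto ages (point calibration, point dates);
bootstrap age intervals would be a separate extension.

## The simulator and what it does (not) show

`simulate_evolution` draws a root genome from the model frequencies,
assigns each site a discrete-gamma rate multiplier, and evolves the
sequence down a rooted tree: per branch the substitution count is
Poisson with mean branch-length × summed site rates, sites are hit
proportionally to their rate (multiple hits allowed), and the new base
is drawn from the GTR jump probabilities of the current base. Short
geometric indels and micro-reorganization events (a window rewritten so
every base differs) are planted at configurable rates; a D-loop span
evolves at an elevated multiplier (default 5×) to exercise exclusion
logic. One random stream per run is split into per-branch streams keyed
by stable branch labels, so output is reproducible independent of
traversal order.

The truth table stores the *realized* end state (every leaf's
differences against the root, grouped into events with carrier sets by
construction from the simulator's internal state) in addition to the
raw process log, which makes recovery tests exact even in the presence
of multiple hits. The `wisent_trio` preset places four 16.3-kb genomes
on `(BRS,(wisent,(bison,yak)))` with branch lengths of 342/15400,
158/15400 and 165/15400 on the wisent, bison and yak terminals (and
230/15400, 340/15400 on the shared branches), so expected unique
mutation counts over the ~15.4-kb coding part approximate the
342/158/165 partition characteristic of the bovid system, under a
transition-biased GTR (Ts/Tv ≈ 17–18) with gamma shape 0.867.

Deliberate simplifications: inserted material does not evolve further;
deletions act only on root-coordinate sites; no selection, no
heteroplasmy, no coalescent population structure, no base-composition
drift. Passing recovery tests therefore demonstrates the pipeline's
bookkeeping and estimators, not robustness to alignment artefacts in
deeply diverged or structurally rearranged real genomes. Sequences
beyond ~15% divergence are outside the anchored aligner's design range
(it will return an empty chain and fall back to a full matrix, slowly).

## Alignment design

The anchored aligner chains k-mers unique in both sequences (default
`k = 12`) by longest-increasing-subsequence dynamic programming, then
runs a banded affine-gap global alignment (defaults: match +1,
mismatch −2, gap open −5, gap extend −1; a gap of length L costs
open + L×extend; band half-width 50) in a corridor following the chain.
Ties in the traceback prefer diagonal over up over left, for bit
reproducibility. When consecutive anchors are offset by more than the
band, the band widens automatically with a warning, up to the full
matrix. Within the band the result provably equals the unconstrained
optimum, which the test suite checks against an independent full-matrix
implementation on random near-identical pairs. Reference-projected
multiple alignments stack insertions at the same reference position
left-aligned without re-aligning them to each other — insertions are
downstream treated as events, not as columns for distance computation.
Externally aligned FASTA can bypass this module entirely; reproducing a
specific published column count generally requires that bypass, since
alignment parameters of older tools are rarely stated.

## Problem sizes used in the checks

The shipped validation uses 16.3-kb four-taxon simulations (20 seeds)
for catalogue recovery, 50 random ≤2-kb pairs for the alignment oracle,
50-kb quartets for branch-length recovery, 200 replicates of 1-kb
quartets for clock-LRT calibration, and 10-kb/1,000-replicate setups
for bootstrap checks. These sizes were chosen as the smallest at which
the corresponding asymptotics are expected to hold to the stated
tolerances.
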