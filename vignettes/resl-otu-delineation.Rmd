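---
title: "Refined single-linkage OTU delineation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refined single-linkage OTU delineation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binclust)
```

## The problem and the model

A DNA barcode survey yields hundreds to thousands of COI sequences, many
from undescribed or unidentifiable species. The package groups them into
operational taxonomic units (OTUs) meant to approximate species, relying
on one empirical regularity: conspecific COI sequences are usually very
similar (maximum intraspecific p-distances of a few tenths of a percent
to about 1%), while each species' nearest heterospecific neighbour is
usually several percent away. Where that barcode gap holds, clustering
at a fixed threshold recovers species well; where intraspecific
structure or very young species blur it, a fixed threshold fails in a
characteristic way — deep conspecific lineages get split only below the
threshold, and sub-threshold discontinuities get merged.

The procedure therefore has two stages. Single-linkage clustering at
threshold $t$ builds initial OTUs: sequences are nodes, pairs at
p-distance $\le t$ are edges, OTUs are connected components. Single
linkage guarantees no member of one OTU is within $t$ of another OTU,
but chaining lets cluster diameters exceed $t$. Markov clustering (MCL)
then re-examines every OTU that could conceivably be partitioned —
three or more members showing any sequence variation — and splits it
when, and only when, the similarity graph shows internal discontinuity.
A silhouette criterion arbitrates among candidate refinements.

All distances are uncorrected p-distances (mismatches over jointly
unambiguous A/C/G/T sites, pairwise deletion). No substitution model is
assumed; this also keeps every comparison an exact integer ratio, which
the implementation exploits to make threshold comparisons immune to
floating-point boundary effects (a distance equal to $t$ is always "at
threshold", never nearly so).

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `t` | 0.022 | proportion | single-linkage link threshold (2.2%) |
| `founder_cutoff` | 2·t = 0.044 | proportion | streaming founder rule; refinement-graph cutoff; neighbour-collapse radius |
| `inflation_grid` | 1.0–2.4 by 0.2 | — | MCL granularity candidates (8) |
| `min_len` | 500 | bp | QC minimum non-gap length |
| `max_ambig` | 0.01 | proportion | QC ambiguity ceiling (strictly greater rejects) |
| `genetic_code` | invertebrate mito | — | stop-codon screen |
| `min_overlap` | 300 | sites | minimum compared sites for a defined distance |
| `epsilon` | 1e-6 | — | MCL max-norm convergence tolerance |
| `max_iter` | 100 | — | MCL iteration cap |

The threshold `t = 2.2%` is taken as a configured constant: it is the
operating point at which the two-stage design is balanced, with single
linkage slightly over-merging and refinement recovering sub-threshold
structure. The derivation of such a threshold from optimal-threshold
sweeps across reference datasets is not re-run here; `threshold_sweep()`
lets users repeat that analysis on their own labelled data.

`min_overlap = 300` is a guard the distance definition needs once real
fragments enter: two 500 bp records can overlap barely at all after
alignment, and a distance over a handful of sites is noise. Pairs below
the overlap floor have *undefined* distance, which every consumer treats
as "beyond any cutoff"; records with no defined distance at all become
singletons, since nothing can justify their membership.

Ambiguity codes are never counted as matches, even when compatible
(N vs A is excluded, not matched). This is the conservative reading of
"ambiguous", and it is deterministic.

## The refinement similarity

MCL operates on a column-stochastic matrix $M$ over a refinement group,
$M_{ij}$ the probability of stepping from sequence $j$ to sequence $i$.
$M$ is initialized from edge weights

$$w_{ij} = \max\!\left(0,\; 1 - d_{ij}/t\right),$$

with a self-loop of weight 1 on every node, each column then divided by
its sum. The choice of scale is the package's central numerical design
decision. A raw similarity $1-d$ is useless here: at barcode scales all
weights sit within 2% of each other, expansion mixes the walk faster
than inflation can sharpen it, and no inflation value in the grid ever
separates anything. Rescaling by the link threshold puts the relevant
contrast on the unit interval: identical sequences get weight 1, pairs
at or beyond $t$ get 0. Prototyping during development showed this form
separates two haplotype clouds 1.5% apart (silhouettes 0.85–0.98 on the
selected candidates), never splits tight clouds of at most 0.5% spread,
and leaves chain-like continua — high variation with no discontinuity —
as single OTUs, which is precisely the behaviour the two-stage design
needs. An intermediate scaling by $2t$ separated only perfectly
homogeneous clouds and failed once clouds had realistic internal spread.

One consequence is worth stating plainly: within a collapsed refinement
group, edges between members of *different* initial OTUs have $d > t$
and hence weight 0, so refinement can confirm the separation of
collapsed neighbours or split OTUs further, but can never re-merge them.
Merging is the province of the single-linkage stage (and, in the
registry, of bridging records).

Expansion squares $M$; inflation takes the elementwise power $r$ and
renormalizes columns. Iteration stops when the max-norm change falls
below `epsilon` (1e-6) or after `max_iter` rounds (non-convergence
returns the current extraction and is logged; all desk-scale instances
converge well before 100 rounds). Attractors are rows with diagonal mass
above `epsilon`; each node follows its largest incoming probability,
with two deterministic guards: probabilities within
$\sqrt{\epsilon}$ of the column maximum are treated as tied, so residual
convergence noise cannot decide an assignment, and ties go to the
lexicographically smallest attractor id. At $r = 1$ inflation is the
identity and a connected group converges to its rank-one stationary
matrix — every column equal — which the tie rule collapses to a single
cluster, as it must.

## Silhouette selection

Each candidate partition is scored on the group's full pairwise
p-distances (not the cutoff-capped graph weights; the graph is a device
for the walk, the distances are the data). For member $i$, $a(i)$ is the
mean distance to its own cluster's other members, $b(i)$ the smallest
mean distance to another cluster, $s(i) = (b-a)/\max(a,b)$; singleton
clusters contribute 0, and a single-cluster partition scores 0 by
convention. The maximum-score candidate wins; ties prefer fewer
clusters, then smaller inflation. The tie policy is deliberately
conservative: a split must positively beat the undivided baseline, so
an MCL candidate that fragments a group into singletons (score 0) never
displaces it.

## The registry

OTUs gain persistent identifiers (`BOLD:` + three letters + four
digits, incremented big-endian with digit rollover). Assignment of a new
record follows the same geometry as clustering: farther than
`founder_cutoff` from every active BIN's representatives founds a new
BIN; a link at $\le t$ joins; a record bridging several BINs merges
them, the youngest URIs synonymized into the oldest, with transitive
resolution. A BIN grown to three or more varying members is re-refined,
and a multi-cluster outcome splits it — the founder's group keeps the
URI. On gapped data this makes record-by-record assignment provably
agree with the batch pipeline (the consistency is asserted in the test
suite); near the threshold, a bridge-merge followed by a validation
re-split is possible and is the same answer the batch pipeline gives on
the same records.

Persistence is an append-only event log (FOUND, JOIN, MERGE, SPLIT,
MOVE, PARTITION, plus FLAG for compliance changes — added so that
replaying the log reconstructs the state exactly) with a derived JSON
snapshot. No identifier is ever reused or deleted. Expert decimal
partitions (`uri.1`, `uri.2`, … by diagnostic positions) require every
member to match exactly one subgroup; a decimally partitioned BIN
refuses merge and split until its partitions are cleared — the
interaction is otherwise undefined, and refusing is the only behaviour
that cannot silently discard expert input.

## The synthetic generator

`simulate_barcodes()` is the validation substrate. It emulates the
divergence structure of well-sampled barcode surveys: species ancestors
are mutated copies of a random stop-free root, with per-ancestor loads
drawn so pairwise distances concentrate modestly above the
nearest-neighbour floor `nn_target` (enforced exactly by resampling
violators); individuals are drawn from their ancestor with per-site
substitution probability `intra_max`/4, and each species' realized
maximum intraspecific distance is capped at `intra_max` by redrawing the
most-implicated individual. Substitutions favour third codon positions
two-to-one and resample on stop-codon creation, so generated data always
pass QC. Defaults (50 species × 10 sequences, `intra_max` 0.5%,
`nn_target` 5%, 658 bp) mirror the density and divergence ranges of
curated regional surveys.

`inject_structure()` adds the three discordance motifs that matter for
validation: a divergent conspecific lineage (SPLIT_CASE), a
near-identical species pair (MERGE_CASE), and two sub-threshold
haplotype clouds inside one species (GAPPED_SUBCLUSTERS — the case only
refinement can resolve).

What the generator does *not* emulate, and what passing tests therefore
do not show: indels and alignment error (simulation is gap-free; the
frame-anchored aligner is exercised separately on constructed
deletions), sequencing error and chimeras, rate heterogeneity along the
gene, non-neutral site structure beyond the third-position bias, and —
most importantly — the taxonomically hard cases of real data:
introgression, incomplete lineage sorting, and very young species pairs
with genuinely overlapping divergence distributions. On real surveys the
MATCH percentage will be lower than on the generator's clean-gap
conditions; the generator measures algorithmic correctness, not
real-world concordance rates.

## Problem sizes and determinism

The test suite validates: streaming single linkage against a union-find
oracle on 200 random instances of 50–300 sequences; MCL against an
independent numpy implementation on 50 random weighted graphs of up to
40 nodes at three inflation values; full-pipeline species recovery on
ten seeded 500-sequence datasets; concordance classification against a
contingency-walk oracle on 500 random instances; and registry replay,
merge and incremental-vs-batch consistency. These sizes were chosen as
the smallest that exercise every code path with comfortable margins;
every random draw is seeded, and `simulate_barcodes()` restores the
RNG state it found.

## Known limitations

- The aligner handles terminal truncation and frame shifts, not internal
  indels; records needing a gapped alignment should be pre-aligned
  upstream and will pass through untouched.
- Refinement cannot re-merge OTUs (by construction of the similarity
  scale); over-split inputs stay over-split unless bridging records
  arrive.
- Silhouette selection favours cutting the extreme ends of very small
  near-symmetric chains (three-member bridges); such splits are honest
  under the scoring but sensitive to single records either way.
- The contaminant screen is a plain distance test against user-supplied
  references (below 5% flags), not a profile or phylogenetic placement;
  chimera detection is out of scope.
- Identifier capacity ends at `ZZZ9999` (about 175 M BINs); exceeding it
  errors rather than wrapping.
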