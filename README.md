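# binclust

Delineates operational taxonomic units (OTUs) from COI DNA-barcode
sequences and maintains a persistent, auditable registry of the results.
It is aimed at biodiversity researchers who need species-proxy units from
barcode surveys — for richness estimates, interim taxonomy, or flagging
possible synonymy and overlooked species — together with stable
identifiers that survive later data growth.

## The method

Most animal species show small COI divergence among conspecifics (rarely
above 2%) and markedly larger divergence to their nearest heterospecific
neighbour (typically above 4%): the *barcode gap*. The package exploits
this structure in a staged procedure:

1. **Quality control.** Records shorter than 500 bp, with more than 1%
   ambiguous bases, with stop codons in every forward reading frame
   (likely pseudogenes), or matching a contaminant reference are
   excluded.
2. **Frame-anchored alignment.** COI barcodes are overwhelmingly
   indel-free, so sequences are trimmed to their stop-free reading frame
   and anchored by codon shifts to a common coordinate system;
   pre-aligned input passes through unchanged.
3. **Single-linkage clustering.** Sequences are linked whenever their
   uncorrected pairwise distance (p-distance, pairwise deletion) is at
   most *t* = 2.2%; clusters are the connected components. A streaming
   variant compares each record only against cluster representatives,
   expanding to full comparison only within 2*t* — exact under the
   triangle inequality, and equal to the exhaustive computation.
4. **Markov-clustering (MCL) refinement.** Each cluster with at least
   three members showing variation (with neighbours below 4.4% collapsed
   in) is re-examined by MCL: a column-stochastic matrix over
   threshold-scaled similarities is alternately squared (expansion) and
   taken to the Hadamard power *r* (inflation) until convergence.
   Inflation values 1.0–2.4 in steps of 0.2 give eight candidate
   partitions per group.
5. **Silhouette selection.** The candidate with the highest Silhouette
   index — mean of (b−a)/max(a,b) over members — is kept. Clusters with
   internal discontinuities are split even when the separation lies
   below *t*; clusters with continuous variation stay whole.

Resulting OTUs can be scored against prior taxonomy (MATCH / SPLIT /
MERGE / MIXTURE categories and the clustering F-measure) and registered
as BINs: persistent `BOLD:AAA0001`-style identifiers with join, merge,
split, decimal-partition and compliance-flag lifecycle, backed by an
append-only audit log whose replay reconstructs the registry exactly.

## Worked example

Simulate a small survey (12 species, 6 sequences each, intraspecific
variation at most 0.5%, nearest neighbours at least 5%), hide a
1.5%-separated pair of haplotype clouds inside species 4, and fit:

```r
library(binclust)

sim <- simulate_barcodes(sim_spec(n_species = 12, seqs_per_species = 6,
                                  intra_max = 0.005, nn_target = 0.05,
                                  seed = 11))
gapped <- inject_structure(sim, "GAPPED_SUBCLUSTERS", species = 4)
fit <- resl(gapped$records)
fit
#> Refined single-linkage OTU delineation
#>   72 sequences in, 72 passed QC
#>   t = 2.2%, founder cutoff = 4.4%
#>   initial clusters: 12; refined OTUs: 13 (12 group(s) refined)
#>   concordance: 91.7% MATCH, F-measure 0.972
```

Single linkage at 2.2% cannot see the 1.5% break and returns 12
clusters; refinement recovers it. The per-group selection table shows
the split: group 4 chose inflation 2.2 with a silhouette of 1, all other
groups kept a single cluster:

```r
summary(fit)$refinement[4, ]
#>   group n   r k silhouette
#> 4     4 6 2.2 2          1

fit$concordance
#> Concordance: 12 species vs 13 OTUs (F-measure 0.972)
#>   MATCH      11 species (91.7%)
#>   SPLIT       1 species (8.3%)
#>   MERGE       0 species (0.0%)
#>   MIXTURE     0 species (0.0%)
```

The split species is scored SPLIT because its specimens now occupy two
pure OTUs — exactly what a deep intraspecific divergence should produce.
`otu_partition(fit)` extracts the OTU assignment, `predict(fit, new)`
assigns new sequences by the founder rule, and `bin_registry()` /
`registry_assign()` register OTUs incrementally with stable URIs.

A command-line front end over the same functions lives at
`inst/cli/binclust` (subcommands `qc`, `align`, `cluster`, `resl`,
`sweep`, `score`, `summary`, `simulate`, `registry`); thresholds on the
command line are percentages.

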