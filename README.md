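# apccooc

Discovering conserved regions in a protein family and clustering them by
co-occurrence.

## What it does

Given a set of homologous protein sequences, `apccooc`:

1. **Discovers patterns** — contiguous substrings with sequence-level
   support ≥ `min_occurrence` and standard-residual significance
   *z* = (O − E)/√E ≥ 1.96 against the order-0 residue background, pruned of
   redundancy: a pattern is removed when a retained contiguous super-pattern
   keeps at least a `delta` fraction (default 0.9) of its support.
2. **Builds Aligned Pattern Clusters (APCs)** — gapped pattern matrices,
   each representing one conserved region with its variation, assembled by
   greedy global-alignment merging under interpretable constraints
   (≥ 3 consecutive matching columns, ≥ 1 fully conserved column, consistent
   placement on shared sequences).
3. **Scores co-occurrence** — the Jaccard index
   J = |Cseq₁ ∩ Cseq₂| / |Cseq₁ ∪ Cseq₂| of the covered-sequence sets, for
   every APC pair, giving a weighted graph W (pairs ranked by score, then
   union size).
4. **Clusters the graph** into Co-occurrence Clusters by random-walk
   Laplacian spectral clustering (L_rw = I − D⁻¹W, eigengap choice of k,
   k-means on the eigenvector embedding), by exact/iterative k-medoids, or
   by maximum-spanning-tree cutting.
5. **Validates in 3D** — maps APCs onto a PDB structure, computes one
   C-alpha centroid per APC region, and compares the mean centroid distance
   of a cluster with the structure's average pairwise C-alpha distance.

A seeded synthetic-family generator (planted motifs with configurable joint
or independent presence, point mutations, indels, and paired synthetic
C-alpha structures in "colocated" and "dispersed" geometries) makes the
whole pipeline testable without downloads.

## Worked example

```r
library(apccooc)

fam <- generate_family(synthetic_spec(seed = 1))   # 100 seqs, 3 planted motifs
fit <- apc_cooccurrence(fam$seqs)
fit
#> apc_cooccurrence fit
#>   sequences:    100
#>   patterns:     19
#>   APCs:         4
#>   clustering:  spectral, k = 1
#>   best cluster: 1 (lowest mean embedding distance)

summary(fit)
#> Co-occurrence clustering of 4 APCs ( spectral )
#>
#> APC1   CPAYQELMSG           coverage  66  cluster 1
#> APC2   WKDGHNVFTR           coverage  66  cluster 1
#> APC3   LRHTEWIKQD           coverage  61  cluster 1
#> APC4   NVFTR                coverage  53  cluster 1
#>
#> eigenvalues: 0.000 1.217 1.361 1.422
#> best (most connected) cluster: 1
#>
#> top co-occurring APC pairs:
#>   apc_i apc_j     score union_size
#> 1  APC1  APC2 0.8082192         73
#> 2  APC2  APC4 0.6760563         71
#> 3  APC1  APC4 0.6527778         72
#> 4  APC1  APC3 0.4431818         88
#> 5  APC2  APC3 0.4431818         88
```

The two jointly planted motifs (`WKDGHNVFTR`, `CPAYQELMSG`, one presence
draw per sequence at p = 0.7) surface as the top-ranked pair at J ≈ 0.81,
well above their co-occurrence with the independently planted motif
(J ≈ 0.44). The eigengap selects k = 1 here because even independent motifs
at p = 0.7 co-occur on ~half the sequences — the graph is far from
disconnected; see the methods vignette for why, and pass `k = 2` or an
`edge_min` threshold to force a split.

Structural validation against the paired synthetic structure:

```r
carrier <- fam$truth$ids[rowSums(fam$truth$presence) == 3][1]
sm <- generate_structure_for(fam$truth, fam$seqs, carrier, "colocated")
structure_mapping(fit$apcs, sm)
#> structure_mapping: 4 of 4 APCs mapped
#>   average APC centroid distance: 3.88 A
#>   average pairwise C-alpha distance: 21.45 A
```

With the co-located geometry the clustered regions sit ~3.9 Å apart against
a 21.5 Å whole-structure baseline; the dispersed geometry reverses the
inequality. For a real family, read sequences with `read_fasta()` and a
deposited structure with `read_structure()`.

A thin command-line front end is installed at
`inst/scripts/apccooc.R` (`simulate`, `discover`, `cluster`, `validate3d`,
`convert` subcommands).

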