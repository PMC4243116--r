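---
title: "Aligned Pattern Clusters and Co-occurrence Clustering: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligned Pattern Clusters and Co-occurrence Clustering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apccooc)
```

## The problem

Homologous protein sequences share conserved regions whose residues evolve
under functional constraint. When two distinct conserved regions tend to
appear on the *same* sequences, that co-occurrence suggests joint
functionality -- binding surfaces, chains of catalytic residues, or
co-operating structural elements. `apccooc` implements a pipeline that (i)
discovers statistically significant sequence patterns, (ii) groups them into
Aligned Pattern Clusters (APCs) that each summarize one conserved region
together with its variation, (iii) scores how often APCs co-occur on the
same sequences, and (iv) partitions the APC co-occurrence graph into
Co-occurrence Clusters. A cluster can then be checked against a reference
3D structure: if its APC regions really co-operate, their C-alpha centroids
should lie closer together than the structure's average pairwise C-alpha
distance.

## Pattern discovery

A pattern is a contiguous string over the 20-letter amino-acid alphabet.
`enumerate_candidates()` collects every substring with length in
`[min_len, max_len]` whose *support* -- the number of distinct sequences
containing at least one occurrence -- reaches `min_occurrence`. Support is
counted per sequence because every downstream quantity (APC coverage, the
Jaccard score) operates on sequence sets; the raw window count is kept
separately for the significance statistic. Enumeration exploits
anti-monotonicity of support (a frequent window has a frequent prefix), so
long windows are only generated at positions whose `min_len`-prefix
survived; the result is provably identical to exhaustive window counting,
and the test suite asserts that equality against a brute-force hash oracle.

Significance is measured as a standard residual against an order-0
(independent-residue) background:

$$ z = \frac{O - E}{\sqrt{E}}, \qquad
   E = W_n \prod_{i=1}^{n} f(p_i), $$

where $O$ is the total occurrence count over all length-$n$ windows, $W_n$
the number of such windows in the set, and $f$ the maximum-likelihood
background frequencies. The default threshold $z \ge 1.96$ is the two-sided
5% normal critical value; both the statistic's form and the threshold are
configurable. This is a deliberate reconstruction choice: the pipeline's
upstream pattern-discovery literature leaves the redundancy and
significance machinery open, and a documented, testable statistic was
preferred over an opaque one.

Redundancy is removed by *delta-closed pruning*: a pattern $p$ is dropped
exactly when some retained contiguous super-pattern $q$ keeps at least a
fraction `delta` (default 0.9) of $p$'s support. Pruning runs from longest
to shortest so retention is well defined, and is idempotent. Only contiguous
super-patterns are considered, matching the contiguous pattern definition.

## Aligned Pattern Clustering

Patterns are merged greedily into APCs. Each APC is an $m \times n$ matrix
over the alphabet plus gap (`-`); each row, with gaps removed, is exactly
one member pattern. Merging aligns cluster consensi by global
Needleman-Wunsch alignment with Hamming-style scoring (+1 identity, 0
mismatch, gap penalty $-0.5$), deterministic with ties resolved toward
fewer, rightmost gaps. A merge is admissible when the merged matrix has

* at least `min_consecutive_column_match` (default 3) consecutive columns in
  which both partners contribute symbols and all non-gap symbols agree,
* at least `min_conserved_columns` (default 1) fully identical columns,
* per-column entropy below `max_column_entropy`, when a cap is set, and
* consistent placement: unless overlap is explicitly allowed, the two
  clusters' matched spans must overlap by at least one position on every
  sequence they both cover. We read "no relative position overlapping" as
  *requiring* the two clusters to describe the same region of the sequences
  rather than adjacent or conflicting regions; the alternative reading
  (forbidding span overlap) would merge unrelated regions and break the
  one-region-per-APC semantics.

Merging repeats with the highest-similarity admissible pair (ties: higher
combined coverage, then lexicographically smallest consensus pair) until no
admissible pair remains. Greedy agglomeration is a heuristic; no global
optimality is claimed. Column entropy is computed in bits over non-gap
symbols, so $0 \le H_j \le \log_2 20$; a column whose entropy exceeds the
configured cap is displayed as the wildcard `*` in the consensus, while `-`
is reserved for length differences.

One practical consequence of the "fully identical column" requirement is
that a short sub-pattern whose span is disjoint from the columns shared by
all current members may stay out of an APC and form its own (e.g. a motif's
C-terminal 5-mer alongside the full-motif APC). This is visible in the
worked examples as 3-4 APCs for three planted motifs.

## The co-occurrence graph and its clustering

APC coverage is the set of sequence ids containing at least one member
pattern. Pairwise similarity is the Jaccard index
$J = |C_1 \cap C_2| / |C_1 \cup C_2|$, with $0/0$ taken as 0. The graph's
weight matrix $W$ has zero diagonal -- self-similarity is uninformative and
a zero diagonal keeps the degree a pure neighbor sum. Pairs are ranked by
score, then union size (a tie covering more sequences ranks higher), then
lexicographic ids, a total deterministic order.

**Spectral clustering.** Isolated vertices are split off first (each one a
singleton cluster) because $D^{-1}$ is undefined for them. On the rest, the
random-walk Laplacian $L_{rw} = I - D^{-1} W$ is eigendecomposed; the number
of clusters $k$ is, by default, the count of eigenvalues before the largest
consecutive gap (smallest index on ties, first `min(|V|, 10)` eigenvalues
considered). Vertices are embedded as rows of the first $k$ eigenvector
columns -- including the constant first column, a harmless shift -- without
row re-normalization (the Shi-Malik convention that matches the random-walk
Laplacian, rather than the Ng-Jordan-Weiss variant). k-means with a fixed
seed (default 1) and 10 restarts partitions the embedding; labels are
relabelled by cluster size. The zero-eigenvalue multiplicity of $L_{rw}$
equals the number of connected components, which the tests assert for 1-4
components, and eigenvalues are validated against the similar symmetric
normalized Laplacian as an independent route.

**k-medoids.** Similarity-maximizing k-medoids: each vertex joins the
medoid with the highest co-occurrence score, and a cluster's medoid is the
member maximizing the summed score to the rest. Because APC graphs are
small, the medoid set is optimized *exactly* (enumerating all
$\binom{n}{k}$ sets) whenever that count is at most 5000; otherwise medoids
are seeded with the first vertex of each connected component, iterated to a
fixed point, and refined by best-improvement swaps. The exact route exists
because pure local iteration can stall in swap-local optima even on
8-vertex graphs. When `k` is not given, candidates from the component count
up to $|V|$ are compared by majority vote of five internal validity indices
computed on the dissimilarity $1 - J$: mean silhouette, Calinski-Harabasz,
Davies-Bouldin, Dunn, and the within/between mean-dissimilarity ratio, with
ties resolved toward the smaller $k$. The five indices are our choice of
standard internal criteria; any set of well-behaved indices would serve.

**MST cutting.** A maximum spanning forest is grown per component with
Prim's algorithm, then the minimal-weight tree edge is cut repeatedly until
`k` clusters remain; equal-weight choices use lexicographic vertex-id
tie-breaks throughout, making the procedure deterministic. Tree weight is
validated against exhaustive spanning-tree enumeration in the tests.

The "best" (most connected) Co-occurrence Cluster is the one minimizing the
mean pairwise Euclidean distance between its members' embedding rows,
singletons excluded.

## Structural validation

`read_structure()` parses the first model of a PDB file via `bio3d`,
keeping one C-alpha per residue (highest occupancy among altlocs, hetero
and waters excluded, non-standard residues skipped with a warning). APC
patterns are scanned against a chain sequence (`*` matches any residue);
when no full pattern matches, maximal partial matches of at least
`min_partial = 5` residues are accepted -- parts of a conserved region still
anchor it. The mapping chain defaults to the chain with the most full
matches; the pairwise C-alpha baseline defaults to *all* chains of the
first model, since the published baseline wording refers to the structure
as a whole, and a `chain` argument exposes the single-chain alternative.
When an APC matches several disjoint regions, the region whose centroid is
nearest to the other APCs' centroids is kept and the alternatives recorded;
this mirrors selecting the copy of a repeated motif that actually sits in
the clustered neighborhood.

The two summary statistics are the mean Euclidean distance among APC region
centroids and the mean over all unordered C-alpha pairs. Both are invariant
under rigid motion (asserted numerically) and are compared directly: a
co-operating cluster should have centroid distances below the pairwise
baseline.

## The synthetic family generator

`synthetic_spec()` fixes the package's reference study conditions: 100
sequences of length 150 over a uniform background, two jointly occurring
10-residue motifs implanted at sites 15 and 65 with one Bernoulli draw per
sequence at probability 0.7, one independent motif at site 115 with its own
probability 0.7, and a per-position mutation rate of 0.05. Implantation
replaces background residues, so sequence length and truth coordinates stay
exact; optional indels perturb only the background segments, with motif
coordinates adjusted. Motif strings are arbitrary fixed 10-mers; sites are
spaced ~50 residues apart so that the dispersed structural geometry
separates them well. These defaults are the conditions under which all
end-to-end results in the README and acceptance script are computed; they
were chosen once, from what a protein-family benchmark of this size
plausibly looks like, and are not tuned per experiment.

The paired synthetic structure is a C-alpha trace with exact 3.8 Å
consecutive spacing. Under `"colocated"` geometry, motif residues perform a
confined walk inside a ~6 Å core ball while linkers make out-and-back
excursions up to ~45 Å, so motif centroids sit within a 15 Å ball and well
below the pairwise baseline; under `"dispersed"`, the chain is fully
extended, so motif regions ≥ 12 residues apart are ≥ 45 Å apart and the
centroid distances exceed the baseline. The generator emulates presence
co-occurrence, point mutations, indels and the two geometric regimes; it
does **not** emulate phylogenetic correlation between sequences, realistic
indel length distributions, physically valid backbone geometry, or
compositional bias. Passing tests therefore demonstrate algorithmic
correctness under controlled conditions, not performance on real families.

## What the study conditions imply for the cluster count

A caveat worth stating explicitly, because it is a property of the method,
not a bug: with the reference conditions above, the independent motif is
present on ~70% of sequences and the joint group on ~70%, so their
coverage sets overlap by chance in ~49% of sequences and the
joint-vs-independent Jaccard is ≈ 0.5. The resulting co-occurrence graph is
far from disconnected, and the eigengap criterion -- largest difference
between consecutive ascending eigenvalues of $L_{rw}$, zero included --
then selects $k = 1$ (spectra look like $\{0, 1.2, 1.4, \ldots\}$; the
first gap dominates). Direct computation on model block graphs shows the
eigengap only reaches $k = 2$ once the cross-group Jaccard drops below
roughly 0.2, i.e. when the graph is nearly disconnected. So under
independent presence at $p = 0.7$ the pipeline, faithfully implementing
the eigengap rule, reports a single Co-occurrence Cluster; separating the
independent motif requires either sparser co-occurrence, an edge threshold
(`edge_min`), or an explicit `k`. With `k = 2` given, the spectral
partition does isolate the weakest-linked APC, and on separable
(zero-cross-weight) graphs spectral and k-medoids agree exactly.

## Numerical choices and degenerate inputs

* Eigendecomposition of the non-symmetric $L_{rw}$ uses base `eigen()`;
  real parts are taken (the spectrum is provably real) and sorted
  ascending. The test suite cross-checks against the symmetric normalized
  Laplacian, which is similar to $L_{rw}$.
* k-means uses `stats::kmeans` with `nstart = 10` under a locally-scoped
  seed, so library calls never disturb the caller's RNG stream.
* A graph where every vertex is isolated yields all-singleton clusters and
  no best cluster (an error states "no connected cluster").
* Empty coverage sets give Jaccard 0 with a warning; `E = 0` in the
  significance statistic yields `+Inf` with a warning.
* Problem sizes in the tests (families of 20-100 sequences, graphs of up to
  10 vertices for exhaustive oracles) were chosen so each oracle stays
  exact and the whole suite runs in about a minute.

## Known limitations

* Greedy APC agglomeration can split one conserved region into a full-motif
  APC plus a short-tail APC (see above); a post-merge pass guided by span
  overlap could consolidate them.
* The eigengap rule is insensitive to moderately-coupled group structure
  (see the cluster-count section); alternative model-order criteria
  (modularity, ncut curves) are deliberate non-goals here.
* Structure mapping is exact-match based (plus wildcards and partial
  windows); it does not align patterns to the structure sequence with
  substitutions, so heavily mutated family members map sparsely.
* mmCIF input, network fetching, and figure-style visualizations are out of
  scope; the plot method shows the cluster-ordered weight matrix only.
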