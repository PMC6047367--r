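---
title: "Bit-packed signature similarity: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bit-packed signature similarity: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitsig)
```

## The problem

Modern expression compendia and genome knowledgebases hold 10^5–10^6
datasets, and the questions asked of them are pairwise: which experiments
share a differential-expression pattern, which genomes share gene content?
With N datasets that is N(N−1)/2 comparisons — `pair_count(1e6)` is about
0.5 × 10^12 — and the overwhelming majority of pairs are dissimilar. A
full-precision metric spends almost all of its time discovering nothing.

The approach implemented here represents each dataset as a *binary
signature*: a 0/1 vector over a feature universe (genes, protein
orthologs) marking which features belong to the dataset's pattern.
Signatures are packed column-wise into 64-bit machine words, so a pairwise
comparison is W = ⌈K/64⌉ bitwise operations plus hardware population
counts instead of K floating-point operations. The three offered
operators are exactly the elementary set statistics:

* `and` — |A ∩ B|, shared features;
* `xor` — |A Δ B|, differing features;
* `or` — |A ∪ B|, combined features.

On 0/1 data the classical metrics are functions of these counts:
cosine(A, B) = AND/√(|A|·|B|) and Euclidean(A, B) = √XOR, which the test
suite asserts against the full-precision implementations to 1e−9. The
intended mode of use is therefore *filter-then-refine*: prune with bit
counts, and evaluate the exact metric on the survivors only
(`filter_then_refine()`).

## Data model and numerical conventions

`pack_signatures()` stores bit k of column j at word `k %/% 64`, bit
position `k %% 64`, least-significant bit first. The on-disk container
(`write_signatures()`) serializes those words little-endian byte by byte,
so files are portable across platforms. The bit order itself is an
internal convention — any fixed order yields identical counts — but fixing
one makes the container bit-exact and diffable.

Padding bits (positions ≥ K in the last word of each column) are forced
to zero at pack time and re-validated on every load and before every
comparison. Because AND, XOR and OR all map zero pads to zero pads, counts
need no masking; this is also why a NOT/complement operator is
deliberately not offered — it would turn pad zeros into ones and require
masking everywhere for no use case in scope.

Counts are stored as 32-bit integers (4 bytes per cell): signature
lengths in both applications are in the 20,000–23,000 range, far below
the 2^31 ceiling. Self-comparisons return a strictly upper triangular
matrix with a zero diagonal — each unordered pair once, no redundant
a_ji — and the blockwise path zeroes the lower parts of blocks that
straddle the diagonal so chunked and in-memory results are cellwise
identical.

For outputs too large for memory, `plan_chunks()` tiles the count matrix
under a caller-set byte budget (default 1 GiB). Rows are split first;
columns only when a single full-width row already exceeds the budget. No
published rule fixes the chunk shape, so the only contract we promise —
and test — is that every plan tiles the output exactly once within budget
and that chunked equals unchunked for any such plan.

There is no randomness anywhere in the comparison engine; results are
bit-identical across runs. Floating-point accumulation in the reference
metrics is sequential over features, so refined values are reproducible
too.

## Binarization

`threshold_binarize()` turns a continuous feature-by-sample matrix into
paired *low*/*high* signatures with strict cuts: low bit iff value <
`low_cut`, high bit iff value > `high_cut` (defaults −0.6 and +0.6). The
inequalities being strict means a value exactly at a cut joins neither
signature, and no value can ever set both bits. Missing values default to
"in neither signature" (`na_action = "zero"`), the conservative reading
for a measurement that produced no call; `na_action = "error"` is
available when silent omission would be wrong.

For centred expression-like data with standard deviation σ = 0.5, cuts of
±0.6 capture a per-tail fraction of Φ(−0.6/0.5) = Φ(−1.2) ≈ 0.115. The
generator reads "N(0, 0.5)" as standard deviation 0.5; σ is an explicit
argument, so the variance-0.5 reading is one keystroke away if a user
prefers it.

Merging a pair of up/down (high/low) AND results is *additive*:
`merge_up_down()` sums the up-shared and down-shared counts, giving one
scalar edge weight per pair. Discordant overlap (up in one experiment,
down in the other) is not subtracted; a signed variant would be a natural
extension point but is not part of the current contract.

## Network layer

`build_graph()` converts a merged self-comparison into an undirected edge
table, by weight threshold or by top-k with deterministic tie-breaking
(weight descending, then both node ids ascending) so regression tests are
bit-exact. `subnetwork()` takes the one-hop closure around seed nodes —
the minimal reading of "query the network with a seed list" — then
optionally caps edges.

`second_order_similarity()` re-applies the bit engine to the graph
itself: binarize the adjacency at `edge_cut` (default 20, a practical cut
below which shared-gene counts are indistinguishable from background),
pack each node's neighbor vector, and AND-self-compare. The count for
(i, j) is their number of common neighbors, a cheap clustering heuristic
for graphs with millions of edges; it depends only on which edges survive
the cut, never on the surviving weights.

`overlap_enrichment()` is the set-overlap half of a Fisher's exact test:
the one-sided (greater) hypergeometric tail P(X ≥ overlap), with the
overlap itself computed through the packed AND count and the tail through
`stats::phyper`. The suite checks it against a direct combinatorial sum
to 1e−12 absolute.

## Genome gene-content layer

Ortholog presence/absence is natively binary, so
`shared_ortholog_counts()` is a bare AND self-comparison.
`within_group_means()` averages a genome's shared counts over the *other*
members of its taxonomic group — a singleton group has no pairs and is
flagged undefined rather than given a number. `group_pair_matrix()` does
the same at group level; its diagonal averages within-group pairs
excluding each genome paired with itself, because self-similarity is
trivially the genome's gene count and would inflate the diagonal. The
grouping level (family, class, genus, …) is a caller parameter: published
group-level views mix levels, so none is hard-wired.
`select_minimal_genomes()` uses inclusive bounds, default [200, 600]
annotated genes, the closed range that picks out genome-reduced obligate
symbionts.

## Synthetic data: what it emulates, what it does not

The three generators make every layer testable without any download, and
their defaults are the study conditions for the test suite:

* `synth_gaussian_matrix()` — i.i.d. N(0, σ = 0.5) values, default
  20,000 features × 500 samples. The full-scale benchmark shape is
  20,000 × 15,000; 500 columns keeps a desk-scale run in seconds while
  leaving the per-cell statistics identical. It emulates only the
  marginal distribution: no gene–gene correlation, no batch structure.
* `synth_lincs()` — 100 up/down signature pairs of 100 features each over
  a 2,000-feature universe, with 5 planted clusters of 10 members sharing
  a 60% core (the remaining signatures are background). Under these
  defaults within-cluster merged counts are ≥ 120 against a background
  expectation near 10, so the planted partition is recoverable exactly;
  recovery is scored by Rand index over the *planted* signatures only,
  since background signatures are singletons by design and scoring their
  pairs would measure background size, not recovery.
* `synth_kegg()` — 32 genomes in 9 groups across three domains over a
  5,000-ortholog universe. Each group has a disjoint core (70% of the
  domain's minimum genome size) plus accessory genes from a shared pool;
  eukaryote genomes are largest, archaea smallest. Disjoint cores
  guarantee within-group > between-group mean sharing with a comfortable
  margin, which the suite asserts for every group.

All generators are pure functions of their arguments plus `seed`, and
leave the caller's RNG state untouched. Passing tests on this synthetic
data shows the machinery is correct under planted structure; it says
nothing about the biology of any real compendium, where cluster overlap,
correlated noise and annotation bias are all harsher.

## Problem sizes and the timing illustration

The default test and acceptance runs use: 1e6 Gaussian draws for tail
calibration (3-standard-error band around Φ(−1.2)); 100 random instances
with K ≤ 512 and N, M ≤ 50 for oracle equivalence; 1,000 random pack/
unpack roundtrips; and the generator defaults above for structure
recovery. `sig_benchmark()` times the packed AND self-comparison of
binarized 20,000 × 500 data against an all-pairs cosine baseline
(computed as a normalized crossproduct, the fastest dense route in R).
The timing is reported, never asserted: wall-clock numbers are
hardware-dependent, and on BLAS-backed R the dense baseline is itself far
from naive. The structural point — bit counts cost a small fixed number
of word operations per pair — holds regardless.

## Known limitations

* No NOT operator (see above); no sparse packing — signatures near 0% or
  100% density pack at the same cost.
* The engine is single-threaded R + C++; no multi-machine distribution.
* `merge_up_down()` ignores discordant regulation.
* The GMT reader keeps the sorted union of members as the universe; sets
  are not validated against an external gene annotation.
* Rendering of graphs (`autoplot`) uses a force-directed layout with a
  fixed internal seed purely for display; no numeric output depends on it.
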