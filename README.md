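# ssosort

Exact sorting distances for gene-order permutations under **super short
operations** (SSOs) — rearrangements that touch at most two adjacent genes:

* a **1-reversal** flips the orientation of one gene,
* a **2-reversal** swaps two adjacent genes and flips both orientations,
* a **2-transposition** swaps two adjacent genes without touching
  orientation.

Such length-limited models are of interest in comparative genomics because
short rearrangements dominate the evolution of some genomes; the distance
between two genomes with the same gene content is the minimum number of
operations separating them, which (after relabelling) is the cost of
*sorting* one signed permutation into the identity.  `ssosort` computes this
distance, and a witness minimum-length scenario, for signed and unsigned
permutations, linear and circular chromosomes, with or without cyclic moves
across the ends.

## The method

For cyclic swaps the package works with **valid displacement vectors**: an
integer vector \(X\) with \(\sum_i x_i = 0\) and
\(|\pi_i| - x_i \equiv i \pmod n\), prescribing the net rightward
displacement of each element in a sorting scenario.  The **crossing value**

\[ c_{ij}(X) = \pm\,\bigl|\{k \in [r..s] : k \equiv 0 \ (\mathrm{mod}\ n)\}\bigr|,
\qquad r = i - j,\quad s = (i + x_i) - (j + x_j), \]

counts how often elements \(\pi_i\) and \(\pi_j\) must swap, and the
**crossing number** \(cn(X) = \tfrac12 \sum_{i \ne j} |c_{ij}(X)|\) is the
minimum number of swaps realizing \(X\).  Signs enter through the
**cyclic permutation graph** \(G^X_\pi\) (edges for positive crossing
values, weights summing to \(cn(X)\)): each connected component containing
an odd number of negative elements costs one extra 1-reversal, so the
distance realized by a vector is

\[ d(\pi, X) = cn(X) + cc^-(G^X_\pi). \]

The sorting distance of a signed linear permutation under cyclic SSOs is
the minimum of \(d(\pi, X)\) over the candidate sets \(S\) (vectors at
minimum crossing number, reached by contracting transformations
\(T_{i,j}\)) and \(S'\) (their single-transformation images); a circular
chromosome is handled by taking the best of its \(2n\) linearizations.
Closed forms for the previously solved variants (inversion count, inversion
graph parity, minimum crossing number, sign/parity mismatches) are included,
as is a brute-force BFS oracle over the full state space for validation at
small \(n\).

## A worked example

```r
library(ssosort)

p <- parse_permutation("(+5 +4 -2 -1 +3)")

linear_signed_sso_distance(p)        # 8   (SSOs, no cyclic moves)
linear_cyclic_distance(p)$distance   # 4   (cyclic SSOs)

pc <- parse_permutation("(+5 +4 -2 -1 +3)", circular = TRUE)
circular_distance(pc)
#> SSO sorting distance: 2
#>   witness vector: (1,-1,0,1,-1)
#>   witness linearization: (-2 -1 +3 +5 +4)

res <- circular_distance(pc, sequence = TRUE)
vapply(res$sequence$ops, format_operation, character(1))
#> [1] "r(1,2)"   "t(4,5,6)"
```

The same permutation costs 8 operations as a signed linear genome, 4 when
operations may wrap around the ends, and only 2 when the chromosome is
circular — the best cut point gives the linear representation
`(-2 -1 +3 +5 +4)`, sorted by one 2-reversal and one 2-transposition.

A brute-force check and a command line are available too:

```r
bfs_distance(p, sso_model("linear", cyclic = TRUE))   # 4
```

```sh
inst/scripts/sso-tool compare "(-6 +4 +2 -3 +1 +5 -7)"
inst/scripts/sso-tool sort "(+4 +2 +3 -1 -5)"
```

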