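---
title: "Sorting gene orders by super short operations"
author: "ssosort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting gene orders by super short operations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssosort)
```

## The model

A genome with no duplicated genes is a signed permutation
$\pi = (\pi_1\,\pi_2 \ldots \pi_n)$: absolute values are the genes, signs
their strand.  Comparing two such genomes reduces, via composition with an
inverse (`perm_compose()`, `perm_inverse()`), to sorting one permutation
into the identity.  The operations considered here are *super short*: they
never move more than two adjacent genes.  Three kinds exist — the
1-reversal (one sign flip), the 2-reversal (adjacent swap, both signs
flip) and the 2-transposition (adjacent swap, signs kept).  Any of the
latter two is a *swap*.  *Cyclic* variants may act across the boundary
between positions $n$ and $1$; a circular chromosome makes those positions
genuinely adjacent.

The interesting model combinations, all implemented here, are:

| model                              | distance                                        | function |
|------------------------------------|-------------------------------------------------|----------|
| unsigned, linear SSOs              | inversion count                                  | `inversion_count()` |
| signed, linear SSOs                | inversions + odd inversion-graph components      | `linear_signed_sso_distance()` |
| unsigned, cyclic SSOs              | minimum crossing number                          | `unsigned_cyclic_distance()` |
| signed, cyclic reversals only      | min crossing number + sign/parity mismatches     | `cyclic_ssr_distance()` |
| signed, cyclic SSOs                | candidate-set minimisation (below)               | `linear_cyclic_distance()` |
| signed circular chromosome, SSOs   | best of the $2n$ linearizations                  | `circular_distance()` |

## Displacement vectors and crossing numbers

A sorting scenario of cyclic swaps gives every element a net displacement
(moves right minus moves left).  Conversely a *valid displacement vector*
(VD-vector) is any integer vector with $\sum_i x_i = 0$ and
$|\pi_i| - x_i \equiv i \pmod n$; every such vector is realized by some
scenario.  For a pair $i \ne j$ the *crossing value* $c_{ij}(X)$ counts the
multiples of $n$ in the closed interval between $r = i - j$ and
$s = (i + x_i) - (j + x_j)$, with a sign giving the direction of the
crossing; it is the number of times the two elements must swap.  The
*crossing number* $cn(X) = \frac12 \sum_{i\ne j} |c_{ij}(X)|$ is the swap
cost of the vector.  The transformation $T_{i,j}$ (send element $i$ once
more around the cycle leftward, element $j$ rightward) preserves validity,
and repeatedly applying it while $x_i - x_j > n$ (`minimize_crossing()`)
reaches the minimum crossing number $cn(\pi)$ over all valid vectors.

### A conservation law, in the form in which it is exact

The classical statement that $T_{i,j}$ changes the crossing number by
exactly $2(n - x_i + x_j)$ is **not** an identity for
$\frac12\sum|c_{ij}|$ on arbitrary valid vectors.  A minimal
counterexample: $n = 3$, $X = (0,0,0)$, $T_{1,2}(X) = (-3,3,0)$.  The
formula predicts $cn = 6$, but four swaps realize the vector (each of the
two looping elements passes the stationary one once and they pass each
other twice), and indeed $cn((-3,3,0)) = 4$.  What does hold, and what the
package's tests assert, is:

* the **quadratic** crossing functional $\frac12 \sum_{i\ne j} c_{ij}^2$
  obeys the $2(n - x_i + x_j)$ delta *exactly, always* (each affected
  crossing value shifts by one unit, $c_{ij}$ by two, and the cross terms
  telescope);
* the two functionals coincide whenever all $|c_{ij}| \le 1$, which is the
  regime of every vector at or near the minimum — so the law holds for
  $cn$ there, and in particular on the published worked example;
* the consequences the algorithm needs hold without exception: strictly
  contracting steps along the reduction trajectory strictly decrease
  $cn$; transformations with $x_i - x_j = n$ applied at a fixed point of
  `minimize_crossing()` preserve $cn$; and the fixed point attains the
  global minimum (cross-checked exhaustively against brute force).

Termination of `minimize_crossing()` does not depend on the law at all:
each strictly contracting step decreases $\sum_i x_i^2$ by
$2n(x_i - x_j - n) > 0$.

## The cyclic permutation graph

Displacement vectors ignore signs.  The *cp-graph* $G^X_\pi$
(`cp_graph()`) restores them: vertices are the signed elements, and every
positive crossing value contributes an edge of that weight, so edge weights
sum to $cn(X)$.  A component is *odd* if it contains an odd number of
negative elements; odd components cost one 1-reversal each, because swaps
flip signs only in pairs.  The distance realized by a vector is
$d(\pi, X) = cn(X) + cc^-(G^X_\pi)$ (`vd_distance()`).

## The distance algorithm

The distance under cyclic SSOs is $\min_X d(\pi, X)$, and the minimiser
need not have minimum crossing number — trading two extra swaps for four
fewer 1-reversals can pay, as the fourteen-element example below shows.
The search space collapses to two finite sets: $S$, the vectors at minimum
crossing number, and $S'$, their single-$T_{i,j}$ images.
`linear_cyclic_distance()`:

1. reduces the initial vector $x_i = |\pi_i| - i$ to a fixed point;
2. expands $S$ by the single-step contracting images ($x_i - x_j = n$);
   this either yields all of $S$ or contains a vector whose cp-graph has
   one component, which is provably already optimal (the early exit);
3. otherwise minimises $d(\pi, X)$ over $S \cup S'$.

```{r}
fig14 <- parse_permutation("(-1 -2 +12 -4 -5 -6 -7 +3 +9 +10 +11 +8 -13 -14)")
X_min <- minimize_crossing(initial_vd(fig14))
crossing_number(X_min)              # minimum crossing number: 16
vd_distance(fig14, X_min)           # but 4 odd components: 16 + 4 = 20
linear_cyclic_distance(fig14)$distance   # a vector in S' does better: 18
```

A `full_closure = TRUE` flag replaces step 2 by the complete breadth-first
closure of $S$ under contracting moves, as a cross-validation aid; the
single-step search is already exact (the two agree on every tested
instance).

For a **circular** chromosome, cutting at each of the $n$ adjacencies in
both orientations gives $2n$ linear representations whose cyclic-SSO
distances upper-bound each other's circular cost; `circular_distance()`
minimises over them and reports the winning cut.  Reading the circle in
the opposite orientation negates every sign — the convention for circular
DNA, where the reverse reading swaps strands.

## Reconstructing a scenario

`reconstruct_sequence()` turns a witness vector into an explicit
minimum-length operation list: while crossing number remains, it applies
the first induced swap in left-position scan order (positions are scanned
$1..n$, the wrap pair last), choosing a 2-transposition by default and a
2-reversal exactly when the default would split an even component into two
odd halves; once no swaps remain, each remaining negative element gets its
1-reversal.  The emitted list always has length $d(\pi, X)$ and replays to
the witness vector (`sequence_displacement()`).  Scan order is an
implementation choice — the contract is the length, not the particular
sequence.  One boundary case: at $n = 2$ the wrap pair coincides with the
inner pair and only the cyclic 2-reversal can express the wrap-direction
swap, so it is preferred there.

## The brute-force oracle

`bfs_distance()` is ground truth by construction: one vectorised
breadth-first search from the identity over the complete state space
($2^n\,n!$ signed states, indexed by Lehmer rank and sign bits), cached
per model.  Circular models search over canonical representatives (the
lexicographically smallest of the $2n$ readings).  Capacity is capped at
$n \le 7$ signed / $n \le 8$ unsigned; beyond that the oracle fails fast
rather than exhausting memory.  `exhaustive_check()` compares the
polynomial distance with the table for *every* permutation of a given
size.

## Validation scales and what they show

The test suite validates the implementation at these problem sizes, chosen
to exercise every branch of the algorithm while staying desk-scale:

* all $3840$ signed linear permutations of $n = 5$, and 200 random
  instances of $n \in \{6, 7\}$, against the full BFS table (cyclic SSOs);
* all signed circular permutations of $n \le 5$ (384 canonical classes at
  $n = 5$) against the canonical-class BFS;
* full sweeps for the closed-form variants (signed SSOs at $n = 4$,
  unsigned cyclic at $n = 5$, cyclic reversals-only at $n = 4$);
* 500 random valid vectors ($n \le 12$) for the conservation law, and 500
  seeded scrambles ($n \le 10$) for the reconstruction contract.

The scramble generator (`scramble()`) applies $k$ uniformly random legal
moves of a model to the identity; it emulates rearrangement scenarios with
a known operation budget, so generated instances certify `distance <= k`
but are *not* a model of real gene orders (no selection, no hotspots, no
length bias among the allowed moves).  Passing these tests shows agreement
with exhaustive search on small state spaces and internal consistency at
moderate $n$; real genomes additionally feature unequal gene content and
duplications, which this model excludes by assumption.

## Numerical and design notes

* Distances, vectors and crossing values are small integers throughout; no
  floating point enters any computation.
* Tie-breaks are deterministic everywhere: `minimize_crossing()` picks the
  largest-donor/smallest-receiver pair (lowest index on ties); among
  equal-distance witnesses the lexicographically smallest vector wins;
  circular ties go to the first winner in rotation-then-reflection order.
* The size class of a reversal is implemented as the reversed block length
  $((j - i) \bmod n) + 1$ rather than a bare $j - i + 1 \pmod n$, which
  degenerates to $0$ when the block covers the whole cycle; the two agree
  in every other case, and the block-length form correctly classifies the
  adjacent 2-reversal at $n = 2$ as super short.
* At $n = 2$ the wrap swap acts on the same unordered pair as the inner
  swap; the wrap 2-transposition is therefore omitted from move
  generation (its index pattern is ill-formed and its effect duplicated).
* The reversals-only distance minimises $cn(X) + |neven \cup podd|$ over
  the full contracting closure of the minimum-$cn$ vectors rather than
  trusting a single vector, since the mismatch count $k$ could in
  principle depend on the chosen vector (empirically it did not, in the
  exhaustive sweeps).
* Unsigned permutations are stored all-positive; sign-changing operations
  on them are rejected at the model boundary.

## Limitations

The model assumes equal gene content, no duplicated genes and single
chromosomes.  The oracle does not scale beyond $n \approx 8$; the
polynomial algorithm itself is $O(n^6)$ in the worst case via the $S'$
enumeration and is comfortable for the gene counts where a super-short
model is biologically sensible.  The package computes distances and one
witness scenario, not the full set of optimal scenarios, and does not
address diameter questions or intergenic-region refinements.
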