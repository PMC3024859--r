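---
title: "Exact planted (l,d)-motif discovery by reference-vertex clique search"
author: "motifClique"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact planted (l,d)-motif discovery by reference-vertex clique search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifClique)
```

## The problem

Transcription factors bind short, degenerate sites. The planted (l,d)-motif
formulation abstracts their discovery: given m DNA sequences, each of length
n over {A,C,G,T}, each sequence contains exactly one instance (OOPS: one
occurrence per sequence) of an unknown length-l motif, mutated in at most d
positions. The task is to recover the motif and the planted positions. The
classic benchmark instance is (l, d, m, n) = (15, 4, 20, 600).

`motifClique` solves this exactly, in the sample-driven style: it searches
over the substrings actually present in the data rather than over the 4^l
candidate strings. The key observation is the triangle inequality: if every
instance is within Hamming distance d of the true motif, any two instances
are within 2d of each other. The m planted instances therefore form an
m-clique in the graph whose vertices are all length-l windows (one vertex
set per sequence) and whose edges connect windows at distance at most 2d.
`findMotifCliques()` enumerates *all* such cliques — the planted one is
guaranteed to be among them — and `cliqueConsensus()` reads the motif off a
clique by column-wise plurality.

## The search

The search fixes the first sequence as the initial reference. For each
window v of sequence 0 it filters every other sequence's window set down to
the candidates within 2d of v. It then recurses: the next reference vertex
is drawn from the filtered candidates of sequence 1, the remaining sets are
filtered again (so membership is cumulative: a surviving candidate is within
2d of *every* reference chosen so far), and so on. The path-continuation
condition is that every remaining sequence retains at least one candidate;
otherwise the search backtracks and substitutes the most recent reference
vertex. Reaching depth m emits the reference path as a clique.

Two properties matter for validation:

* **Soundness** — every emitted tuple is pairwise within 2d by construction
  (each vertex was filtered against all earlier ones). The tests re-verify
  this with an independent O(m²) check.
* **Completeness** — every tuple that is pairwise within 2d survives every
  filter along some branch, so nothing is missed. The tests verify equality
  with a brute-force product-space enumeration on small instances, and
  containment of all witness tuples of an exhaustive pattern-driven solver.

The recursion depth is m and candidate sets shrink geometrically with depth
(by the factor p below), so memory stays modest — the dominant cost is the
level-0 filtering pass, (m−1)(n−l+1)² Hamming evaluations. The inner loops
are compiled (C++); distances are recomputed streamingly rather than cached,
keeping peak memory proportional to the candidate sets themselves.

Output order is deterministic: cliques appear in lexicographic order of
their 0-based start tuples, following the ascending scan order of the
candidate sets, and repeated runs are identical (no hidden state, no
randomization of the reference sequence).

`cliqueSearchAbstract()` exposes the identical control flow driven by an
arbitrary symmetric compatibility predicate on labelled vertices. This
exists to make the algorithm itself testable in isolation from Hamming
geometry: the test suite drives it over a small hand-constructed
compatibility graph with a known pair of cliques and a known dead end,
and its `trace` attribute records every backtracking event (which reference
vertex failed, at which depth, and which part's candidate set emptied).

## The difficulty statistic

Two independent uniform-random bases differ with probability 3/4, so the
Hamming distance between two random l-mers is Binomial(l, 3/4) and

$$p(l, d) \;=\; \sum_{i=0}^{\min(2d,\,l)} \binom{l}{i} \left(\tfrac34\right)^i \left(\tfrac14\right)^{l-i}$$

is the probability that a random window pair passes the 2d filter.
`neighborProbability()` computes this exactly (it reduces to
`pbinom(2d, l, 3/4)`, which the tests use as an independent cross-check).
p is the right difficulty axis for sample-driven search: the expected
candidate-set size after i filtering levels scales with (n−l+1)·p^i, so
large p (weak motifs, e.g. p = 0.283 at (18,6)) floods the search with
spurious partial cliques while small p (e.g. p = 0.057 at the classic
(15,4)) keeps it near-linear. `cmdSearch()` logs p up front for exactly
this reason. p = 1 exactly when 2d ≥ l: every pair passes.

Reported p values are rounded half-up to 3 decimals, the convention of the
published benchmark tables this statistic is checked against.

## Evaluation: recall over base positions

`recallRate()` scores predictions as |K ∩ P| / |K|, where K is the set of
base positions covered by the planted instances (|K| = m·l for OOPS data)
and P the positions covered by predicted windows. Working on base positions
rather than window starts gives partial credit to overlapping but shifted
predictions, which is the literal reading of the metric's definition.
When several cliques are reported, `cmdEvaluate()` aggregates both ways —
the best single clique and the union of all predicted windows — because
which aggregation the published experiments used is not stated; on the
benchmark settings the two coincide at 1.

## Consensus derivation

`cliqueConsensus()` tallies the m clique members per column and emits the
plurality base where its frequency strictly exceeds the dominance threshold
(default 0.5), and `'x'` otherwise — the display convention for motif
columns lacking a dominant base. The threshold is a parameter rather than a
hidden constant because published displays imply a notion of "dominant
base" without defining it; 0.5 (strict majority) is the natural default.
Ties at the plurality are resolved alphabetically (A < C < G < T) when the
consensus must be ACGT-resolved for the within-d validity check; this
affects only the validity flag, never the displayed `'x'`.

## The simulator

`generatePlantedDataset()` reproduces the benchmark protocol: i.i.d.
uniform background, a uniform-random true motif, one instance per sequence
planted at a uniform-random start in 0..n−l, each instance mutated at
distinct uniformly chosen positions with each mutated base replaced by a
uniformly chosen *different* base — so the realised Hamming distance equals
the mutation count. Two mutation modes are provided because the literature
uses both readings: `up_to_d` (default; the count is uniform on 0..d,
matching the problem statement "up to d mutations") and `exact_d` (the
classical challenge-benchmark convention; used in this package's own
(15,4) benchmark reproduction). Everything is reproducible from the seed;
`writePlantedDataset()` output is byte-identical across runs.

What the simulator does *not* emulate: GC skew, Markov-structured
backgrounds, repeats, multiple or zero occurrences per sequence, and
reverse-strand instances. Passing tests on simulated data therefore show
correctness of the combinatorial search under the model's own assumptions,
not robustness to real promoter sequence composition. On real data the
practical workflow is the one the CLI supports: scan l upward and d < l/2,
and inspect the consensus of the reported cliques.

## Numerical and design choices

* **Coordinates** are 0-based half-open windows [j, j+l) throughout the
  API and the TSV report; the CLI log additionally prints 1-based starts
  for human reading, labelled as such.
* **Alphabet** is strictly {A,C,G,T}; IUPAC ambiguity codes are rejected by
  default with an option (`skipAmbiguous`) to drop affected windows
  instead, since real FASTA files contain N runs.
* **Recursion** is implemented with genuine C++ recursion (depth m; m is
  tens, far from any stack limit) allocating fresh candidate vectors per
  reference vertex, which keeps backtracking trivially correct.
* **Early exits**: `firstK` stops after a clique quota; `maxSeconds` is a
  soft wall-clock limit. Both flag the result incomplete rather than
  failing — weak settings such as (18,6) at n = 600 are known to be
  intractable for sample-driven search, and a clean partial answer beats
  an unkillable process.
* **Degenerate inputs**: m < 2, any sequence shorter than l, d ≥ l, and
  n ≤ l for the simulator are contract violations with early errors; zero
  cliques found is a legitimate, logged result with exit status 0.

## Problem sizes used in the test suite

The suite validates the (15,4), m = 20, n = 600 benchmark on 10 seeded
datasets (each solves in a few seconds), checks oracle equivalence
exhaustively at m = 4, n = 20, l = 5, d = 1 (where the 16⁴ product space
is enumerable), and pattern-search containment at (7,1), m = 5, n = 40.
The published n-sweep to 2000, the (40,14) open challenge and all
wall-clock comparisons are outside desk scale and are not reproduced;
the completeness guarantee they rest on is what the oracle-equivalence
suite checks directly.

## A worked run

```{r example, eval = FALSE}
model <- MotifModel(15, 4)
ds <- generatePlantedDataset(m = 20, n = 600, model,
                             mode = "exact_d", seed = 1)
res <- findMotifCliques(ds@sequences, model)
length(res)                          # cliques found
containsPlanted <- any(apply(cliqueStarts(res), 1,
                             function(r) all(r == plantedStarts(ds))))
cliqueConsensus(res, model)@consensus  # equals trueMotif(ds)
```

## Limitations

Single-strand scanning only (no reverse complement); uniform i.i.d.
background assumption in the simulator; exponential worst case for large p
(inherent to the problem, mitigated by `firstK`/`maxSeconds`); no
position-weight-matrix scoring or significance model — the method is purely
combinatorial and exact.
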