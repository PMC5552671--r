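---
title: "Exact MLCS search with a leveled DAG: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact MLCS search with a leveled DAG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Given `d >= 1` sequences over a finite alphabet (DNA, protein, or any
symbol set), the multiple longest common subsequence (MLCS) problem
asks for *all* distinct maximum-length strings that are subsequences
of every input. Already for two sequences the answer is generally not
unique, and the problem is NP-hard in `d`; exact solvers therefore
trade worst-case exponential behavior for aggressive pruning of the
search space. MLCSdag implements one such solver — a leveled directed
acyclic graph over match points with eager deletion of exhausted
nodes — together with two independent exact oracles and a classical
dominant-point baseline, so every answer can be cross-checked.

## Match points, successor tables and the graph

A *match point* of `d` sequences is a vector `p = (p_1, ..., p_d)` of
1-based positions at which all sequences carry the same symbol `C(p)`.
Point `q` *dominates* `p` when it is componentwise `>=` with at least
one strict inequality; `q` is a *successor* of `p` for symbol `x` when
it is the componentwise-first match point of `x` strictly beyond `p`.
Successors are read in `O(d |Sigma|)` from per-sequence *successor
tables*: `ST[i, j]` is the position of the first occurrence of the
`i`-th alphabet symbol strictly after position `j`, with columns `0..n`
(column 0 meaning "before the first symbol") and an explicit `NA`
sentinel for "no further occurrence", so that valid positions and
absence can never collide. Tables are built once per run by a single
reverse sweep and treated as immutable.

The search space is a DAG whose nodes are match points, with edges to
successors, a source sentinel `(0, ..., 0)` and an end sentinel
`(Inf, ..., Inf)`; every maximum-length source-to-end path spells one
MLCS string.

## The leveled construction with generation and deletion

`runLeveledDag()` builds this DAG level by level while continuously
collapsing it:

1. Expand every node of the current level through the successor
   tables, in queue order and alphabet order. An already-known match
   point is linked, never duplicated (the node map is keyed by the
   match point alone — the symbol is derived, since
   `C(p) = s_1[p_1]`). A childless node receives the end sentinel as
   its only successor. Nodes created directly from the source carry
   their single-symbol partial LCS from birth.
2. Delete *outdated* nodes: a node that has been expanded and has no
   incoming edges can never again receive longer partial strings, so
   it bequeaths its partial LCS set `P_LCS` to each successor — with
   the successor's own symbol appended — and is removed. In-degrees
   are maintained as plain counters (incremented on edge creation,
   decremented when a precursor dies), which keeps "no incoming edges"
   decidable without storing reverse edge lists.
3. When no new node can be created, repeated deletion passes shrink
   the graph until only the end sentinel is left; its `P_LCS` is the
   complete MLCS set.

Two semantics of the deletion pass deserve to be explicit because they
are observable through the stepping API (`initGraph()`,
`expandLevel()`, `removeOutdatedPass()`):

* **Snapshot, no cascade.** A pass operates on the set of outdated
  nodes as it stood when the pass started; nodes whose in-degree
  reaches zero *during* the pass wait for the next one. Unexpanded
  nodes are never removed, even at in-degree zero, because expansion
  and removal are interleaved and a frontier node's in-degree is
  transiently zero right after its precursors die.
* **Inheritance compares appended lengths.** When a dying node `p`
  bequeaths to successor `s`, the strings arrive with length
  `|p| + |delta|`, where `delta` is `s`'s symbol for internal nodes
  and empty for the end sentinel. Longer replaces `s`'s current set,
  equal-length unions into it, shorter is discarded. For internal
  successors this is algebraically the classical
  "`|p| >= |s|` replace / `|p| + 1 = |s|` union" rule. At the end
  sentinel, however, the classical comparison would let two
  equal-length maximal nodes overwrite each other's strings — inputs
  `AC` and `CA` would report only one of `{A, C}`. Comparing on the
  appended length is the package's resolution; it changes nothing for
  internal nodes and makes the end node accumulate the full set.

Replacement therefore strictly lengthens a node's set by
construction, every node is inserted exactly once and removed exactly
once, and the final answer is independent of both the symbol
generation order and the processing order within a pass — properties
the test suite asserts directly (the order-independence check reruns
instances under permuted alphabet orders and a reversed pass order).

### Representation of the partial LCS sets

Mid-run, the number of partial strings across live nodes can vastly
exceed the final answer, and copying whole string sets along every
edge dominates the run time. The engine therefore stores each
`P_LCS` structurally: a set is a list of references to the frozen
sets of dead precursors, each tagged with the one appended symbol,
plus any explicit base strings (the single characters of first-level
nodes). Bequeathing is then O(1) per edge, and strings are
materialized — with memoized, deduplicating expansion — only when a
set is inspected (`nodePlcs()`) or at final extraction, where the
reachable references are exactly those on maximum-length paths. The
observable semantics (which strings a node holds at which moment) are
identical to eager storage; the tests that replay the two-sequence
walkthrough read the intermediate sets through exactly this path.

The engine itself is compiled code behind an external pointer; the R
handle has reference semantics, so the stepping functions mutate the
graph in place, as graph construction requires.

## Instrumentation

Every run reports `RunStats`: distinct internal nodes created, the
peak number of simultaneously live internal nodes, expansion rounds,
successor generations counted with multiplicity, and removal passes.
`peakLive` counts internal nodes only — source and end sentinels
excluded — which makes the walkthrough checkpoint "7 nodes left after
the pass that deletes the level-1 nodes" reproducible exactly as
printed. The time complexity is linear in nodes created (each node is
generated and deleted once); the space profile follows the peak live
count plus the `O(d |Sigma| (n + 1))` successor tables.

## The oracles

Two independent solvers guard the engine:

* `dpScoreTable()` fills the classical `(n_1+1) x ... x (n_d+1)`
  dynamic-programming table (flat storage with odometer indexing, so
  any `d` works under the cell cap); `dpAllMlcs()` performs an
  exhaustive memoized traceback that follows *all* tie branches and
  deduplicates at the string level, because distinct traceback paths
  can spell identical strings.
* `bruteForceMlcs()` enumerates every subsequence of the shortest
  input in decreasing length and keeps all strings of the first
  length at which a greedy membership scan accepts one in every other
  sequence.

Both are exponential-cost by design and sit behind `sizeGuard()`
(defaults: `1e7` DP cells, brute-force shortest length 15). They are
selectable as algorithms in their own right on small inputs, but
their role is verification: the suite requires the engine, the DP
traceback and the brute-force enumerator to return identical string
sets on 200 seeded random instances (`d` in 2..4, `n` in 5..12, DNA
and protein).

## The dominant-point baseline

`runDominantPoint()` reproduces the classical level-set method: each
level `D^k` of dominant points is expanded through the successor
tables and pruned with `minima()` — pairwise componentwise comparison,
quadratic in the level size, as the classical description has it;
divide-and-conquer Minima variants are deliberately out of scope. The
last non-empty level index is the MLCS length, and the baseline is
used as a second independent length checker. Whether Minima provably
preserves the *complete set of distinct strings* (rather than the
length and at least one witness) is an open point; empirically, on
random instances the baseline occasionally returns a strict subset of
the true string set while the length always agrees. The tests
therefore assert length equality, assert the exact set only on the
deterministic worked examples, and log any random-instance subset
with its witness rather than failing.

## Synthetic data

`generateRandomSequences(d, n, alphabet, seed)` draws symbols i.i.d.
uniform over the alphabet, restores the caller's RNG state, and stamps
the seed into the sequence ids. Uniform i.i.d. text is the standard
neutral instance model for MLCS benchmarking: it fixes the two
drivers of problem hardness (alphabet size and length) without
importing the compositional bias of any particular genome. It is an
explicit substitute for sampling real biological sequence
collections, not a claim of equivalence: real DNA or protein has
local repeats, skewed composition and long-range correlation, which
typically change the graph's level profile. Passing tests on uniform
instances verify algorithmic correctness, not performance claims on
real data.

## Problem sizes used by the test suite

The cross-verification suite runs 200 seeded instances at `d` in
2..4 and `n` in 5..12 — sizes chosen so the brute-force oracle (the
strictest independent check) stays exhaustive — plus one larger
seeded smoke run at `d = 5, n = 100` DNA, which exercises the engine
on a graph of about two million nodes and checks that the node map
collapses to the end sentinel with `peakLive < nodesCreated`. The
worked examples (`ACTAGCTA`/`TCAGGTAT` and the three-sequence set)
are asserted symbol for symbol, including the intermediate graph
states of the two-sequence walkthrough.

## Degenerate inputs and conventions

* Positions are 1-based project-wide; successor-table columns run
  `0..n`.
* `d = 1` is legal: the single sequence is its own unique MLCS.
* Inputs sharing no symbol (including all-empty sequences) yield
  length 0 with an *empty* string set.
* Duplicate input sequences are allowed.
* Sequences are uppercased on ingest; symbols outside the declared
  alphabet are rejected with the sequence id and position named.
  Ambiguity codes (`N`, `X`) are invalid unless the user declares a
  custom alphabet containing them.
* MLCS strings are always reported sorted lexicographically, and all
  engines are deterministic, so fixed inputs give byte-identical
  reports.

## Known limitations

* Single-threaded throughout; no parallel expansion.
* Worst-case node counts remain exponential in `d`; the leveled
  deletion bounds memory by the live frontier, not the total work.
* The dominant-point baseline guarantees the length only (see above).
* No bounded-memory or approximate modes, and no streaming of partial
  solutions; the engine reports only complete answers.
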