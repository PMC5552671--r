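# MLCSdag

Exact search for **all** multiple longest common subsequences (MLCS)
of `d >= 1` sequences over a finite alphabet — DNA, protein, or any
inferred or user-declared symbol set.

Finding the longest common subsequence of many sequences is a
classical NP-hard problem at the core of sequence-similarity analysis.
MLCSdag's engine organizes the search space as a DAG over *match
points* — position vectors `p = (p_1, ..., p_d)` with
`s_1[p_1] = ... = s_d[p_d]` — and constructs it level by level through
per-sequence successor tables (`ST[i, j]` = first occurrence of symbol
`sigma_i` strictly after position `j`, so all successors of a node
cost `O(d |Sigma|)`). The key idea is *generation and deletion*: as
soon as an expanded node has no incoming edges it can never receive
longer partial subsequences, so it bequeaths its partial-LCS set to
its successors (each appending its own symbol) and is removed. The
graph grows, peaks and collapses; the single surviving end node holds
the complete set of MLCS strings, with no traceback phase at all.

For verification the package also ships the classical
dynamic-programming score table with exhaustive all-ties traceback, a
guarded brute-force enumerator, and the dominant-point (`Minima`)
baseline, all behind one result contract.

## Worked example

```r
library(MLCSdag)

x <- SequenceSet(c("ACTAGCTA", "TCAGGTAT"))
res <- runLeveledDag(x)
res
#> MlcsResult (leveled): length 5, 2 distinct strings
#>    CAGTA TAGTA

mlcsStrings(res)
#> [1] "CAGTA" "TAGTA"
runStats(res)
#> RunStats: 12 nodes created, peak 10 live, 4 levels, 25 candidates, 6 removal passes
```

The two sequences share exactly two longest common subsequences,
`CAGTA` and `TAGTA`, both of length 5; the counters say the engine
created 12 match-point nodes, never held more than 10 at once, and
finished in 4 expansion rounds and 6 removal passes. The independent
solvers agree:

```r
mlcsStrings(dpAllMlcs(x))        # [1] "CAGTA" "TAGTA"
mlcsStrings(bruteForceMlcs(x))   # [1] "CAGTA" "TAGTA"
mlcsLength(runDominantPoint(x))  # [1] 5
```

The construction can also be stepped and inspected, e.g. for the
graph state right after the level-1 nodes die:

```r
dag <- initGraph(x)
expandLevel(dag); removeOutdatedPass(dag)   # level 1, source removed
expandLevel(dag); removeOutdatedPass(dag)   # level 2, three nodes die
liveNodeCount(dag)       # [1] 7
nodePlcs(dag, c(5, 4))   # [1] "AG" "CG" "TG"
```

A shell front end wraps the same functions:

```sh
Rscript inst/scripts/mlcs simulate --num 5 --length 100 --alphabet dna --seed 42 --output random.fasta
Rscript inst/scripts/mlcs run --input random.fasta --algorithm leveled --stats-json stats.json
```

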