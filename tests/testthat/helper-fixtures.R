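# Worked-example fixtures and independent (package-free) oracles used
# across the suite.

pairSeqs <- function() c("ACTAGCTA", "TCAGGTAT")
tripleSeqs <- function() c("ACTAGTGC", "TGCTAGCA", "CATGCGAT")

pairSet <- function() SequenceSet(pairSeqs())
tripleSet <- function() SequenceSet(tripleSeqs())

# forward-scan successor oracle: first position of sym strictly after j
scanNextOccurrence <- function(s, sym, j) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  hits <- which(chars == sym)
  hits <- hits[hits > j]
  if (length(hits) == 0L) NA_integer_ else hits[[1L]]
}

# greedy subsequence check, independent of the package implementation
greedyIsSubseq <- function(sub, s) {
  if (nchar(sub) == 0L) return(TRUE)
  a <- strsplit(sub, "", fixed = TRUE)[[1L]]
  b <- strsplit(s, "", fixed = TRUE)[[1L]]
  i <- 1L
  for (ch in b) {
    if (ch == a[[i]]) {
      i <- i + 1L
      if (i > length(a)) return(TRUE)
    }
  }
  FALSE
}

symbolAt <- function(s, pos) substr(s, pos, pos)

randomInstance <- function(seed, dRange = 2:4, nRange = 5:12,
                           alphabets = list(DNA_ALPHABET, PROTEIN_ALPHABET)) {
  withr::with_seed(seed, {
    d <- sample(dRange, 1L)
    n <- sample(nRange, 1L)
    alpha <- alphabets[[sample(seq_along(alphabets), 1L)]]
    generateRandomSequences(d, n, alpha, seed = seed + 10000L)
  })
}
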