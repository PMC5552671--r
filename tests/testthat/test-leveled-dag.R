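ptKey <- function(p) paste(p, collapse = ",")

test_that("a fresh graph holds only the sentinels", {
  dag <- initGraph(pairSet())
  expect_equal(liveNodeCount(dag), 0L)
  expect_length(livePoints(dag), 0L)
  expect_false(isFinished(dag))
  expect_length(endPlcs(dag), 0L)
  src <- nodeInfo(dag, sourcePoint(2))
  expect_length(src$plcs, 0L)
  expect_false(src$expanded)
  expect_equal(src$incoming, 0L)
  s <- dagCounters(dag)
  expect_equal(s$nodesCreated + s$levels + s$candidatesGenerated +
                 s$removalPasses, 0)
})

test_that("the two-sequence walkthrough unfolds level by level", {
  dag <- initGraph(pairSet())

  # level 1: A(1,3), C(2,2), G(5,4), T(3,1), each with its single char
  expect_equal(expandLevel(dag), 4L)
  lvl1 <- vapply(livePoints(dag), ptKey, character(1))
  expect_setequal(lvl1, c("1,3", "2,2", "5,4", "3,1"))
  expect_identical(nodePlcs(dag, c(1L, 3L)), "A")
  expect_identical(nodePlcs(dag, c(5L, 4L)), "G")

  # the source is the only outdated node so far
  expect_equal(removeOutdatedPass(dag), 1L)
  expect_error(nodePlcs(dag, sourcePoint(2)), "no live node")
  expect_identical(nodePlcs(dag, c(1L, 3L)), "A")   # unchanged by union

  # level 2 creates 6 new nodes; G(5,4) is linked, not re-created
  expect_equal(expandLevel(dag), 6L)
  lvl2 <- vapply(livePoints(dag), ptKey, character(1))
  expect_setequal(lvl2, c("1,3", "2,2", "5,4", "3,1",
                          "4,7", "3,6", "4,3", "8,7", "7,6", "6,2"))
  # childless A(8,7) acquires the end node as its only successor later;
  # right now it is unexpanded with empty partial LCSs
  expect_length(nodePlcs(dag, c(8L, 7L)), 0L)

  # removal deletes the three level-1 nodes; 7 internal nodes remain
  expect_equal(removeOutdatedPass(dag), 3L)
  expect_equal(liveNodeCount(dag), 7L)
  left <- vapply(livePoints(dag), ptKey, character(1))
  expect_setequal(left, c("5,4", "4,7", "3,6", "4,3", "8,7", "7,6", "6,2"))
  # G(5,4) inherited from all three dead precursors
  expect_identical(nodePlcs(dag, c(5L, 4L)), c("AG", "CG", "TG"))
  expect_identical(nodePlcs(dag, c(4L, 7L)), "AA")

  # level 3: T(7,8) and A(8,3) are new; A(8,7) ends up childless
  expect_equal(expandLevel(dag), 2L)
  info87 <- nodeInfo(dag, c(8L, 7L))
  expect_true(info87$expanded)
  expect_length(info87$successors, 1L)
  expect_null(info87$successors[[1L]])     # the end sentinel
  expect_equal(removeOutdatedPass(dag), 3L)  # T(3,6), A(4,3), C(6,2)
  # A(4,7)'s shorter AA was replaced through dying T(3,6)
  expect_identical(nodePlcs(dag, c(4L, 7L)), c("ATA", "CTA"))

  # drive to completion: expand the last level, then drain
  expect_equal(expandLevel(dag), 0L)
  expect_error(expandLevel(dag), "current level is empty")
  while (!isFinished(dag)) expect_gt(removeOutdatedPass(dag), 0L)
  expect_identical(endPlcs(dag), c("CAGTA", "TAGTA"))
  expect_equal(liveNodeCount(dag), 0L)
})

test_that("full runs return the complete MLCS set on the worked examples", {
  res <- runLeveledDag(pairSet())
  expect_identical(mlcsStrings(res), c("CAGTA", "TAGTA"))
  expect_equal(mlcsLength(res), 5L)

  res3 <- runLeveledDag(tripleSet())
  expect_equal(mlcsLength(res3), 4L)
  expect_identical(mlcsStrings(res3), c("CAGC", "CTGC"))
})

test_that("degenerate inputs follow the result contract", {
  s <- "GATTACA"
  twin <- runLeveledDag(SequenceSet(c(s, s)))
  expect_identical(mlcsStrings(twin), s)
  expect_equal(mlcsLength(twin), nchar(s))

  none <- runLeveledDag(SequenceSet(c("AC", "GT"), alphabet = DNA_ALPHABET))
  expect_equal(mlcsLength(none), 0L)
  expect_length(mlcsStrings(none), 0L)

  single <- runLeveledDag(SequenceSet(s))
  expect_identical(mlcsStrings(single), s)

  empty <- runLeveledDag(SequenceSet(c("", ""), alphabet = DNA_ALPHABET))
  expect_equal(mlcsLength(empty), 0L)
  expect_length(mlcsStrings(empty), 0L)
})

test_that("each match point is inserted once and removed once", {
  for (seed in c(101, 202, 303)) {
    x <- randomInstance(seed)
    dag <- initGraph(x)
    .dagRun <- function() {
      while (TRUE) {
        created <- tryCatch(expandLevel(dag), error = function(e) NULL)
        if (is.null(created)) break
        removeOutdatedPass(dag)
      }
      while (!isFinished(dag)) removeOutdatedPass(dag)
    }
    .dagRun()
    s <- dagCounters(dag)
    expect_equal(s$nodesRemoved, s$nodesCreated)
    expect_equal(s$liveInternal, 0)
    expect_lte(s$peakLive, s$nodesCreated)
    expect_gte(s$candidatesGenerated, s$nodesCreated)
  }
})

test_that("live partial-LCS sets stay equal-length after every pass", {
  x <- randomInstance(404)
  dag <- initGraph(x)
  repeat {
    created <- tryCatch(expandLevel(dag), error = function(e) NULL)
    if (is.null(created)) break
    removeOutdatedPass(dag)
    for (p in livePoints(dag)) {
      strs <- nodePlcs(dag, p)
      if (length(strs) > 1L)
        expect_length(unique(nchar(strs)), 1L)
      expect_false(anyDuplicated(strs) > 0L)
    }
  }
  while (!isFinished(dag)) removeOutdatedPass(dag)
  expect_identical(endPlcs(dag), mlcsStrings(dpAllMlcs(x)))
})

test_that("results are invariant to expansion and removal orders", {
  withr::with_seed(55, {
    for (rep in 1:5) {
      x <- randomInstance(500 + rep)
      ref <- mlcsStrings(runLeveledDag(x))
      nsym <- length(alphabet(x))
      for (perm in 1:5) {
        ord <- sample(nsym)
        po <- if (perm %% 2 == 0) "reverse" else "insertion"
        got <- mlcsStrings(runLeveledDag(x, symbolOrder = ord,
                                         passOrder = po))
        expect_identical(got, ref)
      }
    }
  })
})

test_that("leveled engine agrees with both oracles on random instances", {
  for (seed in 1:30) {
    x <- randomInstance(600 + seed)
    lv <- runLeveledDag(x)
    dp <- dpAllMlcs(x)
    bf <- bruteForceMlcs(x)
    expect_identical(mlcsStrings(lv), mlcsStrings(dp))
    expect_identical(mlcsStrings(lv), mlcsStrings(bf))
    expect_equal(mlcsLength(lv), mlcsLength(dp))
    for (w in mlcsStrings(lv))
      for (s in sequences(x))
        expect_true(greedyIsSubseq(w, s))
  }
})
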