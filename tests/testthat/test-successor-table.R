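test_that("successor tables reproduce the printed example lookups", {
  st1 <- buildSuccessorTable("ACTAGCTA", DNA_ALPHABET)
  st2 <- buildSuccessorTable("TCAGGTAT", DNA_ALPHABET)
  # lookups for the node C(2,2): (4,3), (6,-), (5,4), (3,6)
  expect_equal(st1@entries["A", "2"], 4L, ignore_attr = TRUE)
  expect_equal(st2@entries["A", "2"], 3L, ignore_attr = TRUE)
  expect_equal(st1@entries["C", "2"], 6L, ignore_attr = TRUE)
  expect_true(is.na(st2@entries["C", "2"]))
  expect_equal(st1@entries["G", "2"], 5L, ignore_attr = TRUE)
  expect_equal(st2@entries["G", "2"], 4L, ignore_attr = TRUE)
  expect_equal(st1@entries["T", "2"], 3L, ignore_attr = TRUE)
  expect_equal(st2@entries["T", "2"], 6L, ignore_attr = TRUE)
  # column n is all NA: no position exceeds n = 8
  expect_true(all(is.na(st1@entries[, "8"])))
  expect_true(all(is.na(st2@entries[, "8"])))
})

test_that("every table entry equals the naive forward scan", {
  withr::with_seed(21, {
    for (rep in 1:6) {
      alpha <- if (rep %% 2 == 0) DNA_ALPHABET else PROTEIN_ALPHABET
      n <- sample(1:50, 1L)
      s <- paste(sample(alpha, n, replace = TRUE), collapse = "")
      st <- buildSuccessorTable(s, alpha)
      expected <- matrix(NA_integer_, length(alpha), n + 1L,
                         dimnames = list(alpha, as.character(0:n)))
      for (sym in alpha)
        for (j in 0:n)
          expected[sym, j + 1L] <- scanNextOccurrence(s, sym, j)
      expect_identical(st@entries, expected)
      # monotone over defined values for fixed symbol
      for (sym in alpha) {
        row <- st@entries[sym, ]
        defined <- row[!is.na(row)]
        expect_true(!is.unsorted(defined))
      }
    }
  })
})

test_that("successorsOf matches the worked example and its contracts", {
  tabs <- buildSuccessorTables(pairSet())
  s22 <- successorsOf(c(2L, 2L), tabs)
  expect_identical(names(s22), c("A", "G", "T"))   # no C entry
  expect_equal(s22$A, c(4L, 3L))
  expect_equal(s22$G, c(5L, 4L))
  expect_equal(s22$T, c(3L, 6L))

  src <- successorsOf(sourcePoint(2), tabs)
  expect_identical(names(src), c("A", "C", "G", "T"))
  expect_equal(src$A, c(1L, 3L))
  expect_equal(src$C, c(2L, 2L))
  expect_equal(src$G, c(5L, 4L))
  expect_equal(src$T, c(3L, 1L))

  expect_length(successorsOf(c(8L, 8L), tabs), 0L)
  expect_error(successorsOf(c(Inf, Inf), tabs), "end node has no successors")
})

test_that("generated successors strictly dominate and are true match points", {
  withr::with_seed(33, {
    for (rep in 1:10) {
      x <- randomInstance(300 + rep)
      tabs <- buildSuccessorTables(x)
      seqs <- unname(sequences(x))
      pts <- list(sourcePoint(sequenceCount(x)))
      for (step in 1:3) {
        nxt <- list()
        for (p in pts) {
          sucs <- successorsOf(p, tabs)
          expect_identical(names(sucs),
                           intersect(alphabet(x), names(sucs)))
          for (sym in names(sucs)) {
            q <- sucs[[sym]]
            expect_true(all(q > p))          # strict domination
            resolved <- mapply(symbolAt, seqs, q)
            expect_true(all(resolved == sym))  # genuine match point
          }
          nxt <- c(nxt, unname(sucs))
        }
        pts <- unique(nxt)
        if (length(pts) == 0L) break
      }
    }
  })
})
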