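test_that("FASTA and line-per-sequence text parse into validated sets", {
  ss <- readSequences(">s1\nACGT", format = "fasta")
  expect_s4_class(ss, "SequenceSet")
  expect_equal(sequenceCount(ss), 1L)
  expect_equal(unname(sequenceLengths(ss)), 4L)
  expect_equal(seqIds(ss), "s1")

  two <- readSequences("ACTAGCTA\nTCAGGTAT", format = "lines")
  expect_equal(sequenceCount(two), 2L)
  expect_equal(unname(sequenceLengths(two)), c(8L, 8L))
  expect_equal(alphabet(two), c("A", "C", "G", "T"))

  # auto-detection and uppercasing
  auto <- readSequences(">x\nacgt")
  expect_equal(unname(sequences(auto)), "ACGT")
})

test_that("invalid input is rejected with informative errors", {
  expect_error(readSequences("", format = "lines"), "no sequences")
  expect_error(readSequences("  \n \n", format = "lines"), "no sequences")
  expect_error(SequenceSet(c("ACGT", "ACNT"), alphabet = DNA_ALPHABET),
               "invalid symbol 'N' in sequence 'seq_2' at position 3")
  expect_error(SequenceSet(""), "empty alphabet")
  expect_error(inferAlphabet(SequenceSet("", alphabet = DNA_ALPHABET)),
               "empty alphabet")
  # ambiguity codes pass only under a user-declared alphabet
  expect_error(SequenceSet("ACNT", alphabet = DNA_ALPHABET), "invalid symbol")
  expect_silent(SequenceSet("ACNT", alphabet = c(DNA_ALPHABET, "N")))
})

test_that("alphabet inference returns the sorted symbol union", {
  expect_equal(inferAlphabet(pairSet()), c("A", "C", "G", "T"))
  one <- SequenceSet("AAAA")
  expect_equal(inferAlphabet(one), "A")
  expect_equal(length(inferAlphabet(one)), 1L)
  prot <- generateRandomSequences(4, 30, PROTEIN_ALPHABET, seed = 11)
  inferred <- inferAlphabet(prot)
  expect_lte(length(inferred), 20L)
  expect_true(all(inferred %in% PROTEIN_ALPHABET))
})

test_that("FASTA write/read round trip is the identity", {
  x <- SequenceSet(c("ACTAGCTA", "TCAGGTAT"), ids = c("s1", "s2"))
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(x, tf)
  lines <- readLines(tf)
  expect_equal(sum(startsWith(lines, ">")), 2L)
  expect_true(all(nchar(lines) <= 60L))
  back <- readSequences(tf, format = "fasta")
  expect_equal(sequences(back), sequences(x))
  expect_equal(seqIds(back), seqIds(x))
  expect_equal(alphabet(back), alphabet(x))

  # blank ids get default labels on write
  y <- SequenceSet("ACGT", ids = "")
  tf2 <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(y, tf2)
  expect_equal(seqIds(readSequences(tf2)), "seq_1")
})

test_that("the random generator is a pure function of (d, n, alphabet, seed)", {
  a <- generateRandomSequences(5, 100, DNA_ALPHABET, seed = 42)
  b <- generateRandomSequences(5, 100, DNA_ALPHABET, seed = 42)
  expect_identical(sequences(a), sequences(b))
  expect_equal(sequenceCount(a), 5L)
  expect_true(all(sequenceLengths(a) == 100L))
  expect_false(identical(
    sequences(generateRandomSequences(5, 100, DNA_ALPHABET, seed = 43)),
    sequences(a)))

  empty <- generateRandomSequences(1, 0, DNA_ALPHABET, seed = 1)
  expect_equal(unname(sequences(empty)), "")

  # generating must not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generateRandomSequences(2, 5, DNA_ALPHABET, 7))
  expect_identical(runif(1), before)
})

test_that("generated symbols are uniform within the 3-sigma binomial band", {
  x <- generateRandomSequences(3, 10000, DNA_ALPHABET, seed = 1)
  # per sequence, each symbol count ~ Binomial(10000, 1/4):
  # sd = sqrt(10000 * 1/4 * 3/4) = 43.3
  tol <- 3 * sqrt(10000 * 0.25 * 0.75)
  for (s in sequences(x)) {
    counts <- table(factor(strsplit(s, "")[[1L]], levels = DNA_ALPHABET))
    expect_true(all(abs(counts - 2500) <= tol))
  }
})
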