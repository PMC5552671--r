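#' Construct a SequenceSet
#'
#' Validates and uppercases a set of symbol strings. If no alphabet is
#' given it is inferred as the sorted union of observed symbols;
#' symbols outside a declared alphabet are rejected with the offending
#' sequence id and position.
#'
#' @param sequences character vector of sequences (mixed case accepted).
#' @param ids optional labels; defaults to \code{seq_1..seq_d}.
#' @param alphabet optional character vector of allowed symbols (will
#'   be sorted); e.g. [DNA_ALPHABET] or [PROTEIN_ALPHABET].
#' @return A [SequenceSet-class] object.
#' @examples
#' SequenceSet(c("ACTAGCTA", "TCAGGTAT"))
#' @export
SequenceSet <- function(sequences, ids = NULL, alphabet = NULL) {
  sequences <- toupper(as.character(sequences))
  if (is.null(ids))
    ids <- sprintf("seq_%d", seq_along(sequences))
  ids <- as.character(ids)
  blank <- !nzchar(ids) | is.na(ids)
  ids[blank] <- sprintf("seq_%d", which(blank))
  if (is.null(alphabet)) {
    alphabet <- sort(unique(unlist(strsplit(sequences, "", fixed = TRUE))))
    if (length(alphabet) == 0L)
      stop("empty alphabet: all sequences are empty and no alphabet given")
  } else {
    alphabet <- sort(unique(toupper(as.character(alphabet))))
  }
  new("SequenceSet", sequences = sequences, ids = ids, alphabet = alphabet)
}

#' Read a sequence set from FASTA or line-per-sequence text
#'
#' @param source a file path, or raw text (scalar, possibly with
#'   newlines).
#' @param format \code{"auto"} (FASTA if the first non-blank character
#'   is '>'), \code{"fasta"}, or \code{"lines"} (one sequence per
#'   line, ids auto-numbered).
#' @param alphabet optional declared alphabet; inferred when NULL.
#' @return A [SequenceSet-class] preserving input order, symbols
#'   uppercased.
#' @examples
#' readSequences(">s1\nACGT", format = "fasta")
#' readSequences("ACTAGCTA\nTCAGGTAT", format = "lines")
#' @export
readSequences <- function(source, format = c("auto", "fasta", "lines"),
                          alphabet = NULL) {
  format <- match.arg(format)
  stopifnot(is.character(source), length(source) == 1L)
  isFile <- !grepl("\n", source, fixed = TRUE) && file.exists(source)
  text <- if (isFile) readLines(source, warn = FALSE)
          else strsplit(source, "\n", fixed = TRUE)[[1L]]
  nonBlank <- text[nzchar(trimws(text))]
  if (length(nonBlank) == 0L) stop("no sequences in input")
  if (format == "auto")
    format <- if (startsWith(trimws(nonBlank[[1L]]), ">")) "fasta" else "lines"
  if (format == "fasta") {
    if (isFile) {
      bs <- Biostrings::readBStringSet(source)
    } else {
      tmp <- tempfile(fileext = ".fasta")
      on.exit(unlink(tmp), add = TRUE)
      writeLines(text, tmp)
      bs <- Biostrings::readBStringSet(tmp)
    }
    if (length(bs) == 0L) stop("no sequences in input")
    SequenceSet(as.character(bs), ids = names(bs), alphabet = alphabet)
  } else {
    SequenceSet(trimws(nonBlank), alphabet = alphabet)
  }
}

#' Infer the alphabet of a sequence set
#'
#' The sorted union of symbols observed across all sequences of the
#' set (e.g. \{A,C,G,T\} for a DNA set).
#'
#' @param x a [SequenceSet-class].
#' @return Sorted character vector of distinct symbols.
#' @examples
#' inferAlphabet(SequenceSet(c("ACTAGCTA", "TCAGGTAT")))
#' @export
inferAlphabet <- function(x) {
  stopifnot(is(x, "SequenceSet"))
  syms <- sort(unique(unlist(strsplit(x@sequences, "", fixed = TRUE))))
  if (length(syms) == 0L)
    stop("empty alphabet: all sequences are empty")
  syms
}

#' Generate a seeded random sequence set
#'
#' Draws \code{d} sequences of length \code{n} with symbols i.i.d.
#' uniform over the alphabet. The same seed always yields the same
#' set (the caller's RNG state is left untouched), and the seed is
#' recorded in the sequence ids for provenance.
#'
#' @param d number of sequences (>= 1).
#' @param n sequence length (>= 0).
#' @param alphabet symbol set; default [DNA_ALPHABET].
#' @param seed integer seed.
#' @return A [SequenceSet-class] with ids \code{seq<i>_seed<seed>}.
#' @examples
#' generateRandomSequences(3, 10, DNA_ALPHABET, seed = 1)
#' @export
generateRandomSequences <- function(d, n, alphabet = DNA_ALPHABET, seed) {
  stopifnot(d >= 1, n >= 0)
  alphabet <- sort(unique(toupper(as.character(alphabet))))
  seqs <- withr::with_seed(seed, {
    vapply(seq_len(d), function(i) {
      paste(sample(alphabet, n, replace = TRUE), collapse = "")
    }, character(1L))
  })
  SequenceSet(seqs, ids = sprintf("seq%d_seed%d", seq_len(d), as.integer(seed)),
              alphabet = alphabet)
}

#' Write a sequence set as FASTA
#'
#' One record per sequence, 60-column wrapped; blank ids are replaced
#' by \code{seq_<i>}.
#'
#' @param x a [SequenceSet-class].
#' @param destination output file path.
#' @return Invisibly, the destination path.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeFasta(SequenceSet(c("ACTAGCTA", "TCAGGTAT")), tf)
#' @export
writeFasta <- function(x, destination) {
  stopifnot(is(x, "SequenceSet"))
  ids <- x@ids
  blank <- !nzchar(ids)
  ids[blank] <- sprintf("seq_%d", which(blank))
  bs <- Biostrings::BStringSet(setNames(x@sequences, ids))
  tryCatch(
    Biostrings::writeXStringSet(bs, filepath = destination, width = 60L),
    error = function(e) {
      stop(sprintf("cannot write FASTA to '%s': %s",
                   destination, conditionMessage(e)))
    })
  invisible(destination)
}
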