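#' Build the successor table of a sequence
#'
#' One reverse sweep fills the \code{|Sigma| x (n + 1)} table: the
#' entry for symbol sigma_i at column j (0-based columns, column 0 =
#' "before the first symbol") is the position of the first occurrence
#' of sigma_i strictly after position j, or \code{NA} when the symbol
#' does not occur again. Construction is O(|Sigma| (n + 1)).
#'
#' @param sequence a single sequence string (or a [SequenceSet-class],
#'   in which case \code{which} selects the sequence).
#' @param alphabet sorted symbol set defining the row order.
#' @param which index of the sequence when \code{sequence} is a set.
#' @return A [SuccessorTable-class].
#' @examples
#' st <- buildSuccessorTable("ACTAGCTA", DNA_ALPHABET)
#' st@entries["A", "2"]   # first A after position 2 -> 4
#' @export
buildSuccessorTable <- function(sequence, alphabet = NULL, which = 1L) {
  id <- "seq_1"
  if (is(sequence, "SequenceSet")) {
    if (is.null(alphabet)) alphabet <- sequence@alphabet
    id <- sequence@ids[[which]]
    sequence <- sequence@sequences[[which]]
  }
  stopifnot(is.character(sequence), length(sequence) == 1L,
            !is.null(alphabet))
  alphabet <- sort(unique(toupper(as.character(alphabet))))
  s <- toupper(sequence)
  n <- nchar(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (n > 0L && any(!(chars %in% alphabet)))
    stop(sprintf("invalid symbol '%s' in sequence '%s'",
                 chars[which(!(chars %in% alphabet))[1L]], id))
  ent <- matrix(NA_integer_, nrow = length(alphabet), ncol = n + 1L,
                dimnames = list(alphabet, as.character(0:n)))
  nxt <- setNames(rep(NA_integer_, length(alphabet)), alphabet)
  for (j in n:0) {
    ent[, j + 1L] <- nxt
    if (j > 0L) nxt[[chars[[j]]]] <- j
  }
  new("SuccessorTable", entries = ent, symbols = alphabet,
      n = as.integer(n), seqId = id)
}

#' Build successor tables for every sequence of a set
#'
#' @param x a [SequenceSet-class].
#' @return A list of [SuccessorTable-class], one per sequence, in
#'   input order. Tables are built once per run and treated as
#'   immutable.
#' @examples
#' buildSuccessorTables(SequenceSet(c("ACTAGCTA", "TCAGGTAT")))
#' @export
buildSuccessorTables <- function(x) {
  stopifnot(is(x, "SequenceSet"))
  lapply(seq_along(x@sequences), function(k)
    buildSuccessorTable(x, which = k))
}

#' Source match point of a d-sequence set
#'
#' @param d number of sequences.
#' @return The all-zero integer vector (0, ..., 0).
#' @examples
#' sourcePoint(3)
#' @export
sourcePoint <- function(d) rep(0L, as.integer(d))

#' Generate all successors of a match point
#'
#' For each alphabet symbol sigma_i in alphabet order, the candidate
#' point \code{(ST_1[i, p_1], ..., ST_d[i, p_d])} is a successor iff
#' every component is defined. Each returned point is an internal
#' match point whose corresponding symbol is sigma_i, and strictly
#' dominates the query componentwise. A match point has therefore at
#' most \code{|Sigma|} successors, generated in O(d |Sigma|).
#'
#' @param point integer vector of length d: the source (all zeros) or
#'   an internal match point (1-based positions).
#' @param tables list of [SuccessorTable-class], one per sequence.
#' @return Named list of integer vectors; names are the symbols, in
#'   alphabet order. Symbols with an undefined component are absent.
#' @examples
#' ss <- SequenceSet(c("ACTAGCTA", "TCAGGTAT"))
#' successorsOf(c(2L, 2L), buildSuccessorTables(ss))
#' @export
successorsOf <- function(point, tables) {
  d <- length(tables)
  stopifnot(d >= 1L, length(point) == d)
  if (any(!is.finite(point)))
    stop("end node has no successors")
  point <- as.integer(point)
  symbols <- tables[[1L]]@symbols
  out <- vector("list", length(symbols))
  names(out) <- symbols
  for (i in seq_along(symbols)) {
    q <- vapply(seq_len(d), function(k)
      tables[[k]]@entries[i, point[[k]] + 1L], integer(1L))
    if (!anyNA(q)) out[[i]] <- q
  }
  out[!vapply(out, is.null, logical(1L))]
}

# 0-for-NA integer matrices in alphabet-sorted row order, the encoding
# the native engine consumes.
.tablesForNative <- function(tables) {
  lapply(tables, function(tb) {
    ent <- tb@entries
    ent[is.na(ent)] <- 0L
    ent
  })
}
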