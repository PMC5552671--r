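#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib MLCSdag, .registration = TRUE
NULL

#' The four-letter DNA alphabet
#'
#' Sorted symbol sets for the two sequence types most commonly searched
#' for multiple longest common subsequences: nucleotides (|Sigma| = 4)
#' and the 20 standard amino acids (|Sigma| = 20).
#'
#' @format A character vector of single uppercase letters, sorted.
#' @export
DNA_ALPHABET <- c("A", "C", "G", "T")

#' @rdname DNA_ALPHABET
#' @export
PROTEIN_ALPHABET <- sort(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))

.validAlphabet <- function(symbols) {
  if (length(symbols) < 1L)
    return("alphabet must contain at least one symbol")
  if (any(nchar(symbols) != 1L))
    return("alphabet symbols must be single characters")
  if (anyDuplicated(symbols))
    return("alphabet symbols must be unique")
  if (is.unsorted(symbols))
    return("alphabet symbols must be lexicographically sorted")
  TRUE
}

#' A validated set of sequences over a shared alphabet
#'
#' \code{SequenceSet} holds \code{d >= 1} symbol strings (1-based
#' positions), their ids, and the shared alphabet every sequence is
#' validated against. Duplicate sequences are allowed; the MLCS
#' definition tolerates them.
#'
#' @slot sequences character vector of uppercase symbol strings.
#' @slot ids character vector of labels, same length as
#'   \code{sequences}.
#' @slot alphabet sorted character vector of distinct single-character
#'   symbols.
#'
#' @seealso [readSequences()], [generateRandomSequences()],
#'   [runLeveledDag()]
#' @export
setClass("SequenceSet",
         representation(sequences = "character",
                        ids = "character",
                        alphabet = "character"))

setValidity("SequenceSet", function(object) {
  if (length(object@sequences) < 1L)
    return("a SequenceSet needs at least one sequence (d >= 1)")
  if (length(object@ids) != length(object@sequences))
    return("ids and sequences must have equal length")
  ok <- .validAlphabet(object@alphabet)
  if (!isTRUE(ok)) return(ok)
  for (i in seq_along(object@sequences)) {
    chars <- strsplit(object@sequences[[i]], "", fixed = TRUE)[[1L]]
    bad <- which(!(chars %in% object@alphabet))
    if (length(bad) > 0L)
      return(sprintf("invalid symbol '%s' in sequence '%s' at position %d",
                     chars[bad[1L]], object@ids[[i]], bad[1L]))
  }
  TRUE
})

#' Per-sequence successor table
#'
#' For a sequence \code{s} of length \code{n} over an alphabet of size
#' \code{|Sigma|}, the successor table is a \code{|Sigma| x (n + 1)}
#' matrix whose entry for symbol row \code{i} and column \code{j}
#' (columns indexed 0..n) is the smallest position \code{m > j} with
#' \code{s[m]} equal to the i-th alphabet symbol, or \code{NA} if the
#' symbol does not occur after \code{j}. Column \code{n} is entirely
#' \code{NA}. All successors of a match point are then read off in
#' O(d |Sigma|) time.
#'
#' @slot entries integer matrix, rows named by alphabet symbols,
#'   columns named "0".."n"; \code{NA} marks "no successor".
#' @slot symbols the alphabet row order.
#' @slot n sequence length.
#' @slot seqId id of the sequence the table was built from.
#'
#' @seealso [buildSuccessorTable()], [successorsOf()]
#' @export
setClass("SuccessorTable",
         representation(entries = "matrix",
                        symbols = "character",
                        n = "integer",
                        seqId = "character"))

setValidity("SuccessorTable", function(object) {
  if (!is.integer(object@entries))
    return("entries must be an integer matrix")
  if (nrow(object@entries) != length(object@symbols))
    return("one row per alphabet symbol required")
  if (ncol(object@entries) != object@n + 1L)
    return("entries must have n + 1 columns (0..n)")
  if (object@n >= 0L && any(!is.na(object@entries[, object@n + 1L])))
    return("column n must be all NA (no position exceeds n)")
  TRUE
})

#' Instrumentation counters for an MLCS run
#'
#' @slot nodesCreated distinct internal nodes ever inserted into the
#'   graph (source/end sentinels excluded).
#' @slot peakLive maximum number of simultaneously live internal nodes.
#' @slot levels number of level-expansion rounds.
#' @slot candidatesGenerated successor generations, counted with
#'   multiplicity (duplicates included).
#' @slot removalPasses number of remove-outdated passes executed.
#'
#' @export
setClass("RunStats",
         representation(nodesCreated = "numeric",
                        peakLive = "numeric",
                        levels = "numeric",
                        candidatesGenerated = "numeric",
                        removalPasses = "numeric"),
         prototype(nodesCreated = 0, peakLive = 0, levels = 0,
                   candidatesGenerated = 0, removalPasses = 0))

setValidity("RunStats", function(object) {
  vals <- c(object@nodesCreated, object@peakLive, object@levels,
            object@candidatesGenerated, object@removalPasses)
  if (any(vals < 0)) return("all counters must be non-negative")
  if (object@peakLive > object@nodesCreated)
    return("peakLive cannot exceed nodesCreated")
  TRUE
})

#' Result of an MLCS computation
#'
#' The complete answer to an MLCS query: the common length \code{k},
#' the deduplicated set of ALL distinct longest common subsequences
#' (sorted lexicographically), run statistics and the algorithm label.
#' \code{length} 0 comes with an empty string set (the inputs share no
#' symbol).
#'
#' @slot length MLCS length (integer scalar).
#' @slot strings sorted character vector of distinct MLCS strings.
#' @slot stats a [RunStats-class] object.
#' @slot algorithm one of "leveled", "dp", "brute", "dominant".
#' @slot details algorithm-specific extras (e.g. per-level dominant set
#'   sizes for the dominant-point baseline).
#'
#' @seealso [runLeveledDag()], [dpAllMlcs()], [bruteForceMlcs()],
#'   [runDominantPoint()]
#' @export
setClass("MlcsResult",
         representation(length = "integer",
                        strings = "character",
                        stats = "RunStats",
                        algorithm = "character",
                        details = "list"),
         prototype(details = list()))

setValidity("MlcsResult", function(object) {
  if (length(object@length) != 1L || object@length < 0L)
    return("length must be a single non-negative integer")
  if (length(object@strings) > 0L &&
      any(nchar(object@strings) != object@length))
    return("every MLCS string must have the reported length")
  if (anyDuplicated(object@strings))
    return("MLCS strings must be distinct")
  if (object@length > 0L && length(object@strings) == 0L)
    return("a positive MLCS length requires a non-empty string set")
  TRUE
})

#' Mutable handle on a leveled DAG under construction
#'
#' A thin S4 handle over the native graph state (an external pointer),
#' created by [initGraph()] and mutated in place by [expandLevel()] and
#' [removeOutdatedPass()]. The graph holds a node map keyed by match
#' point, the current/next level queues, and the source/end sentinels
#' ((0,...,0) and (Inf,...,Inf)).
#'
#' @slot ptr external pointer to the native graph state.
#' @slot seqset the input [SequenceSet-class].
#'
#' @seealso [initGraph()], [runLeveledDag()], [liveNodeCount()]
#' @export
setClass("LeveledDag",
         representation(ptr = "externalptr",
                        seqset = "SequenceSet"))

#' Dense multi-dimensional LCS score table
#'
#' The classical dynamic-programming table with \code{(n_1+1) x ... x
#' (n_d+1)} cells, stored flat in mixed-radix (odometer) order. Cell
#' \code{T[i_1,...,i_d]} is the MLCS length of the prefixes ending at
#' those positions; any cell with a zero index is 0 and the final cell
#' is the MLCS length of the full inputs.
#'
#' @slot dims integer vector \code{c(n_1+1, ..., n_d+1)}.
#' @slot cells flat integer vector of length \code{prod(dims)}; the
#'   first dimension varies fastest.
#'
#' @seealso [dpScoreTable()], [dpAllMlcs()]
#' @export
setClass("ScoreTable",
         representation(dims = "integer",
                        cells = "integer"))

setValidity("ScoreTable", function(object) {
  if (prod(object@dims) != length(object@cells))
    return("cells length must equal prod(dims)")
  if (any(object@cells < 0L)) return("cells must be non-negative")
  TRUE
})

#' Resource guard for the exact oracles
#'
#' Caps that keep the exhaustive oracles on feasible inputs: the DP
#' table refuses to allocate more than \code{maxCells} cells and the
#' brute-force enumerator refuses shortest sequences longer than
#' \code{maxBruteLength} (it enumerates all 2^n subsequences).
#'
#' @param maxCells cap on \code{prod(n_k + 1)} for [dpScoreTable()];
#'   default 1e7.
#' @param maxBruteLength cap on the shortest-sequence length for
#'   [bruteForceMlcs()]; default 15.
#' @return A \code{SizeGuard} object.
#' @examples
#' sizeGuard(maxCells = 1e5)
#' @export
sizeGuard <- function(maxCells = 1e7, maxBruteLength = 15L) {
  new("SizeGuard", maxCells = as.numeric(maxCells),
      maxBruteLength = as.integer(maxBruteLength))
}

#' @rdname sizeGuard
#' @slot maxCells cap on DP table cells.
#' @slot maxBruteLength cap on brute-force shortest-sequence length.
#' @export
setClass("SizeGuard",
         representation(maxCells = "numeric",
                        maxBruteLength = "integer"),
         prototype(maxCells = 1e7, maxBruteLength = 15L))

setValidity("SizeGuard", function(object) {
  if (object@maxCells <= 0 || object@maxBruteLength <= 0)
    return("guard caps must be positive")
  TRUE
})
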