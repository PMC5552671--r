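#' Accessors for sequence sets and results
#'
#' Small generic accessors in the Bioconductor accessor-over-slot
#' style: \code{sequenceCount} returns \code{d}, \code{sequenceLengths}
#' the per-sequence lengths \code{n_1..n_d}, \code{alphabet} the shared
#' sorted symbol set, \code{seqIds} the labels. On an
#' \code{MlcsResult}, \code{mlcsLength}, \code{mlcsStrings} and
#' \code{runStats} return the MLCS length, the sorted string set and
#' the instrumentation counters.
#'
#' @param x a [SequenceSet-class] or [MlcsResult-class] object.
#' @return See the per-accessor description.
#' @examples
#' ss <- SequenceSet(c("ACTAGCTA", "TCAGGTAT"))
#' sequenceCount(ss)
#' sequenceLengths(ss)
#' alphabet(ss)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sequenceCount", function(x) standardGeneric("sequenceCount"))

#' @rdname accessors
#' @export
setGeneric("sequenceLengths", function(x) standardGeneric("sequenceLengths"))

#' @rdname accessors
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))

#' @rdname accessors
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname accessors
#' @export
setGeneric("mlcsLength", function(x) standardGeneric("mlcsLength"))

#' @rdname accessors
#' @export
setGeneric("mlcsStrings", function(x) standardGeneric("mlcsStrings"))

#' @rdname accessors
#' @export
setGeneric("runStats", function(x) standardGeneric("runStats"))

setMethod("sequenceCount", "SequenceSet", function(x) length(x@sequences))

setMethod("sequenceLengths", "SequenceSet",
          function(x) setNames(nchar(x@sequences), x@ids))

setMethod("alphabet", "SequenceSet", function(x) x@alphabet)

setMethod("seqIds", "SequenceSet", function(x) x@ids)

setMethod("sequences", "SequenceSet",
          function(x) setNames(x@sequences, x@ids))

setMethod("mlcsLength", "MlcsResult", function(x) x@length)

setMethod("mlcsStrings", "MlcsResult", function(x) x@strings)

setMethod("runStats", "MlcsResult", function(x) x@stats)

setMethod("show", "SequenceSet", function(object) {
  lens <- nchar(object@sequences)
  cat(sprintf("SequenceSet with %d sequence%s over {%s}\n",
              length(object@sequences),
              if (length(object@sequences) == 1L) "" else "s",
              paste(object@alphabet, collapse = ",")))
  cat(sprintf("  lengths: %s\n",
              paste(utils::head(lens, 10L), collapse = ", ")))
  invisible(object)
})

setMethod("show", "SuccessorTable", function(object) {
  cat(sprintf("SuccessorTable for '%s' (|Sigma| = %d, n = %d)\n",
              object@seqId, length(object@symbols), object@n))
  invisible(object)
})

setMethod("show", "RunStats", function(object) {
  cat(sprintf(paste0("RunStats: %g nodes created, peak %g live, ",
                     "%g levels, %g candidates, %g removal passes\n"),
              object@nodesCreated, object@peakLive, object@levels,
              object@candidatesGenerated, object@removalPasses))
  invisible(object)
})

setMethod("show", "MlcsResult", function(object) {
  cat(sprintf("MlcsResult (%s): length %d, %d distinct string%s\n",
              object@algorithm, object@length, length(object@strings),
              if (length(object@strings) == 1L) "" else "s"))
  if (length(object@strings) > 0L)
    cat("  ", paste(utils::head(object@strings, 8L), collapse = " "),
        if (length(object@strings) > 8L) "..." else "", "\n")
  invisible(object)
})

setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable: %s cells, final cell = %d\n",
              paste(object@dims, collapse = " x "),
              object@cells[length(object@cells)]))
  invisible(object)
})
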