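#' Greedy subsequence membership test
#'
#' Scans \code{s} left to right, matching the symbols of \code{sub} in
#' order; TRUE iff all of them are found.
#'
#' @param sub candidate subsequence (character scalar; "" is a
#'   subsequence of everything).
#' @param s the containing sequence.
#' @return Logical scalar.
#' @examples
#' isSubsequence("TAGTA", "ACTAGCTA")
#' @export
isSubsequence <- function(sub, s) {
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

# strides for flat (odometer) indexing of a d-dimensional table,
# first dimension fastest
.strides <- function(dims) cumprod(c(1L, dims[-length(dims)]))

#' Build the d-dimensional LCS score table
#'
#' Fills the classical dynamic-programming table: a cell with any zero
#' index is 0; when the d addressed symbols all agree the cell is the
#' diagonal predecessor plus one; otherwise it is the maximum over the
#' d one-step-back neighbors. The final cell is the MLCS length.
#'
#' @param x a [SequenceSet-class].
#' @param guard a [sizeGuard()]; the table refuses to exceed
#'   \code{maxCells} cells.
#' @return A [ScoreTable-class].
#' @examples
#' tab <- dpScoreTable(SequenceSet(c("ACTAGCTA", "TCAGGTAT")))
#' tab@cells[length(tab@cells)]   # MLCS length 5
#' @export
dpScoreTable <- function(x, guard = sizeGuard()) {
  stopifnot(is(x, "SequenceSet"), is(guard, "SizeGuard"))
  lens <- nchar(x@sequences)
  dims <- as.integer(lens + 1L)
  total <- prod(as.numeric(dims))
  if (total > guard@maxCells)
    stop(sprintf("score table too large: %.0f cells exceed the cap of %.0f",
                 total, guard@maxCells))
  d <- length(dims)
  chars <- lapply(x@sequences, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  strides <- .strides(dims)
  cells <- integer(total)
  iv <- integer(d)                       # 0-based odometer
  diagStep <- sum(strides)
  for (idx in seq_len(total)) {
    if (all(iv > 0L)) {
      ch <- chars[[1L]][iv[[1L]]]
      same <- TRUE
      for (k in seq_len(d)[-1L]) {
        if (chars[[k]][iv[[k]]] != ch) { same <- FALSE; break }
      }
      if (same) {
        cells[[idx]] <- cells[[idx - diagStep]] + 1L
      } else {
        best <- 0L
        for (k in seq_len(d)) {
          v <- cells[[idx - strides[[k]]]]
          if (v > best) best <- v
        }
        cells[[idx]] <- best
      }
    }                                     # else: some index 0 -> 0
    # advance odometer
    for (k in seq_len(d)) {
      iv[[k]] <- iv[[k]] + 1L
      if (iv[[k]] < dims[[k]]) break
      iv[[k]] <- 0L
    }
  }
  new("ScoreTable", dims = dims, cells = cells)
}

#' Enumerate all MLCS by exhaustive score-table traceback
#'
#' Memoized traceback from the final cell: where all addressed symbols
#' agree and the cell equals its diagonal predecessor plus one, the
#' matched symbol extends every string of the predecessor; every
#' one-step-back neighbor holding the same value is followed too, so
#' all tie branches are explored and the full deduplicated MLCS set is
#' returned.
#'
#' @param x a [SequenceSet-class].
#' @param table optional pre-built [ScoreTable-class] for \code{x}.
#' @param guard a [sizeGuard()], used when the table must be built.
#' @return An [MlcsResult-class] with \code{algorithm = "dp"}.
#' @examples
#' mlcsStrings(dpAllMlcs(SequenceSet(c("ACTAGCTA", "TCAGGTAT"))))
#' @export
dpAllMlcs <- function(x, table = NULL, guard = sizeGuard()) {
  stopifnot(is(x, "SequenceSet"))
  if (is.null(table)) table <- dpScoreTable(x, guard)
  dims <- table@dims
  cells <- table@cells
  d <- length(dims)
  chars <- lapply(x@sequences, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  strides <- .strides(dims)
  diagStep <- sum(strides)
  memo <- new.env(parent = emptyenv())
  collect <- function(idx, iv) {
    v <- cells[[idx]]
    if (v == 0L) return("")
    key <- as.character(idx)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- character(0L)
    if (all(iv > 0L)) {
      ch <- chars[[1L]][iv[[1L]]]
      same <- all(vapply(seq_len(d), function(k)
        chars[[k]][iv[[k]]] == ch, logical(1L)))
      if (same && cells[[idx - diagStep]] + 1L == v)
        out <- paste0(collect(idx - diagStep, iv - 1L), ch)
    }
    for (k in seq_len(d)) {
      if (iv[[k]] > 0L && cells[[idx - strides[[k]]]] == v) {
        iv2 <- iv
        iv2[[k]] <- iv2[[k]] - 1L
        out <- c(out, collect(idx - strides[[k]], iv2))
      }
    }
    out <- sort(unique(out))
    memo[[key]] <- out
    out
  }
  strings <- collect(length(cells), dims - 1L)
  len <- cells[[length(cells)]]
  strings <- sort(unique(strings[nchar(strings) == len & nzchar(strings)]))
  new("MlcsResult", length = as.integer(len), strings = strings,
      stats = new("RunStats"), algorithm = "dp")
}

#' Enumerate all MLCS by brute force
#'
#' Enumerates every subsequence of the shortest input sequence in
#' decreasing length; at the greatest length where at least one of
#' them is a (greedy-checked) subsequence of every other sequence, all
#' such distinct strings are returned. Exponential in the shortest
#' length, hence guarded.
#'
#' @param x a [SequenceSet-class].
#' @param guard a [sizeGuard()]; shortest length above
#'   \code{maxBruteLength} is refused.
#' @return An [MlcsResult-class] with \code{algorithm = "brute"}.
#' @examples
#' mlcsStrings(bruteForceMlcs(SequenceSet(c("ACTAGCTA", "TCAGGTAT"))))
#' @export
bruteForceMlcs <- function(x, guard = sizeGuard()) {
  stopifnot(is(x, "SequenceSet"), is(guard, "SizeGuard"))
  lens <- nchar(x@sequences)
  shortest <- which.min(lens)
  n <- lens[[shortest]]
  if (n > guard@maxBruteLength)
    stop(sprintf("brute force infeasible: shortest sequence length %d exceeds %d",
                 n, guard@maxBruteLength))
  others <- x@sequences[-shortest]
  subs <- ""
  for (ch in strsplit(x@sequences[[shortest]], "", fixed = TRUE)[[1L]])
    subs <- c(subs, paste0(subs, ch))
  subs <- unique(subs)
  lengths <- nchar(subs)
  best <- character(0L)
  for (len in sort(unique(lengths), decreasing = TRUE)) {
    if (len == 0L) break
    cand <- unique(subs[lengths == len])
    keep <- vapply(cand, function(w)
      all(vapply(others, function(s) isSubsequence(w, s), logical(1L))),
      logical(1L))
    if (any(keep)) {
      best <- sort(cand[keep])
      break
    }
  }
  new("MlcsResult",
      length = if (length(best) > 0L) nchar(best[[1L]]) else 0L,
      strings = best, stats = new("RunStats"), algorithm = "brute")
}
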