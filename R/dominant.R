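#' Minima pruning of a candidate level
#'
#' Collapses duplicates and removes every match point dominated by
#' another candidate (componentwise <= with at least one strict <),
#' by plain pairwise comparison of the d-dimensional vectors. The
#' surviving points form an antichain; applying the operation twice
#' changes nothing.
#'
#' @param candidates a list of equal-length integer vectors, or a
#'   matrix with one point per row.
#' @return A matrix of surviving points (one per row, input order of
#'   first occurrence).
#' @examples
#' minima(list(c(1, 3), c(2, 2), c(5, 4), c(3, 1)))   # drops (5,4)
#' @export
minima <- function(candidates) {
  if (is.list(candidates)) {
    if (length(candidates) == 0L)
      return(matrix(integer(0L), nrow = 0L, ncol = 0L))
    if (length(unique(lengths(candidates))) != 1L)
      stop("match points of mixed dimensionalities")
    m <- do.call(rbind, lapply(candidates, as.integer))
  } else {
    m <- as.matrix(candidates)
    storage.mode(m) <- "integer"
  }
  if (nrow(m) == 0L) return(m)
  m <- m[!duplicated(m), , drop = FALSE]
  n <- nrow(m)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !keep[i]) next
      # j dominates i: all <=, at least one <
      if (all(m[j, ] <= m[i, ]) && any(m[j, ] < m[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  m[keep, , drop = FALSE]
}

#' Find MLCS with the classical dominant-point method
#'
#' Iterates level sets of dominant points: each point of D^k is
#' expanded through the successor tables, the pooled candidates are
#' pruned with [minima()], and every surviving point inherits its
#' parents' partial LCSs extended by its own symbol (longer strings
#' replace, equal-length union). The last non-empty level index is the
#' MLCS length. The length is guaranteed; whether Minima provably
#' preserves the COMPLETE set of distinct MLCS strings is not
#' established, so the string set should be cross-checked against
#' [dpAllMlcs()] (see the package vignette).
#'
#' @param x a [SequenceSet-class].
#' @param tables optional pre-built successor tables.
#' @return An [MlcsResult-class] with \code{algorithm = "dominant"};
#'   \code{@details$levelSizes} holds |D^k| per level and
#'   \code{@details$candidatesPerLevel} the number of successor
#'   generations (with multiplicity) per expansion round.
#' @examples
#' runDominantPoint(SequenceSet(c("ACTAGCTA", "TCAGGTAT")))
#' @export
runDominantPoint <- function(x, tables = NULL) {
  stopifnot(is(x, "SequenceSet"))
  if (is.null(tables)) tables <- buildSuccessorTables(x)
  d <- length(x@sequences)
  level <- list(list(point = sourcePoint(d), plcs = ""))
  levelSizes <- integer(0L)
  candPerLevel <- integer(0L)
  totalCand <- 0
  totalNodes <- 0
  k <- 0L
  repeat {
    candPoints <- list()
    candSym <- character(0L)
    candParent <- integer(0L)
    for (pi in seq_along(level)) {
      sucs <- successorsOf(level[[pi]]$point, tables)
      for (sym in names(sucs)) {
        candPoints[[length(candPoints) + 1L]] <- sucs[[sym]]
        candSym <- c(candSym, sym)
        candParent <- c(candParent, pi)
      }
    }
    if (length(candPoints) == 0L) break
    candPerLevel <- c(candPerLevel, length(candPoints))
    totalCand <- totalCand + length(candPoints)
    surv <- minima(candPoints)
    k <- k + 1L
    levelSizes <- c(levelSizes, nrow(surv))
    totalNodes <- totalNodes + nrow(surv)
    candMat <- do.call(rbind, candPoints)
    nextLevel <- vector("list", nrow(surv))
    for (si in seq_len(nrow(surv))) {
      hits <- which(apply(candMat, 1L,
                          function(r) all(r == surv[si, ])))
      strs <- character(0L)
      for (h in hits) {
        inherited <- paste0(level[[candParent[[h]]]]$plcs, candSym[[h]])
        if (length(strs) == 0L ||
            nchar(inherited[[1L]]) > nchar(strs[[1L]])) {
          strs <- unique(inherited)
        } else if (nchar(inherited[[1L]]) == nchar(strs[[1L]])) {
          strs <- unique(c(strs, inherited))
        }                                  # shorter: discard
      }
      nextLevel[[si]] <- list(point = surv[si, ], plcs = sort(strs))
    }
    level <- nextLevel
  }
  strings <- if (k > 0L)
    sort(unique(unlist(lapply(level, `[[`, "plcs"))))
  else character(0L)
  stats <- new("RunStats",
               nodesCreated = totalNodes,
               peakLive = totalNodes,    # the classical DAG keeps all levels
               levels = k,
               candidatesGenerated = totalCand,
               removalPasses = 0)
  new("MlcsResult", length = k, strings = strings, stats = stats,
      algorithm = "dominant",
      details = list(levelSizes = levelSizes,
                     candidatesPerLevel = candPerLevel))
}
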