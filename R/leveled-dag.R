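#' Initialize a leveled DAG
#'
#' Creates the graph in its starting state: the node map holds exactly
#' the source (0,...,0) and end (Inf,...,Inf) sentinels, both with
#' empty successor and partial-LCS sets, and the current level holds
#' only the source. All run counters are zero.
#'
#' @param x a [SequenceSet-class].
#' @param tables optional pre-built list of [SuccessorTable-class]
#'   (built from \code{x} when NULL).
#' @param symbolOrder optional integer permutation of
#'   \code{seq_along(alphabet(x))} fixing the successor generation
#'   order; default alphabet order. The result is invariant to it.
#' @param passOrder \code{"insertion"} (default) or \code{"reverse"}:
#'   processing order of outdated nodes within a removal pass. The
#'   result is invariant to it.
#' @return A [LeveledDag-class] handle (reference semantics: the
#'   stepping functions mutate it in place).
#' @examples
#' dag <- initGraph(SequenceSet(c("ACTAGCTA", "TCAGGTAT")))
#' liveNodeCount(dag)
#' @export
initGraph <- function(x, tables = NULL, symbolOrder = NULL,
                      passOrder = c("insertion", "reverse")) {
  stopifnot(is(x, "SequenceSet"))
  passOrder <- match.arg(passOrder)
  if (is.null(tables)) tables <- buildSuccessorTables(x)
  stopifnot(length(tables) == length(x@sequences))
  if (is.null(symbolOrder)) symbolOrder <- seq_along(x@alphabet)
  stopifnot(sort(symbolOrder) == seq_along(x@alphabet))
  ptr <- .dagCreate(.tablesForNative(tables), x@alphabet,
                    as.integer(symbolOrder), passOrder == "reverse")
  new("LeveledDag", ptr = ptr, seqset = x)
}

#' Expand the current level of a leveled DAG
#'
#' Generates all successors of every node in the current level, in
#' queue order and (by default) alphabet order. A successor already in
#' the node map is linked only (edge added, in-degree incremented); a
#' new successor is inserted with in-degree 1 and queued for the next
#' level. A childless node gets the end sentinel as its only
#' successor. Nodes created from the source carry their single-symbol
#' partial LCS. Finally the queues advance (current <- next).
#'
#' @param dag a [LeveledDag-class] from [initGraph()].
#' @return The number of newly created nodes (invisibly mutates
#'   \code{dag}).
#' @examples
#' dag <- initGraph(SequenceSet(c("ACTAGCTA", "TCAGGTAT")))
#' expandLevel(dag)   # 4 first-level nodes
#' @export
expandLevel <- function(dag) {
  stopifnot(is(dag, "LeveledDag"))
  .dagExpandLevel(dag@ptr)
}

#' Run one remove-outdated pass
#'
#' Snapshots the live, already-expanded nodes with zero in-degree
#' (never the end sentinel, never an unexpanded node), then, in
#' deterministic insertion order, bequeaths each one's partial LCSs to
#' its successors -- appending the successor's own symbol (nothing for
#' the end node), replacing when the bequeathed strings are longer,
#' unioning when equal, discarding when shorter -- decrements successor
#' in-degrees and deletes the node. Nodes whose in-degree reaches zero
#' during the pass wait for a later pass (no cascade).
#'
#' @param dag a [LeveledDag-class].
#' @return The number of nodes removed in this pass.
#' @examples
#' dag <- initGraph(SequenceSet(c("ACTAGCTA", "TCAGGTAT")))
#' expandLevel(dag)
#' removeOutdatedPass(dag)   # deletes the source
#' @export
removeOutdatedPass <- function(dag) {
  stopifnot(is(dag, "LeveledDag"))
  .dagRemovePass(dag@ptr)
}

#' Number of live internal nodes
#'
#' Counts the nodes currently held in the graph, source and end
#' sentinels excluded.
#'
#' @param dag a [LeveledDag-class].
#' @return Integer count.
#' @export
liveNodeCount <- function(dag) {
  stopifnot(is(dag, "LeveledDag"))
  .dagLiveInternal(dag@ptr)
}

#' Live internal match points
#'
#' @param dag a [LeveledDag-class].
#' @return List of integer vectors, one per live internal node, in
#'   insertion order.
#' @export
livePoints <- function(dag) {
  stopifnot(is(dag, "LeveledDag"))
  .dagLivePoints(dag@ptr)
}

#' Inspect a live node
#'
#' \code{nodePlcs} returns the partial-LCS string set currently stored
#' at the node with the given match point; \code{nodeInfo}
#' additionally returns its symbol, in-degree, expansion flag and
#' successor points (NULL marking the end sentinel). The source is
#' addressed by the all-zero point.
#'
#' @param dag a [LeveledDag-class].
#' @param point integer vector: the match point of a live node.
#' @return Character vector of strings, or a list for \code{nodeInfo}.
#' @export
nodePlcs <- function(dag, point) {
  stopifnot(is(dag, "LeveledDag"))
  .dagNodePlcs(dag@ptr, as.integer(point))
}

#' @rdname nodePlcs
#' @export
nodeInfo <- function(dag, point) {
  stopifnot(is(dag, "LeveledDag"))
  .dagNodeInfo(dag@ptr, as.integer(point))
}

#' Partial LCS set of the end sentinel
#'
#' After the run has finished this is the complete MLCS set.
#'
#' @param dag a [LeveledDag-class].
#' @return Character vector (lexicographically sorted).
#' @export
endPlcs <- function(dag) {
  stopifnot(is(dag, "LeveledDag"))
  .dagEndPlcs(dag@ptr)
}

#' Has the construction finished?
#'
#' TRUE once only the end sentinel is left in the graph.
#'
#' @param dag a [LeveledDag-class].
#' @return Logical scalar.
#' @export
isFinished <- function(dag) {
  stopifnot(is(dag, "LeveledDag"))
  .dagIsFinished(dag@ptr)
}

#' Run statistics of a leveled DAG
#'
#' @param dag a [LeveledDag-class].
#' @return A [RunStats-class]; the extra counters (live internal
#'   nodes, nodes removed) are available via [nodeInfo()]-level
#'   inspection or \code{dagCounters}.
#' @export
dagStats <- function(dag) {
  stopifnot(is(dag, "LeveledDag"))
  s <- .dagStats(dag@ptr)
  new("RunStats",
      nodesCreated = s$nodesCreated,
      peakLive = s$peakLive,
      levels = s$levels,
      candidatesGenerated = s$candidatesGenerated,
      removalPasses = s$removalPasses)
}

#' @rdname dagStats
#' @return \code{dagCounters}: the raw named list of counters,
#'   including \code{liveInternal} and \code{nodesRemoved}.
#' @export
dagCounters <- function(dag) {
  stopifnot(is(dag, "LeveledDag"))
  .dagStats(dag@ptr)
}

setMethod("show", "LeveledDag", function(object) {
  s <- .dagStats(object@ptr)
  cat(sprintf(paste0("LeveledDag over %d sequences: %g live internal ",
                     "nodes, %g created, %g levels%s\n"),
              length(object@seqset@sequences), s$liveInternal,
              s$nodesCreated, s$levels,
              if (.dagIsFinished(object@ptr)) " (finished)" else ""))
  invisible(object)
})

#' Find all MLCS with the leveled-DAG engine
#'
#' Builds the leveled DAG level by level: each round expands the
#' current level through the successor tables, then deletes the
#' outdated (zero in-degree, expanded) nodes after bequeathing their
#' partial LCSs to their successors. When no new node can be created
#' the graph collapses through repeated removal passes until only the
#' end sentinel remains; its partial-LCS set is the complete set of
#' distinct MLCS strings.
#'
#' @inheritParams initGraph
#' @param verbose print per-level progress (level sizes, removals).
#' @return An [MlcsResult-class] with \code{algorithm = "leveled"}.
#' @examples
#' res <- runLeveledDag(SequenceSet(c("ACTAGCTA", "TCAGGTAT")))
#' mlcsStrings(res)   # "CAGTA" "TAGTA"
#' @export
runLeveledDag <- function(x, tables = NULL, symbolOrder = NULL,
                          passOrder = c("insertion", "reverse"),
                          verbose = FALSE) {
  dag <- initGraph(x, tables = tables, symbolOrder = symbolOrder,
                   passOrder = passOrder)
  if (verbose) {
    while (.dagCurLevelSize(dag@ptr) > 0L) {
      created <- expandLevel(dag)
      removed <- removeOutdatedPass(dag)
      s <- dagCounters(dag)
      message(sprintf("level %g: +%d nodes, -%d outdated, %g live",
                      s$levels, created, removed, s$liveInternal))
    }
    while (!isFinished(dag)) {
      removed <- removeOutdatedPass(dag)
      if (removed == 0L)
        stop("internal inconsistency: removal stalled before completion")
    }
  } else {
    .dagRun(dag@ptr)
  }
  strings <- sort(endPlcs(dag))
  new("MlcsResult",
      length = if (length(strings) > 0L) nchar(strings[[1L]]) else 0L,
      strings = strings,
      stats = dagStats(dag),
      algorithm = "leveled")
}
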