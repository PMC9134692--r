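#' Find one source-sink hyperpath avoiding a forbidden edge set
#'
#' The out-set constrained subproblem at the core of hyperpath
#' enumeration: find any source-sink hyperpath disjoint from `out`, or
#' report that none exists. The solver collects the edges forward
#' reachable from the source with `out` excluded and, if the sink is
#' reached, trims them to a minimal subset in which the sink stays
#' reachable (edges are considered for removal in reverse discovery order
#' of the forward sweep); such a minimal subset is exactly a hyperpath.
#'
#' @param g A [hypergraph()].
#' @param source Source vertex id.
#' @param sink Sink vertex id.
#' @param out Character vector of forbidden edge ids.
#' @return A `hyperpath` object, or the empty path when the sink is not
#'   reachable without the forbidden edges.
#' @export
one_hyperpath <- function(g, source, sink, out = character()) {
  stopifnot_vertex(g, source, "source")
  stopifnot_vertex(g, sink, "sink")
  out <- as.character(out)
  stopifnot_edges(g, out, "out")
  si <- unname(g$vid[[source]])
  ti <- unname(g$vid[[sink]])
  fr <- fwd_sweep_i(g, si, active = excluded_mask(g, out))
  if (!(ti %in% fr$verts)) return(empty_hyperpath())
  mask <- logical(length(g$edges))
  mask[fr$edges] <- TRUE
  for (fi in rev(fr$edges)) {  # reverse discovery order of the sweep
    mask[fi] <- FALSE
    if (!fwd_sweep_i(g, si, active = mask, tv = ti)$hit)
      mask[fi] <- TRUE
  }
  as_hyperpath(g, edge_ids(g)[mask], source, sink)
}

#' Enumerate all source-sink hyperpaths
#'
#' Generates every source-sink hyperpath exactly once through a FIFO
#' queue of `(out, keep)` subproblems. The root subproblem has empty
#' sets; a solved subproblem with hyperpath `P` spawns one child per edge
#' `e` of `P` not in its keep-set, forbidding `e` in the child and adding
#' the edges handed to earlier siblings to the child's keep-set. Keep-sets
#' guarantee that the out-sets of all subproblems ever queued are
#' pairwise distinct, so no subproblem is solved twice and at most `2^m`
#' subproblems exist; the same hyperpath can still be produced by
#' different subproblems, so duplicates are filtered on the sorted edge
#' set.
#'
#' @param g A [hypergraph()].
#' @param source Source vertex id.
#' @param sink Sink vertex id.
#' @param max_subproblems Abort (with an error of class
#'   `hyperpaths_budget_error`) when more subproblems than this would be
#'   processed; the worst case is exponential in the number of edges.
#' @return A list of `hyperpath` objects, in first-discovery order, with
#'   attributes `subproblems` (number processed) and `out_sets` (list of
#'   the out-sets processed, for instrumentation).
#' @export
all_hyperpaths <- function(g, source, sink, max_subproblems = 1e6) {
  queue <- list(list(out = character(), keep = character()))
  found <- list()
  seen_keys <- character()
  out_sets <- list()
  processed <- 0L
  while (length(queue) > 0L) {
    sub <- queue[[1L]]
    queue <- queue[-1L]
    processed <- processed + 1L
    if (processed > max_subproblems) {
      stop(structure(class = c("hyperpaths_budget_error", "error",
                               "condition"),
                     list(message = paste0("subproblem budget exceeded (",
                                           format(max_subproblems,
                                                  scientific = FALSE), ")"),
                          call = sys.call())))
    }
    out_sets[[processed]] <- sort(sub$out, method = "radix")
    p <- one_hyperpath(g, source, sink, out = sub$out)
    if (is_empty_path(p)) next
    key <- paste(sort(p$edges, method = "radix"), collapse = "\r")
    if (!(key %in% seen_keys)) {
      seen_keys <- c(seen_keys, key)
      found[[length(found) + 1L]] <- p
    }
    handed <- character()  # edges given to earlier siblings' out-sets
    for (e in p$edges) {   # witness-ordering order fixes the sibling order
      if (e %in% sub$keep) next
      queue[[length(queue) + 1L]] <- list(out = c(sub$out, e),
                                          keep = c(sub$keep, handed))
      handed <- c(handed, e)
    }
  }
  structure(found, subproblems = processed, out_sets = out_sets)
}

#' Shortest hyperpath by exhaustive enumeration
#'
#' The exact (exponential-time) reference solver: enumerates all
#' source-sink hyperpaths and returns one of minimum total weight, ties
#' broken by the lexicographically smallest sorted edge-id list. Used to
#' measure how close the heuristic is to the optimum on instances small
#' enough to enumerate.
#'
#' @inheritParams all_hyperpaths
#' @return A `hyperpath` object, or the empty path when no source-sink
#'   hyperpath exists.
#' @export
shortest_by_enumeration <- function(g, source, sink, max_subproblems = 1e6) {
  paths <- all_hyperpaths(g, source, sink, max_subproblems = max_subproblems)
  if (length(paths) == 0L) return(empty_hyperpath())
  ws <- vapply(paths, function(p) p$weight, numeric(1))
  keys <- vapply(paths, function(p)
    paste(sort(p$edges, method = "radix"), collapse = "\r"), character(1))
  best <- which(ws == min(ws))
  paths[[best[order(keys[best], method = "radix")[1L]]]]
}
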