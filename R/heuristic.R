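#' Shortest source-sink hyperpath heuristic
#'
#' Finds a source-sink hyperpath in a general directed hypergraph,
#' attempting to minimize its total weight. The search is Dijkstra-like
#' but edge-based: it restricts to the doubly-reachable subgraph, seeds a
#' min-heap with the edges whose tail is exactly `{source}`, and
#' repeatedly extracts the hyperedge `e` with the smallest estimated
#' path length. On extraction, a short `s,e`-hyperpath is recovered by
#' [recover_short_hyperpath()] and its weight finalizes `e`'s length
#' estimate; `e` then announces itself to its out-edges `f` (appending to
#' `f`'s in-edge list and decrementing `f`'s uncovered-tail counter), and
#' whenever `f`'s tail is fully covered a hyperpath to `f` is recovered
#' and `f` is inserted into the heap or its key decreased. After the heap
#' empties, hyperpaths are re-recovered for every reached in-edge of the
#' sink and the best resulting source-sink hyperpath is returned.
#'
#' The heuristic always returns a hyperpath when one exists (it returns
#' the empty path exactly when the sink is not forward reachable from the
#' source), and it provably returns a *shortest* hyperpath on
#' singleton-tail hypergraphs with nonnegative weights. On general
#' hypergraphs it is an upper-bound heuristic. Unlike methods restricted
#' to acyclic orderings, it handles cyclic hyperpaths, which do occur in
#' signaling networks whenever a reaction regenerates an upstream
#' species.
#'
#' @param g A [hypergraph()] with nonnegative edge weights.
#' @param source Source vertex id.
#' @param sink Sink vertex id.
#' @return A `hyperpath` object (edges in a witness ordering, total
#'   `weight`, `cyclic` flag), or the empty path (see [is_empty_path()])
#'   when no source-sink hyperpath exists.
#' @examples
#' gad <- cyclic_only_gadget()
#' shortest_hyperpath(gad$graph, gad$source, gad$sink)
#' @export
shortest_hyperpath <- function(g, source, sink) {
  stopifnot_vertex(g, source, "source")
  stopifnot_vertex(g, sink, "sink")
  h <- doubly_reachable_subgraph(g, source, sink)
  if (length(h$edges) == 0L) return(empty_hyperpath())

  state <- new.env(parent = emptyenv())
  for (id in edge_ids(h)) {
    assign(id, list(count = length(setdiff(h$edges[[id]]$tail, source)),
                    inedges = character(), length = NA_real_),
           envir = state)
  }
  covered <- stats::setNames(logical(length(h$vertices)), h$vertices)
  covered[[source]] <- TRUE
  heap <- edge_heap()
  extracted <- character()

  # Seed: edges whose tail is exactly {source}; their recovered path is
  # the edge alone, so the initial key is the edge weight.
  for (id in edge_ids(h)) {
    if (setequal(h$edges[[id]]$tail, source))
      heap$insert(id, h$edges[[id]]$weight)
  }

  while (heap$size() > 0L) {
    e <- heap$extract_min()
    extracted <- c(extracted, e)
    rec <- recover_edge_set(h, source, e, state)
    st <- get(e, envir = state)
    st$length <- rec$weight
    assign(e, st, envir = state)

    eh <- h$edges[[e]]$head
    newly <- eh[!covered[eh]]
    covered[newly] <- TRUE
    outs <- sort(unique(unlist(h$out_index[eh], use.names = FALSE)),
                 method = "radix")
    for (f in outs) {
      if (f %in% extracted) next  # finalized lengths never change
      fs <- get(f, envir = state)
      if (!(e %in% fs$inedges)) fs$inedges <- c(fs$inedges, e)
      hit <- length(intersect(h$edges[[f]]$tail, newly))
      if (hit > 0L) fs$count <- fs$count - hit
      assign(f, fs, envir = state)
      if (fs$count == 0L) {
        w <- recover_edge_set(h, source, f, state)$weight
        if (heap$contains(f)) heap$decrease_key(f, w)
        else heap$insert(f, w)
      }
    }
  }

  sink_in <- intersect(in_edges(h, sink), extracted)
  if (length(sink_in) == 0L) return(empty_hyperpath())
  best <- NULL
  for (e in sort(sink_in, method = "radix")) {
    cand <- recover_edge_set(h, source, e, state)$edges
    cand <- trim_to_sink(h, source, sink, cand, state)
    w <- sum(vapply(h$edges[cand], function(x) x$weight, numeric(1)))
    key <- paste(sort(cand, method = "radix"), collapse = "\r")
    if (is.null(best) || w < best$w || (w == best$w && key < best$key))
      best <- list(edges = cand, w = w, key = key)
  }
  as_hyperpath(g, best$edges, source, sink)
}

# Greedy trim of an edge set to a minimal subset in which `sink` is still
# reachable from `source` (which is exactly a source-sink hyperpath).
# Candidates are considered in decreasing order of finalized length
# estimates, ties broken by descending edge id.
trim_to_sink <- function(h, source, sink, edges, state) {
  lens <- vapply(edges, function(id) get(id, envir = state)$length,
                 numeric(1))
  cand <- edges[order(edges, decreasing = TRUE, method = "radix")]
  cand <- cand[order(-lens[cand], method = "radix")]
  si <- unname(h$vid[[source]])
  ti <- unname(h$vid[[sink]])
  mask <- active_mask(h, edges)
  all_ids <- edge_ids(h)
  for (f in cand) {
    fi <- match(f, all_ids)
    mask[fi] <- FALSE
    if (!fwd_sweep_i(h, si, active = mask, tv = ti)$hit)
      mask[fi] <- TRUE
  }
  all_ids[mask]
}

#' Recover a short hyperpath from the source to a hyperedge
#'
#' The greedy path-construction subroutine of the heuristic. Phase I
#' recovers an `s,e`-superpath `S` by tracing backward from `e` over the
#' recorded in-edge lists: for each tail vertex `v != s` of a traced
#' edge, every recorded in-edge whose head contains `v` is pulled in.
#' Phase II greedily trims `S` to a minimal `s,e`-superpath — an
#' `s,e`-hyperpath — by considering edges `f` in `S \ {e}` for removal in
#' decreasing order of their finalized length estimates (ties broken by
#' descending edge id), removing `f` whenever `e` stays reachable
#' without it. Trimming by estimated path length rather than by edge
#' weight is what keeps the procedure discriminating on unit-weight
#' reaction networks, where all weights tie.
#'
#' @param g A [hypergraph()] (normally the doubly-reachable subgraph the
#'   heuristic works on).
#' @param source Source vertex id.
#' @param edge Target edge id; every tail vertex of it must be covered by
#'   `source` or by heads of edges in the transitive in-edge closure.
#' @param state Per-edge search state: a named list (or environment)
#'   mapping edge id to a list with elements `inedges` (character vector
#'   of finalized in-edges, in arrival order) and `length` (finalized
#'   path-length estimate, `NA` until the edge is extracted).
#' @return A `hyperpath` object for the `s,e`-hyperpath (its ordering
#'   places `edge` last).
#' @export
recover_short_hyperpath <- function(g, source, edge, state) {
  if (is.list(state)) state <- list2env(state, parent = emptyenv())
  rec <- recover_edge_set(g, source, edge, state)
  ord <- peel_all(g, setdiff(rec$edges, edge), source)
  stopifnot(ord$complete)
  new_hyperpath(c(ord$order, edge), rec$weight,
                is_cyclic(g, rec$edges))
}

# Core of RecoverShortHyperpath; returns the edge set and weight only.
recover_edge_set <- function(g, source, edge, state) {
  st_of <- function(id) get(id, envir = state)
  # Phase I: backward trace over recorded in-edge lists.
  set <- edge
  queue <- edge
  while (length(queue) > 0L) {
    f <- queue[[1L]]
    queue <- queue[-1L]
    for (v in setdiff(g$edges[[f]]$tail, source)) {
      for (gid in st_of(f)$inedges) {
        if (v %in% g$edges[[gid]]$head && !(gid %in% set)) {
          set <- c(set, gid)
          queue <- c(queue, gid)
        }
      }
    }
  }
  si <- unname(g$vid[[source]])
  all_ids <- edge_ids(g)
  ei <- match(edge, all_ids)
  mask <- active_mask(g, set)
  if (!fwd_sweep_i(g, si, active = mask, te = ei)$hit)
    stop("internal error: recovered edge set is not an s,e-superpath for '",
         edge, "'")
  # Phase II: greedy trim, decreasing finalized length, ties by
  # descending edge id; the target edge itself is never a candidate.
  cand <- setdiff(set, edge)
  if (length(cand) > 0L) {
    lens <- vapply(cand, function(id) st_of(id)$length, numeric(1))
    if (anyNA(lens))
      stop("internal error: unfinalized length in recovered superpath")
    cand <- cand[order(cand, decreasing = TRUE, method = "radix")]
    cand <- cand[order(-lens[cand], method = "radix")]
    for (f in cand) {
      fi <- match(f, all_ids)
      mask[fi] <- FALSE
      if (!fwd_sweep_i(g, si, active = mask, te = ei)$hit)
        mask[fi] <- TRUE
    }
    set <- all_ids[mask]
  }
  list(edges = set,
       weight = sum(vapply(g$edges[set], function(x) x$weight, numeric(1))))
}

# Wrap an edge set as a certified hyperpath object with witness ordering.
as_hyperpath <- function(g, edges, source, sink) {
  ok <- is_superpath(g, edges, source, sink)
  if (!isTRUE(ok))
    stop("internal error: result is not an s,t-superpath")
  new_hyperpath(attr(ok, "witness"),
                sum(vapply(g$edges[edges], function(x) x$weight, numeric(1))),
                is_cyclic(g, edges))
}
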