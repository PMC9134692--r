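# Integer-indexed forward-reachability sweep (B-connectivity closure).
# `active` is a logical vector over edges (TRUE = usable). Maintains a
# per-edge counter of tail vertices not yet reached and a FIFO vertex
# queue, so work is proportional to the size of the explored subgraph.
# Optional early exits: `te` (edge index) halts as soon as that edge
# fires, `tv` (vertex index) as soon as that vertex is covered; 0 means
# no early exit. Returns hit flag, fired edges (firing order) and
# reached vertices (discovery order), as integer indices.
fwd_sweep_i <- function(g, si, active = NULL, te = 0L, tv = 0L) {
  ne <- length(g$edges)
  nv <- length(g$vertices)
  if (is.null(active)) active <- rep(TRUE, ne)
  count <- g$tail_sizes
  reached_v <- logical(nv)
  fired <- integer(0)
  queue <- integer(nv)
  queue[1L] <- si
  qh <- 1L; qt <- 1L
  reached_v[si] <- TRUE
  if (tv == si) return(list(hit = TRUE, edges = fired, verts = si))
  out_i <- g$out_i
  heads_i <- g$heads_i
  while (qh <= qt) {
    v <- queue[qh]
    qh <- qh + 1L
    for (e in out_i[[v]]) {
      if (!active[e]) next
      count[e] <- count[e] - 1L
      if (count[e] == 0L) {
        if (e == te)
          return(list(hit = TRUE, edges = fired, verts = queue[seq_len(qt)]))
        fired <- c(fired, e)
        for (w in heads_i[[e]]) {
          if (!reached_v[w]) {
            if (w == tv)
              return(list(hit = TRUE, edges = fired,
                          verts = queue[seq_len(qt)]))
            reached_v[w] <- TRUE
            qt <- qt + 1L
            queue[qt] <- w
          }
        }
      }
    }
  }
  list(hit = FALSE, edges = fired, verts = queue[seq_len(qt)])
}

# Integer-indexed backward-traceability sweep from a sink vertex index.
bwd_sweep_i <- function(g, ti) {
  ne <- length(g$edges)
  nv <- length(g$vertices)
  traced_v <- logical(nv)
  marked <- logical(ne)
  edges <- integer(0)
  queue <- integer(nv)
  queue[1L] <- ti
  qh <- 1L; qt <- 1L
  traced_v[ti] <- TRUE
  in_i <- g$in_i
  tails_i <- g$tails_i
  while (qh <= qt) {
    v <- queue[qh]
    qh <- qh + 1L
    for (e in in_i[[v]]) {
      if (marked[e]) next
      marked[e] <- TRUE
      edges <- c(edges, e)
      for (u in tails_i[[e]]) {
        if (!traced_v[u]) {
          traced_v[u] <- TRUE
          qt <- qt + 1L
          queue[qt] <- u
        }
      }
    }
  }
  edges
}

active_mask <- function(g, active_ids) {
  mask <- logical(length(g$edges))
  mask[match(as.character(active_ids), edge_ids(g))] <- TRUE
  mask
}

excluded_mask <- function(g, excluded_ids) {
  mask <- rep(TRUE, length(g$edges))
  mask[match(as.character(excluded_ids), edge_ids(g))] <- FALSE
  mask
}

#' Forward reachability from a source (B-connectivity)
#'
#' A vertex is forward reachable from `source` when there is a superpath
#' from `source` to it; a hyperedge is forward reachable when *all* its
#' tail vertices are. This is the B-connectivity closure: starting from
#' the source, an edge fires once its entire tail is covered, and firing
#' it covers its head. The sweep processes vertices in FIFO order and its
#' work is proportional to the size of the explored subgraph.
#'
#' @param g A [hypergraph()].
#' @param source Source vertex id.
#' @param excluded Character vector of edge ids that may not be used.
#' @return A list with `reached_vertices` and `reached_edges` (character
#'   vectors in discovery order).
#' @export
forward_reachable <- function(g, source, excluded = character()) {
  stopifnot_vertex(g, source, "source")
  stopifnot_edges(g, excluded, "excluded")
  res <- fwd_sweep_i(g, unname(g$vid[[source]]),
                     active = excluded_mask(g, excluded))
  list(reached_vertices = g$vertices[res$verts],
       reached_edges = edge_ids(g)[res$edges])
}

#' Backward traceability from a sink
#'
#' A vertex `v` is backward traceable from `sink` when `v == sink`, or
#' recursively when `v` lies in the tail of an edge some of whose head
#' vertices is backward traceable. A hyperedge is backward traceable when
#' *some* head vertex is. Traceable edges are the only ones that can feed
#' a chain of head-to-tail intersections ending at the sink.
#'
#' @param g A [hypergraph()].
#' @param sink Sink vertex id.
#' @return Character vector of backward-traceable edge ids (discovery
#'   order).
#' @export
backward_traceable <- function(g, sink) {
  stopifnot_vertex(g, sink, "sink")
  edge_ids(g)[bwd_sweep_i(g, unname(g$vid[[sink]]))]
}

#' Early-exit forward reachability test for a single hyperedge
#'
#' Runs the forward-reachability sweep restricted to the `active` edge
#' set, halting as soon as the queried edge is reached. Used heavily by
#' the greedy trimming phase of hyperpath recovery and by
#' [one_hyperpath()].
#'
#' @param g A [hypergraph()].
#' @param source Source vertex id.
#' @param edge Edge id being tested.
#' @param active Character vector of usable edge ids (must contain
#'   `edge`).
#' @return `TRUE` iff `edge` becomes forward reachable from `source`
#'   using only edges in `active`.
#' @export
is_reachable <- function(g, source, edge, active = edge_ids(g)) {
  stopifnot_vertex(g, source, "source")
  stopifnot_edges(g, c(edge, active))
  if (!(edge %in% active)) stop("edge '", edge, "' is not in the active set")
  fwd_sweep_i(g, unname(g$vid[[source]]), active = active_mask(g, active),
              te = match(edge, edge_ids(g)))$hit
}

#' Doubly-reachable restriction of a hypergraph
#'
#' The doubly-reachable edges are those both forward reachable from the
#' source and backward traceable from the sink. Every edge of every
#' source-sink hyperpath is doubly reachable, so restricting to this
#' (often dramatically smaller) subgraph preserves all solutions; the
#' shortest-hyperpath heuristic does nearly all its work here.
#'
#' @param g A [hypergraph()].
#' @param source Source vertex id.
#' @param sink Sink vertex id.
#' @return A `hypergraph` induced by the doubly-reachable edges; the
#'   source and sink vertices are always retained (the result may have no
#'   edges when the sink is unreachable).
#' @export
doubly_reachable_subgraph <- function(g, source, sink) {
  stopifnot_vertex(g, source, "source")
  stopifnot_vertex(g, sink, "sink")
  fwd <- fwd_sweep_i(g, unname(g$vid[[source]]))$edges
  bwd <- bwd_sweep_i(g, unname(g$vid[[sink]]))
  induced_subgraph(g, edge_ids(g)[intersect(fwd, bwd)],
                   keep_vertices = c(source, sink))
}
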