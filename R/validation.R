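#' Certify a source-sink superpath and produce a witness ordering
#'
#' An `s,t`-superpath is an edge subset whose hyperedges can be ordered
#' `e_1, ..., e_k` such that (i) `tail(e_1) = {s}` exactly, (ii) every
#' later edge's tail is covered by `{s}` and the heads of earlier edges,
#' and (iii) `t` lies in `head(e_k)`. The check is constructive: on
#' success the returned `TRUE` carries a `witness` attribute holding one
#' such ordering, built by greedy covered-tail peeling (lowest edge id
#' first among the available edges) with each candidate final edge tried
#' in turn.
#'
#' @param g A [hypergraph()].
#' @param edges Character vector of edge ids (a subset of the edges of
#'   `g`).
#' @param source Source vertex id.
#' @param sink Sink vertex id.
#' @return Logical scalar; when `TRUE`, attribute `witness` holds a valid
#'   ordering of `edges`.
#' @export
is_superpath <- function(g, edges, source, sink) {
  edges <- unique(as.character(edges))
  stopifnot_edges(g, edges)
  if (length(edges) == 0L) return(FALSE)
  finals <- edges[vapply(edges, function(id) sink %in% g$edges[[id]]$head,
                         logical(1))]
  for (fin in sort(finals, method = "radix")) {
    rest <- setdiff(edges, fin)
    peel <- peel_all(g, rest, source)
    if (!peel$complete) next
    if (!all(g$edges[[fin]]$tail %in% peel$covered)) next
    witness <- c(peel$order, fin)
    return(structure(TRUE, witness = witness))
  }
  FALSE
}

# Greedy B-peeling: order `edges` so each tail is covered by {source} and
# earlier heads. Peeling is confluent, so if the greedy order gets stuck
# no order exists. Lowest edge id first for determinism.
peel_all <- function(g, edges, source) {
  remaining <- sort(as.character(edges), method = "radix")
  covered <- source
  order <- character()
  while (length(remaining) > 0L) {
    ok <- vapply(remaining, function(id)
      all(g$edges[[id]]$tail %in% covered), logical(1))
    if (!any(ok))
      return(list(complete = FALSE, order = order, covered = covered))
    pick <- remaining[ok][[1L]]
    order <- c(order, pick)
    covered <- unique(c(covered, g$edges[[pick]]$head))
    remaining <- setdiff(remaining, pick)
  }
  list(complete = TRUE, order = order, covered = covered)
}

#' Certify a source-sink hyperpath (minimal superpath)
#'
#' A hyperpath is a *minimal* superpath: no proper subset of it is a
#' superpath. Because the superpath property is not monotone (adding an
#' edge whose head contains the sink can destroy condition (iii)),
#' minimality must be tested against all proper subsets, not just
#' single-edge removals. The test uses an equivalent reachability
#' characterization: an edge set is a hyperpath iff the sink is forward
#' reachable from the source using only its edges and every one of its
#' edges is necessary for that reachability. (Such a set is orderable by
#' its firing order, with the first sink-reaching edge last, and no
#' proper subset can be a superpath since superpaths keep the sink
#' reachable.)
#'
#' @inheritParams is_superpath
#' @return Logical scalar.
#' @export
is_hyperpath <- function(g, edges, source, sink) {
  edges <- unique(as.character(edges))
  stopifnot_edges(g, edges)
  if (length(edges) == 0L) return(FALSE)
  stopifnot_vertex(g, source, "source")
  stopifnot_vertex(g, sink, "sink")
  si <- unname(g$vid[[source]])
  ti <- unname(g$vid[[sink]])
  mask <- active_mask(g, edges)
  if (!fwd_sweep_i(g, si, active = mask, tv = ti)$hit) return(FALSE)
  if (source == sink) return(FALSE)  # any nonempty set has removable edges
  for (fi in which(mask)) {
    mask[fi] <- FALSE
    if (fwd_sweep_i(g, si, active = mask, tv = ti)$hit) return(FALSE)
    mask[fi] <- TRUE
  }
  TRUE
}

#' Edge-adjacency digraph of a hyperpath
#'
#' The ordinary digraph whose nodes are the hyperpath's edges, with an
#' arc `e -> f` whenever `head(e)` intersects `tail(f)` (including a
#' self-arc when an edge's own head and tail intersect). A hyperpath is
#' cyclic exactly when this digraph contains a directed cycle: a
#' topological order of an acyclic edge-adjacency digraph is a valid
#' ordering with no back-pair, while a digraph cycle forces a back-pair
#' in every linear order.
#'
#' @param g A [hypergraph()].
#' @param edges Character vector of edge ids.
#' @return An [igraph::igraph] directed graph.
#' @export
edge_adjacency_digraph <- function(g, edges) {
  edges <- unique(as.character(edges))
  stopifnot_edges(g, edges)
  from <- character(); to <- character()
  for (e in edges) for (f in edges) {
    if (length(intersect(g$edges[[e]]$head, g$edges[[f]]$tail)) > 0L) {
      from <- c(from, e); to <- c(to, f)
    }
  }
  igraph::graph_from_data_frame(data.frame(from = from, to = to,
                                           stringsAsFactors = FALSE),
                                directed = TRUE,
                                vertices = data.frame(name = edges))
}

#' Test whether a hyperpath is cyclic
#'
#' A hyperpath contains a cycle when *every* valid ordering of its edges
#' has some later edge whose head intersects the tail of an earlier edge.
#' Biologically this arises when a reaction regenerates an upstream
#' species, e.g. a complex breaking up and releasing a component. The
#' test is performed by cycle detection on the edge-adjacency digraph
#' (see [edge_adjacency_digraph()]); a self-loop edge whose head and tail
#' intersect is always cyclic.
#'
#' @param g A [hypergraph()].
#' @param edges Character vector of edge ids forming a hyperpath.
#' @return Logical scalar.
#' @export
is_cyclic <- function(g, edges) {
  edges <- unique(as.character(edges))
  stopifnot_edges(g, edges)
  if (length(edges) == 0L) return(FALSE)
  self_arc <- vapply(edges, function(id) {
    e <- g$edges[[id]]
    length(intersect(e$head, e$tail)) > 0L
  }, logical(1))
  if (any(self_arc)) return(TRUE)
  !igraph::is_dag(edge_adjacency_digraph(g, edges))
}

#' Decide cyclicity by exhaustive scan over valid orderings
#'
#' The reference (brute-force) form of the cycle criterion: a hyperpath
#' is cyclic iff no ordering satisfying the superpath conditions is free
#' of back-pairs (a later edge whose head intersects an earlier edge's
#' tail). Exponential in the number of edges; intended as an independent
#' oracle for [is_cyclic()] on small hyperpaths.
#'
#' @inheritParams is_cyclic
#' @param source Source vertex id of the hyperpath.
#' @param sink Sink vertex id of the hyperpath.
#' @return Logical scalar.
#' @export
is_cyclic_bruteforce <- function(g, edges, source, sink) {
  edges <- unique(as.character(edges))
  stopifnot(isTRUE(is_superpath(g, edges, source, sink)))
  # Search for a valid ordering with no back-pair; cyclic iff none exists.
  recurse <- function(placed, tails_so_far, covered, remaining) {
    if (length(remaining) == 0L) {
      last <- placed[[length(placed)]]
      return(sink %in% g$edges[[last]]$head)
    }
    for (id in remaining) {
      e <- g$edges[[id]]
      if (!all(e$tail %in% covered)) next
      if (length(placed) == 0L && !setequal(e$tail, source)) next
      if (length(intersect(e$head, tails_so_far)) > 0L) next  # back-pair
      if (length(intersect(e$head, e$tail)) > 0L) next        # self-arc
      if (recurse(c(placed, id), union(tails_so_far, e$tail),
                  union(covered, e$head), setdiff(remaining, id)))
        return(TRUE)
    }
    FALSE
  }
  # Condition (iii) applies to the last edge; recurse checks it at the end.
  !recurse(character(), character(), source, edges)
}

#' Enumerate all hyperpaths by exhaustive subset scan
#'
#' The independent oracle for hyperpath enumeration: scans every subset
#' of the hypergraph's edges with the ordering-based superpath test
#' [is_superpath()], then keeps the subset-minimal superpaths (those
#' containing no smaller superpath, determined by dynamic programming
#' over the subset lattice). Cost is `2^m` superpath checks, so a hard
#' cap on `m` is enforced.
#'
#' @param g A [hypergraph()].
#' @param source Source vertex id.
#' @param sink Sink vertex id.
#' @param max_edges Refuse instances with more edges than this.
#' @return A list of character vectors (edge-id sets, each sorted), in
#'   increasing subset-rank order.
#' @export
brute_force_hyperpaths <- function(g, source, sink, max_edges = 14L) {
  ids <- edge_ids(g)
  m <- length(ids)
  if (m > max_edges)
    stop("brute force cap exceeded: m = ", m, " > ", max_edges)
  if (m == 0L) return(list())
  n_sub <- bitwShiftL(1L, m)
  sp <- logical(n_sub)  # sp[mask + 1]: is the subset a superpath?
  masks_edges <- function(mask) ids[bitwAnd(bitwShiftR(mask, 0:(m - 1L)), 1L) == 1L]
  for (mask in seq_len(n_sub - 1L)) {
    sp[mask + 1L] <- isTRUE(is_superpath(g, masks_edges(mask), source, sink))
  }
  # strict_sub[mask + 1]: does some strict subset of mask hold a superpath?
  strict_sub <- logical(n_sub)
  for (mask in seq_len(n_sub - 1L)) {
    bits <- which(bitwAnd(bitwShiftR(mask, 0:(m - 1L)), 1L) == 1L)
    subs <- (mask - bitwShiftL(1L, bits - 1L)) + 1L
    strict_sub[mask + 1L] <- any(sp[subs] | strict_sub[subs])
  }
  out <- list()
  for (mask in seq_len(n_sub - 1L)) {
    if (sp[mask + 1L] && !strict_sub[mask + 1L]) {
      bits <- which(bitwAnd(bitwShiftR(mask, 0:(m - 1L)), 1L) == 1L)
      out[[length(out) + 1L]] <- sort(ids[bits], method = "radix")
    }
  }
  out
}
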