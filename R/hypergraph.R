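#' Construct a directed hyperedge
#'
#' A hyperedge is directed from a nonempty *tail* vertex set to a nonempty
#' *head* vertex set and carries a nonnegative weight. In a reaction
#' network the tail holds the reactants (and positive regulators) and the
#' head holds the products.
#'
#' @param id Character scalar, unique edge identifier within a hypergraph.
#' @param tail Character vector of tail vertex ids (nonempty; duplicates
#'   are dropped).
#' @param head Character vector of head vertex ids (nonempty; duplicates
#'   are dropped).
#' @param weight Nonnegative numeric scalar. The shortest-hyperpath
#'   problem is stated for positive weights, but zero weights are legal
#'   (the multi-source/multi-sink reductions introduce them).
#' @return An object of class `hyperedge`: a list with components `id`,
#'   `tail`, `head`, `weight`.
#' @examples
#' hyperedge("e1", c("a", "b"), "t", 1)
#' @export
hyperedge <- function(id, tail, head, weight = 1) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("edge id must be a nonempty character scalar")
  tail <- unique(as.character(tail))
  head <- unique(as.character(head))
  if (length(tail) == 0L) stop("edge '", id, "': tail must be nonempty")
  if (length(head) == 0L) stop("edge '", id, "': head must be nonempty")
  if (any(!nzchar(tail)) || any(!nzchar(head)))
    stop("edge '", id, "': vertex ids must be nonempty strings")
  weight <- as.numeric(weight)
  if (length(weight) != 1L || is.na(weight) || weight < 0)
    stop("edge '", id, "': weight must be a nonnegative number")
  structure(list(id = id, tail = tail, head = head, weight = weight),
            class = "hyperedge")
}

#' Construct a directed hypergraph
#'
#' A directed hypergraph is a vertex set plus a set of directed
#' hyperedges. Incidence indices are built on construction: `in_index`
#' maps a vertex to the edges whose head contains it (its in-edges) and
#' `out_index` maps a vertex to the edges whose tail contains it (its
#' out-edges).
#'
#' @param edges List of [hyperedge()] objects (possibly empty).
#' @param vertices Optional character vector of extra vertex ids; vertices
#'   named in any tail or head are always included.
#' @return An object of class `hypergraph`: a list with components
#'   `vertices` (character), `edges` (named list of hyperedges, keyed and
#'   sorted by id), `in_index` and `out_index` (named lists of character
#'   vectors of edge ids).
#' @examples
#' g <- hypergraph(list(
#'   hyperedge("e1", "s", "a"), hyperedge("e2", "s", "b"),
#'   hyperedge("e3", c("a", "b"), "t")))
#' size_params(g)
#' @export
hypergraph <- function(edges = list(), vertices = character()) {
  if (inherits(edges, "hyperedge")) edges <- list(edges)
  ids <- vapply(edges, function(e) e$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate edge id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(edges) <- ids
  edges <- edges[order(ids, method = "radix")]
  verts <- unique(c(as.character(vertices),
                    unlist(lapply(edges, function(e) c(e$tail, e$head)),
                           use.names = FALSE)))
  verts <- sort(verts, method = "radix")
  g <- structure(list(vertices = verts, edges = edges,
                      in_index = NULL, out_index = NULL),
                 class = "hypergraph")
  rebuild_indices(g)
}

# Recompute incidence indices from the edge list (idempotent). Besides
# the user-facing character indices, integer-indexed incidence structures
# are precomputed so the reachability sweeps (the innermost loops of
# every algorithm here) run on plain integer vectors.
rebuild_indices <- function(g) {
  nv <- length(g$vertices)
  ne <- length(g$edges)
  vid <- stats::setNames(seq_len(nv), g$vertices)
  inx <- stats::setNames(vector("list", nv), g$vertices)
  outx <- inx
  in_i <- vector("list", nv)
  out_i <- vector("list", nv)
  tails_i <- vector("list", ne)
  heads_i <- vector("list", ne)
  for (j in seq_len(ne)) {
    e <- g$edges[[j]]
    ti <- unname(vid[e$tail])
    hi <- unname(vid[e$head])
    tails_i[[j]] <- ti
    heads_i[[j]] <- hi
    for (v in e$tail) outx[[v]] <- c(outx[[v]], e$id)
    for (v in e$head) inx[[v]] <- c(inx[[v]], e$id)
    for (v in ti) out_i[[v]] <- c(out_i[[v]], j)
    for (v in hi) in_i[[v]] <- c(in_i[[v]], j)
  }
  g$in_index <- lapply(inx, function(x) if (is.null(x)) character() else x)
  g$out_index <- lapply(outx, function(x) if (is.null(x)) character() else x)
  g$vid <- vid
  g$tails_i <- tails_i
  g$heads_i <- heads_i
  g$in_i <- lapply(in_i, function(x) if (is.null(x)) integer() else x)
  g$out_i <- lapply(out_i, function(x) if (is.null(x)) integer() else x)
  g$tail_sizes <- vapply(tails_i, length, integer(1))
  g
}

#' @export
print.hypergraph <- function(x, ...) {
  sp <- size_params(x)
  cat(sprintf("Directed hypergraph: %d vertices, %d hyperedges (size %d, degree %d)\n",
              sp$n, sp$m, sp$ell, sp$d))
  invisible(x)
}

#' @export
print.hyperedge <- function(x, ...) {
  cat(sprintf("%s: {%s} -> {%s}  w=%g\n", x$id,
              paste(x$tail, collapse = ","),
              paste(x$head, collapse = ","), x$weight))
  invisible(x)
}

edge_ids <- function(g) names(g$edges)

in_edges <- function(g, v) g$in_index[[v]]

out_edges <- function(g, v) g$out_index[[v]]

stopifnot_vertex <- function(g, v, what = "vertex") {
  if (!is.character(v) || length(v) != 1L || !(v %in% g$vertices))
    stop(what, " '", v, "' is not a vertex of the hypergraph")
  invisible(v)
}

stopifnot_edges <- function(g, ids, what = "edge set") {
  bad <- setdiff(ids, edge_ids(g))
  if (length(bad) > 0L)
    stop(what, " contains unknown edge id(s): ", paste(bad, collapse = ", "))
  invisible(ids)
}

#' Subgraph induced by a set of hyperedges
#'
#' Restricts a hypergraph to a subset of its hyperedges. The vertex set of
#' the result is the union of the retained tails and heads plus any
#' vertices in `keep_vertices`.
#'
#' @param g A [hypergraph()].
#' @param ids Character vector of edge ids to retain.
#' @param keep_vertices Character vector of vertex ids always retained
#'   (e.g. the source and sink, which must survive even if isolated).
#' @return A `hypergraph`.
#' @export
induced_subgraph <- function(g, ids, keep_vertices = character()) {
  stopifnot_edges(g, ids)
  hypergraph(unname(g$edges[as.character(ids)]),
             vertices = intersect(keep_vertices, g$vertices))
}

#' Hypergraph size and degree parameters
#'
#' Returns the standard size measures of a directed hypergraph: the
#' number of vertices `n`, the number of hyperedges `m`, the size
#' parameter `ell` (the total cardinality of all tail and head sets,
#' which is proportional to the space needed to store the hypergraph),
#' and the degree parameter `d` (the maximum over vertices of the larger
#' of in-degree and out-degree).
#'
#' @param g A [hypergraph()].
#' @return A list with integer components `n`, `m`, `ell`, `d`.
#' @examples
#' size_params(hypergraph(list(hyperedge("e1", "s", "t"))))
#' @export
size_params <- function(g) {
  n <- length(g$vertices)
  m <- length(g$edges)
  ell <- sum(vapply(g$edges, function(e) length(e$tail) + length(e$head),
                    numeric(1)))
  d <- if (n == 0L) 0L else max(0L, vapply(g$vertices, function(v)
    max(length(g$in_index[[v]]), length(g$out_index[[v]])), integer(1)))
  list(n = as.integer(n), m = as.integer(m), ell = as.integer(ell),
       d = as.integer(d))
}

#' Self-loop statistics
#'
#' A hyperedge `e` is a self-loop at vertex `v` when `v` lies in both its
#' tail and its head (the reaction regenerates one of its own inputs). A
#' self-loop is *unreachable* when the looping vertex has no other
#' in-edge, so the edge can never fire unless the vertex is supplied
#' externally; such vertices are treated as sources by
#' [prepare_instance()].
#'
#' @param g A [hypergraph()].
#' @return A list with `self_loops` (edge ids with nonempty tail-head
#'   intersection) and `unreachable_self_loops` (self-loops at a vertex
#'   whose only in-edge is the loop itself).
#' @export
self_loop_stats <- function(g) {
  loops <- names(Filter(function(e) length(intersect(e$tail, e$head)) > 0L,
                        g$edges))
  if (is.null(loops)) loops <- character()
  unreach <- vapply(loops, function(id) {
    e <- g$edges[[id]]
    any(vapply(intersect(e$tail, e$head), function(v)
      identical(g$in_index[[v]], id), logical(1)))
  }, logical(1))
  list(self_loops = loops,
       unreachable_self_loops = loops[unreach])
}
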