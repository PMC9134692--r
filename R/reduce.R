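SUPERSOURCE_ID <- "__SRC__"
SUPERSINK_ID <- "__SNK__"

#' Reduce a multi-source / multi-sink problem to single source and sink
#'
#' Shortest hyperpaths with one source and one sink also capture the
#' multi-source and multi-sink versions of the problem. A fresh
#' supersource `__SRC__` is wired to all sources by a single zero-weight
#' hyperedge `({__SRC__}, sources)`. For the sink side, `sink_mode =
#' "all"` (a hyperpath must reach *every* sink) adds one zero-weight edge
#' `(sinks, {__SNK__})`, while `sink_mode = "any"` (a hyperpath must
#' reach *some* sink) adds one zero-weight edge `({v}, {__SNK__})` per
#' sink `v`. An `__SRC__,__SNK__`-hyperpath in the result corresponds to
#' a solution of the multi-source/multi-sink problem on `g`.
#'
#' @param g A [hypergraph()].
#' @param sources Nonempty character vector of source vertex ids.
#' @param sinks Nonempty character vector of sink vertex ids.
#' @param sink_mode `"all"` or `"any"` (see above).
#' @return A list with components `graph` (the augmented hypergraph),
#'   `source` (`"__SRC__"`) and `sink` (`"__SNK__"`).
#' @export
reduce_sources_sinks <- function(g, sources, sinks,
                                 sink_mode = c("all", "any")) {
  sink_mode <- match.arg(sink_mode)
  sources <- unique(as.character(sources))
  sinks <- unique(as.character(sinks))
  if (length(sources) == 0L) stop("sources must be nonempty")
  if (length(sinks) == 0L) stop("sinks must be nonempty")
  lapply(sources, stopifnot_vertex, g = g, what = "source")
  lapply(sinks, stopifnot_vertex, g = g, what = "sink")
  if (any(c(SUPERSOURCE_ID, SUPERSINK_ID) %in% g$vertices))
    stop("reserved vertex id '", SUPERSOURCE_ID, "' or '", SUPERSINK_ID,
         "' already present in the hypergraph")
  new_edges <- list(hyperedge(src_edge_id(g), SUPERSOURCE_ID, sources, 0))
  if (sink_mode == "all") {
    new_edges <- c(new_edges,
                   list(hyperedge(snk_edge_id(g, 1L), sinks, SUPERSINK_ID, 0)))
  } else {
    for (i in seq_along(sinks))
      new_edges <- c(new_edges,
                     list(hyperedge(snk_edge_id(g, i), sinks[[i]],
                                    SUPERSINK_ID, 0)))
  }
  list(graph = hypergraph(c(unname(g$edges), new_edges),
                          vertices = g$vertices),
       source = SUPERSOURCE_ID, sink = SUPERSINK_ID)
}

src_edge_id <- function(g) fresh_id(g, "__e_src__")

snk_edge_id <- function(g, i) fresh_id(g, sprintf("__e_snk%d__", i))

fresh_id <- function(g, base) {
  if (!(base %in% edge_ids(g))) return(base)
  stop("reserved edge id '", base, "' already present in the hypergraph")
}

#' Prepare a single-target instance with a supersource
#'
#' Mirrors the standard experimental convention for pathway hypergraphs:
#' the *source* vertices are those with no in-edges, plus vertices whose
#' every in-edge is a self-loop (which could otherwise never fire). A
#' fresh supersource `__SRC__` is wired to all of them by one zero-weight
#' hyperedge, and the chosen target is wired to a fresh sink `__SNK__` by
#' one zero-weight edge `({target}, {__SNK__})`.
#'
#' Targets are conventionally vertices with no out-edges; a target that
#' does have out-edges is allowed when `allow_target_out_edges = TRUE`
#' (cyclic instances of biological interest can involve such targets).
#'
#' @param g A [hypergraph()].
#' @param target Vertex id of the target.
#' @param allow_target_out_edges Permit a target that has out-edges.
#' @return A list with components `graph`, `source` (`"__SRC__"`),
#'   `sink` (`"__SNK__"`), and `sources` (the identified source vertices
#'   of `g`).
#' @export
prepare_instance <- function(g, target, allow_target_out_edges = FALSE) {
  stopifnot_vertex(g, target, "target")
  if (length(out_edges(g, target)) > 0L && !allow_target_out_edges)
    stop("target '", target, "' has out-edges; pass ",
         "allow_target_out_edges = TRUE to use it anyway")
  is_src <- vapply(g$vertices, function(v) {
    ine <- g$in_index[[v]]
    length(ine) == 0L ||
      all(vapply(ine, function(id) v %in% g$edges[[id]]$tail, logical(1)))
  }, logical(1))
  sources <- g$vertices[is_src]
  if (length(sources) == 0L)
    stop("no source vertices: every vertex has a non-self-loop in-edge")
  red <- reduce_sources_sinks(g, sources, target, sink_mode = "any")
  red$sources <- sources
  red
}
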