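# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specification for a random hypergraph
#'
#' Collects and validates the parameters of the synthetic hypergraph
#' generator. The defaults mimic the sparsity of curated pathway
#' hypergraphs: small tail sets (sizes 1-3, mean about 2), smaller head
#' sets (sizes 1-2, mean about 1.3), and fewer hyperedges than vertices.
#' A fraction `p_source_edge` of edges get tail exactly `{s}`, emulating
#' the supersource wiring of prepared instances (without it, a randomly
#' tailed sparse hypergraph almost never has a startable edge). Identical
#' specifications produce identical hypergraphs.
#'
#' @param n Number of vertices (>= 2; includes the designated source and
#'   sink).
#' @param m Number of hyperedges.
#' @param tail_sizes Integer vector of admissible tail-set sizes.
#' @param head_sizes Integer vector of admissible head-set sizes.
#' @param weight_range Length-2 nonnegative numeric: edge weights are
#'   drawn uniformly from this interval.
#' @param singleton_tail Force every tail to a single vertex (the class
#'   on which the heuristic is provably optimal).
#' @param p_source_edge Probability that an edge's tail is exactly the
#'   source vertex.
#' @param self_loop_rate Probability that an edge is forced to contain
#'   one of its tail vertices in its head (a self-loop).
#' @param seed Integer RNG seed.
#' @return A validated list of class `gen_spec`.
#' @export
gen_spec <- function(n = 12, m = 10, tail_sizes = 1:3, head_sizes = 1:2,
                     weight_range = c(0, 10), singleton_tail = FALSE,
                     p_source_edge = 0.25, self_loop_rate = 0,
                     seed = 1L) {
  n <- as.integer(n); m <- as.integer(m)
  stopifnot(n >= 2L, m >= 0L,
            length(tail_sizes) >= 1L, all(tail_sizes >= 1L),
            length(head_sizes) >= 1L, all(head_sizes >= 1L),
            length(weight_range) == 2L, all(weight_range >= 0),
            weight_range[1] <= weight_range[2],
            p_source_edge >= 0, p_source_edge <= 1,
            self_loop_rate >= 0, self_loop_rate <= 1)
  if (singleton_tail) tail_sizes <- 1L
  if (max(tail_sizes) > n - 1L || max(head_sizes) > n - 1L)
    stop("tail/head sizes must be smaller than the vertex count")
  structure(list(n = n, m = m, tail_sizes = as.integer(tail_sizes),
                 head_sizes = as.integer(head_sizes),
                 weight_range = as.numeric(weight_range),
                 singleton_tail = isTRUE(singleton_tail),
                 p_source_edge = p_source_edge,
                 self_loop_rate = self_loop_rate,
                 seed = as.integer(seed)),
            class = "gen_spec")
}

#' Generate a seeded random hypergraph instance
#'
#' Draws `m` hyperedges over `n` vertices according to a [gen_spec()]:
#' tails and heads are uniform samples of the admissible sizes (heads are
#' drawn disjoint from the tail unless a self-loop is injected), weights
#' are uniform on `weight_range`, and the first and last vertices are
#' designated source and sink. Reproducible: the same spec always yields
#' the same instance, and the caller's RNG state is left untouched.
#'
#' @param spec A [gen_spec()].
#' @return A list with components `graph` (a [hypergraph()]), `source`,
#'   `sink`, and `reachable` (`TRUE` iff the sink is forward reachable
#'   from the source).
#' @export
random_hypergraph <- function(spec = gen_spec()) {
  stopifnot(inherits(spec, "gen_spec"))
  verts <- sprintf("v%02d", seq_len(spec$n))
  s <- verts[[1L]]
  t <- verts[[spec$n]]
  g <- with_seed(spec$seed, {
    edges <- vector("list", spec$m)
    for (i in seq_len(spec$m)) {
      if (stats::runif(1) < spec$p_source_edge) {
        tail <- s
      } else {
        ts <- sample_one(spec$tail_sizes)
        tail <- sample(setdiff(verts, t), ts)
      }
      hs <- sample_one(spec$head_sizes)
      pool <- setdiff(verts, tail)
      hs <- min(hs, length(pool))
      head <- sample(pool, hs)
      if (spec$self_loop_rate > 0 && stats::runif(1) < spec$self_loop_rate)
        head <- unique(c(head[-1L], sample_one(tail)))
      w <- stats::runif(1, spec$weight_range[1], spec$weight_range[2])
      edges[[i]] <- hyperedge(sprintf("e%03d", i), tail, head, w)
    }
    hypergraph(edges, vertices = verts)
  })
  reach <- forward_reachable(g, s)$reached_vertices
  list(graph = g, source = s, sink = t, reachable = t %in% reach)
}

sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Gadget whose only source-sink hyperpath is cyclic
#'
#' A five-vertex, three-edge hypergraph with unit weights:
#' `e1 = ({s},{a,b})`, `e2 = ({a,b},{c})`, `e3 = ({c},{b,t})`. Its unique
#' `s,t`-hyperpath is all three edges, and it is cyclic (`head(e3)`
#' regenerates `b`, which `e2` consumes), so any solver restricted to
#' acyclic orderings finds nothing here while the heuristic recovers the
#' optimum.
#'
#' @return A list with `graph`, `source`, `sink`.
#' @export
cyclic_only_gadget <- function() {
  g <- hypergraph(list(
    hyperedge("e1", "s", c("a", "b")),
    hyperedge("e2", c("a", "b"), "c"),
    hyperedge("e3", "c", c("b", "t"))))
  list(graph = g, source = "s", sink = "t")
}

#' Fixed micro-instances used throughout the package
#'
#' A named collection of tiny hypergraphs with known solutions:
#' \describe{
#'   \item{chain}{`({s},{a}), ({a},{t})` — a unique 2-edge hyperpath of
#'     weight 2.}
#'   \item{and_gadget}{`({s},{a}), ({s},{b}), ({a,b},{t})` — the sink
#'     edge needs both branches; the unique hyperpath has all 3 edges.}
#'   \item{cyclic}{the [cyclic_only_gadget()].}
#'   \item{two_route}{`e1=({s},{a}) w1, e2=({s},{b}) w5, e3=({a},{t}) w1,
#'     e4=({b},{t}) w1` — exactly two hyperpaths, weights 2 and 6.}
#'   \item{trim}{`e1=({s},{a,b}) w1, e2=({a},{t}) w1, e3=({b},{t}) w10` —
#'     exercises greedy trimming: the recovered superpath must drop the
#'     heavy branch.}
#' }
#'
#' @return A named list; each element has `graph`, `source`, `sink`.
#' @export
worked_examples <- function() {
  mk <- function(g) list(graph = g, source = "s", sink = "t")
  list(
    chain = mk(hypergraph(list(
      hyperedge("e1", "s", "a"),
      hyperedge("e2", "a", "t")))),
    and_gadget = mk(hypergraph(list(
      hyperedge("e1", "s", "a"),
      hyperedge("e2", "s", "b"),
      hyperedge("e3", c("a", "b"), "t")))),
    cyclic = cyclic_only_gadget(),
    two_route = mk(hypergraph(list(
      hyperedge("e1", "s", "a", 1),
      hyperedge("e2", "s", "b", 5),
      hyperedge("e3", "a", "t", 1),
      hyperedge("e4", "b", "t", 1)))),
    trim = mk(hypergraph(list(
      hyperedge("e1", "s", c("a", "b"), 1),
      hyperedge("e2", "a", "t", 1),
      hyperedge("e3", "b", "t", 10)))))
}
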