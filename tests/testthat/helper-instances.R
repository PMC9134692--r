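# Shared helpers for the test suite. All fixtures are generated in code.

path_key <- function(edges) paste(sort(edges, method = "radix"),
                                  collapse = "+")

path_keys <- function(paths) {
  sort(vapply(paths, function(p) {
    if (is.character(p)) path_key(p) else path_key(p$edges)
  }, character(1)))
}

# The study matrix of random general hypergraphs: mixed tail/head sizes
# 1-3, pathway-like sparsity (fewer edges than vertices, with a few denser
# settings), deterministic seeds.
general_matrix <- function(n_instances, seed_base = 40000L) {
  lapply(seq_len(n_instances), function(i) {
    gen_spec(n = 5L + (i %% 8L), m = 4L + (i %% 7L),
             tail_sizes = 1:3, head_sizes = 1:3,
             weight_range = c(0, 10),
             self_loop_rate = if (i %% 5L == 0L) 0.2 else 0,
             seed = seed_base + i)
  })
}

# The singleton-tail study matrix: n up to 30 vertices, edge counts at
# the sparsity of curated pathway hypergraphs (m < n).
singleton_matrix <- function(n_instances, seed_base = 20000L) {
  ratios <- c(0.55, 0.65, 0.8, 0.95)
  lapply(seq_len(n_instances), function(i) {
    n <- 5L + (i %% 26L)
    gen_spec(n = n, m = min(60L, max(3L, round(ratios[1L + (i %% 4L)] * n))),
             singleton_tail = TRUE, head_sizes = 1:2,
             weight_range = c(0, 10), seed = seed_base + i)
  })
}

# Naive forward-reachability oracle: add any edge whose tail is covered
# until stabilization. Independent of the package's FIFO sweep.
naive_forward_oracle <- function(g, source, excluded = character()) {
  ids <- setdiff(names(g$edges), excluded)
  covered <- source
  fired <- character()
  repeat {
    added <- FALSE
    for (id in ids) {
      if (id %in% fired) next
      if (all(g$edges[[id]]$tail %in% covered)) {
        fired <- c(fired, id)
        covered <- unique(c(covered, g$edges[[id]]$head))
        added <- TRUE
      }
    }
    if (!added) break
  }
  list(vertices = covered, edges = fired)
}

run_cli <- function(args) {
  out <- character()
  status <- NULL
  msgs <- capture.output(
    out <- capture.output(status <- hyperpath_cli(args)),
    type = "message")
  list(status = status, stdout = out, stderr = msgs)
}
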