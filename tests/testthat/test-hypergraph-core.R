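test_that("constructors enforce hyperedge and hypergraph invariants", {
  expect_error(hyperedge("e1", character(), "a"), "tail must be nonempty")
  expect_error(hyperedge("e1", "a", character()), "head must be nonempty")
  expect_error(hyperedge("e1", "a", "b", -1), "nonnegative")
  expect_error(hypergraph(list(hyperedge("e1", "a", "b"),
                               hyperedge("e1", "b", "c"))),
               "duplicate edge id")
  # zero weights are legal: the reductions rely on them
  expect_silent(hyperedge("e0", "a", "b", 0))
})

test_that("incidence indices agree exactly with edge tail/head sets", {
  specs <- general_matrix(10)
  for (sp in specs) {
    g <- random_hypergraph(sp)$graph
    for (e in g$edges) {
      for (v in e$tail) expect_true(e$id %in% g$out_index[[v]])
      for (v in e$head) expect_true(e$id %in% g$in_index[[v]])
    }
    for (v in g$vertices) {
      for (id in g$out_index[[v]]) expect_true(v %in% g$edges[[id]]$tail)
      for (id in g$in_index[[v]]) expect_true(v %in% g$edges[[id]]$head)
    }
  }
})

test_that("size parameters follow the n, m, ell, d formulas", {
  ex <- worked_examples()$and_gadget
  sp <- size_params(ex$graph)
  expect_equal(sp$n, 4L)
  expect_equal(sp$m, 3L)
  expect_equal(sp$ell, 7L)  # (1+1) + (1+1) + (2+1)
  expect_equal(sp$d, 2L)    # out(s) = {e1, e2}
  expect_equal(size_params(hypergraph()),
               list(n = 0L, m = 0L, ell = 0L, d = 0L))
  single <- hypergraph(list(hyperedge("e1", "s", "t")))
  expect_equal(size_params(single), list(n = 2L, m = 1L, ell = 2L, d = 1L))
})

test_that("HGR-TSV round trips, sorts deterministically, and rejects bad input", {
  g <- hypergraph(list(hyperedge("e2", "a", "t", 1),
                       hyperedge("e1", c("s", "b"), "a", 0.5)))
  f1 <- withr::local_tempfile(fileext = ".hgr")
  f2 <- withr::local_tempfile(fileext = ".hgr")
  write_hgr(g, f1)
  lines <- readLines(f1)
  expect_equal(lines[[1]], "# hgr v1")
  expect_true(grepl("^e1\t", lines[[2]]))  # edges sorted by id
  g2 <- read_hgr(f1)
  expect_equal(names(g2$edges), names(g$edges))
  expect_equal(g2$edges$e1$tail, sort(g$edges$e1$tail))
  expect_equal(g2$edges$e2$weight, 1)
  write_hgr(g2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  bad <- withr::local_tempfile(fileext = ".hgr")
  writeLines("e1\ts\t\t1.0", bad)
  expect_error(read_hgr(bad), "empty head")
  writeLines(c("e1\ts\ta\t1.0", "e1\ta\tb\t1.0"), bad)
  expect_error(read_hgr(bad), "duplicate edge id")
  writeLines("e1\ts\ta\t-2", bad)
  expect_error(read_hgr(bad), "negative weight")
  writeLines("e1\ts\ta", bad)
  expect_error(read_hgr(bad), "4 tab-separated fields")

  # header-only output for an edgeless hypergraph
  write_hgr(hypergraph(), f1)
  expect_equal(readLines(f1), "# hgr v1")
})

test_that("ell equals the count of set members written to file", {
  for (sp in general_matrix(6)) {
    g <- random_hypergraph(sp)$graph
    f <- withr::local_tempfile(fileext = ".hgr")
    write_hgr(g, f)
    lines <- grep("^#", readLines(f), value = TRUE, invert = TRUE)
    members <- sum(vapply(strsplit(lines, "\t"), function(p) {
      length(strsplit(p[[2]], ",")[[1]]) + length(strsplit(p[[3]], ",")[[1]])
    }, numeric(1)))
    expect_equal(members, size_params(g)$ell)
  }
})

test_that("multi-source/sink reduction wires zero-weight edges as specified", {
  g <- hypergraph(list(hyperedge("e1", "a", "x"),
                       hyperedge("e2", c("x", "b"), "t")),
                  vertices = c("y"))
  red <- reduce_sources_sinks(g, sources = c("a", "b"), sinks = "t",
                              sink_mode = "all")
  expect_equal(red$source, "__SRC__")
  expect_equal(red$sink, "__SNK__")
  src_e <- Filter(function(e) "__SRC__" %in% e$tail, red$graph$edges)
  expect_length(src_e, 1L)
  expect_setequal(src_e[[1]]$head, c("a", "b"))
  expect_equal(src_e[[1]]$weight, 0)
  snk_e <- Filter(function(e) "__SNK__" %in% e$head, red$graph$edges)
  expect_length(snk_e, 1L)
  expect_setequal(snk_e[[1]]$tail, "t")

  red2 <- reduce_sources_sinks(g, sources = "a", sinks = c("x", "t"),
                               sink_mode = "any")
  snk_e2 <- Filter(function(e) "__SNK__" %in% e$head, red2$graph$edges)
  expect_length(snk_e2, 2L)
  expect_setequal(unlist(lapply(snk_e2, function(e) e$tail)), c("x", "t"))
  expect_true(all(vapply(snk_e2, function(e) e$weight, 0) == 0))

  expect_error(reduce_sources_sinks(g, character(), "t"), "nonempty")
  gg <- hypergraph(list(hyperedge("e1", "__SRC__", "x")))
  expect_error(reduce_sources_sinks(gg, "__SRC__", "x"), "reserved")
})

test_that("source equal to sink reduces to a zero-weight two-edge hyperpath", {
  g <- hypergraph(list(hyperedge("e1", "a", "b", 2)))
  red <- reduce_sources_sinks(g, "a", "a", sink_mode = "all")
  p <- shortest_by_enumeration(red$graph, red$source, red$sink)
  expect_equal(p$weight, 0)
  expect_length(p$edges, 2L)
  # confirmed against the exhaustive subset oracle
  bf <- brute_force_hyperpaths(red$graph, red$source, red$sink)
  expect_equal(path_keys(bf), path_keys(list(p)))
})

test_that("reduction preserves optimal weight against a multi-source oracle", {
  # Oracle: brute force over subsets of the *original* edges, feasibility
  # by firing closure seeded with the whole source set.
  multi_opt <- function(g, sources, sinks, mode) {
    ids <- names(g$edges)
    best <- Inf
    for (mask in seq_len(2^length(ids)) - 1L) {
      sel <- ids[bitwAnd(bitwShiftR(mask, seq_along(ids) - 1L), 1L) == 1L]
      covered <- sources
      fired <- character()
      repeat {
        new <- setdiff(sel[vapply(sel, function(id)
          all(g$edges[[id]]$tail %in% covered), logical(1))], fired)
        if (length(new) == 0L) break
        fired <- c(fired, new)
        covered <- unique(c(covered,
                            unlist(lapply(g$edges[new], `[[`, "head"))))
      }
      feas <- if (mode == "all") all(sinks %in% covered)
              else any(sinks %in% covered)
      if (feas) {
        w <- sum(vapply(g$edges[sel], function(e) e$weight, 0))
        best <- min(best, w)
      }
    }
    best
  }
  for (i in 1:8) {
    inst <- random_hypergraph(gen_spec(n = 6, m = 6, seed = 700 + i))
    g <- inst$graph
    sources <- g$vertices[1:2]
    sinks <- g$vertices[c(length(g$vertices) - 1L, length(g$vertices))]
    for (mode in c("all", "any")) {
      red <- reduce_sources_sinks(g, sources, sinks, sink_mode = mode)
      p <- shortest_by_enumeration(red$graph, red$source, red$sink)
      opt <- multi_opt(g, sources, sinks, mode)
      if (is_empty_path(p)) expect_identical(opt, Inf)
      else expect_equal(p$weight, opt)
    }
  }
})

test_that("prepare_instance identifies sources including self-loop-only vertices", {
  chain <- worked_examples()$chain
  prep <- prepare_instance(chain$graph, "t")
  expect_length(prep$graph$edges, 4L)  # m + 2
  src_e <- Filter(function(e) "__SRC__" %in% e$tail, prep$graph$edges)
  expect_setequal(src_e[[1]]$head, "s")

  # b's only in-edge is a self-loop ({b,c},{b,d}): b counts as a source
  g <- hypergraph(list(hyperedge("e1", c("b", "c"), c("b", "d")),
                       hyperedge("e2", "d", "z")))
  prep2 <- prepare_instance(g, "z")
  src_e2 <- Filter(function(e) "__SRC__" %in% e$tail, prep2$graph$edges)
  expect_true("b" %in% src_e2[[1]]$head)
  expect_true("c" %in% src_e2[[1]]$head)  # no in-edges at all

  # every vertex has a non-self-loop in-edge: no sources exist
  ring <- hypergraph(list(hyperedge("e1", "a", "b"),
                          hyperedge("e2", "b", "a")))
  expect_error(prepare_instance(ring, "a", allow_target_out_edges = TRUE),
               "no source vertices")
  expect_error(prepare_instance(ring, "a"), "out-edges")
})

test_that("self-loop statistics distinguish unreachable self-loops", {
  g <- hypergraph(list(
    hyperedge("e1", c("a", "b"), c("b", "c")),  # self-loop at b, b has no other in-edge
    hyperedge("e2", "c", c("c", "d")),          # self-loop at c, but e1 also feeds c
    hyperedge("e3", "d", "z")))
  sl <- self_loop_stats(g)
  expect_setequal(sl$self_loops, c("e1", "e2"))
  expect_equal(sl$unreachable_self_loops, "e1")
})
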