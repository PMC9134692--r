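ex <- worked_examples()

test_that("heuristic solves the worked micro-instances", {
  p <- shortest_hyperpath(ex$chain$graph, "s", "t")
  expect_equal(p$edges, c("e1", "e2"))
  expect_equal(p$weight, 2)
  expect_false(p$cyclic)

  p2 <- shortest_hyperpath(ex$and_gadget$graph, "s", "t")
  expect_setequal(p2$edges, c("e1", "e2", "e3"))
  expect_equal(p2$weight, 3)

  p3 <- shortest_hyperpath(ex$cyclic$graph, "s", "t")
  expect_setequal(p3$edges, c("e1", "e2", "e3"))
  expect_equal(p3$weight, 3)
  expect_true(p3$cyclic)

  p4 <- shortest_hyperpath(ex$two_route$graph, "s", "t")
  expect_setequal(p4$edges, c("e1", "e3"))
  expect_equal(p4$weight, 2)

  # greedy trimming must drop the heavy branch of the trim gadget
  p5 <- shortest_hyperpath(ex$trim$graph, "s", "t")
  expect_setequal(p5$edges, c("e1", "e2"))
  expect_equal(p5$weight, 2)

  unreach <- hypergraph(list(hyperedge("e1", "a", "b")),
                        vertices = c("s", "t"))
  expect_true(is_empty_path(shortest_hyperpath(unreach, "s", "t")))
  expect_error(shortest_hyperpath(ex$chain$graph, "nope", "t"), "not a vertex")
})

test_that("hyperpath recovery traces in-edge lists and trims by length", {
  g <- ex$trim$graph  # e1=({s},{a,b}) w1, e2=({a},{t}) w1, e3=({b},{t}) w10
  # state as it stands when the sink in-edges are re-recovered at the end
  state <- list(
    e1 = list(length = 1, inedges = character()),
    e2 = list(length = 2, inedges = "e1"),
    e3 = list(length = 11, inedges = "e1"))
  # recovering for e2: superpath {e1,e2}, nothing trimmable
  p2 <- recover_short_hyperpath(g, "s", "e2", state)
  expect_equal(p2$edges, c("e1", "e2"))
  expect_equal(p2$weight, 2)

  # seed edge: phase I yields the edge alone
  p1 <- recover_short_hyperpath(g, "s", "e1", list(
    e1 = list(length = NA_real_, inedges = character())))
  expect_equal(p1$edges, "e1")
  expect_equal(p1$weight, 1)

  # AND gadget: neither branch is removable
  g2 <- ex$and_gadget$graph
  st2 <- list(e1 = list(length = 1, inedges = character()),
              e2 = list(length = 1, inedges = character()),
              e3 = list(length = 3, inedges = c("e1", "e2")))
  p3 <- recover_short_hyperpath(g2, "s", "e3", st2)
  expect_setequal(p3$edges, c("e1", "e2", "e3"))
  expect_equal(p3$weight, 3)

  # violated precondition is a hard failure, not a silent empty result
  st_bad <- list(e3 = list(length = NA_real_, inedges = character()))
  expect_error(recover_short_hyperpath(g2, "s", "e3", st_bad),
               "not an s,e-superpath")
})

test_that("heuristic output is feasible exactly when the sink is reachable", {
  n_checked <- 0L
  for (sp in general_matrix(60)) {
    inst <- random_hypergraph(sp)
    p <- shortest_hyperpath(inst$graph, inst$source, inst$sink)
    expect_identical(!is_empty_path(p), inst$reachable)
    if (!is_empty_path(p)) {
      n_checked <- n_checked + 1L
      expect_true(is_hyperpath(inst$graph, p$edges, inst$source, inst$sink))
      sp_ok <- is_superpath(inst$graph, p$edges, inst$source, inst$sink)
      expect_true(isTRUE(sp_ok))
    }
  }
  expect_gt(n_checked, 10L)
})

test_that("witness orderings satisfy the superpath conditions position by position", {
  for (sp in general_matrix(20)) {
    inst <- random_hypergraph(sp)
    p <- shortest_hyperpath(inst$graph, inst$source, inst$sink)
    if (is_empty_path(p)) next
    g <- inst$graph
    covered <- inst$source
    for (i in seq_along(p$edges)) {
      e <- g$edges[[p$edges[[i]]]]
      if (i == 1L) expect_setequal(e$tail, inst$source)
      expect_true(all(e$tail %in% covered))
      covered <- union(covered, e$head)
    }
    expect_true(inst$sink %in%
                  g$edges[[p$edges[[length(p$edges)]]]]$head)
  }
})

test_that("restricting to the doubly-reachable subgraph leaves the result unchanged", {
  for (sp in general_matrix(20)) {
    inst <- random_hypergraph(sp)
    if (!inst$reachable) next
    p <- shortest_hyperpath(inst$graph, inst$source, inst$sink)
    d <- doubly_reachable_subgraph(inst$graph, inst$source, inst$sink)
    pd <- shortest_hyperpath(d, inst$source, inst$sink)
    expect_equal(pd$weight, p$weight)
  }
})

test_that("the heuristic is deterministic and equivariant under weight scaling", {
  for (sp in general_matrix(10)) {
    inst <- random_hypergraph(sp)
    if (!inst$reachable) next
    p1 <- shortest_hyperpath(inst$graph, inst$source, inst$sink)
    p2 <- shortest_hyperpath(inst$graph, inst$source, inst$sink)
    expect_identical(p1, p2)
    scaled <- hypergraph(lapply(unname(inst$graph$edges), function(e)
      hyperedge(e$id, e$tail, e$head, e$weight * 3)),
      vertices = inst$graph$vertices)
    p3 <- shortest_hyperpath(scaled, inst$source, inst$sink)
    expect_identical(sort(p3$edges), sort(p1$edges))
    expect_equal(p3$weight, 3 * p1$weight)
  }
})

test_that("heuristic never beats the enumeration optimum and usually matches it", {
  n_co <- 0L
  n_eq <- 0L
  for (sp in general_matrix(60, seed_base = 51000L)) {
    inst <- random_hypergraph(sp)
    if (!inst$reachable) next
    p <- shortest_hyperpath(inst$graph, inst$source, inst$sink)
    opt <- shortest_by_enumeration(inst$graph, inst$source, inst$sink)
    n_co <- n_co + 1L
    expect_gte(p$weight, opt$weight - 1e-9)
    if (abs(p$weight - opt$weight) < 1e-9) n_eq <- n_eq + 1L
  }
  expect_gt(n_co, 20L)
  expect_gt(n_eq / n_co, 0.9)
})
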