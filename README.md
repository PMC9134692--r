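# hyperpaths

Shortest source–sink hyperpaths and exhaustive hyperpath enumeration in
general directed hypergraphs, with the cell-signaling reaction networks
of systems biology as the motivating application.

## The problem

A biochemical reaction with several reactants (all of which must be
present) and several products (all of which are produced) is not an
ordinary graph edge: it is a **hyperedge** *e*, directed from a tail
vertex set tail(*e*) (reactants and positive regulators) to a head
vertex set head(*e*) (products). A signaling pathway — receptors at the
top, a transcription factor at the bottom — is then a **hyperpath**: an
edge subset *F* that can be ordered *e₁, …, e_k* so that

1. tail(*e₁*) = {*s*},
2. tail(*e_i*) ⊆ {*s*} ∪ head(*e₁*) ∪ … ∪ head(*e_{i−1}*) for *i* > 1, and
3. *t* ∈ head(*e_k*),

and that is *minimal*: no proper subset of *F* can be so ordered. Given
edge weights ω(*e*) ≥ 0, the shortest-hyperpath problem asks for an
*s*,*t*-hyperpath minimizing ω(*F*) = Σ ω(*e*) — the most parsimonious
chain of reactions synthesizing the target from the sources. The
problem is NP-complete, and, unlike a shortest path in an ordinary
graph, a shortest hyperpath can be forced to contain a **cycle** (a
reaction that regenerates an upstream species, e.g. a complex releasing
a component); methods restricted to acyclic orderings find nothing on
such instances.

## What the package provides

* **Reachability primitives** — `forward_reachable()` (B-connectivity
  closure from a source), `backward_traceable()` (head-to-tail chains
  into a sink), `is_reachable()` (early-exit single-edge test), and
  `doubly_reachable_subgraph()`, the restriction on which every
  source–sink hyperpath lives and on which the solvers do nearly all
  their work.
* **A fast shortest-hyperpath heuristic** — `shortest_hyperpath()`, a
  Dijkstra-like, edge-based search: a min-heap of hyperedges keyed by
  the weight of the best recovered hyperpath from the source to each
  edge, with greedy two-phase hyperpath recovery
  (`recover_short_hyperpath()`: backward trace over recorded in-edge
  lists, then greedy trimming in decreasing order of path-length
  estimates). It always returns a hyperpath when one exists, handles
  cyclic hyperpaths, and is provably optimal on singleton-tail
  hypergraphs (every |tail(*e*)| = 1) with nonnegative weights.
* **Exact enumeration** — `all_hyperpaths()` generates every
  *s*,*t*-hyperpath exactly once via a queue of out-set-constrained
  subproblems with keep-sets (at most 2^m subproblems, all with
  distinct out-sets), and `shortest_by_enumeration()` is the resulting
  exact (exponential-time) reference solver.
* **Validation** — `is_superpath()` / `is_hyperpath()` certify
  candidate edge sets (with constructive witness orderings),
  `is_cyclic()` decides the cycle criterion on the edge-adjacency
  digraph, and `brute_force_hyperpaths()` is an independent exhaustive
  oracle used throughout the tests.
* **Instance preparation and I/O** — `reduce_sources_sinks()` and
  `prepare_instance()` wire multi-source / multi-target problems to a
  single supersource and sink with zero-weight edges; `read_hgr()` /
  `write_hgr()` handle a plain-text tab-separated edge-list format.
* **Synthetic generators** — `gen_spec()` / `random_hypergraph()`
  (seeded, reproducible, with the sparsity of curated pathway
  hypergraphs), `cyclic_only_gadget()`, `worked_examples()`.
* **A command line** — `exec/hyperpath` with subcommands `shortest`,
  `enumerate`, `reach`, `validate`, `stats`, `simulate`.

## A worked example

The smallest instance on which acyclic methods fail outright:

```r
library(hyperpaths)
gad <- cyclic_only_gadget()   # e1=({s},{a,b}), e2=({a,b},{c}), e3=({c},{b,t})
p <- shortest_hyperpath(gad$graph, gad$source, gad$sink)
p
#> s,t-hyperpath: 3 edges, weight 3, cyclic
#>   [e1 -> e2 -> e3]
paths <- all_hyperpaths(gad$graph, gad$source, gad$sink)
length(paths)                 # 1: the cyclic hyperpath is the only one
#> [1] 1
write_hyperpath_json(p)
#> {"edges":["e1","e2","e3"],"weight":3,"cyclic":true}
```

`e3` regenerates `b`, which `e2` already consumed, so every valid
ordering has a later head feeding an earlier tail — the hyperpath is
cyclic, and it is the unique solution: the heuristic finds it, an
acyclic-only solver finds nothing.

On a random weighted instance the heuristic can be checked against the
exact enumeration:

```r
inst <- random_hypergraph(gen_spec(n = 12, m = 10, seed = 12))
shortest_hyperpath(inst$graph, inst$source, inst$sink)
#> s,t-hyperpath: 2 edges, weight 7.76327
#>   [e007 -> e003]
shortest_by_enumeration(inst$graph, inst$source, inst$sink)$weight
#> [1] 7.763275
```

From a shell (the script is installed at
`system.file("exec", "hyperpath", package = "hyperpaths")`; put it on
your `PATH` or call it by full path):

```sh
hyperpath simulate --n 12 --m 10 --seed 12 --out g.hgr
hyperpath shortest --graph g.hgr --source v01 --sink v12
hyperpath enumerate --graph g.hgr --source v01 --sink v12
hyperpath stats --graph g.hgr --source v01 --sink v12
```

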