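---
title: "Shortest hyperpaths in directed hypergraphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shortest hyperpaths in directed hypergraphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperpaths)
```

## The model

A directed hypergraph is a pair (V, E) where each hyperedge
e = (tail(e), head(e)) is directed from one nonempty vertex set to
another. In a reaction network the tail holds the reactants and
positive regulators of a reaction (all must be present for it to
proceed) and the head holds its products (all are produced). An
**s,t-superpath** is an edge set orderable as $e_1,\dots,e_k$ with
$\mathrm{tail}(e_1)=\{s\}$, each later tail covered by $\{s\}$ and
earlier heads, and $t \in \mathrm{head}(e_k)$; an **s,t-hyperpath** is a
*minimal* superpath — no proper subset is a superpath. With weights
$\omega(e) \ge 0$ and $\omega(F) = \sum_{e \in F}\omega(e)$, the
shortest-hyperpath problem is NP-complete even for singleton-head
hypergraphs, so the package pairs a polynomial-time heuristic with an
exact exponential-time enumerator that doubles as its oracle.

Two points that make hypergraphs genuinely different from graphs drive
the design throughout:

* **Minimality is a subset condition, not an edge condition.** The
  superpath property is non-monotone: adding an edge whose head
  contains $t$ can *break* condition (iii), because every edge of the
  set must appear in the ordering and the last one must contain $t$.
  Consequently a set can survive every single-edge removal yet strictly
  contain a smaller superpath (the suite constructs such a set
  explicitly), and `is_hyperpath()` therefore tests minimality against
  all proper subsets. It does so through an equivalent reachability
  characterization: $F$ is a hyperpath iff $t$ is forward reachable
  from $s$ using only edges of $F$ and *every* edge of $F$ is necessary
  for that reachability. (Necessity of all edges forces all of them to
  fire in the B-connectivity closure, the firing order is a valid
  ordering whose last edge reaches $t$, and any proper superpath subset
  would keep $t$ reachable after a removal.) The exhaustive oracle
  `brute_force_hyperpaths()` deliberately does *not* use this
  characterization: it applies the ordering-based `is_superpath()` test
  to every subset and extracts the subset-minimal ones by dynamic
  programming over the subset lattice, so the two routes stay
  independent and are compared in the tests.
* **A hyperpath can be forced to contain a cycle.** `is_cyclic()`
  decides the criterion "every valid ordering has a later edge whose
  head intersects an earlier edge's tail" by cycle detection on the
  edge-adjacency digraph (arc $e \to f$ iff
  $\mathrm{head}(e)\cap\mathrm{tail}(f)\neq\emptyset$, self-arcs
  included): a topological order of an acyclic digraph is a valid
  back-pair-free ordering, while a digraph cycle forces a back-pair in
  every linear order. An edge whose own head and tail intersect (a
  self-loop) counts as cyclic. Rather than trusting this reduction, the
  suite checks it against `is_cyclic_bruteforce()`, an exhaustive scan
  over all valid orderings, on every small hyperpath it encounters.

## The heuristic

`shortest_hyperpath()` is an edge-based Dijkstra-like search:

1. **Restriction.** The input is restricted to the doubly-reachable
   subgraph (edges both forward reachable from $s$ and backward
   traceable from $t$). Every edge of every s,t-hyperpath is doubly
   reachable, so nothing is lost, and on pathway-like inputs the
   restriction is dramatically smaller than the input.
2. **Search.** A min-heap holds hyperedges keyed by the weight of the
   best *recovered* hyperpath from $s$ to the edge. Edges with tail
   exactly $\{s\}$ seed the heap with key $\omega(e)$. When an edge $e$
   is extracted, its length estimate is finalized as the weight of a
   freshly recovered s,e-hyperpath; $e$ then announces itself to every
   out-edge $f$ of its head vertices — appending to $f$'s in-edge list,
   decrementing $f$'s uncovered-tail counter — and whenever $f$'s tail
   is fully covered, a hyperpath to $f$ is recovered and $f$ is
   inserted or its key decreased. Keys are always weights of fully
   recovered hyperpaths, never sums of parts: hyperpaths to different
   in-edges can share edges arbitrarily, so no simple composition rule
   exists — this is the heart of why the problem is hard and the method
   a heuristic.
3. **Recovery** (`recover_short_hyperpath()`). Phase I collects an
   s,e-superpath by tracing backward from $e$ over the recorded in-edge
   lists (for each non-source tail vertex, every recorded in-edge
   covering it). Phase II greedily trims: candidates $f \neq e$ are
   considered in decreasing order of their finalized length estimates
   and removed whenever $e$ stays reachable without them. Trimming by
   path length rather than by edge weight matters on real reaction
   networks, where weights are typically all 1 and weight-based
   trimming would degenerate to random order.
4. **Finish.** After the heap drains, hyperpaths are re-recovered for
   every reached in-edge of $t$; each is additionally trimmed to a
   minimal set keeping *t* reachable, and the best result is returned.
   The extra trim matters only when the sink has several in-edges and
   one recovered set contains two of them — then minimality with
   respect to reaching the edge and with respect to reaching $t$
   differ; instances prepared with a single sink wiring never hit the
   case, but random instances do, and the returned object must certify
   as a hyperpath.

Guarantees carried by the tests: the heuristic returns a hyperpath iff
the sink is forward reachable (feasibility); its weight never beats the
enumeration optimum (upper bound); and on singleton-tail hypergraphs
with nonnegative weights it is exactly optimal — there, a shortest
hyperpath decomposes into shortest hyperpaths to its edges and the
greedy machinery provably recovers them.

Deterministic tie-breaking is fixed everywhere so identical inputs give
identical outputs: the heap breaks equal keys by earliest insertion;
trimming breaks equal length estimates by descending edge id; witness
construction peels lowest edge id first; final candidates tie-break on
the lexicographically smallest sorted edge set. Already-extracted edges
are never re-keyed, and an edge's finalized length never changes.

The heap is a binary heap with a position index (the search only relies
on the insert / extract-min / decrease-key contract; the log-factor
difference from pointer-based heaps is irrelevant at the problem sizes
the package targets, where total time is dominated by recovery calls).

## Enumeration

`all_hyperpaths()` maintains a FIFO queue of subproblems (Out, Keep):
find a hyperpath disjoint from Out, where descendants may not forbid
edges in Keep. A solved subproblem with hyperpath $P$ spawns one child
per edge of $P$ outside Keep (in witness order — any fixed order is
correct, this one makes runs reproducible); the child forbids that edge
and keeps the edges handed to its earlier siblings. Keep-sets make all
queued out-sets pairwise distinct, so at most $2^m$ subproblems exist;
the same hyperpath can still arise from different subproblems, so
duplicates are filtered on the sorted edge set. The per-subproblem
solver `one_hyperpath()` takes the forward-reachable edge set with Out
excluded and trims it (in reverse discovery order, a free choice fixed
for determinism) to a minimal set keeping the sink reachable — exactly
a hyperpath by the characterization above. The in-set-constrained
variant that classical inclusion–exclusion enumeration would need is
NP-complete and deliberately avoided. A subproblem budget (default
$10^6$) aborts with an explicit error condition rather than returning a
silent partial answer.

## Instance preparation

Multi-source and multi-sink problems reduce to the single-source,
single-sink case by zero-weight wiring: one edge
$(\{s^*\}, S)$ from a fresh supersource; for sinks, either one edge
$(T, \{t^*\})$ ("reach all") or one edge $(\{v\},\{t^*\})$ per sink
("reach any"). `prepare_instance()` applies the standard convention for
curated pathway hypergraphs: sources are the vertices with no in-edges
plus those whose every in-edge is a self-loop (otherwise those loops
could never fire), and a chosen target is wired to a fresh sink.
Zero-weight edges are therefore legal throughout, even though the
shortest-hyperpath problem is usually stated with positive weights; all
optimality machinery only needs nonnegativity. The reserved ids
`__SRC__` / `__SNK__` collide loudly rather than renaming silently.

## The synthetic generator

`random_hypergraph()` draws tails and heads uniformly at the sizes of
curated pathway hypergraphs: tail sizes 1–3 (mean near 2), head sizes
1–2 (mean near 1.3), and — in the default study matrices — fewer edges
than vertices, matching the sparsity of curated signaling databases
such as NCI-PID and Reactome, where reactions are consistently fewer
than species and complexes. Because a
sparse hypergraph with uniformly random tails almost never contains an
edge whose tail is exactly the source, a fraction of edges
(`p_source_edge`, default 0.25) get tail $\{s\}$, emulating supersource
wiring; a `self_loop_rate` option injects self-loops to exercise the
cycle machinery. Everything is seeded and byte-reproducible, and the
caller's RNG state is left untouched.

The study batteries used by the tests and the acceptance script are:
100 general instances (5–12 vertices, 4–10 edges) for the
enumeration-oracle comparison; 200 singleton-tail instances (5–30
vertices, edges at 0.55–0.95 of the vertex count, weights uniform on
[0, 10]) for exact optimality; 500 general instances for feasibility;
and the cyclic-only gadget end to end. Sizes were chosen so the
exponential oracles stay comfortably tractable: enumeration cost grows
with the number of distinct hyperpaths, which explodes on *dense*
random hypergraphs (edges ≫ vertices) — a regime the real networks are
far from. What these batteries do emulate is the combinatorial
structure (AND-tails, shared subpaths, cycles, unreachable targets);
what they do not emulate is biological annotation, reaction
stoichiometry, compartments, or the degree distributions of any
particular database, so passing them shows algorithmic correctness at
realistic sparsity, not biological fidelity.

## Numerical and degenerate-input choices

* Weights are validated nonnegative at construction and parse time;
  negative weights are rejected. Weight comparisons in tests use an
  absolute tolerance of $10^{-9}$; the algorithms themselves compare
  exactly (ties are broken structurally, as above).
* The empty hypergraph, edgeless hypergraphs, isolated sources and
  sinks, and `source == sink` are all legal inputs; solvers return the
  empty path rather than erroring when no hyperpath exists.
* `recover_short_hyperpath()` treats a violated precondition (a tail
  vertex not covered by the in-edge closure) as a hard internal error,
  never a silent empty result.
* The HGR-TSV writer sorts edges by id and set members
  lexicographically, so write → read → write is byte-identical; this
  backs the CLI determinism guarantee.

## Limitations

* The heuristic is an upper bound on general hypergraphs; on the random
  batteries it matches the enumeration optimum on about 97–100% of
  instances, but no approximation ratio is possible in general (the
  problem is inapproximable within $(1-o(1))\ln n$ unless P = NP), and
  adversarial instances can make it suboptimal — the in-edge lists
  recorded during the search need not contain the edges of an optimal
  hyperpath.
* `all_hyperpaths()` is exponential in the worst case and intended for
  oracle duty and moderate instances; the budget makes overruns loud.
* Edge weights model reaction costs only; there is no stoichiometry,
  no rate semantics, and regulators are not distinguished from
  reactants beyond tail membership.
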