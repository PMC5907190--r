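---
title: "Minimum-damage enzyme combination identification in Boolean metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-damage enzyme combination identification in Boolean metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eciopt)
```

## The problem

Many metabolic diseases are driven by the accumulation of particular
metabolites, and many drugs act by inhibiting the enzymes that feed those
metabolites.  An inhibition rarely stops only the intended compound: every
other metabolite whose production collapses alongside it is a potential
side-effect.  `eciopt` formalizes the trade-off on a Boolean model of the
metabolic network and answers one question exactly: *which set of enzymes
should be inhibited so that every target compound stops being producible,
while the fewest non-target compounds are lost?*  We call the count of lost
non-target compounds the **damage** of an inhibition, and the optimization
problem **enzyme combination identification (ECI)**.

## The Boolean model

A network consists of three disjoint node classes:

* **compounds** (`C`), of which those with no producing reaction are
  **sources** -- seed metabolites assumed always available;
* **reactions** (`R`), each consuming a set of input compounds under a set
  of catalyzing enzymes and producing a non-empty set of product
  compounds;
* **enzymes** (`E`), the only nodes a drug can act on.

Every node carries a Boolean value.  A reaction is an **AND** node: active
iff all of its inputs are producible and all of its enzymes uninhibited.
A compound is an **OR** node: producible iff at least one producing
reaction is active.  Sources are fixed to 1, inhibited enzymes to 0.

These consistency conditions alone do not pin down a unique state on
cyclic networks: a cycle of reactions feeding each other admits an
"all active" solution with no external support.  Chemically that state is
spurious -- nothing is produced from nothing -- so the package defines
producibility as the **least fixed point**: the unique consistent state in
which every active node has a finite derivation from the sources.
`propagate()` computes it by monotone (Kleene) iteration, which is
order-independent and linear-time per sweep; `damage()` and
`stops_targets()` evaluate inhibitions on top of it.

```{r}
net <- demo_network()
net
damage(net, inhibited = "E2", targets = "C5")
```

The bundled demo network is deliberately cyclic (`C2 -> R2 -> C7 -> R1 ->
C2`), and illustrates a subtlety: inhibiting `E1` starves that cycle, so
`C2` is lost *in addition to* the four compounds directly downstream of
`E1`-dependent reactions -- the least fixed point, not visual path-tracing,
is the arbiter.

```{r}
damage(net, inhibited = "E1", targets = "C5")
```

## The integer linear program

`build_ilp()` encodes an instance over one complementary pair of binary
variables per node, `T_x + F_x = 1`, with `T_x = 1` meaning the node's
Boolean value is 1.  A Boolean definition is turned into linear rows
through its conjunctive normal form; every disjunction becomes a row
"sum of the matching T/F variables >= 1":

* reaction `r = AND(u1, ..., uk)` (inputs and enzymes alike):
  `T_r + F_u1 + ... + F_uk >= 1` and, per input, `F_r + T_ui >= 1`;
* compound `c = OR(r1, ..., rk)` over its producing reactions:
  `F_c + T_r1 + ... + T_rk >= 1` and, per producer, `T_c + F_ri >= 1`;
* single-input definitions collapse to the copy equality `T_out = T_in`;
* sources are fixed `T = 1`, targets `F = 1`.

The objective minimizes the damage directly: `min` of the sum of `F_c`
over **non-target** compounds.  Targets are excluded because their `F` is
already fixed, and reactions and enzymes never enter the objective -- the
enzyme variables are the free decisions, everything else follows.  The
model has exactly `2(m + n + l)` binaries for `m` compounds, `n` reactions
and `l` enzymes, so its size is linear in the network.

```{r}
build_ilp(demo_instance(), acyclic_encoding = "none")
```

### Cycles need one more idea

The rows above enforce *consistency* only.  On a cyclic network a
damage-minimizing objective will happily exploit the spurious
"self-sustaining cycle" fixed point, reporting compounds as producible
that the least fixed point says are dead.  With
`acyclic_encoding = "levels"` (the default in `solve_eci()`) the model
adds an integer level `L_x` in `[0, m + n]` per compound and reaction,
support indicators per multi-producer edge, and big-M rows (`M = m+n+1`)
forcing every producible non-source compound to select an active producer
of strictly lower level and every active reaction to sit strictly above
its inputs, with sources at level 0.  Circular support then has no
feasible level assignment, and optimal solutions coincide with the least
fixed point on every network.  The added variables stay within
`(m + n) + |arcs|`, preserving linear model size.

```{r}
cyc <- metabolic_network(
  compounds = c("A", "B", "S", "P"),
  reactions = list(
    list(id = "RA", inputs = "B", enzymes = character(), products = "A"),
    list(id = "RB", inputs = "A", enzymes = character(), products = "B"),
    list(id = "RP", inputs = "S", enzymes = "E", products = "P")),
  enzymes = "E")
inst <- eci_instance(cyc, "P")
solve_eci(inst, acyclic_encoding = "none", verify = FALSE)$damage  # spurious
solve_eci(inst)$damage                                             # true
```

`solve_eci(..., acyclic_encoding = "none")` (with verification left on)
reproduces the literal consistency-only system and falls back to the
level encoding automatically whenever post-hoc verification against
`propagate()` detects a cycle artefact.

### The solver

No mixed-integer programming backend is available as an R package in this
package's dependency set, so `eciopt` ships its own exact optimizer,
`backend = "bnb"`.  It exploits the model's structure rather than
implementing general MILP: because every base row is a disjunction over
complementary pairs, the system compiles to clause form, and a
depth-first branch and bound with unit propagation and an objective lower
bound (the count of already-falsified objective compounds; all remaining
terms are nonnegative) enumerates implicitly.  The level subsystem is a
set of *conditional difference constraints*; once all binaries are fixed
it is an ordinary difference-constraint system, which is decided exactly
-- and constructively -- by a longest-path peeling over the support graph
at each complete leaf.  Branching follows a fixed variable order
(enzymes, then compounds, then reactions, in declaration order), tries
value 1 first, and replaces an incumbent only when strictly better, so
repeated runs return the same optimum among ties.  Every optimum is
re-verified against `propagate()` before it is returned.

On the instance sizes the test-suite uses (up to roughly a dozen
compounds and ten reactions, or reduced edge-cover graphs of up to eight
vertices) a solve takes milliseconds; an optional `time_limit` aborts
with the best incumbent reported in the error for larger inputs.

## Why the problem is genuinely hard

ECI generalizes **minimum edge cover** (MEC).  `reduce_mec_to_eci()`
makes the reduction executable: every edge of an undirected graph becomes
a compound, every vertex a reaction that consumes its incident
edge-compounds and produces a single target `c_t`.  Stopping `c_t` forces
every vertex-reaction off, which requires removing at least one incident
edge-compound per vertex -- exactly an edge cover -- and the minimum
damage equals the minimum cover size.  So that compound removal is an
enzyme decision within the standard formalism, each edge-compound is
produced by a dedicated virtual reaction gated by a virtual enzyme and
fed from one universal source.  The test suite cross-validates the
equivalence against `brute_force_mec()`, an enumerating exact cover
solver, on a hundred seeded random graphs.  (Polynomial MEC algorithms
via maximum matching exist; enumeration is used deliberately as an
independent oracle, not as a recommendation.)

## The random-network generator

`generate_random_network()` produces the test universe and is part of the
package surface, not a fixture.  Design choices, made once:

* **Validity by construction.**  A non-empty source subset is chosen
  (never fewer than `m - n * max_outdegree` sources, so that the
  reactions' product capacity suffices), reactions draw inputs only from
  compounds already derivable, every non-source compound receives a
  producer and every reaction at least one product.
* **Cycles are injected, not hoped for.**  Wiring is acyclic first; with
  probability `cycle_probability` one back edge is added by letting a
  reaction also *produce* a non-source compound it already consumes (or,
  if no reaction consumes a non-source compound, by routing a product of
  the first, source-fed reaction through another reaction).  Adding a
  producer edge never reduces producibility, so generated networks always
  satisfy `damage({}) = 0` -- the no-inhibition state loses nothing --
  while still exercising the cycle code paths.
* **Degree bounds** default to 2 for both reaction indegree and assigned
  outdegree (cycle injection may exceed the outdegree by one), echoing
  the sparsity of curated pathway maps.
* **Determinism.**  The same seed and configuration yield an identical
  network, and the caller's RNG state is left untouched.

What the generator does *not* emulate: reversible reactions,
stoichiometry, compartments, currency metabolites, or the heavy-tailed
degree distributions of genome-scale reconstructions.  Green equivalence
suites on generated networks therefore certify the algorithms, not the
biology of any particular pathway; real pathways should be encoded in the
network file format (see the README for a worked KEGG-style example) and
judged individually.

## Numerical and degenerate-input choices

* Reactions with no inputs and no enzymes are constant-active; the model
  fixes `T_r = 1`.
* Reactions with zero enzymes are legal (the edge-cover reduction relies
  on them); they simply offer no inhibition handle.
* Targets that are sources are rejected at instance construction -- no
  inhibition can stop a seed compound -- rather than surfacing as solver
  infeasibility.
* Tie-breaks: `brute_force_eci()` enumerates by cardinality then
  lexicographic id order and keeps the first optimum; the branch-and-bound
  keeps the first incumbent of each objective value under its fixed
  branching order.  Equal-damage optima may differ between the two routes;
  the damage itself is the comparable quantity.
* `big-M` is `m + n + 1`, the smallest value dominating any level
  difference, so the LP relaxation is as tight as this encoding allows.

## Known limitations

* All compounds and enzymes are weighted equally; weighted damage is a
  deliberate non-goal.
* The built-in solver targets the small-to-medium instances of the test
  universe; genome-scale networks would warrant an external MILP backend
  behind the same `build_ilp()`/`write_lp()` surface (`write_lp()` exports
  standard LP format for exactly that purpose).
* Quantitative kinetics, reversibility and regulation are out of scope;
  the model is purely Boolean.
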