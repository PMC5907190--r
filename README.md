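# eciopt

Exact minimum-damage drug-target selection on Boolean metabolic networks.

Metabolic diseases are often driven by the accumulation of specific
metabolites, and drugs intervene by inhibiting enzymes.  But an enzyme
inhibition rarely stops only the intended compound: every other
metabolite whose production collapses with it is a potential
side-effect.  `eciopt` is for computational biologists who want that
trade-off made exact on a Boolean network model: given compounds,
reactions and enzymes, and a set of **target** compounds to stop, find
the enzyme set whose inhibition stops every target while rendering the
fewest **non-target** compounds non-producible.  That count is the
**damage**; the problem is **enzyme combination identification (ECI)**.

## The model and the optimization

Reactions are AND nodes (active iff all input compounds and catalyzing
enzymes are on), compounds are OR nodes (producible iff some producing
reaction is active), compounds with no producer are always-on sources.
Producibility is the **least fixed point** of this AND/OR system —
a node is on only if it has a finite derivation from the sources, so
self-sustaining cycles never count as producible.

The optimization is a 0/1 integer linear program over complementary
variable pairs `T_x + F_x = 1` per node: CNF-derived rows encode the
AND/OR definitions (e.g. `T_R1 + F_C1 + F_C7 + F_E2 >= 1` for a
reaction, `F_C7 + T_R2 + T_R3 >= 1` for a compound with two producers),
sources are fixed `T = 1`, targets `F = 1`, and the objective is

```
min  sum over non-target compounds c of F_c        (the damage)
```

which uses `2(m+n+l)` binaries for `m` compounds, `n` reactions, `l`
enzymes.  An acyclic-support ("levels") extension pins optimal solutions
to the least fixed point on cyclic networks; the package solves the
model with a built-in exact branch-and-bound and re-verifies every
optimum against ground-truth propagation.  An exhaustive-search oracle,
a seeded random-network generator, and an executable reduction from
minimum edge cover (the problem's NP-hardness source) round out the
toolkit.  See `vignette("enzyme-combination-identification")` for the
full account.

## Worked example

The bundled demo network has nine compounds (sources `C1`, `C3`, `C6`),
three reactions and two enzymes, with a cycle `C2 -> R2 -> C7 -> R1 ->
C2`; the target is `C5`.

```r
library(eciopt)

net <- demo_network()
net
#> Boolean metabolic network: 9 compounds, 3 reactions, 2 enzymes
#>   sources: C1, C3, C6

damage(net, inhibited = "E2", targets = "C5")
#> $count
#> [1] 2
#>
#> $knocked_out
#> [1] "C2" "C4"
```

Inhibiting `E2` stops the target and costs damage 2: `C2` and `C4` are
lost, while `C7` survives through its second producer `R3`.  (Inhibiting
`E1` would also stop `C5`, but at damage 5 — the cycle starves `C2` too.)
The optimizer confirms `{E2}` is the minimum-damage choice:

```r
solve_eci(demo_instance())
#> ECI solution (ilp-levels)
#>   status: optimal
#>   inhibited enzymes: E2
#>   damage: 2
#>   knocked-out non-targets: C2, C4

build_ilp(demo_instance(), acyclic_encoding = "none")
#> ILP model: 28 variables (14 binary T/F pairs), 37 rows, consistency-only encoding
#>   objective: minimize damage over 8 non-target compounds
```

The same run from the shell (the `eci` script is installed under the
package's `exec/` directory):

```sh
eci optimize inst/extdata/demo.net --targets C5
# {"instance":"inst/extdata/demo.net","targets":["C5"],"inhibited":["E2"],
#  "damage":2,"knocked_out":["C2","C4"],"status":"optimal","backend":"bnb",
#  "wall_time":0.27}
```

Other subcommands: `validate`, `simulate` (assignment as TSV plus a
damage summary), `reduce-mec` (edge-cover graph to ECI network),
`gen-random` (seeded random instances).

## Encoding a real pathway

Real pathways are written in the same line-oriented format, one record
per line; identifiers are opaque, so KEGG-style accessions work as-is:

```
compound  C00909
compound  C02165
enzyme    E3.3.2.6
reaction  R_LTA4H  inputs=C00909  enzymes=E3.3.2.6  products=C02165
```

Then `eci optimize pathway.net --targets C02165`, or
`eci simulate pathway.net --inhibit E3.3.2.6 --targets C02165` to score
a specific drug's enzyme set.  Network topology must be curated by the
user (database pathway maps are version-dependent); results are only as
good as the encoded topology.

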