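# Shared fixtures, all built in code.

# Two-compound self-sustaining cycle (A <-> B via RA/RB) with no source-fed
# derivation, plus an independent source-fed target P gated by enzyme E.
# Least-fixed-point semantics must keep A and B at 0 always.
cycle_fixture_network <- function() {
  metabolic_network(
    compounds = c("A", "B", "S", "P"),
    reactions = list(
      list(id = "RA", inputs = "B", enzymes = character(), products = "A"),
      list(id = "RB", inputs = "A", enzymes = character(), products = "B"),
      list(id = "RP", inputs = "S", enzymes = "E", products = "P")),
    enzymes = "E")
}

cycle_fixture_instance <- function() {
  eci_instance(cycle_fixture_network(), "P")
}

# Target producible only through an enzyme-free chain from a source: no
# enzyme subset can stop it.
infeasible_instance <- function() {
  net <- metabolic_network(
    compounds = c("S", "T", "Q"),
    reactions = list(
      list(id = "R1", inputs = "S", enzymes = character(), products = "T"),
      list(id = "R2", inputs = "T", enzymes = "E1", products = "Q")),
    enzymes = "E1")
  eci_instance(net, "T")
}

# Deterministic random instance used by the equivalence suites: mixes
# sizes and cycle probabilities from the seed alone.
random_instance <- function(seed) {
  cp <- c(0, 0.5, 1)[seed %% 3 + 1]
  net <- generate_random_network(
    m = 4 + seed %% 9, n = 2 + seed %% 9, l = 2 + seed %% 5,
    cycle_probability = cp, seed = seed)
  nonsrc <- setdiff(net$compounds, identify_sources(net))
  if (!length(nonsrc)) return(NULL)
  eci_instance(net, nonsrc[1 + seed %% length(nonsrc)])
}

# Random undirected graph without isolated vertices (each vertex first
# receives one incident edge, then a few extras), 3..8 vertices.
random_mec_graph <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(3:8, 1)
    verts <- paste0("v", seq_len(n))
    ends <- list()
    for (v in verts) {
      u <- sample(setdiff(verts, v), 1)
      ends[[length(ends) + 1]] <- sort(c(v, u))
    }
    for (k in seq_len(sample(0:4, 1)))
      ends[[length(ends) + 1]] <- sort(sample(verts, 2))
    ends <- unique(ends)
    mec_graph(verts, stats::setNames(ends, paste0("e", seq_along(ends))))
  })
}

# producing reactions per compound, rebuilt from the public surface
producers_of_public <- function(net) {
  out <- stats::setNames(vector("list", length(net$compounds)), net$compounds)
  for (r in net$reactions) for (p in r$products) out[[p]] <- c(out[[p]], r$id)
  out
}

demo_net_file <- function() {
  path <- system.file("extdata", "demo.net", package = "eciopt")
  if (!nzchar(path)) path <- testthat::test_path("..", "..", "inst", "extdata", "demo.net")
  path
}
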