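test_that("propagation reproduces the demo network walk-through", {
  net <- demo_network()

  # inhibiting E2 stops R1 hence C2, C4, C5; C7 survives via R3
  v <- propagate(net, "E2")
  expect_identical(unname(v[c("C2", "C4", "C5")]), c(0L, 0L, 0L))
  expect_identical(unname(v[c("C7", "C8", "C9")]), c(1L, 1L, 1L))

  # nothing inhibited: every node active
  v0 <- propagate(net)
  expect_true(all(v0 == 1L))

  # inhibiting E1 kills R2 and R3; the C2-R2-C7-R1 cycle then starves C2
  v1 <- propagate(net, "E1")
  expect_identical(unname(v1[c("R2", "R3", "C2", "C7")]), c(0L, 0L, 0L, 0L))
})

test_that("damage counts non-target compounds only", {
  net <- demo_network()
  d2 <- damage(net, "E2", "C5")
  expect_identical(d2$count, 2L)
  expect_identical(d2$knocked_out, c("C2", "C4"))

  d0 <- damage(net, character(), "C5")
  expect_identical(d0$count, 0L)
  expect_identical(d0$knocked_out, character(0))

  # least-fixed-point semantics: the cycle starves C2 too, so E1 costs 5
  d1 <- damage(net, "E1", "C5")
  expect_identical(d1$count, 5L)
  expect_setequal(d1$knocked_out, c("C2", "C4", "C7", "C8", "C9"))

  # the target itself is never counted
  expect_false("C5" %in% d1$knocked_out)
})

test_that("stops_targets matches the walk-through", {
  net <- demo_network()
  expect_true(stops_targets(net, "E2", "C5"))
  expect_true(stops_targets(net, "E1", "C5"))
  expect_false(stops_targets(net, character(), "C5"))
})

test_that("unknown enzyme and target ids are rejected", {
  net <- demo_network()
  expect_error(propagate(net, "E9"), "unknown enzyme")
  expect_error(damage(net, "E1", "C99"), "not a declared compound")
  expect_error(stops_targets(net, "E1", "C99"), "not a declared compound")
})

test_that("a self-sustaining cycle with no external derivation stays 0", {
  # pure two-compound cycle, no sources at all
  pure <- metabolic_network(
    c("A", "B"),
    list(list(id = "RA", inputs = "B", enzymes = character(), products = "A"),
         list(id = "RB", inputs = "A", enzymes = character(), products = "B")))
  expect_identical(validate_network(pure), character(0))
  v <- propagate(pure)
  expect_true(all(v[c("A", "B", "RA", "RB")] == 0L))

  # cycle beside a source-fed branch: cycle still dead, branch alive
  v2 <- propagate(cycle_fixture_network())
  expect_identical(unname(v2[c("A", "B")]), c(0L, 0L))
  expect_identical(unname(v2[c("S", "P")]), c(1L, 1L))
})

test_that("inhibiting more never produces more (monotonicity)", {
  for (s in 0:14) {
    net <- generate_random_network(m = 5 + s %% 8, n = 2 + s %% 7, l = 3,
                                   cycle_probability = c(0, 0.5, 1)[s %% 3 + 1],
                                   seed = 200 + s)
    vA <- propagate(net, "E1")
    vB <- propagate(net, c("E1", "E2"))
    expect_true(all(vA[vB == 1L] == 1L))
  }
})

test_that("propagation is invariant under declaration-order permutation", {
  net <- demo_network()
  shuffled <- metabolic_network(
    compounds = rev(net$compounds),
    reactions = unname(net$reactions)[c(3, 1, 2)],
    enzymes = rev(net$enzymes))
  for (inh in list(character(), "E1", "E2", c("E1", "E2"))) {
    a <- propagate(net, inh)
    b <- propagate(shuffled, inh)
    expect_identical(as.integer(a[names(a)]), as.integer(b[names(a)]))
  }
})

test_that("no damage without inhibition on generated networks", {
  for (s in 0:19) {
    net <- generate_random_network(m = 5 + s %% 8, n = 2 + s %% 6, l = 2,
                                   cycle_probability = c(0, 0.5, 1)[s %% 3 + 1],
                                   seed = 300 + s)
    expect_identical(damage(net, character(), net$compounds[1])$count, 0L)
  }
})

test_that("exhaustive search finds the minimum-damage enzyme set", {
  sol <- brute_force_eci(demo_instance())
  expect_identical(sol$status, "optimal")
  expect_identical(sol$inhibited, "E2")
  expect_identical(sol$damage, 2L)
  expect_identical(sol$knocked_out, c("C2", "C4"))

  # the witnessing assignment satisfies the validity conditions
  net <- demo_network()
  v <- sol$assignment
  for (cid in identify_sources(net)) expect_identical(v[[cid]], 1L)
  for (r in net$reactions)
    expect_identical(v[[r$id]],
                     as.integer(all(v[r$inputs] == 1L) & all(v[r$enzymes] == 1L)))
  prods <- producers_of_public(net)
  for (cid in setdiff(net$compounds, identify_sources(net)))
    expect_identical(v[[cid]], as.integer(any(v[prods[[cid]]] == 1L)))
})

test_that("exhaustive search reports infeasibility and honours the cap", {
  sol <- brute_force_eci(infeasible_instance())
  expect_identical(sol$status, "infeasible")
  expect_true(is.na(sol$damage))
  expect_error(brute_force_eci(demo_instance(), enumeration_cap = 2),
               "exceeds the cap")
  # bounded-cardinality search waives the cap
  sol2 <- brute_force_eci(demo_instance(), max_set_size = 1,
                          enumeration_cap = 2)
  expect_identical(sol2$inhibited, "E2")
})
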