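# sample() treats a length-1 numeric vector as 1:x; this keeps set sampling honest
resample <- function(x, size) x[sample.int(length(x), size)]

#' Generate a random Boolean metabolic network
#'
#' Wires a valid network deterministically from a seed: a non-empty source
#' subset is chosen, reactions are processed in order and draw their
#' inputs from compounds already available (sources or earlier products),
#' every non-source compound is guaranteed at least one producing
#' reaction, every reaction at least one product, and each reaction gets
#' one or two catalyzing enzymes (when any are requested).  The wiring is
#' acyclic by construction; with probability `cycle_probability` one back
#' edge is then injected: a non-source compound some reaction already
#' consumes additionally becomes one of that reaction's products (or, when
#' no reaction consumes a non-source compound, a product of the first,
#' source-fed reaction is routed through another reaction as both input
#' and product).  Either move creates a compound-reaction cycle while
#' keeping every compound producible under no inhibition, because the
#' compound retains a derivation through its original, acyclic producer.
#'
#' @param m number of compounds (>= 1).
#' @param n number of reactions (>= 0).
#' @param l number of enzymes (>= 0).
#' @param max_indegree maximum number of input compounds per reaction.
#' @param max_outdegree maximum number of products assigned per reaction
#'   during acyclic wiring (cycle injection may add one more).
#' @param cycle_probability probability in `[0, 1]` of injecting a cycle.
#' @param seed integer seed; the same seed and configuration always yield
#'   a structurally identical network (the caller's RNG state is left
#'   untouched).
#' @return A valid `metabolic_network` with compounds `C1..Cm`, reactions
#'   `R1..Rn` and enzymes `E1..El`.
#' @export
generate_random_network <- function(m, n, l, max_indegree = 2,
                                    max_outdegree = 2,
                                    cycle_probability = 0, seed = 1) {
  stopifnot(m >= 1, n >= 0, l >= 0, max_indegree >= 1, max_outdegree >= 1,
            cycle_probability >= 0, cycle_probability <= 1)
  comps <- paste0("C", seq_len(m))
  enz <- if (l > 0) paste0("E", seq_len(l)) else character()
  if (n == 0)
    return(metabolic_network(comps, list(), enz))
  # sources are derived, so feasibility is a matter of choosing enough of
  # them: at least max(1, m - n*max_outdegree) compounds must stay sources
  min_sources <- max(1L, m - n * max_outdegree)

  withr::with_seed(seed, {
    n_src <- if (m == 1) 1L else
      sample(min_sources:(m - 1L), 1L)
    sources <- resample(comps, n_src)
    unproduced <- resample(setdiff(comps, sources),
                           length(setdiff(comps, sources)))
    available <- sources
    produced <- character()
    rxns <- vector("list", n)
    for (j in seq_len(n)) {
      # at least `need` products here or later reactions run out of capacity
      need <- max(0L, length(unproduced) - (n - j) * max_outdegree)
      take <- min(length(unproduced),
                  max(need, min(1L, length(unproduced)),
                      sample.int(max_outdegree, 1L)))
      if (take > 0) {
        prods_j <- unproduced[seq_len(take)]
        unproduced <- unproduced[-seq_len(take)]
      } else {
        # all compounds placed; reuse an existing non-source as extra product
        prods_j <- resample(if (length(produced)) produced else comps, 1L)
      }
      # a reused product must not feed its own (possibly only) producer
      ins_pool <- if (take > 0) available else setdiff(available, prods_j)
      ins_j <- if (length(ins_pool))
        resample(ins_pool, sample.int(min(max_indegree, length(ins_pool)), 1L))
      else character()
      enz_j <- if (l > 0)
        resample(enz, sample.int(min(2L, l), 1L)) else character()
      rxns[[j]] <- list(id = paste0("R", j), inputs = ins_j,
                        enzymes = enz_j, products = prods_j)
      produced <- c(produced, setdiff(prods_j, produced))
      available <- c(sources, produced)
    }

    if (n >= 2 && length(produced) && stats::runif(1) < cycle_probability) {
      # Preferred: some reaction j already consumes a non-source compound
      # w; adding w to j's products closes the cycle w -> j -> w while only
      # *adding* a producer edge, which can never reduce producibility.
      pairs <- list()
      for (j in seq_len(n))
        for (w in intersect(rxns[[j]]$inputs, produced))
          pairs[[length(pairs) + 1L]] <- list(j = j, w = w)
      if (length(pairs)) {
        p <- pairs[[sample.int(length(pairs), 1L)]]
        if (!p$w %in% rxns[[p$j]]$products)
          rxns[[p$j]]$products <- c(rxns[[p$j]]$products, p$w)
      } else if (length(rxns[[1L]]$products)) {
        # Fallback: every input anywhere is a source.  The first reaction
        # derives from sources alone, so its products are producible
        # independently of any other reaction; route one of them (w)
        # through a different reaction j as both input and product.
        w <- resample(rxns[[1L]]$products, 1L)
        j <- resample(2:n, 1L)
        r <- rxns[[j]]
        if (length(r$inputs) >= max_indegree)
          r$inputs <- r$inputs[-which(r$inputs %in% sources)[1]]
        r$inputs <- c(r$inputs, w)
        if (!w %in% r$products) r$products <- c(r$products, w)
        rxns[[j]] <- r
      }
    }
    metabolic_network(comps, rxns, enz)
  })
}

#' Does a network contain a directed compound-reaction cycle?
#'
#' Depth-first search over the directed graph with edges compound -> reaction
#' (inputs) and reaction -> compound (products).
#'
#' @param network a valid `metabolic_network`.
#' @return `TRUE` iff a directed cycle exists.
#' @export
has_network_cycle <- function(network) {
  succ <- c(
    lapply(stats::setNames(network$compounds, network$compounds), function(cid)
      names(network$reactions)[vapply(network$reactions,
                                      function(r) cid %in% r$inputs,
                                      logical(1))]),
    lapply(network$reactions, `[[`, "products"))
  state <- stats::setNames(rep(0L, length(succ)), names(succ)) # 0 new, 1 open, 2 done
  found <- FALSE
  visit <- function(v) {
    if (found || state[[v]] == 2L) return(invisible())
    if (state[[v]] == 1L) { found <<- TRUE; return(invisible()) }
    state[[v]] <<- 1L
    for (w in succ[[v]]) {
      visit(w)
      if (found) break
    }
    state[[v]] <<- 2L
    invisible()
  }
  for (v in names(succ)) {
    if (!found) visit(v)
  }
  found
}
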