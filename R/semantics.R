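#' Least-fixed-point producibility under enzyme inhibition
#'
#' Computes the ground-truth Boolean state of every node: sources and
#' uninhibited enzymes start at 1, everything else at 0, and activation is
#' propagated monotonically -- a reaction becomes active once all of its
#' input compounds and enzymes are 1, a compound becomes producible once
#' any producing reaction is active -- until stable.  Monotone (Kleene)
#' iteration makes the result the unique *least* fixed point of the AND/OR
#' system, independent of iteration order: a node is 1 only if it has a
#' finite derivation from the sources, so self-sustaining cycles with no
#' external support stay 0.
#'
#' @param network a valid `metabolic_network`.
#' @param inhibited character vector of inhibited enzyme ids (subset of the
#'   declared enzymes).
#' @return A `boolean_assignment`: a named integer vector of 0/1 values
#'   over every compound, reaction and enzyme id.
#' @examples
#' propagate(demo_network(), inhibited = "E2")
#' @export
propagate <- function(network, inhibited = character()) {
  stopifnot(inherits(network, "metabolic_network"))
  inhibited <- as.character(inhibited)
  unknown <- setdiff(inhibited, network$enzymes)
  if (length(unknown))
    stop("unknown enzyme id '", unknown[1], "' in inhibited set", call. = FALSE)

  rids <- names(network$reactions)
  val <- stats::setNames(
    integer(length(network$compounds) + length(rids) + length(network$enzymes)),
    c(network$compounds, rids, network$enzymes))
  val[network$enzymes] <- 1L
  val[inhibited] <- 0L
  val[identify_sources(network)] <- 1L

  repeat {
    changed <- FALSE
    for (r in network$reactions) {
      if (val[[r$id]] == 1L) next
      if (all(val[r$inputs] == 1L) && all(val[r$enzymes] == 1L)) {
        val[[r$id]] <- 1L
        val[r$products] <- 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(val, class = "boolean_assignment", inhibited = inhibited)
}

#' @export
print.boolean_assignment <- function(x, ...) {
  cat(sprintf("Boolean assignment over %d nodes (%d active)\n",
              length(x), sum(x == 1L)))
  inh <- attr(x, "inhibited")
  if (length(inh)) cat("  inhibited:", paste(inh, collapse = ", "), "\n")
  zero <- names(x)[x == 0L & !names(x) %in% inh]
  cat("  value 0:", if (length(zero)) paste(zero, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Damage of an enzyme inhibition
#'
#' Damage is the number of *non-target* compounds rendered non-producible
#' by inhibiting the given enzyme set, evaluated on the least fixed point.
#' Target compounds forced to 0 are never counted, and reactions and
#' enzymes never contribute.  The inhibition is not required to actually
#' stop the targets -- use [stops_targets()] for that.
#'
#' @inheritParams propagate
#' @param targets character vector of target compound ids.
#' @return A list with `count` (integer damage) and `knocked_out` (the
#'   non-target compounds with value 0, in declaration order).
#' @examples
#' damage(demo_network(), inhibited = "E2", targets = "C5")
#' @export
damage <- function(network, inhibited, targets) {
  targets <- as.character(targets)
  unknown <- setdiff(targets, network$compounds)
  if (length(unknown))
    stop("target '", unknown[1], "' is not a declared compound", call. = FALSE)
  val <- propagate(network, inhibited)
  knocked <- setdiff(network$compounds[val[network$compounds] == 0L], targets)
  list(count = length(knocked), knocked_out = knocked)
}

#' Does an inhibition stop every target?
#'
#' @inheritParams damage
#' @return `TRUE` iff every target compound has value 0 in the least fixed
#'   point under `inhibited`.
#' @export
stops_targets <- function(network, inhibited, targets) {
  targets <- as.character(targets)
  unknown <- setdiff(targets, network$compounds)
  if (length(unknown))
    stop("target '", unknown[1], "' is not a declared compound", call. = FALSE)
  val <- propagate(network, inhibited)
  all(val[targets] == 0L)
}

new_eci_solution <- function(inhibited, damage, knocked_out, assignment,
                             status, method) {
  structure(list(inhibited = inhibited, damage = damage,
                 knocked_out = knocked_out, assignment = assignment,
                 status = status, method = method),
            class = "eci_solution")
}

#' @export
print.eci_solution <- function(x, ...) {
  cat("ECI solution (", x$method, ")\n", sep = "")
  cat("  status:", x$status, "\n")
  if (identical(x$status, "optimal")) {
    cat("  inhibited enzymes:",
        if (length(x$inhibited)) paste(x$inhibited, collapse = ", ") else "(none)", "\n")
    cat("  damage:", x$damage, "\n")
    cat("  knocked-out non-targets:",
        if (length(x$knocked_out)) paste(x$knocked_out, collapse = ", ") else "(none)", "\n")
  }
  invisible(x)
}

#' Exhaustive-search oracle for enzyme combination identification
#'
#' Enumerates enzyme subsets in order of increasing cardinality, then
#' lexicographic id order, evaluates each by least-fixed-point propagation,
#' and returns a minimum-damage subset among those stopping every target.
#' Ties are resolved by the enumeration order itself (smaller subsets
#' first, then lexicographically), so the result is deterministic.  The
#' number of subsets grows as `2^l`, so this is the small-instance ground
#' truth against which the integer-programming route is cross-checked,
#' not a scalable solver.
#'
#' @param instance an `eci_instance`.
#' @param max_set_size optional cap on the cardinality of enumerated
#'   subsets; when set, the enumeration cap is waived.
#' @param enumeration_cap refuse instances where `2^l` exceeds this
#'   (default `2^20`) unless `max_set_size` is given.
#' @return An `eci_solution` with `status` `"optimal"` or `"infeasible"`
#'   (no enzyme subset, not even all enzymes, stops every target).
#' @examples
#' brute_force_eci(demo_instance())
#' @export
brute_force_eci <- function(instance, max_set_size = NULL,
                            enumeration_cap = 2^20) {
  stopifnot(inherits(instance, "eci_instance"))
  net <- instance$network
  enz <- sort(net$enzymes)
  l <- length(enz)
  if (is.null(max_set_size)) {
    if (2^l > enumeration_cap)
      stop("enumeration of 2^", l, " enzyme subsets exceeds the cap; ",
           "set max_set_size to search bounded cardinalities", call. = FALSE)
    kmax <- l
  } else {
    kmax <- min(max_set_size, l)
  }

  best <- NULL
  for (k in 0:kmax) {
    subsets <- if (k == 0) list(character()) else
      utils::combn(enz, k, simplify = FALSE)
    for (X in subsets) {
      val <- propagate(net, X)
      if (!all(val[instance$targets] == 0L)) next
      knocked <- setdiff(net$compounds[val[net$compounds] == 0L],
                         instance$targets)
      if (is.null(best) || length(knocked) < best$damage)
        best <- new_eci_solution(X, length(knocked), knocked, val,
                                 "optimal", "exhaustive")
    }
  }
  if (is.null(best))
    best <- new_eci_solution(character(), NA_integer_, character(), NULL,
                             "infeasible", "exhaustive")
  best
}
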