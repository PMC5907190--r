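# Exact optimizer for the 0/1 model built by build_ilp().
#
# Because every node carries a complementary T/F pair, each base row is
# equivalent to a disjunction over node literals, so the model compiles to
# clause form: "and"/"or" rows become clauses, the copy equality becomes
# two clauses, fixings become unit clauses, and complement rows vanish
# into the literal mapping (F_x == NOT T_x).  A depth-first branch and
# bound with unit propagation and an objective lower bound (the count of
# already-falsified objective compounds; remaining terms are nonnegative)
# then enumerates implicitly.  The level subsystem consists of conditional
# difference constraints; once all binaries are fixed it is an ordinary
# difference-constraint system, decided exactly (and constructively) by a
# longest-path peeling over the support graph at each complete leaf.
#
# Branching is on the first unassigned variable in a fixed order (enzymes,
# then compounds, then reactions, each in declaration order), value 1
# first, and an incumbent is replaced only when strictly better, so the
# returned optimum is deterministic.

compile_clauses <- function(model, idx) {
  lit <- function(vn) {
    neg <- startsWith(vn, "F_")
    i <- idx[substring(vn, 3L)]
    ifelse(neg, -i, i)
  }
  clauses <- list()
  for (row in model$rows) {
    lab <- row$label
    if (lab == "complement" || startsWith(lab, "level") ||
        startsWith(lab, "support")) next
    if (lab %in% c("and", "or")) {
      clauses[[length(clauses) + 1L]] <- unname(lit(names(row$coef)))
    } else if (lab == "copy") {
      a <- lit(names(row$coef)[row$coef > 0])
      b <- lit(names(row$coef)[row$coef < 0])
      clauses[[length(clauses) + 1L]] <- c(a, -b)
      clauses[[length(clauses) + 1L]] <- c(-a, b)
    } else { # source / target / fix_const: single-variable equality to 1
      clauses[[length(clauses) + 1L]] <- unname(lit(names(row$coef)))
    }
  }
  clauses
}

unit_propagate <- function(x, clauses) {
  repeat {
    changed <- FALSE
    for (cl in clauses) {
      v <- x[abs(cl)]
      if (any((cl > 0L & v == 1L) | (cl < 0L & v == 0L), na.rm = TRUE)) next
      un <- which(is.na(v))
      if (!length(un)) return(list(ok = FALSE))
      if (length(un) == 1L) {
        l <- cl[un]
        x[abs(l)] <- if (l > 0L) 1L else 0L
        changed <- TRUE
      }
    }
    if (!changed) return(list(ok = TRUE, x = x))
  }
}

# Feasibility of the level (acyclic-support) subsystem for a complete 0/1
# assignment: every value-1 reaction must have all inputs leveled below it
# and every value-1 non-source compound must have a leveled value-1
# producer.  Constructs levels greedily; feasible iff all value-1 nodes
# get one (equivalently, iff the assignment's support is acyclic).
acyclic_support_ok <- function(net, x, idx, src, prods) {
  lev <- stats::setNames(rep(NA_real_, length(x)), names(idx))
  lev[src] <- 0
  repeat {
    changed <- FALSE
    for (r in net$reactions) {
      if (x[idx[[r$id]]] != 1L || !is.na(lev[[r$id]])) next
      li <- lev[r$inputs]
      if (!anyNA(li)) {
        lev[[r$id]] <- if (length(li)) max(li) + 1 else 0
        changed <- TRUE
      }
    }
    for (cid in setdiff(net$compounds, src)) {
      if (x[idx[[cid]]] != 1L || !is.na(lev[[cid]])) next
      pr <- prods[[cid]]
      pr_on <- pr[x[idx[pr]] == 1L]
      lp <- lev[pr_on]
      lp <- lp[!is.na(lp)]
      if (length(lp)) {
        lev[[cid]] <- min(lp) + 1
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  on <- names(idx)[x == 1L]
  on <- setdiff(intersect(on, c(net$compounds, names(net$reactions))), src)
  !anyNA(lev[on])
}

solve_ilp <- function(model, time_limit = Inf) {
  net <- model$network
  nodes <- c(net$compounds, names(net$reactions), net$enzymes)
  idx <- stats::setNames(seq_along(nodes), nodes)
  clauses <- compile_clauses(model, idx)
  obj_idx <- unname(idx[substring(names(model$objective), 3L)])
  order_idx <- unname(c(idx[net$enzymes], idx[net$compounds],
                        idx[names(net$reactions)]))
  use_levels <- identical(model$acyclic_encoding, "levels")
  src <- identify_sources(net)
  prods <- producers_of(net)

  st <- new.env(parent = emptyenv())
  st$best_obj <- Inf
  st$best_x <- NULL
  st$nodes <- 0L
  st$timed_out <- FALSE
  t0 <- Sys.time()

  rec <- function(x) {
    if (st$timed_out) return(invisible())
    st$nodes <- st$nodes + 1L
    if (st$nodes %% 512L == 0L &&
        as.numeric(Sys.time() - t0, units = "secs") > time_limit) {
      st$timed_out <- TRUE
      return(invisible())
    }
    up <- unit_propagate(x, clauses)
    if (!up$ok) return(invisible())
    x <- up$x
    lb <- sum(x[obj_idx] == 0L, na.rm = TRUE)
    if (lb >= st$best_obj) return(invisible())
    free <- order_idx[is.na(x[order_idx])]
    if (!length(free)) {
      if (use_levels && !acyclic_support_ok(net, x, idx, src, prods))
        return(invisible())
      st$best_obj <- lb
      st$best_x <- x
      return(invisible())
    }
    j <- free[1L]
    x1 <- x; x1[j] <- 1L; rec(x1)
    x0 <- x; x0[j] <- 0L; rec(x0)
    invisible()
  }
  rec(rep(NA_integer_, length(nodes)))

  if (st$timed_out && is.infinite(st$best_obj))
    stop("time limit of ", time_limit, " s reached with no incumbent",
         call. = FALSE)
  if (st$timed_out)
    stop("time limit of ", time_limit, " s reached (best incumbent damage ",
         st$best_obj, ", optimality unproven)", call. = FALSE)
  if (is.infinite(st$best_obj))
    return(list(status = "infeasible"))
  list(status = "optimal",
       objective = as.integer(st$best_obj),
       x = stats::setNames(st$best_x, nodes),
       nodes_explored = st$nodes)
}

#' Solve enzyme combination identification by integer programming
#'
#' Builds the 0/1 model of [build_ilp()] and optimizes it exactly with the
#' package's built-in branch-and-bound backend (`"bnb"`, the only backend
#' available; unit propagation over the clause-form rows, objective
#' lower-bound pruning, and exact leaf checking of the level subsystem by
#' longest-path construction).  The optimum is read back as the inhibited
#' enzyme set `{e : T_e = 0}`, the damage (objective value), and the
#' knocked-out non-target compounds `{c : T_c = 0}`, and is re-checked
#' against the ground-truth semantics with [verify_solution()] before
#' being returned.  If verification fails under
#' `acyclic_encoding = "none"` -- the signature of a self-sustaining cycle
#' spuriously counted as producible by the consistency-only rows -- the
#' solve is retried with the level encoding.
#'
#' @param instance an `eci_instance`.
#' @param backend MILP backend name; only `"bnb"` is available.
#' @param acyclic_encoding `"levels"` (default; optimal solutions agree
#'   with the least fixed point on every network) or `"none"` (the literal
#'   consistency-only system plus post-hoc verification).
#' @param time_limit wall-clock limit in seconds; on expiry an error is
#'   raised reporting the best incumbent damage, if any.
#' @param verify re-check the optimum by propagation (default `TRUE`);
#'   disable to inspect the raw consistency-only optimum on cyclic
#'   networks.
#' @return An `eci_solution` with `status` `"optimal"` or `"infeasible"`.
#' @examples
#' solve_eci(demo_instance())
#' @export
solve_eci <- function(instance, backend = "bnb",
                      acyclic_encoding = c("levels", "none"),
                      time_limit = Inf, verify = TRUE) {
  stopifnot(inherits(instance, "eci_instance"))
  acyclic_encoding <- match.arg(acyclic_encoding)
  if (!identical(backend, "bnb"))
    stop("unknown backend '", backend, "'; available backends: bnb",
         call. = FALSE)
  model <- build_ilp(instance, acyclic_encoding)
  res <- solve_ilp(model, time_limit)
  if (identical(res$status, "infeasible"))
    return(new_eci_solution(character(), NA_integer_, character(), NULL,
                            "infeasible", paste0("ilp-", acyclic_encoding)))
  net <- instance$network
  x <- res$x
  inhibited <- net$enzymes[x[net$enzymes] == 0L]
  knocked <- setdiff(net$compounds[x[net$compounds] == 0L],
                     instance$targets)
  assignment <- structure(as.integer(x), names = names(x),
                          class = "boolean_assignment", inhibited = inhibited)
  sol <- new_eci_solution(inhibited, res$objective, knocked, assignment,
                          "optimal", paste0("ilp-", acyclic_encoding))
  if (verify && !verify_solution(instance, sol)) {
    if (acyclic_encoding == "none")
      return(solve_eci(instance, backend, "levels", time_limit, verify))
    stop("internal error: verified solve with level encoding disagrees ",
         "with propagation", call. = FALSE)
  }
  sol
}
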