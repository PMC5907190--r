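# Variable naming: each node x gets a complementary binary pair T_x / F_x
# (T_x = 1 iff the node's Boolean value is 1).  Level and support variables
# of the acyclic encoding are L_x and S_<compound>__<reaction>.
var_T <- function(id) paste0("T_", id)
var_F <- function(id) paste0("F_", id)
var_L <- function(id) paste0("L_", id)
var_S <- function(cid, rid) paste0("S_", cid, "__", rid)

ilp_row <- function(coef, sense, rhs, label) {
  list(coef = coef, sense = sense, rhs = rhs, label = label)
}

#' Linear rows for a Boolean AND definition
#'
#' Encodes `out = in_1 AND in_2 AND ... AND in_k` over complementary T/F
#' binary pairs.  The defining biconditional in conjunctive normal form is
#' `(out OR !in_1 OR ... OR !in_k) AND (!out OR in_1) AND ... AND
#' (!out OR in_k)`, and each disjunction becomes the linear row "sum of the
#' corresponding T/F variables >= 1": one row
#' `T_out + F_in1 + ... + F_ink >= 1` plus, per input, `F_out + T_in >= 1`.
#' With a single input the pair collapses to the copy equality
#' `T_out = T_in`.
#'
#' @param output node id being defined.
#' @param inputs non-empty character vector of input node ids.
#' @return List of linear rows (each a list with `coef`, a named
#'   coefficient vector; `sense`; `rhs`; `label`).
#' @seealso [clause_or()], [build_ilp()]
#' @export
clause_and <- function(output, inputs) {
  inputs <- as.character(inputs)
  if (!length(inputs))
    stop("clause_and() requires at least one input; a reaction with no ",
         "inputs and no enzymes is constant 1 and is fixed by the caller",
         call. = FALSE)
  if (length(inputs) == 1)
    return(list(ilp_row(stats::setNames(c(1, -1),
                                        c(var_T(output), var_T(inputs))),
                        "==", 0, "copy")))
  rows <- list(ilp_row(
    stats::setNames(rep(1, 1 + length(inputs)),
                    c(var_T(output), var_F(inputs))), ">=", 1, "and"))
  for (u in inputs)
    rows <- c(rows, list(ilp_row(
      stats::setNames(c(1, 1), c(var_F(output), var_T(u))), ">=", 1, "and")))
  rows
}

#' Linear rows for a Boolean OR definition
#'
#' Encodes `out = in_1 OR ... OR in_k`: CNF
#' `(!out OR in_1 OR ... OR in_k) AND (out OR !in_1) AND ...` gives the row
#' `F_out + T_in1 + ... + T_ink >= 1` plus, per input,
#' `T_out + F_in >= 1`; a single input collapses to `T_out = T_in`.
#'
#' @inheritParams clause_and
#' @return List of linear rows as in [clause_and()].
#' @export
clause_or <- function(output, inputs) {
  inputs <- as.character(inputs)
  if (!length(inputs))
    stop("clause_or() requires at least one input", call. = FALSE)
  if (length(inputs) == 1)
    return(list(ilp_row(stats::setNames(c(1, -1),
                                        c(var_T(output), var_T(inputs))),
                        "==", 0, "copy")))
  rows <- list(ilp_row(
    stats::setNames(rep(1, 1 + length(inputs)),
                    c(var_F(output), var_T(inputs))), ">=", 1, "or"))
  for (u in inputs)
    rows <- c(rows, list(ilp_row(
      stats::setNames(c(1, 1), c(var_T(output), var_F(u))), ">=", 1, "or")))
  rows
}

#' Build the integer linear program for an ECI instance
#'
#' Constructs the 0/1 model over one complementary T/F binary pair per
#' node: per reaction a [clause_and()] over its inputs and enzymes; per
#' non-source compound a [clause_or()] over its producing reactions; per
#' source `T = 1`; per target `F = 1`; per node the complement row
#' `T + F = 1`.  The objective minimizes the sum of `F` over non-target
#' compounds, i.e. the damage (targets are excluded: their `F` is already
#' fixed to 1, so including them would only shift the objective by a
#' constant).
#'
#' The base rows only enforce *consistency* of the assignment, which on a
#' cyclic network admits self-sustaining cycles counted as producible --
#' exactly what a damage-minimizing objective would exploit.  With
#' `acyclic_encoding = "levels"` (the default in [solve_eci()]) the model
#' additionally carries integer level variables `L` in `[0, m+n]` and
#' per-edge support indicators: every producible non-source compound must
#' select an active producing reaction of strictly lower level, and every
#' active reaction must sit strictly above all of its inputs (big-M form,
#' `M = m+n+1`), with sources at level 0.  Circular support is thereby
#' infeasible and optimal solutions coincide with the least fixed point.
#'
#' @param instance an `eci_instance`.
#' @param acyclic_encoding `"levels"` or `"none"` (the literal
#'   consistency-only system).
#' @return An object of class `ilp_model` with `variables` (a data frame
#'   with columns `name`, `node`, `role`, `type`, `lb`, `ub`), `rows`,
#'   `objective` (named coefficient vector), `sense`, plus the instance
#'   pieces needed by the solver.
#' @examples
#' m <- build_ilp(demo_instance(), acyclic_encoding = "none")
#' m
#' @export
build_ilp <- function(instance, acyclic_encoding = c("levels", "none")) {
  stopifnot(inherits(instance, "eci_instance"))
  acyclic_encoding <- match.arg(acyclic_encoding)
  net <- instance$network
  targets <- instance$targets
  src <- identify_sources(net)
  prods <- producers_of(net)
  nodes <- c(net$compounds, names(net$reactions), net$enzymes)

  rows <- list()
  for (r in net$reactions) {
    ins <- c(r$inputs, r$enzymes)
    rows <- c(rows, if (length(ins)) clause_and(r$id, ins) else
      list(ilp_row(stats::setNames(1, var_T(r$id)), "==", 1, "fix_const")))
  }
  for (cid in setdiff(net$compounds, src))
    rows <- c(rows, clause_or(cid, prods[[cid]]))
  for (cid in src)
    rows <- c(rows, list(ilp_row(stats::setNames(1, var_T(cid)), "==", 1,
                                 "source")))
  for (t in targets)
    rows <- c(rows, list(ilp_row(stats::setNames(1, var_F(t)), "==", 1,
                                 "target")))
  for (x in nodes)
    rows <- c(rows, list(ilp_row(stats::setNames(c(1, 1),
                                                 c(var_T(x), var_F(x))),
                                 "==", 1, "complement")))

  vars <- data.frame(
    name = c(var_T(nodes), var_F(nodes)),
    node = c(nodes, nodes),
    role = "tf", type = "binary", lb = 0,
    ub = 1, stringsAsFactors = FALSE)

  if (acyclic_encoding == "levels") {
    mn <- length(net$compounds) + length(net$reactions)
    M <- mn + 1
    lev_nodes <- c(net$compounds, names(net$reactions))
    vars <- rbind(vars, data.frame(
      name = var_L(lev_nodes), node = lev_nodes, role = "level",
      type = "integer", lb = 0, ub = mn, stringsAsFactors = FALSE))
    for (cid in src)
      rows <- c(rows, list(ilp_row(stats::setNames(1, var_L(cid)), "==", 0,
                                   "level_source")))
    for (cid in setdiff(net$compounds, src)) {
      pr <- prods[[cid]]
      if (length(pr) == 1) {
        rows <- c(rows, list(ilp_row(
          stats::setNames(c(1, -1, M), c(var_L(cid), var_L(pr), var_F(cid))),
          ">=", 1, "level_copy")))
      } else {
        svars <- var_S(cid, pr)
        vars <- rbind(vars, data.frame(
          name = svars, node = cid, role = "support", type = "binary",
          lb = 0, ub = 1, stringsAsFactors = FALSE))
        rows <- c(rows, list(ilp_row(
          stats::setNames(c(rep(1, length(svars)), -1),
                          c(svars, var_T(cid))), ">=", 0, "support_cover")))
        for (i in seq_along(pr)) {
          rows <- c(rows, list(
            ilp_row(stats::setNames(c(1, -1), c(var_T(pr[i]), svars[i])),
                    ">=", 0, "support_link"),
            ilp_row(stats::setNames(c(1, -1, -M),
                                    c(var_L(cid), var_L(pr[i]), svars[i])),
                    ">=", 1 - M, "level_edge")))
        }
      }
    }
    for (r in net$reactions)
      for (u in r$inputs)
        rows <- c(rows, list(ilp_row(
          stats::setNames(c(1, -1, M), c(var_L(r$id), var_L(u), var_F(r$id))),
          ">=", 1, "level_reaction")))
  }

  objective <- stats::setNames(rep(1, length(setdiff(net$compounds, targets))),
                               var_F(setdiff(net$compounds, targets)))
  structure(list(variables = vars, rows = rows, objective = objective,
                 sense = "min", network = net, targets = targets,
                 acyclic_encoding = acyclic_encoding),
            class = "ilp_model")
}

#' @export
print.ilp_model <- function(x, ...) {
  cat(sprintf("ILP model: %d variables (%d binary T/F pairs), %d rows, %s\n",
              nrow(x$variables), sum(x$variables$role == "tf") / 2,
              length(x$rows),
              if (x$acyclic_encoding == "levels")
                "acyclic-support (level) encoding" else
                "consistency-only encoding"))
  cat("  objective: minimize damage over",
      length(x$objective), "non-target compounds\n")
  invisible(x)
}

#' Export a model in CPLEX LP text format
#'
#' Writes the constructed model (objective, rows, bounds, integrality) in
#' the standard LP file format, mainly for debugging and for feeding the
#' model to an external solver.
#'
#' @param model an `ilp_model`.
#' @param file path to write to, or `NULL` to return the text.
#' @return The LP text, invisibly when `file` is given.
#' @export
write_lp <- function(model, file = NULL) {
  term <- function(coef) {
    paste(vapply(seq_along(coef), function(i) {
      v <- unname(coef[i])
      sprintf("%s %g %s", if (v < 0) "-" else "+", abs(v), names(coef)[i])
    }, character(1)), collapse = " ")
  }
  lines <- c("Minimize", paste(" obj:", term(model$objective)), "Subject To")
  for (i in seq_along(model$rows)) {
    r <- model$rows[[i]]
    op <- c(">=" = ">=", "<=" = "<=", "==" = "=")[[r$sense]]
    lines <- c(lines, sprintf(" c%d: %s %s %g", i, term(r$coef), op, r$rhs))
  }
  v <- model$variables
  ints <- v$name[v$type == "integer"]
  if (length(ints)) {
    lines <- c(lines, "Bounds",
               sprintf(" %g <= %s <= %g", v$lb[v$type == "integer"], ints,
                       v$ub[v$type == "integer"]),
               "Generals", paste("", paste(ints, collapse = " ")))
  }
  bins <- v$name[v$type == "binary"]
  lines <- c(lines, "Binaries", paste("", paste(bins, collapse = " ")), "End")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(text, file, sep = "")
    return(invisible(text))
  }
  text
}

#' Check a claimed ECI solution against the ground-truth semantics
#'
#' Re-propagates the network under the claimed inhibited set and verifies
#' that every target has value 0, that the knocked-out set is exactly the
#' set of non-target compounds with value 0 in the least fixed point, and
#' that the damage equals its size.
#'
#' @param instance an `eci_instance`.
#' @param solution an `eci_solution`.
#' @return `TRUE` or `FALSE`.
#' @export
verify_solution <- function(instance, solution) {
  if (!inherits(solution, "eci_solution") ||
      !identical(solution$status, "optimal")) return(FALSE)
  net <- instance$network
  val <- propagate(net, solution$inhibited)
  knocked <- setdiff(net$compounds[val[net$compounds] == 0L],
                     instance$targets)
  all(val[instance$targets] == 0L) &&
    setequal(knocked, solution$knocked_out) &&
    identical(as.integer(solution$damage), length(knocked))
}
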