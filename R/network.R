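#' Construct a Boolean metabolic network
#'
#' A metabolic network is modelled as a directed graph over three disjoint
#' node classes: compounds, reactions and enzymes.  A reaction is an AND
#' node: it is active if and only if all of its input compounds are
#' producible and all of its catalyzing enzymes are uninhibited.  A compound
#' is an OR node: it is producible if and only if at least one reaction
#' producing it is active.  Compounds with no producing reaction are
#' *sources* (seed compounds) and are always producible.
#'
#' Identifiers are case-sensitive opaque strings, so KEGG-style ids such as
#' `"C02165"` or `"E3.3.2.6"` are legal.  Sources are derived (a compound is
#' a source precisely when no reaction produces it), never declared, which
#' removes a whole class of inconsistent inputs.
#'
#' @param compounds character vector of compound identifiers.
#' @param reactions list of reaction records; each record is a list with
#'   elements `id` (string), `inputs` (character vector of compound ids,
#'   possibly empty), `enzymes` (character vector of enzyme ids, possibly
#'   empty -- uncatalyzed reactions are permitted), and `products`
#'   (non-empty character vector of compound ids).
#' @param enzymes character vector of enzyme identifiers.
#'
#' @return An object of class `metabolic_network` with elements `compounds`,
#'   `reactions` (named by reaction id) and `enzymes`, declaration order
#'   preserved throughout.
#' @seealso [validate_network()], [identify_sources()], [read_network()],
#'   [demo_network()]
#' @examples
#' net <- metabolic_network(
#'   compounds = c("A", "B"),
#'   reactions = list(list(id = "R1", inputs = "A", enzymes = "E1",
#'                         products = "B")),
#'   enzymes = "E1")
#' identify_sources(net)
#' @export
metabolic_network <- function(compounds, reactions = list(), enzymes = character()) {
  reactions <- lapply(reactions, function(r) {
    list(id       = as.character(r$id),
         inputs   = as.character(r$inputs %||% character()),
         enzymes  = as.character(r$enzymes %||% character()),
         products = as.character(r$products %||% character()))
  })
  net <- structure(
    list(compounds = as.character(compounds),
         reactions = stats::setNames(reactions,
                                     vapply(reactions, `[[`, "", "id")),
         enzymes   = as.character(enzymes)),
    class = "metabolic_network")
  viol <- validate_network(net)
  if (length(viol))
    stop("invalid metabolic network:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a metabolic network
#'
#' Checks every structural invariant of the model: identifier uniqueness
#' within each class, pairwise disjointness of the compound / reaction /
#' enzyme identifier sets, non-empty product sets, and that every compound
#' or enzyme referenced by a reaction is declared.  (The remaining model
#' condition -- every non-source compound has at least one producing
#' reaction -- holds by construction because sources are *defined* as the
#' compounds with no producer.)
#'
#' @param network a `metabolic_network` (or a structurally similar list;
#'   violations are reported rather than thrown).
#' @return Character vector of human-readable violations; empty when the
#'   network is valid.
#' @export
validate_network <- function(network) {
  viol <- character()
  comps <- network$compounds
  enz   <- network$enzymes
  rxns  <- network$reactions
  rids  <- vapply(rxns, `[[`, "", "id")

  dup <- function(x, what) {
    d <- unique(x[duplicated(x)])
    if (length(d)) sprintf("duplicate %s id '%s'", what, d) else character()
  }
  viol <- c(viol, dup(comps, "compound"), dup(enz, "enzyme"),
            dup(rids, "reaction"))

  for (x in intersect(comps, rids))
    viol <- c(viol, sprintf("id '%s' declared as both compound and reaction", x))
  for (x in intersect(comps, enz))
    viol <- c(viol, sprintf("id '%s' declared as both compound and enzyme", x))
  for (x in intersect(rids, enz))
    viol <- c(viol, sprintf("id '%s' declared as both reaction and enzyme", x))

  for (r in rxns) {
    if (!length(r$products))
      viol <- c(viol, sprintf("reaction '%s' has no products", r$id))
    for (u in setdiff(c(r$inputs, r$products), comps))
      viol <- c(viol, sprintf("reaction '%s' references undeclared compound '%s'",
                              r$id, u))
    for (e in setdiff(r$enzymes, enz))
      viol <- c(viol, sprintf("reaction '%s' references undeclared enzyme '%s'",
                              r$id, e))
  }
  viol
}

#' Identify source compounds
#'
#' Sources are the compounds produced by no reaction; in the Boolean model
#' they are the seed metabolites, always assigned value 1.
#'
#' @param network a valid `metabolic_network`.
#' @return Character vector of source compound ids, in declaration order.
#' @export
identify_sources <- function(network) {
  produced <- unique(unlist(lapply(network$reactions, `[[`, "products")))
  setdiff(network$compounds, produced)
}

# producing reactions per compound, as a named list (declaration order)
producers_of <- function(network) {
  out <- stats::setNames(vector("list", length(network$compounds)),
                         network$compounds)
  for (r in network$reactions)
    for (p in r$products)
      out[[p]] <- c(out[[p]], r$id)
  out
}

#' @export
print.metabolic_network <- function(x, ...) {
  src <- identify_sources(x)
  cat(sprintf("Boolean metabolic network: %d compounds, %d reactions, %d enzymes\n",
              length(x$compounds), length(x$reactions), length(x$enzymes)))
  cat("  sources:", if (length(src)) paste(src, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Construct an enzyme-combination-identification instance
#'
#' Pairs a network with the non-empty set of target compounds whose
#' production must be stopped.  Targets that are source compounds are
#' rejected immediately: a seed compound is producible under every enzyme
#' inhibition, so such an instance is provably infeasible and is better
#' reported at construction than as solver infeasibility.
#'
#' @param network a valid `metabolic_network`.
#' @param targets non-empty character vector of target compound ids.
#' @return An object of class `eci_instance` with elements `network` and
#'   `targets`.
#' @seealso [solve_eci()], [brute_force_eci()]
#' @export
eci_instance <- function(network, targets) {
  stopifnot(inherits(network, "metabolic_network"))
  targets <- unique(as.character(targets))
  if (!length(targets)) stop("at least one target compound is required", call. = FALSE)
  unknown <- setdiff(targets, network$compounds)
  if (length(unknown))
    stop("target '", unknown[1], "' is not a declared compound", call. = FALSE)
  on_src <- intersect(targets, identify_sources(network))
  if (length(on_src))
    stop("target '", on_src[1], "' is a source compound and can never be ",
         "stopped by enzyme inhibition", call. = FALSE)
  structure(list(network = network, targets = targets), class = "eci_instance")
}

#' @export
print.eci_instance <- function(x, ...) {
  print(x$network)
  cat("  targets:", paste(x$targets, collapse = ", "), "\n")
  invisible(x)
}
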