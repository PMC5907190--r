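#' Construct an undirected graph for minimum edge cover
#'
#' Minimum edge cover (MEC) asks for the smallest edge set such that every
#' vertex is incident to a chosen edge; it is the combinatorial core from
#' which minimum-damage enzyme identification inherits its hardness, via
#' the reduction in [reduce_mec_to_eci()].
#'
#' @param vertices character vector of vertex ids.
#' @param edges named list mapping edge id to a length-2 character vector
#'   of distinct endpoint vertex ids (self-loops are rejected).
#' @return An object of class `mec_graph`.
#' @export
mec_graph <- function(vertices, edges) {
  vertices <- as.character(vertices)
  edges <- lapply(edges, as.character)
  if (is.null(names(edges)) || any(!nzchar(names(edges))))
    stop("every edge needs an id (a named list)", call. = FALSE)
  if (anyDuplicated(vertices))
    stop("duplicate vertex id", call. = FALSE)
  if (anyDuplicated(names(edges)))
    stop("duplicate edge id", call. = FALSE)
  for (eid in names(edges)) {
    e <- edges[[eid]]
    if (length(e) != 2 || e[1] == e[2])
      stop("edge '", eid, "' must join two distinct vertices", call. = FALSE)
    if (!all(e %in% vertices))
      stop("edge '", eid, "' references an undeclared vertex", call. = FALSE)
  }
  structure(list(vertices = vertices, edges = edges), class = "mec_graph")
}

#' @export
print.mec_graph <- function(x, ...) {
  cat(sprintf("Undirected graph: %d vertices, %d edges\n",
              length(x$vertices), length(x$edges)))
  invisible(x)
}

isolated_vertices <- function(graph) {
  setdiff(graph$vertices, unique(unlist(graph$edges)))
}

#' Parse an edge-list graph document
#'
#' Line-oriented format: `edge <id> <u> <v>` records plus optional
#' `vertex <id>` declarations (needed only for isolated vertices);
#' `#` starts a comment.
#'
#' @param text a string or character vector of lines.
#' @return An `mec_graph`.
#' @export
parse_mec_graph <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  vertices <- character(); edges <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    if (!nzchar(trimws(line))) next
    tok <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (tok[1] == "vertex" && length(tok) == 2) {
      vertices <- c(vertices, tok[2])
    } else if (tok[1] == "edge" && length(tok) == 4) {
      edges[[tok[2]]] <- tok[3:4]
      vertices <- c(vertices, tok[3:4])
    } else {
      stop(sprintf("line %d: expected 'vertex <id>' or 'edge <id> <u> <v>'", i),
           call. = FALSE)
    }
  }
  mec_graph(unique(vertices), edges)
}

#' Reduce minimum edge cover to enzyme combination identification
#'
#' Builds, in time linear in the graph size, an ECI instance whose
#' minimum damage equals the minimum edge cover size: one compound `c_<e>`
#' per edge, one reaction `r_<v>` per vertex taking as inputs the
#' compounds of its incident edges and producing the single target
#' compound `c_t`.  Stopping `c_t` forces every vertex-reaction off, which
#' requires knocking out at least one incident edge-compound per vertex --
#' an edge cover -- and conversely.  So that "removing compound `c_<e>`"
#' is an enzyme decision within the standard formalism, each edge-compound
#' is produced by its own virtual reaction `rhat_<e>` fed from one
#' universal source `s` and gated by a virtual enzyme `ehat_<e>`:
#' inhibiting `ehat_<e>` removes exactly `c_<e>`.
#'
#' Vertex reaction indegrees equal the corresponding vertex degrees, and
#' every knocked-out compound in an optimal solution is an edge-compound.
#'
#' @param graph an `mec_graph` with no isolated vertex (otherwise no edge
#'   cover, hence no feasible inhibition, exists).
#' @return An `eci_instance` with target `c_t`.
#' @seealso [brute_force_mec()]
#' @export
reduce_mec_to_eci <- function(graph) {
  stopifnot(inherits(graph, "mec_graph"))
  iso <- isolated_vertices(graph)
  if (length(iso))
    stop("vertex '", iso[1], "' is isolated; the graph has no edge cover",
         call. = FALSE)
  eids <- names(graph$edges)
  compounds <- c("s", paste0("c_", eids), "c_t")
  enzymes <- paste0("ehat_", eids)
  vertex_rxns <- lapply(graph$vertices, function(v) {
    incident <- eids[vapply(graph$edges, function(e) v %in% e, logical(1))]
    list(id = paste0("r_", v), inputs = paste0("c_", incident),
         enzymes = character(), products = "c_t")
  })
  virtual_rxns <- lapply(eids, function(e)
    list(id = paste0("rhat_", e), inputs = "s",
         enzymes = paste0("ehat_", e), products = paste0("c_", e)))
  net <- metabolic_network(compounds, c(vertex_rxns, virtual_rxns), enzymes)
  eci_instance(net, "c_t")
}

#' Exact minimum edge cover by enumeration
#'
#' Enumerates edge subsets by increasing cardinality (starting at the
#' `ceiling(n/2)` lower bound) in lexicographic id order and returns the
#' first cover found, which is therefore a deterministic minimum.
#'
#' @param graph an `mec_graph` with no isolated vertex.
#' @param max_edges capacity guard; enumeration is refused for graphs with
#'   more edges than this (default 24).
#' @return A list with `size` and `cover` (edge ids).
#' @export
brute_force_mec <- function(graph, max_edges = 24) {
  stopifnot(inherits(graph, "mec_graph"))
  iso <- isolated_vertices(graph)
  if (length(iso))
    stop("vertex '", iso[1], "' is isolated; no edge cover exists",
         call. = FALSE)
  eids <- sort(names(graph$edges))
  m <- length(eids)
  if (m > max_edges)
    stop("enumeration over ", m, " edges exceeds the capacity guard",
         call. = FALSE)
  nverts <- length(graph$vertices)
  for (k in max(1L, ceiling(nverts / 2)):m) {
    for (sel in utils::combn(eids, k, simplify = FALSE)) {
      covered <- unique(unlist(graph$edges[sel]))
      if (length(covered) == nverts)
        return(list(size = k, cover = sel))
    }
  }
  stop("internal error: full edge set is not a cover", call. = FALSE)
}
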