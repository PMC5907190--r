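#' Parse a metabolic network document
#'
#' Two dialects are accepted and auto-detected:
#'
#' * a line-oriented TSV format: `compound <id>`, `enzyme <id>`, and
#'   `reaction <id> inputs=<c1,c2,...> enzymes=<e1,...> products=<c1,...>`
#'   records (whitespace-separated fields; `#` starts a comment; an empty
#'   value after `=` denotes the empty set);
#' * a JSON document with top-level keys `compounds`, `enzymes` and
#'   `reactions`, each reaction an object with `id`, `inputs`, `enzymes`
#'   and `products` arrays.
#'
#' @param text the document, as a single string or a character vector of
#'   lines.
#' @return A valid `metabolic_network`; declaration order is preserved, so
#'   parsing is deterministic.
#' @seealso [write_network()], [read_network()]
#' @export
parse_network <- function(text) {
  joined <- paste(text, collapse = "\n")
  if (grepl("^\\s*\\{", joined)) parse_network_json(joined)
  else parse_network_tsv(strsplit(joined, "\n", fixed = TRUE)[[1]])
}

parse_network_tsv <- function(lines) {
  compounds <- character(); enzymes <- character(); reactions <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    if (!nzchar(trimws(line))) next
    tok <- strsplit(trimws(line), "[ \t]+")[[1]]
    kind <- tok[1]
    if (kind == "compound") {
      if (length(tok) != 2)
        stop(sprintf("line %d: expected 'compound <id>'", i), call. = FALSE)
      compounds <- c(compounds, tok[2])
    } else if (kind == "enzyme") {
      if (length(tok) != 2)
        stop(sprintf("line %d: expected 'enzyme <id>'", i), call. = FALSE)
      enzymes <- c(enzymes, tok[2])
    } else if (kind == "reaction") {
      if (length(tok) < 3)
        stop(sprintf("line %d: expected 'reaction <id> key=value ...'", i),
             call. = FALSE)
      rec <- list(id = tok[2], inputs = character(),
                  enzymes = character(), products = character())
      for (kv in tok[-(1:2)]) {
        m <- regmatches(kv, regexec("^(inputs|enzymes|products)=(.*)$", kv))[[1]]
        if (!length(m))
          stop(sprintf("line %d: malformed field '%s'", i, kv), call. = FALSE)
        vals <- strsplit(m[3], ",", fixed = TRUE)[[1]]
        rec[[m[2]]] <- vals[nzchar(vals)]
      }
      reactions <- c(reactions, list(rec))
    } else {
      stop(sprintf("line %d: unknown record type '%s'", i, kind), call. = FALSE)
    }
  }
  metabolic_network(compounds, reactions, enzymes)
}

parse_network_json <- function(text) {
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  rxns <- lapply(doc$reactions, function(r)
    list(id       = as.character(r$id),
         inputs   = as.character(unlist(r$inputs)),
         enzymes  = as.character(unlist(r$enzymes)),
         products = as.character(unlist(r$products))))
  metabolic_network(as.character(unlist(doc$compounds)), rxns,
                    as.character(unlist(doc$enzymes)))
}

#' Serialize a metabolic network
#'
#' Emits the canonical form of either dialect: records in declaration
#' order, fields in the fixed order `inputs`, `enzymes`, `products`.
#' Serialization is idempotent -- `write_network(parse_network(d))` equals
#' `write_network(x)` for any valid `x` that produced `d` -- and
#' `parse_network(write_network(x))` is structurally identical to `x`.
#'
#' @param network a valid `metabolic_network`.
#' @param file optional path; when given the document is written there.
#' @param format `"tsv"` (default) or `"json"`.
#' @return The document as a single string, invisibly when `file` is given.
#' @export
write_network <- function(network, file = NULL, format = c("tsv", "json")) {
  format <- match.arg(format)
  doc <- if (format == "json") {
    as.character(jsonlite::toJSON(list(
      compounds = network$compounds,
      enzymes   = network$enzymes,
      reactions = lapply(unname(network$reactions), function(r)
        list(id = jsonlite::unbox(r$id), inputs = r$inputs,
             enzymes = r$enzymes, products = r$products))),
      pretty = TRUE))
  } else {
    lines <- c(
      if (length(network$compounds))
        paste("compound", network$compounds, sep = "\t"),
      if (length(network$enzymes))
        paste("enzyme", network$enzymes, sep = "\t"),
      vapply(network$reactions, function(r)
        paste("reaction", r$id,
              paste0("inputs=", paste(r$inputs, collapse = ",")),
              paste0("enzymes=", paste(r$enzymes, collapse = ",")),
              paste0("products=", paste(r$products, collapse = ",")),
              sep = "\t"),
        character(1), USE.NAMES = FALSE))
    paste0(paste(lines, collapse = "\n"), "\n")
  }
  if (!is.null(file)) {
    writeLines(doc, file, sep = "")
    return(invisible(doc))
  }
  doc
}

#' Read a metabolic network from a file
#'
#' The JSON dialect is assumed for `.json` paths, the TSV dialect otherwise
#' (content-based detection still applies, so a JSON document under any
#' extension parses too).
#'
#' @param file path to a network file.
#' @return A valid `metabolic_network`.
#' @export
read_network <- function(file) {
  parse_network(readLines(file, warn = FALSE))
}
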