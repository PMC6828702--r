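# Minimal RDF triple model. A graph is a data.frame of triples plus a prefix
# map; terms are encoded positionally so that validation and mutation can be
# vectorised over plain character columns.
#
# Encoding:
#   s      subject: absolute IRI, or blank node as "_:<label>"
#   p      predicate: absolute IRI
#   o      object: IRI, "_:<label>", or literal lexical form
#   o_kind one of "iri", "bnode", "literal"
#   dt     datatype IRI for typed literals, else NA
#   lang   language tag, else NA

NS_RDF  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
NS_OWL  <- "http://www.w3.org/2002/07/owl#"
NS_XSD  <- "http://www.w3.org/2001/XMLSchema#"
NS_SKOS <- "http://www.w3.org/2004/02/skos/core#"

RDF_TYPE  <- paste0(NS_RDF, "type")
RDF_FIRST <- paste0(NS_RDF, "first")
RDF_REST  <- paste0(NS_RDF, "rest")
RDF_NIL   <- paste0(NS_RDF, "nil")

XSD_STRING  <- paste0(NS_XSD, "string")
XSD_INTEGER <- paste0(NS_XSD, "integer")
XSD_DOUBLE  <- paste0(NS_XSD, "double")
XSD_BOOLEAN <- paste0(NS_XSD, "boolean")
XSD_ANYURI  <- paste0(NS_XSD, "anyURI")

default_prefixes <- function() {
  c(rdf = NS_RDF, rdfs = NS_RDFS, owl = NS_OWL, xsd = NS_XSD, skos = NS_SKOS)
}

empty_triples <- function() {
  data.frame(s = character(), p = character(), o = character(),
             o_kind = character(), dt = character(), lang = character(),
             stringsAsFactors = FALSE)
}

#' Create an empty RDF graph
#'
#' An `rdf_graph` is the package's in-memory triple container: a data frame of
#' subject/predicate/object rows plus a prefix map used when serialising.
#'
#' @param prefixes Named character vector mapping prefix labels to namespace
#'   IRIs. The RDF/RDFS/OWL/XSD/SKOS core prefixes are always present.
#' @return An object of class `rdf_graph`.
#' @export
rdf_graph <- function(prefixes = character()) {
  pf <- default_prefixes()
  if (length(prefixes)) pf[names(prefixes)] <- unname(prefixes)
  structure(list(triples = empty_triples(), prefixes = pf),
            class = "rdf_graph")
}

is_bnode <- function(x) startsWith(x, "_:")

triple_rows <- function(s, p, o, o_kind, dt = NA_character_,
                        lang = NA_character_) {
  data.frame(s = s, p = p, o = o, o_kind = o_kind, dt = dt, lang = lang,
             stringsAsFactors = FALSE)
}

graph_add <- function(graph, rows) {
  graph$triples <- rbind(graph$triples, rows)
  graph
}

graph_size <- function(graph) nrow(graph$triples)

#' @export
print.rdf_graph <- function(x, ...) {
  cat("<rdf_graph> ", graph_size(x), " triples, ",
      length(unique(x$triples$s)), " subjects\n", sep = "")
  invisible(x)
}

# All objects of a (subject, predicate) pair, in row order.
graph_objects <- function(graph, s, p) {
  t <- graph$triples
  t[t$s == s & t$p == p, , drop = FALSE]
}

# Shorten an IRI against a prefix map; NA when no namespace matches. The
# default (empty) prefix is stored under the key ":".
shorten_iri <- function(iri, prefixes) {
  for (i in seq_along(prefixes)) {
    ns <- prefixes[[i]]
    if (startsWith(iri, ns)) {
      local <- substring(iri, nchar(ns) + 1L)
      if (grepl("^[A-Za-z_][A-Za-z0-9_-]*$", local) || local == "") {
        label <- names(prefixes)[i]
        if (label == ":") label <- ""
        return(paste0(label, ":", local))
      }
    }
  }
  NA_character_
}

prefix_key <- function(pfx) if (pfx == "") ":" else pfx

is_absolute_iri <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x) & !grepl("[ <>\"{}|\\\\^`]", x)
}
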