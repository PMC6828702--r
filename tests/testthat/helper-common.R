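# Shared fixtures and comparison helpers.

# W3C namespace constants, restated here so the helpers (in particular the
# ShEx oracle) stay independent of package internals.
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

# Structural isomorphism of two schemas: same classes (IRI, name, parent),
# same ordered property lists with identical targets/multiplicities/
# descriptions, same annotations, same value sets with identical member trees.
expect_schemas_isomorphic <- function(a, b) {
  expect_identical(a$base_iri, b$base_iri)
  expect_setequal(names(a$classes), names(b$classes))
  expect_setequal(names(a$value_sets), names(b$value_sets))
  for (iri in names(a$classes)) {
    ca <- a$classes[[iri]]
    cb <- b$classes[[iri]]
    expect_identical(ca$name, cb$name, info = iri)
    expect_identical(ca$parent, cb$parent, info = iri)
    expect_identical(names(ca$properties), names(cb$properties), info = iri)
    for (nm in names(ca$properties)) {
      pa <- ca$properties[[nm]]
      pb <- cb$properties[[nm]]
      expect_identical(pa$iri, pb$iri, info = paste(iri, nm))
      expect_identical(unclass(pa$target), unclass(pb$target),
                       info = paste(iri, nm))
      expect_identical(unclass(pa$mult), unclass(pb$mult),
                       info = paste(iri, nm))
      expect_identical(pa$description, pb$description, info = paste(iri, nm))
    }
    expect_identical(unclass(ca$annotations), unclass(cb$annotations),
                     info = iri)
  }
  for (iri in names(a$value_sets)) {
    expect_identical(sort(names(a$value_sets[[iri]]$members)),
                     sort(names(b$value_sets[[iri]]$members)), info = iri)
    expect_identical(a$value_sets[[iri]]$members[
      sort(names(a$value_sets[[iri]]$members))],
      b$value_sets[[iri]]$members[sort(names(b$value_sets[[iri]]$members))],
      info = iri)
  }
  invisible(TRUE)
}

# Parse RDF text with python rdflib (the standards-conformant reference
# parser available in this toolchain); returns the triple count, or stops.
rdflib_triple_count <- function(text, format = c("turtle", "xml")) {
  format <- match.arg(format)
  tmp <- tempfile(fileext = if (format == "turtle") ".ttl" else ".rdf")
  on.exit(unlink(tmp))
  writeLines(text, tmp, useBytes = TRUE)
  out <- suppressWarnings(system2("python", c("-c", shQuote(sprintf(
    "import rdflib; g = rdflib.Graph(); g.parse('%s', format='%s'); print(len(g))",
    tmp, format))), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("rdflib failed to parse: ", paste(out, collapse = "\n"))
  }
  as.integer(out[length(out)])
}

# A two-class protein mini-schema: the canonical closed-world example (every
# protein has one and only one amino acid sequence).
protein_schema <- function() {
  base <- "http://example.org/prot/"
  schema(base,
         classes = list(
           class_def(paste0(base, "Protein"), "Protein", properties = list(
             property_def("sequence", paste0(base, "sequence"),
                          target_primitive("string"), multiplicity(1, 1),
                          "the amino acid sequence"),
             property_def("encodedBy", paste0(base, "encodedBy"),
                          target_external(), multiplicity(0, 1)))),
           class_def(paste0(base, "Enzyme"), "Enzyme",
                     parent = paste0(base, "Protein"), properties = list(
             property_def("ecNumber", paste0(base, "ecNumber"),
                          target_primitive("string"), multiplicity(0, 1))))),
         prefixes = c(p = base), base_prefix = "p")
}

# A regulation-site mini-schema exercising value sets.
regulation_schema <- function() {
  base <- "http://example.org/reg/"
  schema(base,
         classes = list(
           class_def(paste0(base, "RegulationSite"), "RegulationSite",
                     properties = list(
             property_def("regulatoryClass", paste0(base, "regulatoryClass"),
                          target_value_set(paste0(base, "RegulatoryClass")),
                          multiplicity(1, 1))))),
         value_sets = list(
           value_set_def(paste0(base, "RegulatoryClass"), "RegulatoryClass",
                         members = paste0(base, c("Promoter", "Enhancer",
                                                  "Silencer")))),
         prefixes = c(r = base), base_prefix = "r")
}

# Minimal typed instance graph builders.
ttl_graph <- function(...) {
  turtle_parse(paste(c(...), collapse = "\n"))
}

class_by_name_iri <- function(sch, name) {
  for (cls in sch$classes) if (cls$name == name) return(cls$iri)
  stop("no class ", name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

local_name_of <- function(store, inst) {
  iri <- if (inherits(inst, "og_instance")) inst$iri else inst
  sub("^.*/", "", store$instances[[iri]]$class_iri)
}
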