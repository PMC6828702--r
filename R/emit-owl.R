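# OWL ontology emission. Property constraints use the allValuesFrom axiom
# with optional min/max cardinality 1; someValuesFrom is never emitted, so
# that every referenced object is forced to the expected type. Classes,
# properties and value sets are ordered by IRI: output is deterministic and
# re-serialising the parsed file reproduces it byte for byte.

owl_target_iri <- function(target) {
  switch(target$kind,
         primitive = primitive_xsd(target$datatype),
         class = target$target_iri,
         value_set = target$target_iri,
         external = if (is.null(target$target_iri)) {
           paste0(NS_RDFS, "Resource")
         } else target$target_iri)
}

#' Emit the OWL ontology for a schema
#'
#' @param schema An `og_schema`.
#' @param format `"turtle"` or `"rdfxml"`.
#' @param path Relative path recorded on the artifact.
#' @return A `generated_artifact` of kind `"owl"`.
#' @export
emit_owl <- function(schema, format = c("turtle", "rdfxml"),
                     path = NULL) {
  format <- match.arg(format)
  if (is.null(path)) {
    path <- if (format == "turtle") "ontology.ttl" else "ontology.owl"
  }
  di <- dialect_iris(schema$base_iri)
  owl_class <- paste0(NS_OWL, "Class")
  sub_of <- paste0(NS_RDFS, "subClassOf")
  acc <- list(triple_rows(schema$base_iri, RDF_TYPE,
                          paste0(NS_OWL, "Ontology"), "iri"))
  order <- schema$base_iri
  rn <- 0L
  # property declarations, one per distinct IRI, sorted
  prop_index <- list()
  for (cls in schema$classes) {
    for (p in cls$properties) {
      if (is.null(prop_index[[p$iri]])) prop_index[[p$iri]] <- p
    }
  }
  for (iri in sort(names(schema$classes))) {
    cls <- schema$classes[[iri]]
    acc <- c(acc, list(triple_rows(iri, RDF_TYPE, owl_class, "iri")))
    if (!is.null(cls$parent)) {
      acc <- c(acc, list(triple_rows(iri, sub_of, cls$parent, "iri")))
    }
    acc <- c(acc, annotation_triples(iri, cls$annotations, cls$name, di))
    order <- c(order, iri)
    props <- cls$properties
    props <- props[order(vapply(props, function(p) p$iri, ""))]
    for (p in props) {
      rn <- rn + 1L
      bn <- paste0("_:r", rn)
      acc <- c(acc, list(
        triple_rows(iri, sub_of, bn, "bnode"),
        triple_rows(bn, RDF_TYPE, paste0(NS_OWL, "Restriction"), "iri"),
        triple_rows(bn, paste0(NS_OWL, "onProperty"), p$iri, "iri"),
        triple_rows(bn, paste0(NS_OWL, "allValuesFrom"),
                    owl_target_iri(p$target), "iri")))
      if (p$mult$min == 1L) {
        acc <- c(acc, list(triple_rows(
          bn, paste0(NS_OWL, "minCardinality"), "1", "literal",
          dt = paste0(NS_XSD, "nonNegativeInteger"))))
      }
      if (!is.infinite(p$mult$max)) {
        acc <- c(acc, list(triple_rows(
          bn, paste0(NS_OWL, "maxCardinality"), "1", "literal",
          dt = paste0(NS_XSD, "nonNegativeInteger"))))
      }
      order <- c(order, bn)
    }
  }
  for (piri in sort(names(prop_index))) {
    p <- prop_index[[piri]]
    ptype <- if (p$target$kind == "primitive") "DatatypeProperty"
    else "ObjectProperty"
    acc <- c(acc, list(
      triple_rows(piri, RDF_TYPE, paste0(NS_OWL, ptype), "iri"),
      triple_rows(piri, paste0(NS_RDFS, "label"), p$name, "literal")))
    if (!is.null(p$description)) {
      acc <- c(acc, list(triple_rows(piri, paste0(NS_SKOS, "description"),
                                     p$description, "literal")))
    }
    order <- c(order, piri)
  }
  if (length(schema$value_sets)) {
    acc <- c(acc, list(triple_rows(di$enumerated_value, RDF_TYPE, owl_class,
                                   "iri")))
    order <- c(order, di$enumerated_value)
  }
  for (iri in sort(names(schema$value_sets))) {
    vs <- schema$value_sets[[iri]]
    acc <- c(acc, list(triple_rows(iri, RDF_TYPE, owl_class, "iri"),
                       triple_rows(iri, sub_of, di$enumerated_value, "iri")))
    acc <- c(acc, annotation_triples(iri, vs$annotations, vs$name, di))
    order <- c(order, iri)
    for (m in sort(names(vs$members))) {
      acc <- c(acc, list(triple_rows(m, RDF_TYPE, owl_class, "iri"),
                         triple_rows(m, sub_of, vs$members[[m]], "iri")))
      order <- c(order, m)
    }
  }
  graph <- rdf_graph(schema$prefixes)
  graph$triples <- do.call(rbind, acc)
  content <- if (format == "turtle") {
    turtle_serialize(graph, subject_order = order)
  } else {
    rdfxml_serialize(graph)
  }
  generated_artifact("owl", path, content)
}
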