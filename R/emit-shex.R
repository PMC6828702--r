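# ShEx (ShExC) emission. One shape per class, carrying the class's flattened
# (own + inherited) properties so every shape is self-contained. Shapes are
# CLOSED with rdf:type in an EXTRA clause: a conforming node may carry
# additional rdf:type triples but no predicate outside its shape, which is
# what catches predicate typos under closed-world validation.
#
# Cardinality mapping: 0..1 -> '?', 1..1 -> (none), 0..N -> '*', 1..N -> '+'.
# Ordered-list properties point at a generated list shape describing a
# well-formed RDF collection of the element type; the multiplicity then
# applies to the elements inside the single collection node. Numbered-list
# properties (rdf:_1, rdf:_2, ... containers) have no ShExC equivalent; the
# container node is emitted as an unconstrained value and deep-checked only by
# the package validator (a documented divergence between the two).

shex_ref <- function(iri, prefixes) {
  short <- shorten_iri(iri, prefixes)
  if (!is.na(short)) short else paste0("<", iri, ">")
}

shex_value_expr <- function(target, schema, prefixes) {
  switch(target$kind,
         primitive = shex_ref(primitive_xsd(target$datatype), prefixes),
         # a subclass instance carries its own (wider) closed shape, so a
         # class target is the disjunction over the class and its descendants
         class = {
           alts <- vapply(sort(compatible_types(schema, target$target_iri)),
                          function(iri) paste0("@", shex_ref(iri, prefixes)),
                          "")
           if (length(alts) == 1L) alts
           else paste0("( ", paste(alts, collapse = " OR "), " )")
         },
         value_set = paste0(
           "[ ",
           paste(vapply(sort(value_set_members(schema, target$target_iri)),
                        shex_ref, "", prefixes = prefixes),
                 collapse = " "),
           " ]"),
         external = "IRI")
}

shex_cardinality <- function(mult) {
  if (mult$min == 0L && !is.infinite(mult$max)) return("?")
  if (mult$min == 1L && !is.infinite(mult$max)) return("")
  if (mult$min == 0L) return("*")
  "+"
}

#' Emit the full ShEx schema for a schema
#'
#' @param schema An `og_schema`.
#' @param path Relative path recorded on the artifact.
#' @return A `generated_artifact` of kind `"shex"` (ShExC text).
#' @export
emit_shex <- function(schema, path = "shapes.shex") {
  pf <- c(default_prefixes(), schema$prefixes)
  pf <- pf[!duplicated(names(pf))]
  header <- c(vapply(seq_along(pf), function(i) {
    sprintf("PREFIX %s: <%s>", if (names(pf)[i] == ":") "" else names(pf)[i],
            pf[[i]])
  }, ""), "")
  list_shapes <- character(0)
  list_shape_iris <- character(0)
  blocks <- vapply(sort(names(schema$classes)), function(iri) {
    cls <- schema$classes[[iri]]
    props <- effective_properties(schema, iri)
    type_values <- vapply(sort(compatible_types(schema, iri)), shex_ref, "",
                          prefixes = pf)
    constraints <- paste0("  rdf:type [ ", paste(type_values, collapse = " "),
                          " ]")
    for (p in props) {
      pref <- shex_ref(p$iri, pf)
      if (p$mult$ordered == "ordered") {
        ls_iri <- paste0(iri, "_", p$name, "_List")
        if (!ls_iri %in% list_shape_iris) {
          list_shape_iris <<- c(list_shape_iris, ls_iri)
          elem <- shex_value_expr(p$target, schema, pf)
          list_shapes <<- c(list_shapes, paste0(
            "<", ls_iri, "> CLOSED {\n",
            "  rdf:first ", elem, " ;\n",
            "  rdf:rest ( @<", ls_iri, "> OR [ rdf:nil ] )\n",
            "}"))
        }
        card <- if (p$mult$min == 0L) " ?" else ""
        constraints <- c(constraints,
                         paste0("  ", pref, " @<", ls_iri, ">", card))
      } else if (p$mult$ordered == "numbered") {
        card <- if (p$mult$min == 0L) " ?" else ""
        constraints <- c(constraints,
                         paste0("  ", pref, " .", card,
                                "  # rdf:_n container; deep-checked by the validator"))
      } else {
        expr <- shex_value_expr(p$target, schema, pf)
        card <- shex_cardinality(p$mult)
        constraints <- c(constraints,
                         paste0("  ", pref, " ", expr,
                                if (nzchar(card)) paste0(" ", card) else ""))
      }
    }
    paste0(shex_ref(iri, pf), " CLOSED EXTRA rdf:type {\n",
           paste(constraints, collapse = " ;\n"), "\n}")
  }, "")
  content <- paste(c(header, blocks, list_shapes, ""), collapse = "\n\n")
  generated_artifact("shex", path, content)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
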