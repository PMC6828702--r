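# RDF/XML reader and writer (xml2-backed). The writer emits the flat
# rdf:Description profile; the reader additionally accepts typed node
# elements, which generic OWL editors produce.

split_iri_ns <- function(iri) {
  # namespace/local split at the last '#' or '/'
  m <- regexpr("[#/][^#/]*$", iri)
  if (m < 0) stop("cannot split IRI into namespace + local name: ", iri)
  list(ns = substring(iri, 1L, m), local = substring(iri, m + 1L))
}

#' Serialise an RDF graph as RDF/XML
#'
#' @param graph An [rdf_graph()].
#' @return RDF/XML text.
#' @export
rdfxml_serialize <- function(graph) {
  t <- graph$triples
  pf <- graph$prefixes
  # every predicate namespace needs a declared prefix
  pred_ns <- unique(vapply(unique(t$p), function(p) split_iri_ns(p)$ns, ""))
  extra <- setdiff(pred_ns, unname(pf))
  if (length(extra)) {
    names(extra) <- paste0("ns", seq_along(extra))
    pf <- c(pf, extra)
  }
  doc <- xml2::xml_new_root("rdf:RDF")
  for (i in seq_along(pf)) {
    xml2::xml_set_attr(doc, paste0("xmlns:", names(pf)[i]), pf[[i]])
  }
  qname <- function(iri) {
    sp <- split_iri_ns(iri)
    pfx <- names(pf)[match(sp$ns, unname(pf))]
    paste0(pfx, ":", sp$local)
  }
  for (s in unique(t$s)) {
    node <- xml2::xml_add_child(doc, "rdf:Description")
    if (is_bnode(s)) xml2::xml_set_attr(node, "rdf:nodeID", substring(s, 3L))
    else xml2::xml_set_attr(node, "rdf:about", s)
    rows <- t[t$s == s, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      el <- xml2::xml_add_child(node, qname(rows$p[j]))
      if (rows$o_kind[j] == "iri") {
        xml2::xml_set_attr(el, "rdf:resource", rows$o[j])
      } else if (rows$o_kind[j] == "bnode") {
        xml2::xml_set_attr(el, "rdf:nodeID", substring(rows$o[j], 3L))
      } else {
        if (!is.na(rows$dt[j]) && rows$dt[j] != XSD_STRING) {
          xml2::xml_set_attr(el, "rdf:datatype", rows$dt[j])
        }
        if (!is.na(rows$lang[j])) {
          xml2::xml_set_attr(el, "xml:lang", rows$lang[j])
        }
        xml2::xml_set_text(el, rows$o[j])
      }
    }
  }
  as.character(doc)
}

#' Parse RDF/XML into an RDF graph
#'
#' @param text RDF/XML document text, or `NULL` when `file` is given.
#' @param file Path to an RDF/XML file.
#' @return An [rdf_graph()].
#' @export
rdfxml_parse <- function(text = NULL, file = NULL) {
  doc <- if (!is.null(text)) xml2::read_xml(text) else xml2::read_xml(file)
  nsmap <- xml2::xml_ns(doc)
  graph <- rdf_graph()
  for (i in seq_along(nsmap)) {
    pfx <- names(nsmap)[i]
    if (!pfx %in% c("xml", "d1")) graph$prefixes[pfx] <- nsmap[[i]]
  }
  acc <- list()
  bn_auto <- 0L
  fresh <- function() {
    bn_auto <<- bn_auto + 1L
    paste0("_:x", bn_auto)
  }
  el_iri <- function(el) {
    # resolve the element's qualified name to a full IRI via the ns map
    qn <- xml2::xml_name(el, ns = nsmap)
    parts <- strsplit(qn, ":", fixed = TRUE)[[1]]
    if (length(parts) == 1L) stop("unprefixed element in RDF/XML: ", qn)
    paste0(nsmap[[parts[1]]], paste(parts[-1], collapse = ":"))
  }
  handle_node <- function(el) {
    about <- xml2::xml_attr(el, "about")
    node_id <- xml2::xml_attr(el, "nodeID")
    subj <- if (!is.na(about)) about
    else if (!is.na(node_id)) paste0("_:", node_id)
    else fresh()
    tiri <- el_iri(el)
    if (tiri != paste0(NS_RDF, "Description")) {
      acc[[length(acc) + 1L]] <<- triple_rows(subj, RDF_TYPE, tiri, "iri")
    }
    for (child in xml2::xml_children(el)) {
      p <- el_iri(child)
      res <- xml2::xml_attr(child, "resource")
      nid <- xml2::xml_attr(child, "nodeID")
      dt <- xml2::xml_attr(child, "datatype")
      lang <- xml2::xml_attr(child, "lang")
      kids <- xml2::xml_children(child)
      if (!is.na(res)) {
        acc[[length(acc) + 1L]] <<- triple_rows(subj, p, res, "iri")
      } else if (!is.na(nid)) {
        acc[[length(acc) + 1L]] <<- triple_rows(subj, p, paste0("_:", nid),
                                                "bnode")
      } else if (length(kids)) {
        obj <- handle_node(kids[[1]])
        kind <- if (is_bnode(obj)) "bnode" else "iri"
        acc[[length(acc) + 1L]] <<- triple_rows(subj, p, obj, kind)
      } else {
        acc[[length(acc) + 1L]] <<- triple_rows(
          subj, p, xml2::xml_text(child), "literal",
          if (is.na(dt)) NA_character_ else dt,
          if (is.na(lang)) NA_character_ else lang)
      }
    }
    subj
  }
  for (el in xml2::xml_children(doc)) handle_node(el)
  graph$triples <- if (length(acc)) do.call(rbind, acc) else empty_triples()
  graph
}
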