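# Reader for the combined OWL + simplified-ShEx definition format, and the
# matching emitter (the two are exact inverses; round-trip identity is part of
# the test suite).
#
# Definition file conventions:
#   * one subject typed owl:Ontology carries the base IRI of the schema;
#   * classes are owl:Class nodes, hierarchy via rdfs:subClassOf;
#   * value sets are the direct rdfs:subClassOf children of
#     <base>EnumeratedValue; their own subClassOf subtrees are the members;
#   * per-class properties live in one literal under the annotation property
#     <base>propertyDefinitions, one property per line:
#         [# description]
#         <name> <target> <multiplicity>
#     where target is xsd:<datatype>, a (prefixed) class name, @ValueSet,
#     a <full-iri>, or the keyword IRI for an unconstrained external
#     reference, and multiplicity is 0..1 / 1..1 / 0..N / 1..N with an
#     optional leading '=' (ordered list) or '~' (numbered list);
#   * rdfs:label and skos:description carry the name and definition; usage,
#     editorial and ddbj annotations use <base>usageComment,
#     <base>editorialComment and <base>ddbjLabel; cross-links use
#     skos:exactMatch.

dialect_iris <- function(base_iri) {
  list(property_definitions = paste0(base_iri, "propertyDefinitions"),
       enumerated_value = paste0(base_iri, "EnumeratedValue"),
       usage_comment = paste0(base_iri, "usageComment"),
       editorial_comment = paste0(base_iri, "editorialComment"),
       ddbj_label = paste0(base_iri, "ddbjLabel"))
}

local_name <- function(iri, base_iri) {
  if (startsWith(iri, base_iri)) return(substring(iri, nchar(base_iri) + 1L))
  split_iri_ns(iri)$local
}

#' Parse a multiplicity token
#'
#' Legal forms are `0..1`, `1..1`, `0..N`, `1..N`, with an optional leading
#' `=` (ordered list) or `~` (numbered list) on the unbounded forms.
#'
#' @param token Multiplicity token text.
#' @return A [multiplicity()].
#' @export
parse_multiplicity <- function(token) {
  raw <- token
  ordered <- "none"
  if (startsWith(token, "=")) {
    ordered <- "ordered"
    token <- substring(token, 2L)
  } else if (startsWith(token, "~")) {
    ordered <- "numbered"
    token <- substring(token, 2L)
  }
  spec <- c("0..1" = 1, "1..1" = 1, "0..N" = Inf, "1..N" = Inf)
  if (!token %in% names(spec)) {
    og_stop(paste0("unknown multiplicity token '", raw,
                   "' (expected 0..1, 1..1, 0..N or 1..N)"), "syntax_error")
  }
  mn <- as.integer(substring(token, 1L, 1L))
  mx <- spec[[token]]
  if (ordered != "none" && !is.infinite(mx)) {
    og_stop(paste0("list marker on single-valued multiplicity '", raw, "'"),
            "syntax_error")
  }
  multiplicity(mn, mx, ordered)
}

resolve_dialect_name <- function(token, prefixes, base_iri, where, line) {
  if (grepl("^<.*>$", token)) return(substr(token, 2L, nchar(token) - 1L))
  if (grepl(":", token, fixed = TRUE)) {
    pfx <- sub(":.*$", "", token)
    ns <- prefixes[prefix_key(pfx)]
    if (is.na(ns)) {
      og_stop(paste0(where, " line ", line, ": unknown prefix '", pfx, "'"),
              "syntax_error")
    }
    return(paste0(ns, sub("^[^:]*:", "", token)))
  }
  paste0(base_iri, token)
}

#' Parse one propertyDefinitions block
#'
#' @param text Full annotation literal for one class.
#' @param prefixes Named prefix map used to resolve prefixed target names.
#' @param base_iri Schema base IRI (property IRIs are minted under it;
#'   unprefixed targets resolve against it).
#' @param where Label used in error messages (normally the class IRI).
#' @return List of [property_def()]s in file order.
#' @export
parse_property_block <- function(text, prefixes, base_iri, where = "block") {
  lines <- strsplit(text, "\r\n|\r|\n")[[1]]
  props <- list()
  pending_comment <- character(0)
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      pending_comment <- c(pending_comment, trimws(sub("^#", "", line)))
      next
    }
    toks <- strsplit(line, "[ \t]+")[[1]]
    if (length(toks) != 3L) {
      og_stop(paste0(where, " line ", ln,
                     ": expected '<name> <target> <multiplicity>', got '",
                     line, "'"), "syntax_error")
    }
    name <- toks[1L]
    if (!grepl(PROP_NAME_RE, name)) {
      og_stop(paste0(where, " line ", ln, ": invalid property name '", name,
                     "'"), "syntax_error")
    }
    if (name %in% vapply(props, function(p) p$name, "")) {
      og_stop(paste0(where, " line ", ln, ": duplicate property '", name,
                     "'"), "duplicate_property")
    }
    tgt_tok <- toks[2L]
    target <- if (grepl("^xsd:", tgt_tok)) {
      dt <- sub("^xsd:", "", tgt_tok)
      if (!dt %in% PRIMITIVE_TYPES) {
        og_stop(paste0(where, " line ", ln, ": unsupported datatype '",
                       tgt_tok, "'"), "syntax_error")
      }
      target_primitive(dt)
    } else if (tgt_tok == "IRI") {
      target_external()
    } else if (startsWith(tgt_tok, "@")) {
      target_value_set(resolve_dialect_name(substring(tgt_tok, 2L), prefixes,
                                            base_iri, where, ln))
    } else if (grepl("^<.*>$", tgt_tok)) {
      target_external(substr(tgt_tok, 2L, nchar(tgt_tok) - 1L))
    } else {
      target_class(resolve_dialect_name(tgt_tok, prefixes, base_iri, where,
                                        ln))
    }
    mult <- tryCatch(parse_multiplicity(toks[3L]), ontogen_error = function(e) {
      og_stop(paste0(where, " line ", ln, ": ", conditionMessage(e)),
              "syntax_error")
    })
    props[[length(props) + 1L]] <- property_def(
      name = name, iri = paste0(base_iri, name), target = target,
      mult = mult,
      description = if (length(pending_comment)) {
        paste(pending_comment, collapse = "\n")
      } else NULL)
    pending_comment <- character(0)
  }
  props
}

first_literal <- function(graph, s, p) {
  rows <- graph_objects(graph, s, p)
  rows <- rows[rows$o_kind == "literal", , drop = FALSE]
  if (nrow(rows)) rows$o[1L] else NULL
}

#' Parse a definition graph into a schema
#'
#' @param graph An [rdf_graph()] holding a combined OWL + simplified-ShEx
#'   definition (see [read_schema()] for reading from a file).
#' @return A validated `og_schema`.
#' @export
parse_schema <- function(graph) {
  t <- graph$triples
  onto <- unique(t$s[t$p == RDF_TYPE & t$o == paste0(NS_OWL, "Ontology")])
  if (length(onto) != 1L) {
    og_stop("definition graph must declare exactly one owl:Ontology subject (its IRI is the schema base)",
            "input_error")
  }
  base_iri <- onto
  di <- dialect_iris(base_iri)
  owl_classes <- unique(t$s[t$p == RDF_TYPE & t$o == paste0(NS_OWL, "Class")])
  sub_of <- t[t$p == paste0(NS_RDFS, "subClassOf") & t$o_kind == "iri", ,
              drop = FALSE]
  children_of <- function(iri) unique(sub_of$s[sub_of$o == iri])
  subtree_below <- function(iri) {
    out <- character(0)
    frontier <- children_of(iri)
    while (length(frontier)) {
      out <- c(out, frontier)
      frontier <- unique(unlist(lapply(frontier, children_of)))
      frontier <- setdiff(frontier, out)
    }
    out
  }
  vs_roots <- children_of(di$enumerated_value)
  vs_member_space <- unique(unlist(lapply(vs_roots, subtree_below)))
  class_iris <- setdiff(owl_classes,
                        c(di$enumerated_value, vs_roots, vs_member_space))
  ann_of <- function(iri, fallback_name) {
    def <- first_literal(graph, iri, paste0(NS_SKOS, "description"))
    em <- graph_objects(graph, iri, paste0(NS_SKOS, "exactMatch"))
    annotation_set(
      definition = if (is.null(def)) fallback_name else def,
      usage_comment = first_literal(graph, iri, di$usage_comment),
      editorial_comment = first_literal(graph, iri, di$editorial_comment),
      ddbj_label = first_literal(graph, iri, di$ddbj_label),
      exact_matches = em$o[em$o_kind == "iri"])
  }
  classes <- lapply(sort(class_iris), function(iri) {
    name <- first_literal(graph, iri, paste0(NS_RDFS, "label"))
    if (is.null(name)) name <- local_name(iri, base_iri)
    parents <- sub_of$o[sub_of$s == iri]
    parents <- setdiff(parents, paste0(NS_OWL, "Thing"))
    if (length(parents) > 1L) {
      og_stop(paste0("class ", name, " has multiple parents (single inheritance required)"),
              "cyclic_hierarchy")
    }
    block <- first_literal(graph, iri, di$property_definitions)
    props <- if (is.null(block)) list()
    else parse_property_block(block, graph$prefixes, base_iri, where = iri)
    class_def(iri = iri, name = name,
              parent = if (length(parents)) parents else NULL,
              properties = props, annotations = ann_of(iri, name))
  })
  value_sets <- lapply(sort(vs_roots), function(iri) {
    name <- first_literal(graph, iri, paste0(NS_RDFS, "label"))
    if (is.null(name)) name <- local_name(iri, base_iri)
    members <- subtree_below(iri)
    parents <- vapply(members, function(m) sub_of$o[sub_of$s == m][1L], "")
    value_set_def(iri = iri, name = name,
                  members = structure(unname(parents), names = members),
                  annotations = ann_of(iri, name))
  })
  pf <- graph$prefixes
  base_label <- names(pf)[match(base_iri, pf)]
  if (is.na(base_label)) base_label <- "ns"
  schema(base_iri, classes = classes, value_sets = value_sets,
         prefixes = pf,
         base_prefix = if (base_label == ":") "" else base_label)
}

#' Read a schema definition file
#'
#' Turtle is the primary format; files ending in `.rdf`, `.owl` or `.xml` are
#' read as RDF/XML.
#'
#' @param path Definition file path.
#' @return A validated `og_schema`.
#' @export
read_schema <- function(path) {
  graph <- if (grepl("\\.(rdf|owl|xml)$", path, ignore.case = TRUE)) {
    rdfxml_parse(file = path)
  } else {
    turtle_parse(file = path)
  }
  parse_schema(graph)
}

format_target_token <- function(target, schema) {
  ref <- function(iri) {
    if (startsWith(iri, schema$base_iri)) {
      return(substring(iri, nchar(schema$base_iri) + 1L))
    }
    short <- shorten_iri(iri, schema$prefixes)
    if (!is.na(short)) short else paste0("<", iri, ">")
  }
  switch(target$kind,
         primitive = paste0("xsd:", target$datatype),
         class = ref(target$target_iri),
         value_set = paste0("@", ref(target$target_iri)),
         external = if (is.null(target$target_iri)) "IRI"
         else paste0("<", target$target_iri, ">"))
}

format_property_block <- function(cls, schema) {
  lines <- unlist(lapply(cls$properties, function(p) {
    c(if (!is.null(p$description)) {
      paste0("# ", strsplit(p$description, "\n", fixed = TRUE)[[1]])
    },
    paste(p$name, format_target_token(p$target, schema), format(p$mult)))
  }))
  paste(lines, collapse = "\n")
}

annotation_triples <- function(iri, ann, name, di) {
  rows <- list(
    triple_rows(iri, paste0(NS_RDFS, "label"), name, "literal"),
    triple_rows(iri, paste0(NS_SKOS, "description"), ann$definition,
                "literal"))
  if (!is.null(ann$usage_comment)) {
    rows <- c(rows, list(triple_rows(iri, di$usage_comment, ann$usage_comment,
                                     "literal")))
  }
  if (!is.null(ann$editorial_comment)) {
    rows <- c(rows, list(triple_rows(iri, di$editorial_comment,
                                     ann$editorial_comment, "literal")))
  }
  if (!is.null(ann$ddbj_label)) {
    rows <- c(rows, list(triple_rows(iri, di$ddbj_label, ann$ddbj_label,
                                     "literal")))
  }
  for (em in ann$exact_matches) {
    rows <- c(rows, list(triple_rows(iri, paste0(NS_SKOS, "exactMatch"), em,
                                     "iri")))
  }
  rows
}

#' Emit a schema as a combined OWL + simplified-ShEx definition file
#'
#' The exact inverse of [parse_schema()]: parsing the emitted text yields an
#' isomorphic schema.
#'
#' @param schema An `og_schema`.
#' @param path Relative path recorded on the artifact.
#' @return A `generated_artifact` of kind `"definition"` (Turtle text).
#' @export
emit_definition <- function(schema, path = "schema.ttl") {
  di <- dialect_iris(schema$base_iri)
  acc <- list(triple_rows(schema$base_iri, RDF_TYPE,
                          paste0(NS_OWL, "Ontology"), "iri"))
  order <- schema$base_iri
  owl_class <- paste0(NS_OWL, "Class")
  sub_of <- paste0(NS_RDFS, "subClassOf")
  if (length(schema$value_sets)) {
    acc <- c(acc, list(triple_rows(di$enumerated_value, RDF_TYPE, owl_class,
                                   "iri")))
    order <- c(order, di$enumerated_value)
  }
  for (iri in sort(names(schema$classes))) {
    cls <- schema$classes[[iri]]
    acc <- c(acc, list(triple_rows(iri, RDF_TYPE, owl_class, "iri")))
    if (!is.null(cls$parent)) {
      acc <- c(acc, list(triple_rows(iri, sub_of, cls$parent, "iri")))
    }
    acc <- c(acc, annotation_triples(iri, cls$annotations, cls$name, di))
    if (length(cls$properties)) {
      acc <- c(acc, list(triple_rows(iri, di$property_definitions,
                                     format_property_block(cls, schema),
                                     "literal")))
    }
    order <- c(order, iri)
  }
  for (iri in sort(names(schema$value_sets))) {
    vs <- schema$value_sets[[iri]]
    acc <- c(acc, list(
      triple_rows(iri, RDF_TYPE, owl_class, "iri"),
      triple_rows(iri, sub_of, di$enumerated_value, "iri")))
    acc <- c(acc, annotation_triples(iri, vs$annotations, vs$name, di))
    order <- c(order, iri)
    for (m in names(vs$members)) {
      acc <- c(acc, list(triple_rows(m, RDF_TYPE, owl_class, "iri"),
                         triple_rows(m, sub_of, vs$members[[m]], "iri")))
      order <- c(order, m)
    }
  }
  graph <- rdf_graph(schema$prefixes)
  graph$triples <- do.call(rbind, acc)
  generated_artifact("definition", path,
                     turtle_serialize(graph, subject_order = order))
}

#' Generated artifact container
#'
#' @param kind Artifact kind (`"owl"`, `"shex"`, `"definition"`, `"api"`,
#'   `"doc"`).
#' @param path Relative output path.
#' @param content Full text content.
#' @return A `generated_artifact`.
#' @export
generated_artifact <- function(kind, path, content) {
  structure(list(kind = kind, path = path, content = content),
            class = "generated_artifact")
}

#' @export
print.generated_artifact <- function(x, ...) {
  cat("<generated_artifact> [", x$kind, "] ", x$path, " (",
      nchar(x$content), " chars)\n", sep = "")
  invisible(x)
}

#' Write a generated artifact (or list of artifacts) to disk
#'
#' @param artifact A `generated_artifact` or list of them.
#' @param dir Output directory (created if missing).
#' @return Written paths, invisibly.
#' @export
write_artifact <- function(artifact, dir = ".") {
  if (inherits(artifact, "generated_artifact")) artifact <- list(artifact)
  paths <- vapply(artifact, function(a) {
    out <- file.path(dir, a$path)
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    writeLines(a$content, out, useBytes = TRUE)
    out
  }, "")
  invisible(paths)
}
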