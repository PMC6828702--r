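# In-memory schema model: classes with single-inheritance, typed
# multiplicity-constrained properties, and value sets (controlled
# vocabularies modelled as class subtrees under EnumeratedValue).

og_stop <- function(msg, class, ...) {
  stop(structure(class = c(paste0("ontogen_", class), "ontogen_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

UNBOUNDED <- Inf

#' Property multiplicity
#'
#' Only the four forms `0..1`, `1..1`, `0..N`, `1..N` are legal; `N` is
#' represented as `Inf`. Unbounded properties may additionally be flagged as
#' ordered (stored as an RDF collection) or numbered (stored with `rdf:_n`
#' container membership properties).
#'
#' @param min 0 or 1.
#' @param max 1 or `Inf`.
#' @param ordered One of `"none"`, `"ordered"`, `"numbered"`.
#' @return A `multiplicity` object.
#' @export
multiplicity <- function(min, max, ordered = "none") {
  if (!min %in% c(0, 1)) og_stop("multiplicity min must be 0 or 1",
                                 "syntax_error")
  if (!(identical(max, 1) || identical(max, 1L) || is.infinite(max))) {
    og_stop("multiplicity max must be 1 or Inf", "syntax_error")
  }
  ordered <- match.arg(ordered, c("none", "ordered", "numbered"))
  if (ordered != "none" && !is.infinite(max)) {
    og_stop("ordered/numbered list markers require an unbounded multiplicity",
            "syntax_error")
  }
  structure(list(min = as.integer(min), max = if (is.infinite(max)) Inf else 1L,
                 ordered = ordered),
            class = "multiplicity")
}

#' @export
format.multiplicity <- function(x, ...) {
  marker <- switch(x$ordered, none = "", ordered = "=", numbered = "~")
  paste0(marker, x$min, "..", if (is.infinite(x$max)) "N" else x$max)
}

#' @export
print.multiplicity <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

PRIMITIVE_TYPES <- c("string", "integer", "double", "boolean", "anyURI")

primitive_xsd <- function(name) {
  paste0(NS_XSD, name)
}

#' Property target descriptors
#'
#' A property targets exactly one of: a primitive XSD datatype, another class
#' in the schema, a value set in the schema, or an external IRI (a resource in
#' a foreign ontology, never dereferenced or closed-world checked).
#'
#' @param datatype One of `"string"`, `"integer"`, `"double"`, `"boolean"`,
#'   `"anyURI"`.
#' @param iri Target class / value-set IRI.
#' @return A `target_ref` object.
#' @export
target_primitive <- function(datatype) {
  datatype <- match.arg(datatype, PRIMITIVE_TYPES)
  structure(list(kind = "primitive", datatype = datatype, target_iri = NULL),
            class = "target_ref")
}

#' @rdname target_primitive
#' @export
target_class <- function(iri) {
  structure(list(kind = "class", datatype = NULL, target_iri = iri),
            class = "target_ref")
}

#' @rdname target_primitive
#' @export
target_value_set <- function(iri) {
  structure(list(kind = "value_set", datatype = NULL, target_iri = iri),
            class = "target_ref")
}

#' @rdname target_primitive
#' @export
target_external <- function(iri = NULL) {
  structure(list(kind = "external", datatype = NULL, target_iri = iri),
            class = "target_ref")
}

#' Class and property annotations
#'
#' Every class and property carries a short definition; optionally a usage
#' comment, an editorial comment (about the development of the schema itself),
#' a ddbj label marking presence in the GenBank standard, and exact-match
#' cross-links to terms in external ontologies.
#'
#' @param definition Required non-empty definition text.
#' @param usage_comment,editorial_comment,ddbj_label Optional annotation text.
#' @param exact_matches Character vector of absolute external IRIs.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(definition, usage_comment = NULL,
                           editorial_comment = NULL, ddbj_label = NULL,
                           exact_matches = character()) {
  if (!is.character(definition) || length(definition) != 1L ||
      !nzchar(trimws(definition))) {
    og_stop("every class and property needs a non-empty definition",
            "syntax_error")
  }
  bad <- exact_matches[!is_absolute_iri(exact_matches)]
  if (length(bad)) {
    og_stop(paste0("exact_matches must be absolute IRIs: ",
                   paste(bad, collapse = ", ")), "syntax_error")
  }
  structure(list(definition = definition, usage_comment = usage_comment,
                 editorial_comment = editorial_comment,
                 ddbj_label = ddbj_label,
                 exact_matches = sort(unique(exact_matches))),
            class = "annotation_set")
}

CLASS_NAME_RE <- "^[A-Z][A-Za-z0-9]*$"
PROP_NAME_RE <- "^[a-z][A-Za-z0-9]*$"

#' Define a property
#'
#' @param name Property local name; must be lowerCamelCase.
#' @param iri Full property IRI.
#' @param target A [target_primitive()] / [target_class()] /
#'   [target_value_set()] / [target_external()] descriptor.
#' @param mult A [multiplicity()].
#' @param description Optional free-text description.
#' @return A `property_def` object.
#' @export
property_def <- function(name, iri, target, mult, description = NULL) {
  if (!grepl(PROP_NAME_RE, name)) {
    og_stop(paste0("property name must be lowerCamelCase without whitespace: '",
                   name, "'"), "invalid_name")
  }
  stopifnot(inherits(target, "target_ref"), inherits(mult, "multiplicity"))
  structure(list(name = name, iri = iri, target = target, mult = mult,
                 description = description),
            class = "property_def")
}

#' Define a class
#'
#' @param iri Full class IRI.
#' @param name Local name; must be UpperCamelCase.
#' @param parent Optional parent class IRI (single inheritance).
#' @param properties List of [property_def()]s, in declaration order.
#' @param annotations An [annotation_set()]; defaults to a definition equal to
#'   the class name.
#' @return A `class_def` object.
#' @export
class_def <- function(iri, name, parent = NULL, properties = list(),
                      annotations = NULL) {
  if (!grepl(CLASS_NAME_RE, name)) {
    og_stop(paste0("class name must be UpperCamelCase without whitespace: '",
                   name, "'"), "invalid_name")
  }
  nms <- vapply(properties, function(p) p$name, "")
  if (anyDuplicated(nms)) {
    og_stop(paste0("duplicate property name in class ", name, ": ",
                   paste(unique(nms[duplicated(nms)]), collapse = ", ")),
            "duplicate_property")
  }
  if (is.null(annotations)) annotations <- annotation_set(name)
  names(properties) <- nms
  structure(list(iri = iri, name = name, parent = parent,
                 properties = properties, annotations = annotations),
            class = "class_def")
}

#' Define a value set
#'
#' Members form a tree: each member maps to its parent (the value-set IRI for
#' direct members). Any member of the subtree is a legal value.
#'
#' @param iri Value-set IRI (modelled as a subclass of `EnumeratedValue`).
#' @param name Local name (UpperCamelCase).
#' @param members Named character vector: names are member IRIs, values are
#'   their parent IRIs (the value-set IRI for top-level members).
#' @param annotations Optional [annotation_set()].
#' @return A `value_set_def` object.
#' @export
value_set_def <- function(iri, name, members, annotations = NULL) {
  if (!grepl(CLASS_NAME_RE, name)) {
    og_stop(paste0("value-set name must be UpperCamelCase: '", name, "'"),
            "invalid_name")
  }
  if (is.null(names(members))) {
    members <- structure(rep(iri, length(members)), names = members)
  }
  if (length(members) == 0L) {
    og_stop(paste0("value set ", name, " has no members"), "syntax_error")
  }
  if (anyDuplicated(names(members))) {
    og_stop(paste0("duplicate member IRIs in value set ", name),
            "syntax_error")
  }
  bad <- setdiff(unname(members), c(iri, names(members)))
  if (length(bad)) {
    og_stop(paste0("member parent(s) outside value set ", name, ": ",
                   paste(bad, collapse = ", ")), "syntax_error")
  }
  if (is.null(annotations)) annotations <- annotation_set(name)
  structure(list(iri = iri, name = name, members = members,
                 annotations = annotations),
            class = "value_set_def")
}

#' Assemble and validate a schema
#'
#' Validates all structural invariants: acyclic single-parent class hierarchy,
#' no property redefinition along inheritance chains, resolvable class and
#' value-set references, and disjoint class / value-set IRI spaces.
#'
#' @param base_iri Namespace IRI the schema's terms live under (with trailing
#'   `/` or `#`).
#' @param classes List of [class_def()]s.
#' @param value_sets List of [value_set_def()]s.
#' @param prefixes Named character vector of additional prefix bindings; a
#'   binding for `base_iri` is added automatically under the given
#'   `base_prefix`.
#' @param base_prefix Prefix label for `base_iri`.
#' @return A validated `og_schema` object.
#' @export
schema <- function(base_iri, classes = list(), value_sets = list(),
                   prefixes = character(), base_prefix = "") {
  names(classes) <- vapply(classes, function(c) c$iri, "")
  names(value_sets) <- vapply(value_sets, function(v) v$iri, "")
  pf <- prefixes
  pf[prefix_key(base_prefix)] <- base_iri
  sch <- structure(list(base_iri = base_iri, classes = classes,
                        value_sets = value_sets, prefixes = pf),
                   class = "og_schema")
  validate_schema(sch)
  sch
}

validate_schema <- function(sch) {
  classes <- sch$classes
  vsets <- sch$value_sets
  overlap <- intersect(names(classes), names(vsets))
  member_iris <- unlist(lapply(vsets, function(v) names(v$members)),
                        use.names = FALSE)
  overlap <- c(overlap, intersect(names(classes), member_iris))
  if (length(overlap)) {
    og_stop(paste0("IRIs used both as class and value set/member: ",
                   paste(unique(overlap), collapse = ", ")),
            "unresolved_reference")
  }
  # hierarchy: single parent is structural (one parent field); check acyclic
  for (iri in names(classes)) {
    seen <- character(0)
    node <- iri
    while (!is.null(node)) {
      if (node %in% seen) {
        og_stop(paste0("subClassOf cycle involving ", node),
                "cyclic_hierarchy")
      }
      seen <- c(seen, node)
      parent <- classes[[node]]$parent
      if (!is.null(parent) && is.null(classes[[parent]])) {
        og_stop(paste0("class ", classes[[node]]$name,
                       " has unknown parent ", parent),
                "unresolved_reference")
      }
      node <- parent
    }
  }
  # property references resolve; no redefinition along the parent chain
  for (iri in names(classes)) {
    cls <- classes[[iri]]
    inherited <- character(0)
    node <- cls$parent
    while (!is.null(node)) {
      inherited <- c(inherited, names(classes[[node]]$properties))
      node <- classes[[node]]$parent
    }
    clash <- intersect(names(cls$properties), inherited)
    if (length(clash)) {
      og_stop(paste0("class ", cls$name, " redefines inherited property: ",
                     paste(clash, collapse = ", ")), "duplicate_property")
    }
    for (p in cls$properties) {
      tgt <- p$target
      if (tgt$kind == "class" && is.null(classes[[tgt$target_iri]])) {
        og_stop(paste0("property ", cls$name, ".", p$name,
                       " references undefined class ", tgt$target_iri),
                "unresolved_reference")
      }
      if (tgt$kind == "value_set" && is.null(vsets[[tgt$target_iri]])) {
        og_stop(paste0("property ", cls$name, ".", p$name,
                       " references undefined value set ", tgt$target_iri),
                "unresolved_reference")
      }
    }
  }
  invisible(sch)
}

#' @export
print.og_schema <- function(x, ...) {
  st <- schema_stats(x)
  cat("<og_schema> base ", x$base_iri, "\n  ",
      st$classes, " classes, ", st$properties, " properties, ",
      st$value_sets, " value sets\n", sep = "")
  invisible(x)
}

#' Count classes, properties and value sets
#'
#' Properties are counted as owned (declared on the class itself), never
#' inherited; value-set member classes count toward the value-set tally only.
#'
#' @param schema An `og_schema`.
#' @return A list with components `classes`, `properties`, `value_sets`.
#' @export
schema_stats <- function(schema) {
  structure(list(
    classes = length(schema$classes),
    properties = sum(vapply(schema$classes,
                            function(c) length(c$properties), 0L)),
    value_sets = length(schema$value_sets)),
    class = "schema_stats")
}

#' @export
print.schema_stats <- function(x, ...) {
  cat(jsonlite::toJSON(unclass(x), auto_unbox = TRUE), "\n")
  invisible(x)
}

#' Flattened property list of a class
#'
#' Own properties plus all ancestors' properties, ancestor-first.
#'
#' @param schema An `og_schema`.
#' @param class_iri IRI of a class in the schema.
#' @return Named list of `property_def`s.
#' @export
effective_properties <- function(schema, class_iri) {
  if (is.null(schema$classes[[class_iri]])) {
    og_stop(paste0("unknown class ", class_iri), "unknown_class")
  }
  chain <- character(0)
  node <- class_iri
  while (!is.null(node)) {
    chain <- c(node, chain)
    node <- schema$classes[[node]]$parent
  }
  props <- list()
  for (iri in chain) props <- c(props, schema$classes[[iri]]$properties)
  props
}

#' All member IRIs of a value set
#'
#' Includes transitive sub-members: a member's sub-member is itself a legal
#' value of the set.
#'
#' @param schema An `og_schema`.
#' @param vs_iri Value-set IRI.
#' @return Character vector of member IRIs.
#' @export
value_set_members <- function(schema, vs_iri) {
  vs <- schema$value_sets[[vs_iri]]
  if (is.null(vs)) og_stop(paste0("unknown value set ", vs_iri),
                           "unknown_value_set")
  names(vs$members)
}

# All classes whose ancestor chain includes class_iri (excluding itself).
schema_descendants <- function(schema, class_iri) {
  parents <- vapply(schema$classes,
                    function(c) if (is.null(c$parent)) NA_character_
                    else c$parent, "")
  out <- character(0)
  frontier <- class_iri
  while (length(frontier)) {
    kids <- names(parents)[!is.na(parents) & parents %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

# class_iri itself plus descendants: the set of types assignable to a target.
compatible_types <- function(schema, class_iri) {
  c(class_iri, schema_descendants(schema, class_iri))
}

#' Merge two schemas with disjoint term spaces
#'
#' @param a,b `og_schema` objects. The merged schema keeps `a`'s base IRI.
#' @return An `og_schema`.
#' @export
schema_merge <- function(a, b) {
  schema(a$base_iri,
         classes = c(unname(a$classes), unname(b$classes)),
         value_sets = c(unname(a$value_sets), unname(b$value_sets)),
         prefixes = c(a$prefixes, b$prefixes[setdiff(names(b$prefixes),
                                                     names(a$prefixes))]),
         base_prefix = names(a$prefixes)[match(a$base_iri, a$prefixes)])
}

# Look up a class by local name (fixtures and tests address classes by name).
class_by_name <- function(schema, name) {
  for (cls in schema$classes) if (cls$name == name) return(cls)
  og_stop(paste0("unknown class name ", name), "unknown_class")
}
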