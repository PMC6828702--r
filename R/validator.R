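# Closed-world conformance checking of an RDF instance graph against a
# schema. Every subject carrying an rdf:type is checked against that type's
# flattened property list: required links must be present (the closed-world
# interpretation: their absence is an error, not an unknown), cardinalities
# must hold, referenced objects must carry a compatible type, value-set values
# must be members of the set, and any predicate outside the property list
# (other than rdf:type) is reported as unknown.
#
# The checker runs on plain character vectors with a per-subject row index,
# built once per graph: the mutation-robustness suites validate thousands of
# small graphs, so per-call overhead matters.

VIOLATION_KINDS <- c("UNKNOWN_PREDICATE", "MISSING_REQUIRED",
                     "CARDINALITY_EXCEEDED", "WRONG_TARGET_TYPE",
                     "UNTYPED_NODE", "VALUE_SET_VIOLATION", "MALFORMED_LIST",
                     "NON_SCHEMA_TYPE")

violation_row <- function(kind, subject, predicate, detail) {
  data.frame(kind = kind, subject = subject,
             predicate = if (is.null(predicate)) NA_character_ else predicate,
             detail = detail, stringsAsFactors = FALSE)
}

empty_violations <- function() {
  violation_row(character(0), character(0), character(0), character(0))
}

# Flattened per-class property tables and type-compatibility sets, computed
# once per validation run.
schema_index <- function(schema) {
  idx <- new.env(parent = emptyenv())
  idx$classes <- names(schema$classes)
  idx$props <- lapply(schema$classes, function(cls) NULL)
  for (iri in names(schema$classes)) {
    props <- effective_properties(schema, iri)
    idx$props[[iri]] <- list(
      by_iri = structure(props, names = vapply(props, function(p) p$iri, "")),
      iris = vapply(props, function(p) p$iri, ""))
  }
  idx$compatible <- lapply(structure(names(schema$classes),
                                     names = names(schema$classes)),
                           function(iri) compatible_types(schema, iri))
  idx$vs_members <- lapply(schema$value_sets, function(v) names(v$members))
  idx
}

# Column-wise view of a graph plus per-subject row index and object-type map.
graph_index <- function(graph) {
  t <- graph$triples
  g <- new.env(parent = emptyenv())
  g$s <- t$s; g$p <- t$p; g$o <- t$o
  g$ok <- t$o_kind; g$dt <- t$dt; g$lang <- t$lang
  g$rows_by_s <- split(seq_along(g$s), g$s)
  is_type <- g$p == RDF_TYPE & g$ok != "literal"
  g$types_of_node <- split(g$o[is_type], g$s[is_type])
  g$typed <- unique(g$s[is_type])
  g
}

walk_collection_idx <- function(g, head, head_kind) {
  rows <- integer(0)
  seen <- character(0)
  node <- head
  kind <- head_kind
  repeat {
    if (kind == "literal") {
      return(list(ok = FALSE, rows = rows,
                  detail = "rdf:rest points at a literal"))
    }
    if (node == RDF_NIL) return(list(ok = TRUE, rows = rows, detail = ""))
    if (node %in% seen) {
      return(list(ok = FALSE, rows = rows, detail = "cyclic rdf:rest chain"))
    }
    seen <- c(seen, node)
    rs <- g$rows_by_s[[node]]
    firsts <- rs[g$p[rs] == RDF_FIRST]
    rests <- rs[g$p[rs] == RDF_REST]
    if (length(firsts) != 1L || length(rests) != 1L) {
      return(list(ok = FALSE, rows = rows,
                  detail = sprintf("list node has %d rdf:first and %d rdf:rest",
                                   length(firsts), length(rests))))
    }
    rows <- c(rows, firsts)
    node <- g$o[rests]
    kind <- g$ok[rests]
  }
}

walk_container_idx <- function(g, node, node_kind) {
  if (node_kind == "literal") {
    return(list(ok = FALSE, rows = integer(0),
                detail = "container head is a literal"))
  }
  rs <- g$rows_by_s[[node]]
  memb <- rs[startsWith(g$p[rs], paste0(NS_RDF, "_"))]
  memb <- memb[grepl("^[0-9]+$", substring(g$p[memb], nchar(NS_RDF) + 2L))]
  if (length(memb) == 0L) {
    return(list(ok = FALSE, rows = integer(0),
                detail = "container has no rdf:_n members"))
  }
  n <- as.integer(substring(g$p[memb], nchar(NS_RDF) + 2L))
  if (anyDuplicated(n) || !setequal(n, seq_len(max(n)))) {
    return(list(ok = FALSE, rows = integer(0),
                detail = "rdf:_n membership indices not contiguous from 1"))
  }
  list(ok = TRUE, rows = memb[order(n)], detail = "")
}

check_literal_lex <- function(lex, dt, lang, datatype) {
  ok <- switch(datatype,
    string = is.na(dt) || dt == XSD_STRING || !is.na(lang),
    integer = (!is.na(dt) && dt == XSD_INTEGER) ||
      (is.na(dt) && grepl("^[+-]?[0-9]+$", lex)),
    double = (!is.na(dt) && dt %in% c(XSD_DOUBLE, paste0(NS_XSD, "decimal"),
                                      paste0(NS_XSD, "float"))) ||
      (is.na(dt) && grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$",
                          lex)),
    boolean = (!is.na(dt) && dt == XSD_BOOLEAN) ||
      (is.na(dt) && lex %in% c("true", "false")),
    anyURI = (is.na(dt) || dt == XSD_ANYURI) && is_absolute_iri(lex))
  if (ok) NULL
  else sprintf("value \"%s\"%s is not a valid xsd:%s", lex,
               if (!is.na(dt)) paste0("^^<", dt, ">") else "", datatype)
}

check_node_against_class_idx <- function(node, class_iri, g, idx) {
  out <- list()
  add <- function(kind, predicate, detail) {
    out[[length(out) + 1L]] <<- list(kind, node, predicate, detail)
  }
  if (!class_iri %in% idx$classes) {
    add("NON_SCHEMA_TYPE", RDF_TYPE,
        sprintf("rdf:type <%s> is not a class of the schema", class_iri))
    return(out)
  }
  pinfo <- idx$props[[class_iri]]
  rs <- g$rows_by_s[[node]]
  p_here <- g$p[rs]
  unknown <- setdiff(unique(p_here), c(pinfo$iris, RDF_TYPE))
  for (p in unknown) {
    add("UNKNOWN_PREDICATE", p,
        sprintf("predicate <%s> is not defined for class <%s>", p, class_iri))
  }
  for (p in pinfo$by_iri) {
    vrows <- rs[p_here == p$iri]
    nv <- length(vrows)
    if (p$mult$ordered != "none") {
      if (nv == 0L) {
        if (p$mult$min == 1L) {
          add("MISSING_REQUIRED", p$iri,
              sprintf("required list property %s is absent", p$name))
        }
        next
      }
      if (nv > 1L) {
        add("CARDINALITY_EXCEEDED", p$iri,
            sprintf("%d list heads for property %s (at most 1 allowed)", nv,
                    p$name))
      }
      walked <- if (p$mult$ordered == "ordered") {
        walk_collection_idx(g, g$o[vrows[1L]], g$ok[vrows[1L]])
      } else {
        walk_container_idx(g, g$o[vrows[1L]], g$ok[vrows[1L]])
      }
      if (!walked$ok) {
        add("MALFORMED_LIST", p$iri,
            sprintf("property %s: %s", p$name, walked$detail))
        next
      }
      if (p$mult$min == 1L && length(walked$rows) == 0L) {
        add("MISSING_REQUIRED", p$iri,
            sprintf("required list property %s is empty", p$name))
      }
      vrows <- walked$rows
      nv <- length(vrows)
    } else {
      if (nv < p$mult$min) {
        add("MISSING_REQUIRED", p$iri,
            sprintf("required property %s is absent", p$name))
        next
      }
      if (nv > p$mult$max) {
        add("CARDINALITY_EXCEEDED", p$iri,
            sprintf("%d values for property %s (at most %d allowed)", nv,
                    p$name, p$mult$max))
      }
    }
    if (nv == 0L) next
    tgt <- p$target
    if (tgt$kind == "primitive") {
      for (i in vrows) {
        if (g$ok[i] != "literal") {
          add("WRONG_TARGET_TYPE", p$iri,
              sprintf("property %s expects a %s literal, found %s", p$name,
                      tgt$datatype, g$ok[i]))
          next
        }
        detail <- check_literal_lex(g$o[i], g$dt[i], g$lang[i], tgt$datatype)
        if (!is.null(detail)) {
          add("WRONG_TARGET_TYPE", p$iri,
              sprintf("property %s: %s", p$name, detail))
        }
      }
    } else if (tgt$kind == "class") {
      compat <- idx$compatible[[tgt$target_iri]]
      if (is.null(compat)) compat <- tgt$target_iri
      for (i in vrows) {
        if (g$ok[i] == "literal") {
          add("WRONG_TARGET_TYPE", p$iri,
              sprintf("property %s expects an object, found literal \"%s\"",
                      p$name, g$o[i]))
          next
        }
        otypes <- g$types_of_node[[g$o[i]]]
        if (is.null(otypes)) {
          add("UNTYPED_NODE", p$iri,
              sprintf("object <%s> of property %s has no rdf:type", g$o[i],
                      p$name))
        } else if (!any(otypes %in% compat)) {
          add("WRONG_TARGET_TYPE", p$iri,
              sprintf("object <%s> of property %s is typed [%s], expected %s",
                      g$o[i], p$name, paste(otypes, collapse = ", "),
                      tgt$target_iri))
        }
      }
    } else if (tgt$kind == "value_set") {
      members <- idx$vs_members[[tgt$target_iri]]
      for (i in vrows) {
        if (g$ok[i] != "iri" || !g$o[i] %in% members) {
          add("VALUE_SET_VIOLATION", p$iri,
              sprintf("value %s of property %s is not a member of <%s>",
                      if (g$ok[i] == "literal") paste0("\"", g$o[i], "\"")
                      else paste0("<", g$o[i], ">"),
                      p$name, tgt$target_iri))
        }
      }
    } else { # external
      for (i in vrows) {
        if (g$ok[i] == "literal") {
          add("WRONG_TARGET_TYPE", p$iri,
              sprintf("property %s expects an IRI, found literal \"%s\"",
                      p$name, g$o[i]))
        } else if (g$ok[i] == "iri" && !is_absolute_iri(g$o[i])) {
          add("WRONG_TARGET_TYPE", p$iri,
              sprintf("property %s: <%s> is not an absolute IRI", p$name,
                      g$o[i]))
        }
      }
    }
  }
  out
}

collect_violations <- function(records) {
  if (!length(records)) return(empty_violations())
  v <- data.frame(
    kind = vapply(records, `[[`, "", 1L),
    subject = vapply(records, `[[`, "", 2L),
    predicate = vapply(records, `[[`, "", 3L),
    detail = vapply(records, `[[`, "", 4L),
    stringsAsFactors = FALSE)
  v <- v[!duplicated(v[c("kind", "subject", "predicate")]), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Validate an instance graph against a schema
#'
#' @param data An [rdf_graph()] of instance data (or a path to a Turtle file).
#' @param schema An `og_schema`.
#' @return A `validation_report`: violations table, number of checked
#'   instances, and a `conforms` flag that is `TRUE` iff no violations were
#'   found.
#' @export
validate_graph <- function(data, schema) {
  if (is.character(data)) {
    data <- tryCatch(turtle_parse(file = data), error = function(e) {
      og_stop(paste0("cannot parse data graph: ", conditionMessage(e)),
              "input_error")
    })
  }
  idx <- schema_index(schema)
  g <- graph_index(data)
  acc <- list()
  for (node in g$typed) {
    for (cls in g$types_of_node[[node]]) {
      acc <- c(acc, check_node_against_class_idx(node, cls, g, idx))
    }
  }
  violations <- collect_violations(acc)
  structure(list(violations = violations,
                 checked_instances = length(g$typed),
                 conforms = nrow(violations) == 0L),
            class = "validation_report")
}

#' Check a single typed node against one class
#'
#' The per-instance unit of [validate_graph()]: returns only violations
#' attributable to `node` interpreted as an instance of `class_iri`.
#'
#' @param node Subject IRI or blank-node label.
#' @param class_iri Class to check against; a class outside the schema yields
#'   a `NON_SCHEMA_TYPE` violation, not an error.
#' @param data An [rdf_graph()].
#' @param schema An `og_schema`.
#' @return A data frame of violations (possibly empty).
#' @export
check_instance <- function(node, class_iri, data, schema) {
  idx <- schema_index(schema)
  g <- graph_index(data)
  collect_violations(check_node_against_class_idx(node, class_iri, g, idx))
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", x$checked_instances, " instance(s) checked: ",
      if (x$conforms) "conforms" else
        paste0(nrow(x$violations), " violation(s)"), "\n", sep = "")
  if (!x$conforms) {
    tab <- x$violations
    tab$subject <- substr(tab$subject, 1L, 48L)
    tab$detail <- substr(tab$detail, 1L, 60L)
    print(tab[, c("kind", "subject", "detail")], right = FALSE)
  }
  invisible(x)
}

#' Serialise a validation report as JSON
#'
#' @param report A `validation_report`.
#' @param path Optional output path; when given the JSON is written there.
#' @return JSON text, invisibly when `path` is given.
#' @export
report_to_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(list(conforms = report$conforms,
                                checked_instances = report$checked_instances,
                                violations = report$violations),
                           auto_unbox = TRUE, na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
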