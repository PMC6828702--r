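# Instance store: the runtime behind the generated data-binding API. Data
# built through it is correct by construction — setters type-check their
# targets and multiplicities at call time, and export refuses to serialise
# while any instance misses a required property or references an object
# absent from the store.

#' Create an instance store
#'
#' @param schema An `og_schema`; instances are checked against it at set time
#'   and again at export time.
#' @return An `instance_store` (environment).
#' @export
new_instance_store <- function(schema) {
  store <- new.env(parent = emptyenv())
  store$schema <- schema
  store$instances <- list()   # iri -> list(class_iri, props)
  store$order <- character(0)
  store$counter <- 0L
  class(store) <- "instance_store"
  store
}

#' @export
print.instance_store <- function(x, ...) {
  cat("<instance_store> ", length(x$instances), " instance(s) under ",
      x$schema$base_iri, "\n", sep = "")
  invisible(x)
}

resolve_class_iri <- function(schema, class_ref) {
  if (!is.null(schema$classes[[class_ref]])) return(class_ref)
  class_by_name(schema, class_ref)$iri
}

#' Create a typed instance in a store
#'
#' Every instance records its `rdf:type` on creation. When `iri` is `NULL` a
#' fresh IRI is minted as `<base><ClassName>_<n>` with a monotone counter,
#' collision-checked against the store (duplicate IRIs are an error class the
#' validator exists to prevent).
#'
#' @param store An [new_instance_store()].
#' @param class_ref Class IRI or local class name.
#' @param iri Optional explicit IRI.
#' @return An `og_instance` handle.
#' @export
store_create <- function(store, class_ref, iri = NULL) {
  schema <- store$schema
  class_iri <- resolve_class_iri(schema, class_ref)
  if (is.null(iri)) {
    repeat {
      store$counter <- store$counter + 1L
      iri <- paste0(schema$base_iri, schema$classes[[class_iri]]$name, "_",
                    store$counter)
      if (is.null(store$instances[[iri]])) break
    }
  } else if (!is.null(store$instances[[iri]])) {
    og_stop(paste0("IRI already in use in this store: ", iri),
            "binding_error")
  }
  store$instances[[iri]] <- list(class_iri = class_iri, props = list())
  store$order <- c(store$order, iri)
  structure(list(iri = iri, class_iri = class_iri), class = "og_instance")
}

#' @export
print.og_instance <- function(x, ...) {
  cat("<og_instance> <", x$iri, "> a <", x$class_iri, ">\n", sep = "")
  invisible(x)
}

instance_iri <- function(x) {
  # accepts an og_instance, a generated binding object (a list carrying $iri),
  # or a bare IRI string
  if (is.list(x) && !is.null(x$iri)) x$iri else x
}

find_property <- function(schema, class_iri, name) {
  props <- effective_properties(schema, class_iri)
  p <- props[[name]]
  if (is.null(p)) {
    og_stop(paste0("class ", schema$classes[[class_iri]]$name,
                   " has no property '", name, "'"), "binding_error")
  }
  p
}

# Coerce + type-check one value for a property target; returns the stored
# representation: list(o, o_kind, dt).
check_value <- function(store, p, value) {
  schema <- store$schema
  tgt <- p$target
  fail <- function(msg) {
    og_stop(paste0("property ", p$name, ": ", msg), "binding_error")
  }
  if (tgt$kind == "primitive") {
    ok <- switch(tgt$datatype,
                 string = is.character(value),
                 integer = is.numeric(value) && !is.na(value) &&
                   value == round(value),
                 double = is.numeric(value),
                 boolean = is.logical(value) && !is.na(value),
                 anyURI = is.character(value) && is_absolute_iri(value))
    if (length(value) != 1L || !ok) {
      fail(paste0("expected a scalar ", tgt$datatype))
    }
    lex <- switch(tgt$datatype,
                  string = value,
                  integer = sprintf("%d", as.integer(value)),
                  double = sprintf("%.15g", as.double(value)),
                  boolean = if (value) "true" else "false",
                  anyURI = value)
    dt <- if (tgt$datatype == "string") NA_character_
    else primitive_xsd(tgt$datatype)
    return(list(o = lex, o_kind = "literal", dt = dt))
  }
  if (tgt$kind == "class") {
    iri <- instance_iri(value)
    if (!is.character(iri) || length(iri) != 1L) {
      fail("expected an instance (or its IRI)")
    }
    inst <- store$instances[[iri]]
    if (!is.null(inst)) {
      compat <- compatible_types(schema, tgt$target_iri)
      if (!inst$class_iri %in% compat) {
        fail(paste0("instance <", iri, "> has type <", inst$class_iri,
                    ">, expected ", tgt$target_iri, " or a subclass"))
      }
    }
    # unknown IRIs stay allowed here; export checks for dangling references
    return(list(o = iri, o_kind = if (is_bnode(iri)) "bnode" else "iri",
                dt = NA_character_))
  }
  if (tgt$kind == "value_set") {
    iri <- instance_iri(value)
    members <- value_set_members(schema, tgt$target_iri)
    if (!is.character(iri) || length(iri) != 1L) {
      fail("expected a value-set member IRI or local name")
    }
    if (!iri %in% members) {
      # member local names are accepted as a convenience
      hit <- members[vapply(members, function(m) {
        local_name(m, schema$base_iri) == iri
      }, NA)]
      if (length(hit) == 1L) iri <- unname(hit)
      else fail(paste0("value is not a member of the ",
                       schema$value_sets[[tgt$target_iri]]$name, " set"))
    }
    return(list(o = iri, o_kind = "iri", dt = NA_character_))
  }
  # external
  iri <- instance_iri(value)
  if (!is.character(iri) || length(iri) != 1L || !is_absolute_iri(iri)) {
    fail("expected an absolute IRI")
  }
  list(o = iri, o_kind = "iri", dt = NA_character_)
}

#' Set a single-valued property
#'
#' Overwrites any previous value. Only legal for `0..1` / `1..1` properties.
#'
#' @param store An [new_instance_store()].
#' @param instance An `og_instance` (or its IRI).
#' @param name Property local name.
#' @param value New value: an R scalar for primitive targets, an instance or
#'   IRI for class targets, a member IRI (or member local name) for value-set
#'   targets, an absolute IRI for external targets.
#' @return `instance`, invisibly.
#' @export
store_set <- function(store, instance, name, value) {
  iri <- instance_iri(instance)
  inst <- store$instances[[iri]]
  if (is.null(inst)) og_stop(paste0("no such instance: ", iri),
                             "binding_error")
  p <- find_property(store$schema, inst$class_iri, name)
  if (is.infinite(p$mult$max)) {
    og_stop(paste0("property ", name,
                   " is multi-valued; use store_add()"), "binding_error")
  }
  store$instances[[iri]]$props[[name]] <- list(check_value(store, p, value))
  invisible(instance)
}

#' Append a value to a multi-valued property
#'
#' Only legal for `0..N` / `1..N` properties; insertion order is preserved
#' (and is the serialised order for ordered/numbered list properties).
#'
#' @inheritParams store_set
#' @return `instance`, invisibly.
#' @export
store_add <- function(store, instance, name, value) {
  iri <- instance_iri(instance)
  inst <- store$instances[[iri]]
  if (is.null(inst)) og_stop(paste0("no such instance: ", iri),
                             "binding_error")
  p <- find_property(store$schema, inst$class_iri, name)
  if (!is.infinite(p$mult$max)) {
    og_stop(paste0("property ", name,
                   " is single-valued; use store_set()"), "binding_error")
  }
  cur <- store$instances[[iri]]$props[[name]]
  store$instances[[iri]]$props[[name]] <- c(
    if (is.null(cur)) list() else cur, list(check_value(store, p, value)))
  invisible(instance)
}

#' Remove values from a multi-valued property
#'
#' @inheritParams store_set
#' @param value Value to remove; `NULL` removes all values.
#' @return `instance`, invisibly.
#' @export
store_remove <- function(store, instance, name, value = NULL) {
  iri <- instance_iri(instance)
  inst <- store$instances[[iri]]
  if (is.null(inst)) og_stop(paste0("no such instance: ", iri),
                             "binding_error")
  if (is.null(value)) {
    store$instances[[iri]]$props[[name]] <- NULL
  } else {
    tgt <- instance_iri(value)
    cur <- inst$props[[name]]
    keep <- vapply(cur, function(v) !identical(v$o, as.character(tgt)), NA)
    store$instances[[iri]]$props[[name]] <-
      if (any(keep)) cur[keep] else NULL
  }
  invisible(instance)
}

#' Read back stored values of a property
#'
#' @inheritParams store_set
#' @return Character vector of stored lexical forms / IRIs, in insertion
#'   order.
#' @export
store_get <- function(store, instance, name) {
  inst <- store$instances[[instance_iri(instance)]]
  vapply(inst$props[[name]], function(v) v$o, "")
}

#' Export the store as a Turtle document
#'
#' Refuses to serialise while any instance misses a required (min-cardinality
#' 1) property or references an object absent from the store; the error lists
#' every offending instance/property. Ordered-list properties serialise as RDF
#' collections, numbered-list properties as `rdf:_1`, `rdf:_2`, ... container
#' membership.
#'
#' @param store An [new_instance_store()].
#' @param path Optional file path to also write the Turtle text to.
#' @return Turtle text (invisibly when `path` is given).
#' @export
export_graph <- function(store, path = NULL) {
  schema <- store$schema
  problems <- character(0)
  for (iri in store$order) {
    inst <- store$instances[[iri]]
    props <- effective_properties(schema, inst$class_iri)
    for (p in props) {
      vals <- inst$props[[p$name]]
      if (p$mult$min == 1L && length(vals) == 0L) {
        problems <- c(problems, sprintf(
          "missing required: <%s> lacks property %s", iri, p$name))
      }
      if (!is.null(vals) && p$target$kind == "class") {
        for (v in vals) {
          if (is.null(store$instances[[v$o]])) {
            problems <- c(problems, sprintf(
              "dangling reference: <%s> property %s points at <%s> which is not in the store",
              iri, p$name, v$o))
          }
        }
      }
      if (!is.null(vals) && p$target$kind == "value_set") {
        members <- value_set_members(schema, p$target$target_iri)
        for (v in vals) {
          if (!v$o %in% members) {
            problems <- c(problems, sprintf(
              "value-set violation: <%s> property %s value <%s>", iri,
              p$name, v$o))
          }
        }
      }
    }
  }
  if (length(problems)) {
    og_stop(paste0("export refused; the store is inconsistent:\n  ",
                   paste(problems, collapse = "\n  ")), "export_error",
            problems = problems)
  }
  acc <- list()
  order <- character(0)
  bn <- 0L
  for (iri in store$order) {
    inst <- store$instances[[iri]]
    acc[[length(acc) + 1L]] <- triple_rows(iri, RDF_TYPE, inst$class_iri,
                                           "iri")
    order <- c(order, iri)
    props <- effective_properties(schema, inst$class_iri)
    for (p in props) {
      vals <- inst$props[[p$name]]
      if (is.null(vals)) next
      if (p$mult$ordered == "ordered") {
        nodes <- vapply(seq_along(vals), function(k) {
          bn <<- bn + 1L
          paste0("_:l", bn)
        }, "")
        acc[[length(acc) + 1L]] <- triple_rows(iri, p$iri, nodes[1L], "bnode")
        for (k in seq_along(vals)) {
          v <- vals[[k]]
          acc[[length(acc) + 1L]] <- triple_rows(nodes[k], RDF_FIRST, v$o,
                                                 v$o_kind, v$dt)
          nxt <- if (k < length(vals)) nodes[k + 1L] else RDF_NIL
          acc[[length(acc) + 1L]] <- triple_rows(
            nodes[k], RDF_REST, nxt, if (nxt == RDF_NIL) "iri" else "bnode")
          order <- c(order, nodes[k])
        }
      } else if (p$mult$ordered == "numbered") {
        bn <- bn + 1L
        cn <- paste0("_:c", bn)
        acc[[length(acc) + 1L]] <- triple_rows(iri, p$iri, cn, "bnode")
        for (k in seq_along(vals)) {
          v <- vals[[k]]
          acc[[length(acc) + 1L]] <- triple_rows(
            cn, paste0(NS_RDF, "_", k), v$o, v$o_kind, v$dt)
        }
        order <- c(order, cn)
      } else {
        for (v in vals) {
          acc[[length(acc) + 1L]] <- triple_rows(iri, p$iri, v$o, v$o_kind,
                                                 v$dt)
        }
      }
    }
  }
  graph <- rdf_graph(schema$prefixes)
  if (length(acc)) graph$triples <- do.call(rbind, acc)
  text <- turtle_serialize(graph, subject_order = order,
                           all_prefixes = length(acc) == 0L)
  if (!is.null(path)) {
    writeLines(text, path, useBytes = TRUE)
    return(invisible(text))
  }
  text
}
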