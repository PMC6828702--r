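# Conformance testkit: seeded generation of random schemas, conforming
# instance graphs, and minimal single-fault mutations, one per violation kind.
# All randomness flows through with_seed(); the global RNG state is left
# untouched.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rand_word <- function(n = 1L, len = 6L) {
  vapply(seq_len(n), function(i) {
    paste(sample(letters, len, replace = TRUE), collapse = "")
  }, "")
}

#' Generate a random valid schema
#'
#' A random single-parent class tree with properties drawn over all target
#' kinds and all four multiplicities (including ordered and numbered list
#' forms), plus optional value sets with nested members. Identical seeds give
#' identical schemas.
#'
#' @param seed Integer seed.
#' @param n_classes Number of classes (>= 1).
#' @param n_value_sets Number of value sets.
#' @return An `og_schema`.
#' @export
random_schema <- function(seed, n_classes = 8L, n_value_sets = 1L) {
  stopifnot(n_classes >= 1L)
  with_seed(seed, {
    base <- "http://example.org/schema/"
    vsets <- lapply(seq_len(n_value_sets), function(j) {
      vs_iri <- paste0(base, "Set", j)
      n_members <- sample(2:4, 1L)
      members <- paste0(vs_iri, "Member", seq_len(n_members))
      parents <- rep(vs_iri, n_members)
      if (n_members > 2L && stats::runif(1) < 0.4) {
        parents[n_members] <- members[1L]   # one nested sub-member
      }
      value_set_def(vs_iri, paste0("Set", j),
                    members = structure(parents, names = members))
    })
    prop_counter <- 0L
    class_iris <- paste0(base, "Class", seq_len(n_classes))
    classes <- vector("list", n_classes)
    for (i in seq_len(n_classes)) {
      parent <- if (i > 1L && stats::runif(1) < 0.7) {
        class_iris[sample.int(i - 1L, 1L)]
      } else NULL
      n_props <- sample(0:3, 1L)
      props <- lapply(seq_len(n_props), function(k) {
        prop_counter <<- prop_counter + 1L
        name <- paste0("prop", prop_counter, rand_word(1L, 3L))
        kind <- sample(c("primitive", "class", "value_set", "external"), 1L,
                       prob = c(0.4, 0.3, if (n_value_sets) 0.2 else 0, 0.1))
        target <- switch(kind,
          primitive = target_primitive(sample(PRIMITIVE_TYPES, 1L)),
          class = target_class(class_iris[sample.int(n_classes, 1L)]),
          value_set = target_value_set(
            vsets[[sample.int(n_value_sets, 1L)]]$iri),
          external = if (stats::runif(1) < 0.5) target_external()
          else target_external(paste0("http://other.org/onto/T",
                                      sample.int(99L, 1L))))
        mult_form <- sample(c("0..1", "1..1", "0..N", "1..N"), 1L)
        ordered <- "none"
        if (grepl("N", mult_form) && stats::runif(1) < 0.35) {
          ordered <- sample(c("ordered", "numbered"), 1L)
        }
        property_def(name, paste0(base, name), target,
                     multiplicity(as.integer(substring(mult_form, 1L, 1L)),
                                  if (grepl("N", mult_form)) Inf else 1,
                                  ordered),
                     description = if (stats::runif(1) < 0.3) {
                       paste("randomly generated property", name)
                     } else NULL)
      })
      classes[[i]] <- class_def(class_iris[i], paste0("Class", i),
                                parent = parent, properties = props)
    }
    schema(base, classes = classes, value_sets = vsets,
           prefixes = c(ex = base), base_prefix = "ex")
  })
}

random_literal <- function(datatype) {
  switch(datatype,
         string = rand_word(1L, sample(3:8, 1L)),
         integer = sample.int(1000000L, 1L) - 1L,
         double = round(stats::runif(1) * 1000, 3),
         boolean = sample(c(TRUE, FALSE), 1L),
         anyURI = paste0("http://example.org/res/", rand_word(1L, 5L)))
}

#' Generate a conforming instance graph for a schema
#'
#' Instances are allocated first and linked afterwards, so mutually required
#' references never deadlock. The data is built through the binding runtime
#' ([new_instance_store()]) and exported, so the result is correct by
#' construction; [validate_graph()] on the output reports zero violations.
#'
#' @param schema An `og_schema`.
#' @param seed Integer seed.
#' @param n_instances Number of seed instances (dependencies may add more).
#' @return An [rdf_graph()].
#' @export
conforming_instances <- function(schema, seed, n_instances = 6L) {
  with_seed(seed, {
    store <- new_instance_store(schema)
    class_iris <- names(schema$classes)
    cap <- n_instances * 5L + 20L
    queue <- character(0)
    for (i in seq_len(n_instances)) {
      inst <- store_create(store, class_iris[sample.int(length(class_iris),
                                                        1L)])
      queue <- c(queue, inst$iri)
    }
    of_type <- function(compat) {
      hits <- names(store$instances)[vapply(store$instances, function(x) {
        x$class_iri %in% compat
      }, NA)]
      hits
    }
    while (length(queue)) {
      iri <- queue[1L]
      queue <- queue[-1L]
      inst <- store$instances[[iri]]
      for (p in effective_properties(schema, inst$class_iri)) {
        present <- p$mult$min == 1L || stats::runif(1) < 0.5
        if (!present) next
        n_vals <- if (is.infinite(p$mult$max)) sample.int(2L, 1L) else 1L
        for (k in seq_len(n_vals)) {
          value <- switch(p$target$kind,
            primitive = random_literal(p$target$datatype),
            external = paste0("http://other.org/ref/", rand_word(1L, 5L)),
            value_set = {
              members <- value_set_members(schema, p$target$target_iri)
              members[sample.int(length(members), 1L)]
            },
            class = {
              compat <- compatible_types(schema, p$target$target_iri)
              cands <- of_type(compat)
              if (length(cands) &&
                  (length(store$instances) >= cap || stats::runif(1) < 0.7)) {
                cands[sample.int(length(cands), 1L)]
              } else {
                child <- store_create(
                  store, compat[sample.int(length(compat), 1L)])
                queue <- c(queue, child$iri)
                child$iri
              }
            })
          if (is.infinite(p$mult$max)) store_add(store, iri, p$name, value)
          else store_set(store, iri, p$name, value)
        }
      }
    }
    turtle_parse(export_graph(store))
  })
}

value_triples_of_typed <- function(graph, idx, types_of_node) {
  # rows of property triples whose subject is typed with a schema class;
  # annotated with the property descriptor
  t <- graph$triples
  out <- list()
  for (node in names(types_of_node)) {
    for (cls in types_of_node[[node]]) {
      if (!cls %in% idx$classes) next
      pinfo <- idx$props[[cls]]
      rows <- which(t$s == node & t$p %in% pinfo$iris)
      for (r in rows) {
        out[[length(out) + 1L]] <- list(row = r, node = node, cls = cls,
                                        p = pinfo$by_iri[[t$p[r]]])
      }
    }
  }
  out
}

mutation_record <- function(kind, seed, subject, predicate, description) {
  structure(list(kind = kind, seed = seed, subject = subject,
                 predicate = predicate, description = description),
            class = "og_mutation")
}

#' @export
print.og_mutation <- function(x, ...) {
  cat("<og_mutation> ", x$kind, " at <", x$subject, "> ",
      if (!is.na(x$predicate)) paste0("<", x$predicate, "> ") else "",
      "(seed ", x$seed, ")\n  ", x$description, "\n", sep = "")
  invisible(x)
}

#' Corrupt a conforming graph with one seeded fault
#'
#' Applies the minimal edit that induces exactly the requested violation kind;
#' the same seed always picks the same site and edit. When the graph offers no
#' site for the kind (e.g. no list-valued property for `MALFORMED_LIST`), an
#' error of class `ontogen_not_applicable` is raised.
#'
#' @param graph A conforming [rdf_graph()].
#' @param schema The `og_schema` it conforms to.
#' @param kind One of the eight violation kinds.
#' @param seed Integer seed.
#' @return `list(graph = <mutated graph>, mutation = <og_mutation>)`.
#' @export
mutate_graph <- function(graph, schema, kind, seed) {
  kind <- match.arg(kind, VIOLATION_KINDS)
  idx <- schema_index(schema)
  t <- graph$triples
  type_rows <- t[t$p == RDF_TYPE & t$o_kind != "literal", , drop = FALSE]
  types_of_node <- split(type_rows$o, type_rows$s)
  vt <- value_triples_of_typed(graph, idx, types_of_node)
  not_applicable <- function(why) {
    og_stop(paste0("cannot induce ", kind, ": ", why), "not_applicable")
  }
  pick <- function(cands) cands[[sample.int(length(cands), 1L)]]
  with_seed(seed, {
    res <- switch(kind,
      MISSING_REQUIRED = {
        cands <- Filter(function(v) {
          v$p$mult$min == 1L && sum(t$s == v$node & t$p == v$p$iri) == 1L
        }, vt)
        if (!length(cands)) not_applicable("no required single-valued site")
        v <- pick(cands)
        t <- t[-v$row, , drop = FALSE]
        list(t, v$node, v$p$iri,
             sprintf("deleted the only value of required property %s",
                     v$p$name))
      },
      CARDINALITY_EXCEEDED = {
        cands <- Filter(function(v) {
          !is.infinite(v$p$mult$max) && v$p$mult$ordered == "none" &&
            (v$p$target$kind != "class" ||
               length(unique(t$s[t$p == RDF_TYPE &
                                   t$o %in% idx$compatible[[
                                     v$p$target$target_iri]]])) >= 2L)
        }, vt)
        if (!length(cands)) not_applicable("no single-valued site")
        v <- pick(cands)
        extra <- switch(v$p$target$kind,
          primitive = {
            lex <- switch(v$p$target$datatype,
              boolean = if (t$o[v$row] == "true") "false" else "true",
              integer = sprintf("%d", as.integer(t$o[v$row]) + 1L),
              double = sprintf("%.15g", as.numeric(t$o[v$row]) + 1),
              paste0(t$o[v$row], "x"))
            triple_rows(v$node, v$p$iri, lex, "literal", t$dt[v$row])
          },
          value_set = {
            members <- setdiff(idx$vs_members[[v$p$target$target_iri]],
                               t$o[v$row])
            if (!length(members)) {
              members <- idx$vs_members[[v$p$target$target_iri]]
            }
            triple_rows(v$node, v$p$iri, members[1L], "iri")
          },
          class = {
            compat <- idx$compatible[[v$p$target$target_iri]]
            objs <- setdiff(unique(t$s[t$p == RDF_TYPE & t$o %in% compat]),
                            t$o[v$row])
            triple_rows(v$node, v$p$iri, objs[1L],
                        if (is_bnode(objs[1L])) "bnode" else "iri")
          },
          external = triple_rows(v$node, v$p$iri,
                                 "http://other.org/ref/extra", "iri"))
        t <- rbind(t, extra)
        list(t, v$node, v$p$iri,
             sprintf("added a second value to single-valued property %s",
                     v$p$name))
      },
      UNKNOWN_PREDICATE = {
        cands <- Filter(function(v) {
          sum(t$s == v$node & t$p == v$p$iri) > v$p$mult$min
        }, vt)
        if (!length(cands)) not_applicable("every property sits at its minimum")
        v <- pick(cands)
        all_props <- unique(unlist(lapply(idx$props, function(p) p$iris)))
        typo <- paste0(t$p[v$row], "x")
        ch <- substring(t$p[v$row], nchar(t$p[v$row]))
        alt <- paste0(substring(t$p[v$row], 1L, nchar(t$p[v$row]) - 1L),
                      if (ch == "z") "y" else "z")
        if (!alt %in% all_props) typo <- alt
        t$p[v$row] <- typo
        list(t, v$node, typo,
             sprintf("perturbed predicate of %s to a typo", v$p$name))
      },
      WRONG_TARGET_TYPE = {
        cands <- Filter(function(v) v$p$target$kind == "primitive" &&
                          v$p$mult$ordered == "none", vt)
        if (length(cands)) {
          v <- pick(cands)
          if (v$p$target$datatype == "string") {
            t$o[v$row] <- "http://other.org/not/a/literal"
            t$o_kind[v$row] <- "iri"
            t$dt[v$row] <- NA_character_
          } else {
            t$o[v$row] <- "notanumber"
            t$dt[v$row] <- NA_character_
          }
          list(t, v$node, v$p$iri,
               sprintf("replaced %s value with an ill-typed one", v$p$name))
        } else {
          cands <- Filter(function(v) {
            v$p$target$kind == "class" && v$p$mult$ordered == "none" &&
              length(setdiff(
                unique(t$s[t$p == RDF_TYPE]),
                c(unique(t$s[t$p == RDF_TYPE &
                               t$o %in% idx$compatible[[
                                 v$p$target$target_iri]]]), v$node))) > 0L
          }, vt)
          if (!length(cands)) not_applicable("no typable site")
          v <- pick(cands)
          compat <- idx$compatible[[v$p$target$target_iri]]
          wrong <- setdiff(unique(t$s[t$p == RDF_TYPE]),
                           c(unique(t$s[t$p == RDF_TYPE & t$o %in% compat]),
                             v$node))
          t$o[v$row] <- wrong[1L]
          t$o_kind[v$row] <- if (is_bnode(wrong[1L])) "bnode" else "iri"
          list(t, v$node, v$p$iri,
               sprintf("repointed %s at an instance of an incompatible class",
                       v$p$name))
        }
      },
      UNTYPED_NODE = {
        cands <- Filter(function(v) {
          v$p$target$kind == "class" && v$p$mult$ordered == "none" &&
            t$o[v$row] != v$node
        }, vt)
        if (!length(cands)) not_applicable("no object-valued site")
        v <- pick(cands)
        obj <- t$o[v$row]
        t <- t[!(t$s == obj & t$p == RDF_TYPE), , drop = FALSE]
        list(t, v$node, v$p$iri,
             sprintf("deleted rdf:type of <%s>, the object of %s", obj,
                     v$p$name))
      },
      VALUE_SET_VIOLATION = {
        cands <- Filter(function(v) v$p$target$kind == "value_set" &&
                          v$p$mult$ordered == "none", vt)
        if (!length(cands)) not_applicable("no value-set site")
        v <- pick(cands)
        t$o[v$row] <- paste0(schema$base_iri, "NotAMemberOfAnything")
        t$o_kind[v$row] <- "iri"
        list(t, v$node, v$p$iri,
             sprintf("replaced %s value with a non-member IRI", v$p$name))
      },
      MALFORMED_LIST = {
        cands <- Filter(function(v) v$p$mult$ordered != "none", vt)
        if (!length(cands)) not_applicable("no list-valued property")
        v <- pick(cands)
        if (v$p$mult$ordered == "ordered") {
          heads <- t$o[v$row]
          rest_rows <- which(t$p == RDF_REST)
          # walk to collect the chain nodes, drop one rdf:rest
          chain <- character(0)
          node <- heads
          while (node != RDF_NIL) {
            chain <- c(chain, node)
            node <- t$o[t$s == node & t$p == RDF_REST][1L]
          }
          drop_node <- chain[sample.int(length(chain), 1L)]
          t <- t[!(t$s == drop_node & t$p == RDF_REST), , drop = FALSE]
          list(t, v$node, v$p$iri,
               "removed one rdf:rest link from an ordered collection")
        } else {
          cn <- t$o[v$row]
          memb <- which(t$s == cn & grepl(paste0("^", NS_RDF, "_[0-9]+$"),
                                          t$p))
          r <- memb[sample.int(length(memb), 1L)]
          t$p[r] <- paste0(NS_RDF, "_",
                           as.integer(sub(paste0("^", NS_RDF, "_"), "",
                                          t$p[r])) + 17L)
          list(t, v$node, v$p$iri,
               "renumbered one rdf:_n membership property out of sequence")
        }
      },
      NON_SCHEMA_TYPE = {
        referenced <- unique(t$o[t$o_kind != "literal" & t$p != RDF_TYPE])
        cands <- setdiff(names(types_of_node), referenced)
        if (!length(cands)) not_applicable("every typed node is referenced")
        node <- cands[sample.int(length(cands), 1L)]
        r <- which(t$s == node & t$p == RDF_TYPE)[1L]
        t$o[r] <- paste0(schema$base_iri, "AlienClass")
        list(t, node, RDF_TYPE,
             "retyped an unreferenced instance with a class outside the schema")
      })
    out <- graph
    out$triples <- res[[1]]
    rownames(out$triples) <- NULL
    list(graph = out,
         mutation = mutation_record(kind, seed, res[[2]], res[[3]], res[[4]]))
  })
}
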