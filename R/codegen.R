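# Data-binding API generation. One R source unit per class and per value set:
# classes become constructor functions returning an accessor object (GET/SET
# for single-valued properties, GET/ADD/REMOVE for multi-valued ones), value
# sets become named constant vectors of member IRIs. The accessors delegate to
# the instance-store runtime, so everything built through the generated API is
# type- and multiplicity-checked at call time.

R_RESERVED <- c("if", "else", "repeat", "while", "function", "for", "next",
                "break", "TRUE", "FALSE", "NULL", "Inf", "NaN", "NA",
                "NA_integer_", "NA_real_", "NA_character_")

safe_unit_name <- function(name) {
  if (name %in% R_RESERVED) {
    warning("reserved word '", name, "' renamed to '", name, "_'",
            call. = FALSE)
    paste0(name, "_")
  } else name
}

upper_camel <- function(name) {
  paste0(toupper(substring(name, 1L, 1L)), substring(name, 2L))
}

accessor_kinds <- function(p) {
  if (is.infinite(p$mult$max)) c("get", "add", "remove") else c("get", "set")
}

gen_class_unit <- function(schema, cls) {
  fname <- safe_unit_name(cls$name)
  props <- effective_properties(schema, cls$iri)
  lines <- c(
    sprintf("# %s: %s", cls$name, cls$annotations$definition),
    if (!is.null(cls$parent)) {
      sprintf("# subclass of %s", schema$classes[[cls$parent]]$name)
    },
    sprintf("%s <- function(store, iri = NULL) {", fname),
    sprintf("  self <- ontogen::store_create(store, \"%s\", iri)", cls$iri),
    "  obj <- list(iri = self$iri, class_iri = self$class_iri)")
  for (p in props) {
    acc <- upper_camel(p$name)
    desc <- sprintf("  # %s (%s, %s)%s", p$name,
                    switch(p$target$kind,
                           primitive = paste0("xsd:", p$target$datatype),
                           class = local_name(p$target$target_iri,
                                              schema$base_iri),
                           value_set = paste0(
                             "@", local_name(p$target$target_iri,
                                             schema$base_iri)),
                           external = "IRI"),
                    format(p$mult),
                    if (!is.null(p$description)) {
                      paste0(": ", gsub("\n", " ", p$description))
                    } else "")
    lines <- c(lines, desc)
    if (is.infinite(p$mult$max)) {
      lines <- c(lines,
        sprintf("  obj$add%s <- function(value) { ontogen::store_add(store, self, \"%s\", value); invisible(obj) }",
                acc, p$name),
        sprintf("  obj$remove%s <- function(value = NULL) { ontogen::store_remove(store, self, \"%s\", value); invisible(obj) }",
                acc, p$name))
    } else {
      lines <- c(lines,
        sprintf("  obj$set%s <- function(value) { ontogen::store_set(store, self, \"%s\", value); invisible(obj) }",
                acc, p$name))
    }
    lines <- c(lines,
      sprintf("  obj$get%s <- function() ontogen::store_get(store, self, \"%s\")",
              acc, p$name))
  }
  lines <- c(lines, "  obj", "}", "")
  generated_artifact("api", paste0(fname, ".R"), paste(lines, collapse = "\n"))
}

gen_value_set_unit <- function(schema, vs) {
  members <- sort(names(vs$members))
  lines <- c(
    sprintf("# %s: %s (value set, %d members)", vs$name,
            vs$annotations$definition, length(members)),
    sprintf("%s <- c(", safe_unit_name(vs$name)),
    paste0("  ", vapply(members, function(m) {
      sprintf("%s = \"%s\"", local_name(m, schema$base_iri), m)
    }, ""), c(rep(",", length(members) - 1L), "")),
    ")", "")
  generated_artifact("api", paste0(safe_unit_name(vs$name), ".R"),
                     paste(lines, collapse = "\n"))
}

schema_checksum <- function(schema) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(emit_definition(schema)$content, tmp, useBytes = TRUE)
  unname(tools::md5sum(tmp))
}

#' Generate the typed data-binding API for a schema
#'
#' @param schema An `og_schema`.
#' @param out_dir Output directory; one `.R` source unit per class and value
#'   set plus a `manifest.json` is written when not `NULL`.
#' @return List of `generated_artifact`s (including the manifest), invisibly
#'   when `out_dir` is given.
#' @export
generate_api <- function(schema, out_dir = NULL) {
  units <- c(
    lapply(schema$classes[sort(names(schema$classes))],
           function(cls) gen_class_unit(schema, cls)),
    lapply(schema$value_sets[sort(names(schema$value_sets))],
           function(vs) gen_value_set_unit(schema, vs)))
  units <- unname(units)
  manifest <- jsonlite::toJSON(list(
    schema_base = schema$base_iri,
    schema_checksum = schema_checksum(schema),
    units = vapply(units, function(u) u$path, "")),
    auto_unbox = TRUE, pretty = TRUE)
  units <- c(units, list(generated_artifact("manifest", "manifest.json",
                                            as.character(manifest))))
  if (!is.null(out_dir)) {
    write_artifact(units, out_dir)
    return(invisible(units))
  }
  units
}
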