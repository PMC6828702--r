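# Markdown documentation generation: one page per class and per value set,
# laid out as <Name>/index.md so a static site rooted at the namespace makes
# the term IRIs resolvable, plus an index page with the class tree and a
# mkdocs site configuration enumerating every page.

doc_link <- function(from_root, name) {
  if (from_root) sprintf("[%s](%s/index.md)", name, name)
  else sprintf("[%s](../%s/index.md)", name, name)
}

doc_target_cell <- function(p, schema) {
  tgt <- p$target
  switch(tgt$kind,
    primitive = paste0("`xsd:", tgt$datatype, "`"),
    class = doc_link(FALSE, schema$classes[[tgt$target_iri]]$name),
    value_set = doc_link(FALSE, schema$value_sets[[tgt$target_iri]]$name),
    external = if (is.null(tgt$target_iri)) "external IRI"
    else sprintf("[%s](%s)", tgt$target_iri, tgt$target_iri))
}

doc_property_table <- function(props, schema) {
  if (!length(props)) return("*(none)*")
  rows <- vapply(props, function(p) {
    sprintf("| <a id=\"%s\"></a>`%s` | %s | `%s` | %s |", p$name, p$name,
            doc_target_cell(p, schema), format(p$mult),
            if (!is.null(p$description)) gsub("\n", " ", p$description)
            else "")
  }, "")
  paste(c("| Property | Target | Multiplicity | Description |",
          "| --- | --- | --- | --- |", rows), collapse = "\n")
}

doc_annotations_md <- function(ann) {
  out <- character(0)
  if (!is.null(ann$usage_comment)) {
    out <- c(out, paste0("**Usage:** ", ann$usage_comment))
  }
  if (!is.null(ann$editorial_comment)) {
    out <- c(out, paste0("**Editorial note:** ", ann$editorial_comment))
  }
  if (!is.null(ann$ddbj_label)) {
    out <- c(out, paste0("**DDBJ/GenBank label:** `", ann$ddbj_label, "`"))
  }
  if (length(ann$exact_matches)) {
    out <- c(out, paste0("**Exact matches:** ",
                         paste(sprintf("[%s](%s)", ann$exact_matches,
                                       ann$exact_matches),
                               collapse = ", ")))
  }
  out
}

doc_class_page <- function(schema, cls) {
  kids <- sort(vapply(
    Filter(function(c) identical(c$parent, cls$iri), schema$classes),
    function(c) c$name, "", USE.NAMES = FALSE))
  own <- cls$properties
  inherited <- effective_properties(schema, cls$iri)
  inherited <- inherited[setdiff(names(inherited), names(own))]
  body <- c(
    paste0("# ", cls$name),
    "",
    paste0("`<", cls$iri, ">`"),
    "",
    cls$annotations$definition,
    "",
    doc_annotations_md(cls$annotations),
    if (!is.null(cls$parent)) {
      c("", paste0("**Parent:** ",
                   doc_link(FALSE, schema$classes[[cls$parent]]$name)))
    },
    if (length(kids)) {
      c("", paste0("**Children:** ",
                   paste(vapply(kids, doc_link, "", from_root = FALSE),
                         collapse = ", ")))
    },
    "",
    "## Properties",
    "",
    doc_property_table(own, schema),
    if (length(inherited)) {
      c("", "## Inherited properties", "",
        doc_property_table(inherited, schema))
    })
  generated_artifact("doc", file.path(cls$name, "index.md"),
                     paste(body, collapse = "\n"))
}

doc_value_set_page <- function(schema, vs) {
  member_lines <- vapply(sort(names(vs$members)), function(m) {
    lvl <- if (vs$members[[m]] == vs$iri) "- " else "    - "
    paste0(lvl, "`<", m, ">`")
  }, "")
  body <- c(
    paste0("# ", vs$name),
    "",
    paste0("`<", vs$iri, ">`"),
    "",
    vs$annotations$definition,
    "",
    doc_annotations_md(vs$annotations),
    "",
    paste0("Value set with ", length(vs$members), " member(s):"),
    "",
    member_lines)
  generated_artifact("doc", file.path(vs$name, "index.md"),
                     paste(body, collapse = "\n"))
}

doc_tree_lines <- function(schema, parent = NULL, depth = 0L) {
  here <- Filter(function(c) identical(c$parent, parent), schema$classes)
  here <- here[order(vapply(here, function(c) c$name, ""))]
  unlist(lapply(here, function(c) {
    c(paste0(strrep("    ", depth), "- ", doc_link(TRUE, c$name)),
      doc_tree_lines(schema, c$iri, depth + 1L))
  }))
}

#' Generate Markdown documentation for a schema
#'
#' @param schema An `og_schema`.
#' @param out_dir Output directory; written when not `NULL`.
#' @return List of `generated_artifact`s: one page per class and value set, an
#'   index page, and a `mkdocs.yml` site configuration.
#' @export
generate_docs <- function(schema, out_dir = NULL) {
  classes <- schema$classes[sort(names(schema$classes))]
  vsets <- schema$value_sets[sort(names(schema$value_sets))]
  pages <- c(lapply(classes, function(c) doc_class_page(schema, c)),
             lapply(vsets, function(v) doc_value_set_page(schema, v)))
  pages <- unname(pages)
  index <- c(
    paste0("# Schema `", schema$base_iri, "`"),
    "",
    sprintf("%d classes, %d properties, %d value set(s).",
            schema_stats(schema)$classes, schema_stats(schema)$properties,
            schema_stats(schema)$value_sets),
    "",
    "## Class tree",
    "",
    doc_tree_lines(schema),
    if (length(vsets)) {
      c("", "## Value sets", "",
        vapply(vsets, function(v) paste0("- ", doc_link(TRUE, v$name)), ""))
    })
  pages <- c(list(generated_artifact("doc", "index.md",
                                     paste(index, collapse = "\n"))), pages)
  nav <- c(list(list(Home = "index.md")),
           lapply(pages[-1L], function(p) {
             stats::setNames(list(p$path), dirname(p$path))
           }))
  cfg <- yaml::as.yaml(list(site_name = paste0("Schema ", schema$base_iri),
                            docs_dir = ".", nav = nav))
  pages <- c(pages, list(generated_artifact("config", "mkdocs.yml", cfg)))
  if (!is.null(out_dir)) {
    write_artifact(pages, out_dir)
    return(invisible(pages))
  }
  pages
}
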