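# Independent ShExC oracle: parses the emitted ShExC text and evaluates nodes
# against shapes directly, without ever touching the schema model. Used to
# cross-check both the ShEx emitter (output must parse) and the closed-world
# validator (conformance verdicts must agree, apart from the two documented
# validator extensions: deep checks on rdf:_n containers and UNTYPED_NODE
# reporting granularity).

shex_oracle_parse <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub(" #.*$", "", lines)
  prefixes <- character(0)
  shapes <- list()
  resolve <- function(tok) {
    if (grepl("^<.*>$", tok)) return(substr(tok, 2L, nchar(tok) - 1L))
    if (grepl("^[A-Za-z0-9_]*:", tok)) {
      pfx <- sub(":.*$", "", tok)
      key <- if (pfx == "") ":" else pfx
      ns <- prefixes[key]
      if (is.na(ns)) stop("oracle: undeclared prefix in '", tok, "'")
      return(paste0(ns, sub("^[^:]*:", "", tok)))
    }
    stop("oracle: cannot resolve '", tok, "'")
  }
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (grepl("^PREFIX ", line)) {
      m <- regmatches(line, regexec("^PREFIX ([^ :]*): <([^>]*)>$", line))[[1]]
      if (length(m) != 3L) stop("oracle: bad PREFIX line: ", line)
      prefixes[if (m[2] == "") ":" else m[2]] <- m[3]
      i <- i + 1L
      next
    }
    m <- regmatches(line, regexec(
      "^(\\S+) CLOSED( EXTRA rdf:type)? \\{$", line))[[1]]
    if (!length(m)) stop("oracle: expected shape header, got: ", line)
    label <- resolve(m[2])
    extra_type <- nzchar(m[3])
    constraints <- list()
    i <- i + 1L
    repeat {
      if (i > n) stop("oracle: unterminated shape ", label)
      cline <- trimws(lines[i])
      i <- i + 1L
      if (cline == "}") break
      cline <- sub(" ;$", "", cline)
      if (!nzchar(cline)) next
      toks <- strsplit(cline, " +")[[1]]
      pred <- resolve(toks[1])
      rest <- toks[-1]
      card <- c(1L, 1L)
      last <- rest[length(rest)]
      if (last %in% c("?", "*", "+")) {
        card <- switch(last, "?" = c(0L, 1L), "*" = c(0L, .Machine$integer.max),
                       "+" = c(1L, .Machine$integer.max))
        rest <- rest[-length(rest)]
      }
      parse_expr <- function(toks) {
        if (length(toks) >= 2L && toks[1] == "(" &&
            toks[length(toks)] == ")") {
          toks <- toks[-c(1L, length(toks))]
        }
        # split into OR alternatives at bracket depth 0
        depth <- 0L
        alt_starts <- 1L
        alts <- list()
        cur <- character(0)
        for (tk in toks) {
          if (tk %in% c("(", "[")) depth <- depth + 1L
          if (tk %in% c(")", "]")) depth <- depth - 1L
          if (tk == "OR" && depth == 0L) {
            alts[[length(alts) + 1L]] <- cur
            cur <- character(0)
          } else cur <- c(cur, tk)
        }
        alts[[length(alts) + 1L]] <- cur
        if (length(alts) > 1L) {
          return(list(kind = "or", alts = lapply(alts, parse_expr)))
        }
        toks <- alts[[1L]]
        if (toks[1] == "[") {
          vals <- toks[-c(1L, length(toks))]
          list(kind = "values", values = vapply(vals, resolve, ""))
        } else if (startsWith(toks[1], "@")) {
          list(kind = "ref", ref = resolve(sub("^@", "", toks[1])))
        } else if (toks[1] == "IRI") {
          list(kind = "nodekind_iri")
        } else if (toks[1] == ".") {
          list(kind = "wildcard")
        } else {
          list(kind = "datatype", datatype = resolve(toks[1]))
        }
      }
      constraints[[length(constraints) + 1L]] <- list(pred = pred,
                                                      expr = parse_expr(rest),
                                                      card = card)
    }
    shapes[[label]] <- list(extra_type = extra_type,
                            constraints = constraints)
    if (i <= n && nzchar(trimws(lines[i]))) next
  }
  list(prefixes = prefixes, shapes = shapes)
}

shex_oracle_node_conforms <- function(node, shape_label, shapes, g, memo) {
  key <- paste0(node, "\r", shape_label)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)   # in-progress recursion assumes TRUE
  memo[[key]] <- TRUE
  shape <- shapes[[shape_label]]
  if (is.null(shape)) { memo[[key]] <- FALSE; return(FALSE) }
  t <- g$triples
  rows <- which(t$s == node)
  preds <- t$p[rows]
  closed_ok <- all(preds %in% c(vapply(shape$constraints, `[[`, "", "pred"),
                                if (shape$extra_type) RDF_TYPE))
  ok <- closed_ok
  for (con in shape$constraints) {
    if (!ok) break
    crows <- rows[preds == con$pred]
    eval_expr <- function(e, r) {
      switch(e$kind,
        or = any(vapply(e$alts, eval_expr, NA, r = r)),
        values = t$o_kind[r] != "literal" && t$o[r] %in% e$values,
        ref = t$o_kind[r] != "literal" &&
          shex_oracle_node_conforms(t$o[r], e$ref, shapes, g, memo),
        nodekind_iri = t$o_kind[r] == "iri",
        wildcard = TRUE,
        datatype = {
          if (t$o_kind[r] != "literal") FALSE
          else {
            dt <- t$dt[r]
            lex <- t$o[r]
            switch(sub("^.*#", "", e$datatype),
              string = is.na(dt) || dt == XSD_STRING || !is.na(t$lang[r]),
              integer = (!is.na(dt) && dt == XSD_INTEGER) ||
                (is.na(dt) && grepl("^[+-]?[0-9]+$", lex)),
              double = (!is.na(dt) && dt %in% c(XSD_DOUBLE,
                                                paste0(NS_XSD, "decimal"),
                                                paste0(NS_XSD, "float"))) ||
                (is.na(dt) && grepl("^[+-]?[0-9.eE+-]+$", lex)),
              boolean = (!is.na(dt) && dt == XSD_BOOLEAN) ||
                (is.na(dt) && lex %in% c("true", "false")),
              anyURI = (is.na(dt) || dt == XSD_ANYURI) &&
                grepl("^[A-Za-z][A-Za-z0-9+.-]*:", lex),
              FALSE)
          }
        })
    }
    value_ok <- vapply(crows, function(r) eval_expr(con$expr, r), NA)
    if (con$pred == RDF_TYPE && shape$extra_type) {
      n_match <- sum(value_ok)
      if (n_match < con$card[1] || n_match > con$card[2]) ok <- FALSE
    } else {
      if (any(!value_ok)) ok <- FALSE
      n_match <- sum(value_ok)
      if (n_match < con$card[1] || n_match > con$card[2]) ok <- FALSE
    }
  }
  memo[[key]] <- ok
  ok
}

# Closed-world conformance verdict for a whole graph: every node typed with a
# schema type must satisfy the shape of that type; types without a shape are
# nonconforming.
shex_oracle_conforms <- function(graph, parsed) {
  t <- graph$triples
  type_rows <- which(t$p == RDF_TYPE & t$o_kind != "literal")
  memo <- new.env(parent = emptyenv())
  for (r in type_rows) {
    if (!shex_oracle_node_conforms(t$s[r], t$o[r], parsed$shapes, graph,
                                   memo)) {
      return(FALSE)
    }
  }
  TRUE
}
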