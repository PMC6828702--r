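# Turtle reader and writer.
#
# The reader covers the Turtle constructs the toolchain itself emits plus what
# hand-edited definition files need: @prefix / PREFIX, prefixed names, <IRI>s,
# blank nodes (labelled, [] and [ ... ] property lists), collections,
# short/long string literals with escapes, numeric and boolean shorthand,
# datatype (^^) and language tags, 'a', and comments. It is line-aware so
# syntax errors carry a 1-based line number.

turtle_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  line <- 1L
  toks <- vector("list", 256L)
  nt <- 0L
  push <- function(type, value) {
    nt <<- nt + 1L
    toks[[nt]] <<- list(type = type, value = value, line = line)
  }
  peek <- function(k = 0L) if (i + k <= n) chars[i + k] else ""
  err <- function(msg) stop(sprintf("Turtle syntax error (line %d): %s",
                                    line, msg), call. = FALSE)
  read_escape <- function() {
    # cursor sits on the backslash
    i <<- i + 1L
    e <- peek()
    i <<- i + 1L
    switch(e,
      "t" = "\t", "n" = "\n", "r" = "\r", "b" = "\b", "f" = "\f",
      "\"" = "\"", "'" = "'", "\\" = "\\",
      "u" = {
        hex <- paste0(chars[i:(i + 3L)], collapse = "")
        i <<- i + 4L
        intToUtf8(strtoi(hex, 16L))
      },
      "U" = {
        hex <- paste0(chars[i:(i + 7L)], collapse = "")
        i <<- i + 8L
        intToUtf8(strtoi(hex, 16L))
      },
      err(paste0("unknown escape \\", e)))
  }
  while (i <= n) {
    c0 <- chars[i]
    if (c0 == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (c0 %in% c(" ", "\t", "\r")) { i <- i + 1L; next }
    if (c0 == "#") {
      while (i <= n && chars[i] != "\n") i <- i + 1L
      next
    }
    if (c0 == "<") {
      j <- i + 1L
      buf <- character(0)
      while (j <= n && chars[j] != ">") {
        if (chars[j] == "\n") err("newline inside IRI")
        buf <- c(buf, chars[j])
        j <- j + 1L
      }
      if (j > n) err("unterminated IRI")
      push("iri", paste0(buf, collapse = ""))
      i <- j + 1L
      next
    }
    if (c0 == "\"" || c0 == "'") {
      q <- c0
      long <- peek(1L) == q && peek(2L) == q
      if (long) {
        i <- i + 3L
        buf <- character(0)
        repeat {
          if (i > n) err("unterminated long string")
          if (peek() == q && peek(1L) == q && peek(2L) == q) {
            i <- i + 3L
            break
          }
          if (peek() == "\\") buf <- c(buf, read_escape())
          else {
            if (peek() == "\n") line <- line + 1L
            buf <- c(buf, peek()); i <- i + 1L
          }
        }
      } else {
        i <- i + 1L
        buf <- character(0)
        repeat {
          if (i > n) err("unterminated string")
          ch <- peek()
          if (ch == q) { i <- i + 1L; break }
          if (ch == "\n") err("newline in short string")
          if (ch == "\\") buf <- c(buf, read_escape())
          else { buf <- c(buf, ch); i <- i + 1L }
        }
      }
      push("string", paste0(buf, collapse = ""))
      next
    }
    if (c0 == "^" && peek(1L) == "^") { push("dtsep", "^^"); i <- i + 2L; next }
    if (c0 == "@") {
      j <- i + 1L
      buf <- character(0)
      while (j <= n && grepl("[A-Za-z-]", chars[j])) {
        buf <- c(buf, chars[j]); j <- j + 1L
      }
      word <- paste0(buf, collapse = "")
      if (word %in% c("prefix", "base")) push(paste0("at_", word), word)
      else push("langtag", word)
      i <- j
      next
    }
    if (c0 %in% c(".", ";", ",", "[", "]", "(", ")")) {
      # distinguish statement dot from decimal point handled under numbers
      push(switch(c0, "." = "dot", ";" = "semi", "," = "comma",
                  "[" = "lbracket", "]" = "rbracket",
                  "(" = "lparen", ")" = "rparen"), c0)
      i <- i + 1L
      next
    }
    if (grepl("[0-9+-]", c0)) {
      j <- i
      buf <- character(0)
      while (j <= n && grepl("[0-9+.eE-]", chars[j])) {
        # a dot followed by whitespace/EOF terminates the statement instead
        if (chars[j] == "." && (j == n || !grepl("[0-9eE]", chars[j + 1L]))) break
        buf <- c(buf, chars[j]); j <- j + 1L
      }
      push("number", paste0(buf, collapse = ""))
      i <- j
      next
    }
    # PNAME, blank node label, bare keywords (a, true, false, PREFIX, BASE)
    j <- i
    buf <- character(0)
    while (j <= n && grepl("[A-Za-z0-9_:.%-]", chars[j])) {
      if (chars[j] == "." && (j == n || !grepl("[A-Za-z0-9_]", chars[j + 1L]))) break
      buf <- c(buf, chars[j]); j <- j + 1L
    }
    word <- paste0(buf, collapse = "")
    if (word == "") err(paste0("unexpected character '", c0, "'"))
    i <- j
    if (word == "a") { push("kw_a", word); next }
    if (word %in% c("true", "false")) { push("boolean", word); next }
    if (toupper(word) == "PREFIX") { push("at_prefix", word); next }
    if (toupper(word) == "BASE") { push("at_base", word); next }
    if (startsWith(word, "_:")) { push("bnode", word); next }
    if (grepl(":", word, fixed = TRUE)) { push("pname", word); next }
    err(paste0("bare word '", word, "' is not valid Turtle"))
  }
  toks[seq_len(nt)]
}

#' Parse Turtle text into an RDF graph
#'
#' @param text Turtle document as a single string, or `NULL` when `file` is
#'   given.
#' @param file Path to a Turtle file.
#' @return An [rdf_graph()].
#' @export
turtle_parse <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    text <- paste(readLines(file, warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")
  }
  toks <- turtle_tokenize(text)
  graph <- rdf_graph()
  base <- ""
  nt <- length(toks)
  k <- 1L
  bn_auto <- 0L
  acc <- vector("list", 64L)
  nacc <- 0L
  emit <- function(s, p, o, o_kind, dt = NA_character_,
                   lang = NA_character_) {
    nacc <<- nacc + 1L
    acc[[nacc]] <<- triple_rows(s, p, o, o_kind, dt, lang)
  }
  peek <- function() if (k <= nt) toks[[k]] else list(type = "eof", line = NA)
  take <- function(type = NULL) {
    t <- peek()
    if (t$type == "eof") stop("Turtle syntax error: unexpected end of input",
                              call. = FALSE)
    if (!is.null(type) && t$type != type) {
      stop(sprintf("Turtle syntax error (line %d): expected %s, got %s '%s'",
                   t$line, type, t$type, t$value), call. = FALSE)
    }
    k <<- k + 1L
    t
  }
  resolve_pname <- function(pn, ln) {
    m <- regmatches(pn, regexpr("^[^:]*:", pn))
    pfx <- sub(":$", "", m)
    local <- substring(pn, nchar(m) + 1L)
    ns <- graph$prefixes[prefix_key(pfx)]
    if (is.na(ns)) {
      stop(sprintf("Turtle syntax error (line %d): undeclared prefix '%s'",
                   ln, pfx), call. = FALSE)
    }
    paste0(ns, local)
  }
  fresh_bnode <- function() {
    bn_auto <<- bn_auto + 1L
    paste0("_:g", bn_auto)
  }
  parse_object <- NULL
  parse_pol <- function(subject) {
    repeat {
      vt <- peek()
      p <- if (vt$type == "kw_a") { take(); RDF_TYPE }
      else if (vt$type == "iri") { take(); vt$value }
      else if (vt$type == "pname") { take(); resolve_pname(vt$value, vt$line) }
      else stop(sprintf(
        "Turtle syntax error (line %d): expected predicate, got '%s'",
        vt$line, vt$value), call. = FALSE)
      repeat {
        obj <- parse_object()
        emit(subject, p, obj$o, obj$kind, obj$dt, obj$lang)
        if (peek()$type == "comma") take() else break
      }
      if (peek()$type == "semi") {
        take()
        # tolerate trailing ';' before '.' or ']'
        if (peek()$type %in% c("dot", "rbracket")) break
      } else break
    }
  }
  parse_object <<- function() {
    t <- peek()
    if (t$type == "iri") { take(); return(list(o = t$value, kind = "iri",
                                               dt = NA, lang = NA)) }
    if (t$type == "pname") {
      take()
      return(list(o = resolve_pname(t$value, t$line), kind = "iri",
                  dt = NA, lang = NA))
    }
    if (t$type == "bnode") { take(); return(list(o = t$value, kind = "bnode",
                                                 dt = NA, lang = NA)) }
    if (t$type == "string") {
      take()
      dt <- NA_character_
      lang <- NA_character_
      if (peek()$type == "dtsep") {
        take()
        dtt <- peek()
        dt <- if (dtt$type == "iri") { take(); dtt$value }
        else resolve_pname(take("pname")$value, dtt$line)
      } else if (peek()$type == "langtag") {
        lang <- take()$value
      }
      return(list(o = t$value, kind = "literal", dt = dt, lang = lang))
    }
    if (t$type == "number") {
      take()
      dt <- if (grepl("[eE]", t$value)) XSD_DOUBLE
      else if (grepl(".", t$value, fixed = TRUE)) paste0(NS_XSD, "decimal")
      else XSD_INTEGER
      return(list(o = t$value, kind = "literal", dt = dt, lang = NA))
    }
    if (t$type == "boolean") {
      take()
      return(list(o = t$value, kind = "literal", dt = XSD_BOOLEAN, lang = NA))
    }
    if (t$type == "lbracket") {
      take()
      bn <- fresh_bnode()
      if (peek()$type != "rbracket") parse_pol(bn)
      take("rbracket")
      return(list(o = bn, kind = "bnode", dt = NA, lang = NA))
    }
    if (t$type == "lparen") {
      take()
      elems <- list()
      while (peek()$type != "rparen") elems[[length(elems) + 1L]] <- parse_object()
      take("rparen")
      if (length(elems) == 0L) {
        return(list(o = RDF_NIL, kind = "iri", dt = NA, lang = NA))
      }
      nodes <- vapply(elems, function(e) fresh_bnode(), "")
      for (idx in seq_along(elems)) {
        e <- elems[[idx]]
        emit(nodes[idx], RDF_FIRST, e$o, e$kind, e$dt, e$lang)
        nxt <- if (idx < length(elems)) nodes[idx + 1L] else RDF_NIL
        emit(nodes[idx], RDF_REST, nxt, if (nxt == RDF_NIL) "iri" else "bnode")
      }
      return(list(o = nodes[1L], kind = "bnode", dt = NA, lang = NA))
    }
    stop(sprintf("Turtle syntax error (line %d): expected object, got '%s'",
                 t$line, t$value), call. = FALSE)
  }
  while (peek()$type != "eof") {
    t <- peek()
    if (t$type == "at_prefix") {
      take()
      pn <- take("pname")$value
      pfx <- sub(":$", "", pn)
      iri <- take("iri")$value
      graph$prefixes[prefix_key(pfx)] <- iri
      if (peek()$type == "dot") take()
      next
    }
    if (t$type == "at_base") {
      take()
      base <- take("iri")$value
      if (peek()$type == "dot") take()
      next
    }
    subject <- if (t$type == "iri") { take(); t$value }
    else if (t$type == "pname") { take(); resolve_pname(t$value, t$line) }
    else if (t$type == "bnode") { take(); t$value }
    else if (t$type == "lbracket") {
      take()
      bn <- fresh_bnode()
      if (peek()$type != "rbracket") parse_pol(bn)
      take("rbracket")
      bn
    } else stop(sprintf(
      "Turtle syntax error (line %d): expected subject, got '%s'",
      t$line, t$value), call. = FALSE)
    if (!(t$type == "lbracket" && peek()$type == "dot")) parse_pol(subject)
    take("dot")
  }
  graph$triples <- if (nacc) do.call(rbind, acc[seq_len(nacc)])
  else empty_triples()
  graph
}

escape_short_string <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

escape_long_string <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub("\"", "\\\"", x, fixed = TRUE)
}

format_term_ttl <- function(o, kind, dt, lang, prefixes) {
  if (kind == "bnode") return(o)
  if (kind == "iri") {
    short <- shorten_iri(o, prefixes)
    return(if (!is.na(short)) short else paste0("<", o, ">"))
  }
  lex <- if (grepl("\n", o, fixed = TRUE)) {
    paste0("\"\"\"", escape_long_string(o), "\"\"\"")
  } else {
    paste0("\"", escape_short_string(o), "\"")
  }
  if (!is.na(lang)) return(paste0(lex, "@", lang))
  if (!is.na(dt) && dt != XSD_STRING) {
    return(paste0(lex, "^^", format_term_ttl(dt, "iri", NA, NA, prefixes)))
  }
  lex
}

#' Serialise an RDF graph as Turtle
#'
#' Output is deterministic: prefixes in map order, subjects in order of first
#' appearance (or `subject_order`), `rdf:type` first within a subject, then
#' remaining predicates in order of first appearance.
#'
#' @param graph An [rdf_graph()].
#' @param subject_order Optional character vector fixing subject order.
#' @param all_prefixes Emit every prefix binding, not only the ones the
#'   triples use (so even an empty document declares its namespaces).
#' @return A single Turtle string.
#' @export
turtle_serialize <- function(graph, subject_order = NULL,
                             all_prefixes = FALSE) {
  t <- graph$triples
  pf <- graph$prefixes
  used_ns <- if (all_prefixes) names(pf) else unique(c(
    vapply(unique(c(t$s, t$p, t$o[t$o_kind == "iri"],
                    t$dt[!is.na(t$dt)])), function(x) {
      s <- shorten_iri(x, pf)
      if (is.na(s)) NA_character_ else prefix_key(sub(":.*$", "", s))
    }, "")))
  used_ns <- used_ns[!is.na(used_ns)]
  header <- vapply(names(pf)[names(pf) %in% used_ns], function(p) {
    sprintf("@prefix %s: <%s> .", if (p == ":") "" else p, pf[[p]])
  }, "")
  subjects <- unique(t$s)
  if (!is.null(subject_order)) {
    subjects <- c(subject_order[subject_order %in% subjects],
                  setdiff(subjects, subject_order))
  }
  blocks <- vapply(subjects, function(s) {
    rows <- t[t$s == s, , drop = FALSE]
    preds <- unique(rows$p)
    preds <- c(preds[preds == RDF_TYPE], preds[preds != RDF_TYPE])
    lines <- vapply(preds, function(p) {
      pr <- rows[rows$p == p, , drop = FALSE]
      objs <- vapply(seq_len(nrow(pr)), function(i) {
        format_term_ttl(pr$o[i], pr$o_kind[i], pr$dt[i], pr$lang[i], pf)
      }, "")
      pstr <- if (p == RDF_TYPE) "a"
      else format_term_ttl(p, "iri", NA, NA, pf)
      paste0("    ", pstr, " ", paste(objs, collapse = ", "))
    }, "")
    sstr <- format_term_ttl(s, if (is_bnode(s)) "bnode" else "iri",
                            NA, NA, pf)
    paste0(sstr, "\n", paste(lines, collapse = " ;\n"), " .")
  }, "")
  paste0(paste(header, collapse = "\n"), "\n\n",
         paste(blocks, collapse = "\n\n"), "\n")
}

#' Write a graph to a Turtle file
#' @param graph An [rdf_graph()].
#' @param path Output file path.
#' @param subject_order Optional subject ordering, see [turtle_serialize()].
#' @return `path`, invisibly.
#' @export
turtle_write <- function(graph, path, subject_order = NULL) {
  writeLines(turtle_serialize(graph, subject_order), path, useBytes = TRUE)
  invisible(path)
}
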