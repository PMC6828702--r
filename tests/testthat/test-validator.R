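prot_ttl_header <- c(
  "@prefix p: <http://example.org/prot/> .",
  "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .")

test_that("a protein without its one-and-only sequence is reported", {
  sch <- protein_schema()
  g <- ttl_graph(prot_ttl_header, "p:p1 a p:Protein .")
  rep <- validate_graph(g, sch)
  expect_false(rep$conforms)
  expect_identical(rep$violations$kind, "MISSING_REQUIRED")
  expect_identical(rep$violations$predicate, "http://example.org/prot/sequence")

  ok <- ttl_graph(prot_ttl_header, 'p:p1 a p:Protein ; p:sequence "MKV" .')
  expect_true(validate_graph(ok, sch)$conforms)
})

test_that("predicate typos surface as UNKNOWN_PREDICATE", {
  sch <- regulation_schema()
  g <- ttl_graph(
    "@prefix r: <http://example.org/reg/> .",
    "r:s1 a r:RegulationSite ; r:regulatoryClass r:Promoter ;",
    "  r:regulatoryClas r:Promoter .")
  rep <- validate_graph(g, sch)
  expect_identical(rep$violations$kind, "UNKNOWN_PREDICATE")
  expect_identical(rep$violations$predicate,
                   "http://example.org/reg/regulatoryClas")
})

test_that("value-set values outside the set are violations", {
  sch <- regulation_schema()
  g <- ttl_graph(
    "@prefix r: <http://example.org/reg/> .",
    "r:s1 a r:RegulationSite ; r:regulatoryClass r:Purple .")
  rep <- validate_graph(g, sch)
  expect_identical(rep$violations$kind, "VALUE_SET_VIOLATION")
})

test_that("check_instance reports per-node violations", {
  sch <- protein_schema()
  g <- ttl_graph(prot_ttl_header,
    'p:p1 a p:Protein ; p:sequence "MKV" ;',
    "  p:encodedBy <http://g.org/g1>, <http://g.org/g2> .")
  v <- check_instance("http://example.org/prot/p1",
                      "http://example.org/prot/Protein", g, sch)
  expect_identical(v$kind, "CARDINALITY_EXCEEDED")

  ok <- ttl_graph(prot_ttl_header, 'p:p2 a p:Protein ; p:sequence "MSA" .')
  expect_identical(nrow(check_instance("http://example.org/prot/p2",
                                       "http://example.org/prot/Protein",
                                       ok, sch)), 0L)
  # unknown class is a violation, not an exception
  v2 <- check_instance("http://example.org/prot/p2",
                       "http://example.org/prot/Alien", ok, sch)
  expect_identical(v2$kind, "NON_SCHEMA_TYPE")
})

test_that("class-ref objects need a compatible type", {
  base <- "http://example.org/z/"
  sch <- schema(base, classes = list(
    class_def(paste0(base, "A"), "A", properties = list(
      property_def("next", paste0(base, "next"),
                   target_class(paste0(base, "B")), multiplicity(1, 1)))),
    class_def(paste0(base, "B"), "B"),
    class_def(paste0(base, "B2"), "B2", parent = paste0(base, "B")),
    class_def(paste0(base, "C"), "C")), prefixes = c(z = base),
    base_prefix = "z")
  head <- "@prefix z: <http://example.org/z/> ."
  # subclass substitutability: a B2 satisfies a B-typed target
  expect_true(validate_graph(ttl_graph(
    head, "z:a1 a z:A ; z:next z:b1 . z:b1 a z:B2 ."), sch)$conforms)
  # sibling class fails
  rep <- validate_graph(ttl_graph(
    head, "z:a1 a z:A ; z:next z:c1 . z:c1 a z:C ."), sch)
  expect_identical(rep$violations$kind, "WRONG_TARGET_TYPE")
  # untyped object
  rep2 <- validate_graph(ttl_graph(
    head, "z:a1 a z:A ; z:next z:ghost ."), sch)
  expect_identical(rep2$violations$kind, "UNTYPED_NODE")
})

test_that("list-valued properties are checked structurally", {
  loc <- build_locations_schema()
  head <- c("@prefix gbol: <http://gbol.life/0.1/> .",
            "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
            "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .")
  region <- c(
    'gbol:r1 a gbol:Region ; gbol:begin gbol:e1 ; gbol:end gbol:e2 .',
    'gbol:e1 a gbol:ExactPosition ; gbol:position "1"^^xsd:integer .',
    'gbol:e2 a gbol:ExactPosition ; gbol:position "9"^^xsd:integer .')
  good <- ttl_graph(head, region,
    "gbol:c1 a gbol:OrderedCollectionOfRegions ;",
    "  gbol:memberRegions ( gbol:r1 ) .")
  expect_true(validate_graph(good, loc)$conforms)
  # broken rdf:rest chain
  broken <- ttl_graph(head, region,
    "gbol:c1 a gbol:OrderedCollectionOfRegions ; gbol:memberRegions _:n1 .",
    "_:n1 rdf:first gbol:r1 .")
  rep <- validate_graph(broken, loc)
  expect_true("MALFORMED_LIST" %in% rep$violations$kind)
  # numbered containers must be contiguous from rdf:_1
  numbered <- ttl_graph(head, region,
    "gbol:c2 a gbol:NumberedCollectionOfRegions ; gbol:numberedRegions _:n2 .",
    "_:n2 rdf:_2 gbol:r1 .")
  rep2 <- validate_graph(numbered, loc)
  expect_true("MALFORMED_LIST" %in% rep2$violations$kind)
})

test_that("plain literals are accepted leniently for numeric targets", {
  base <- "http://example.org/n/"
  sch <- schema(base, classes = list(class_def(
    paste0(base, "N"), "N", properties = list(
      property_def("count", paste0(base, "count"),
                   target_primitive("integer"), multiplicity(1, 1))))),
    prefixes = c(n = base), base_prefix = "n")
  head <- "@prefix n: <http://example.org/n/> ."
  # lexically valid untyped literal passes
  expect_true(validate_graph(ttl_graph(
    head, 'n:x a n:N ; n:count "17" .'), sch)$conforms)
  # lexically invalid value is a violation
  rep <- validate_graph(ttl_graph(
    head, 'n:x a n:N ; n:count "seventeen" .'), sch)
  expect_identical(rep$violations$kind, "WRONG_TARGET_TYPE")
})

test_that("validate_graph equals the union of per-instance checks", {
  sch <- random_schema(21, n_classes = 6, n_value_sets = 1)
  g <- conforming_instances(sch, 22, n_instances = 5)
  res <- mutate_graph(g, sch, "MISSING_REQUIRED", 1)
  rep <- validate_graph(res$graph, sch)
  t <- res$graph$triples
  typed <- t[t$p == RDF_TYPE & t$o_kind != "literal", , drop = FALSE]
  per_node <- do.call(rbind, lapply(seq_len(nrow(typed)), function(i) {
    check_instance(typed$s[i], typed$o[i], res$graph, sch)
  }))
  per_node <- per_node[!duplicated(per_node[c("kind", "subject",
                                              "predicate")]), , drop = FALSE]
  expect_identical(nrow(per_node), nrow(rep$violations))
  expect_setequal(paste(per_node$kind, per_node$subject, per_node$predicate),
                  paste(rep$violations$kind, rep$violations$subject,
                        rep$violations$predicate))
})

test_that("unparseable data is an input error, not a violation", {
  tmp <- tempfile(fileext = ".ttl")
  writeLines("this is (not turtle", tmp)
  expect_error(validate_graph(tmp, protein_schema()),
               class = "ontogen_input_error")
})
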