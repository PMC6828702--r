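# Source generated binding units into a fresh environment and return it.
load_api <- function(schema) {
  units <- generate_api(schema)
  env <- new.env(parent = getNamespace("ontogen"))
  for (u in units) {
    if (u$kind == "api") eval(parse(text = u$content), envir = env)
  }
  attr(env, "units") <- units
  env
}

test_that("accessor kinds follow the multiplicity", {
  api <- load_api(build_locations_schema())
  store <- new_instance_store(build_locations_schema())
  region <- api$Region(store)
  expect_true(all(c("setBegin", "setEnd", "setStrand", "setReference",
                    "getBegin") %in% names(region)))
  expect_false(any(c("addBegin", "removeBegin") %in% names(region)))
  coll <- api$OrderedCollectionOfRegions(store)
  expect_true(all(c("addMemberRegions", "removeMemberRegions",
                    "getMemberRegions") %in% names(coll)))
  expect_false("setMemberRegions" %in% names(coll))
})

test_that("generated bindings reconstruct every location kind", {
  sch <- build_locations_schema()
  api <- load_api(sch)
  store <- new_instance_store(sch)
  seqi <- api$Sequence(store)
  mkpos <- function(n) {
    p <- api$ExactPosition(store)
    p$setPosition(n)
    p
  }
  region <- api$Region(store)
  region$setBegin(mkpos(10L))$setEnd(mkpos(20L))
  region$setStrand("ReverseStrandPosition")
  region$setReference(seqi$iri)
  base <- api$BaseLocation(store)
  base$setAt(mkpos(5L))$setReference(seqi$iri)
  ib <- api$InBetweenLocation(store)
  ib$setAfter(mkpos(102L))$setReference(seqi$iri)
  fz <- api$InRangePosition(store)
  fz$setBeginPosition(3L)$setEndPosition(8L)
  oo <- api$OneOfPosition(store)
  oo$addPosition(4L)$addPosition(7L)
  bp <- api$BeforePosition(store)
  bp$setPosition(2L)
  ap <- api$AfterPosition(store)
  ap$setPosition(11L)
  region2 <- api$Region(store)
  region2$setBegin(bp$iri)$setEnd(ap$iri)$setReference(seqi$iri)
  coll <- api$OrderedCollectionOfRegions(store)
  coll$addMemberRegions(region$iri)$addMemberRegions(region2$iri)
  coll$setReference(seqi$iri)
  un <- api$UnorderedCollectionOfRegions(store)
  un$addMembers(region$iri)$setReference(seqi$iri)
  nn <- api$NumberedCollectionOfRegions(store)
  nn$addNumberedRegions(region$iri)$setReference(seqi$iri)
  expect_true(validate_graph(turtle_parse(export_graph(store)),
                             sch)$conforms)
})

test_that("setters reject wrong types, non-members and misuse", {
  sch <- build_demo_schema()
  api <- load_api(sch)
  store <- new_instance_store(sch)
  seqi <- api$Sequence(store)
  expect_error(seqi$setSequence(42), class = "ontogen_binding_error")
  expect_error(seqi$setStrandType("Purple"), class = "ontogen_binding_error")
  feat <- api$Feature(store)
  # a Feature is not a Location
  expect_error(feat$setLocation(feat$iri), class = "ontogen_binding_error")
  # add on a single-valued property
  expect_error(store_add(store, feat, "locus", "x"),
               class = "ontogen_binding_error")
  expect_error(store_set(store, seqi, "feature", feat),
               class = "ontogen_binding_error")
})

test_that("value sets become enumerations of member IRIs", {
  base <- "http://example.org/f/"
  sch <- schema(base,
    classes = list(class_def(paste0(base, "Doc"), "Doc")),
    value_sets = list(value_set_def(paste0(base, "FileType"), "FileType",
                                    members = paste0(base, c("CSV", "TXT",
                                                             "TSV")))),
    prefixes = c(f = base), base_prefix = "f")
  api <- load_api(sch)
  expect_length(api$FileType, 3L)
  expect_setequal(names(api$FileType), c("CSV", "TXT", "TSV"))
  expect_setequal(unname(api$FileType), paste0(base, c("CSV", "TXT", "TSV")))
})

test_that("an empty schema generates only the manifest scaffold", {
  units <- generate_api(schema("http://example.org/empty/"))
  expect_length(units, 1L)
  expect_identical(units[[1]]$path, "manifest.json")
  m <- jsonlite::fromJSON(units[[1]]$content)
  expect_length(m$units, 0L)
})

test_that("an empty store exports a valid empty document with prefixes", {
  ttl <- export_graph(new_instance_store(build_demo_schema()))
  expect_match(ttl, "@prefix gbol: <http://gbol.life/0.1/> .", fixed = TRUE)
  expect_identical(nrow(turtle_parse(ttl)$triples), 0L)
})

test_that("export refuses while required properties are missing", {
  sch <- protein_schema()
  store <- new_instance_store(sch)
  store_create(store, "Protein", "http://example.org/prot/p1")
  err <- tryCatch(export_graph(store), ontogen_export_error = function(e) e)
  expect_s3_class(err, "ontogen_export_error")
  expect_match(conditionMessage(err), "sequence")
  # the violation list names every offending instance
  expect_match(conditionMessage(err), "p1")
  store_set(store, "http://example.org/prot/p1", "sequence", "MKV")
  expect_true(validate_graph(turtle_parse(export_graph(store)),
                             sch)$conforms)
})

test_that("export refuses dangling references", {
  sch <- build_demo_schema()
  store <- new_instance_store(sch)
  feat <- store_create(store, "Feature")
  store_set(store, feat, "locus", "TOY_1")
  store_set(store, feat, "featureType", "gene")
  store_set(store, feat, "location", "http://gbol.life/0.1/nowhere")
  expect_error(export_graph(store), class = "ontogen_export_error")
})

test_that("ordered collections serialise in insertion order", {
  sch <- build_locations_schema()
  store <- new_instance_store(sch)
  mkregion <- function(a, b) {
    r <- store_create(store, "Region")
    for (nm in c("begin", "end")) {
      p <- store_create(store, "ExactPosition")
      store_set(store, p, "position", if (nm == "begin") a else b)
      store_set(store, r, nm, p)
    }
    r
  }
  rs <- list(mkregion(1L, 2L), mkregion(5L, 6L), mkregion(9L, 12L))
  coll <- store_create(store, "OrderedCollectionOfRegions")
  for (r in rs) store_add(store, coll, "memberRegions", r)
  g <- turtle_parse(export_graph(store))
  # brute-force walk of the rdf:rest chain
  t <- g$triples
  node <- t$o[t$s == coll$iri & t$p == "http://gbol.life/0.1/memberRegions"]
  seen <- character(0)
  while (node != RDF_NIL) {
    seen <- c(seen, t$o[t$s == node & t$p == RDF_FIRST])
    node <- t$o[t$s == node & t$p == RDF_REST]
  }
  expect_identical(seen, vapply(rs, function(r) r$iri, ""))
})

test_that("numbered collections serialise with rdf:_n membership", {
  sch <- build_locations_schema()
  store <- new_instance_store(sch)
  r <- store_create(store, "Region")
  for (nm in c("begin", "end")) {
    p <- store_create(store, "ExactPosition")
    store_set(store, p, "position", 3L)
    store_set(store, r, nm, p)
  }
  nc <- store_create(store, "NumberedCollectionOfRegions")
  store_add(store, nc, "numberedRegions", r)
  ttl <- export_graph(store)
  expect_match(ttl, "rdf:_1 ")
  expect_true(validate_graph(turtle_parse(ttl), sch)$conforms)
})

test_that("export is deterministic and minting is collision-checked", {
  sch <- protein_schema()
  build <- function() {
    store <- new_instance_store(sch)
    a <- store_create(store, "Protein")
    store_set(store, a, "sequence", "MKV")
    b <- store_create(store, "Enzyme")
    store_set(store, b, "sequence", "MSA")
    export_graph(store)
  }
  expect_identical(build(), build())
  store <- new_instance_store(sch)
  store_create(store, "Protein", "http://example.org/prot/x")
  expect_error(store_create(store, "Protein", "http://example.org/prot/x"),
               class = "ontogen_binding_error")
})

test_that("reserved host-language words are renamed with a warning", {
  base <- "http://example.org/r/"
  sch <- schema(base, classes = list(class_def(paste0(base, "Inf"), "Inf")),
                prefixes = c(r = base), base_prefix = "r")
  expect_warning(units <- generate_api(sch), regexp = "reserved")
  expect_true("Inf_.R" %in% vapply(units, function(u) u$path, ""))
})
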