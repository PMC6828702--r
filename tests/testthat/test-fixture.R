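test_that("the locations fixture matches its published shape", {
  loc <- build_locations_schema()
  st <- schema_stats(loc)
  expect_identical(unclass(st),
                   list(classes = 16L, properties = 17L, value_sets = 1L))
  # the FALDO deltas:
  # reference lives on Location, not on positions
  expect_true("reference" %in% names(
    loc$classes[[class_by_name_iri(loc, "Location")]]$properties))
  for (nm in c("ExactPosition", "BeforePosition", "AfterPosition")) {
    expect_false("reference" %in% names(effective_properties(
      loc, class_by_name_iri(loc, nm))), info = nm)
  }
  # BaseLocation, InBetweenLocation, CollectionOfRegions, Region are
  # children of Location
  for (nm in c("BaseLocation", "InBetweenLocation", "CollectionOfRegions",
               "Region")) {
    expect_identical(loc$classes[[class_by_name_iri(loc, nm)]]$parent,
                     class_by_name_iri(loc, "Location"), info = nm)
  }
  # the strand is a value set, not a Position subclass
  expect_true("http://gbol.life/0.1/StrandPosition" %in%
                names(loc$value_sets))
  pos_desc <- c(class_by_name_iri(loc, "Position"),
                unlist(lapply(loc$classes, function(c) {
                  if (identical(c$parent,
                                class_by_name_iri(loc, "Position"))) c$iri
                })))
  expect_false("StrandPosition" %in%
                 vapply(loc$classes, function(c) c$name, ""))
  # fuzzy positions hold integers, never nested position objects
  for (nm in c("BeforePosition", "AfterPosition", "InRangePosition",
               "OneOfPosition")) {
    cls <- loc$classes[[class_by_name_iri(loc, nm)]]
    for (p in cls$properties) {
      expect_identical(p$target$kind, "primitive", info = nm)
      expect_identical(p$target$datatype, "integer", info = nm)
    }
  }
  # no N-/C-terminal position classes, no reflective beginOf/endOf
  nms <- vapply(loc$classes, function(c) c$name, "")
  expect_false(any(grepl("Terminal", nms)))
  all_props <- unlist(lapply(loc$classes,
                             function(c) names(c$properties)))
  expect_false(any(c("beginOf", "endOf") %in% all_props))
})

test_that("the bundled definition file reproduces the builder exactly", {
  path <- system.file("extdata", "gbol_locations.ttl", package = "ontogen")
  expect_true(nzchar(path))
  sch <- read_schema(path)
  expect_identical(unclass(schema_stats(sch)),
                   list(classes = 16L, properties = 17L, value_sets = 1L))
  expect_schemas_isomorphic(sch, build_locations_schema())
})

test_that("GenBank location strings survive a decode-encode round trip", {
  strs <- c("100..400", "complement(500..800)", "join(900..950,960..1000)",
            "5..5", "102^103", "42", "<5..10", "10..>20", "(5.8)..20",
            "one-of(5,8)..20", "order(1..2,4..6)", "complement(102^103)",
            "complement(join(10..20,30..40))", "complement(7)",
            "one-of(3,4,9)..one-of(12,15)", "<1..>99",
            "join(1..2,complement(8..9))")
  sch <- build_demo_schema()
  store <- new_instance_store(sch)
  seqi <- store_create(store, "Sequence")
  store_set(store, seqi, "sequence", "ACGT")
  store_set(store, seqi, "strandType", "DoubleStrandedDNA")
  for (s in strs) {
    inst <- encode_location(s, seqi, store)
    expect_identical(decode_location(store, inst), s, info = s)
  }
  # the encoded store is itself schema-conformant
  expect_true(validate_graph(turtle_parse(export_graph(store)),
                             sch)$conforms)
})

test_that("location string semantics match the model", {
  sch <- build_locations_schema()
  store <- new_instance_store(sch)
  seqi <- store_create(store, "Sequence")
  # in-between site 102^103 records the preceding base 102
  ib <- encode_location("102^103", seqi, store)
  expect_identical(local_name_of(store, ib), "InBetweenLocation")
  after <- store_get(store, ib, "after")
  expect_identical(store_get(store, after, "position"), "102")
  # single-base interval maps to a Region with begin = end
  r <- encode_location("5..5", seqi, store)
  expect_identical(local_name_of(store, r), "Region")
  expect_identical(store_get(store, store_get(store, r, "begin"), "position"),
                   store_get(store, store_get(store, r, "end"), "position"))
  # complement maps to the reverse strand
  rc <- encode_location("complement(1..9)", seqi, store)
  expect_identical(store_get(store, rc, "strand"),
                   "http://gbol.life/0.1/ReverseStrandPosition")
  # fuzzy begins/ends
  fb <- encode_location("<5..10", seqi, store)
  expect_identical(local_name_of(store, store_get(store, fb, "begin")),
                   "BeforePosition")
  # joins become ordered collections of regions
  j <- encode_location("join(10..20,30..40)", seqi, store)
  expect_identical(local_name_of(store, j), "OrderedCollectionOfRegions")
  expect_length(store_get(store, j, "memberRegions"), 2L)
})

test_that("malformed location strings are parse errors", {
  sch <- build_locations_schema()
  store <- new_instance_store(sch)
  seqi <- store_create(store, "Sequence")
  for (bad in c("", "abc", "10..", "102^104", "join(5..6)", "(8.5)..9",
                "one-of(7)..9", "join(1^2,3..4)")) {
    expect_error(encode_location(bad, seqi, store),
                 class = "ontogen_parse_error", info = bad)
  }
})

test_that("the strand rule is enforced per sequence kind", {
  sch <- build_demo_schema()
  kinds <- c(DoubleStrandedDNA = 0L, SingleStrandedDNA = 1L, RNA = 1L,
             Protein = 1L)
  # exhaustive over (location stranded?) x (sequence kind)
  for (kind in names(kinds)) {
    for (stranded in c(TRUE, FALSE)) {
      store <- new_instance_store(sch)
      seqi <- store_create(store, "Sequence")
      store_set(store, seqi, "sequence", "ACGT")
      store_set(store, seqi, "strandType", kind)
      loc <- encode_location(if (stranded) "complement(1..4)" else "1..4",
                             seqi, store)
      v <- strand_rule_check(store)
      expected <- if (stranded) kinds[[kind]] else 0L
      expect_identical(nrow(v), expected,
                       info = paste(kind, "stranded:", stranded))
      if (expected > 0L) {
        expect_identical(unique(v$kind), "STRAND_RULE_VIOLATION")
      }
    }
  }
  # a stranded location with no reference is a dangling-reference error
  store <- new_instance_store(sch)
  r <- store_create(store, "Region")
  p <- store_create(store, "ExactPosition")
  store_set(store, p, "position", 1L)
  store_set(store, r, "begin", p)
  store_set(store, r, "end", p)
  store_set(store, r, "strand", "ForwardStrandPosition")
  expect_error(strand_rule_check(store),
               class = "ontogen_dangling_reference")
})

test_that("provenance subclasses extend the schema without mutating it", {
  sch <- build_demo_schema()
  pa <- class_by_name_iri(sch, "ProvenanceAnnotation")
  blast <- class_def("http://gbol.life/0.1/Blast", "Blast", parent = pa,
                     properties = list(property_def(
                       "bitScore", "http://gbol.life/0.1/bitScore",
                       target_primitive("double"), multiplicity(1, 1))))
  ext <- extend_with_provenance_subclass(sch, blast)
  expect_true("http://gbol.life/0.1/Blast" %in% names(ext$classes))
  expect_false("http://gbol.life/0.1/Blast" %in% names(sch$classes))

  g <- ttl_graph(
    "@prefix gbol: <http://gbol.life/0.1/> .",
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
    'gbol:b1 a gbol:Blast ; gbol:bitScore "210.5"^^xsd:double .')
  expect_true(validate_graph(g, ext)$conforms)
  # against the unextended schema the same instance is a non-schema type
  rep <- validate_graph(g, sch)
  expect_identical(rep$violations$kind, "NON_SCHEMA_TYPE")

  # wrong parent is an extension error
  wrong <- class_def("http://gbol.life/0.1/Hmm", "Hmm",
                     parent = class_by_name_iri(sch, "Feature"))
  expect_error(extend_with_provenance_subclass(sch, wrong),
               class = "ontogen_extension_error")
  # duplicate property versus the parent is rejected at assembly
  dup <- class_def("http://gbol.life/0.1/Dup", "Dup", parent = pa,
                   properties = list(property_def(
                     "experiment", "http://gbol.life/0.1/experiment2",
                     target_external(), multiplicity(0, 1))))
  expect_error(extend_with_provenance_subclass(sch, dup),
               class = "ontogen_duplicate_property")
})

test_that("the toy annotation graph conforms and carries full provenance", {
  store <- build_toy_annotation_store()
  sch <- build_demo_schema()
  g <- turtle_parse(export_graph(store))
  expect_true(validate_graph(g, sch)$conforms)
  # the emitted ShEx accepts the toy graph (independent oracle)
  parsed <- shex_oracle_parse(emit_shex(sch)$content)
  expect_true(shex_oracle_conforms(g, parsed))
  # every feature's annotated property has reachable element-wise provenance
  t <- g$triples
  feats <- t$s[t$p == RDF_TYPE & t$o == "http://gbol.life/0.1/Feature"]
  for (f in feats) {
    provs <- t$o[t$s == f & t$p == "http://gbol.life/0.1/provenance"]
    expect_true(length(provs) >= 1L, info = f)
    for (pv in provs) {
      expect_length(t$o[t$s == pv & t$p == "http://gbol.life/0.1/onProperty"],
                    1L)
      ann <- t$o[t$s == pv & t$p == "http://gbol.life/0.1/annotation"]
      expect_length(ann, 1L)
      # and the binding to the dataset-wise activity is present
      expect_length(t$o[t$s == pv & t$p == "http://gbol.life/0.1/origin"],
                    1L)
    }
  }
  # automatic activities carry agent, parameters and files
  acts <- t$s[t$p == RDF_TYPE &
                t$o == "http://gbol.life/0.1/AutomaticAnnotationActivity"]
  for (a in acts) {
    for (p in c("softwareAgent", "parameters", "inputFile", "outputFile")) {
      expect_true(length(t$o[t$s == a &
                               t$p == paste0("http://gbol.life/0.1/", p)]) >=
                    1L, info = p)
    }
  }
})

test_that("the bundled toy files agree with the in-code builders", {
  dir <- system.file("extdata", package = "ontogen")
  toy <- file.path(dir, "toy_instances.ttl")
  expect_true(file.exists(toy))
  g <- turtle_parse(file = toy)
  expect_true(validate_graph(g, build_demo_schema())$conforms)
  built <- turtle_parse(export_graph(build_toy_annotation_store()))
  expect_identical(nrow(g$triples), nrow(built$triples))
  locs <- readLines(file.path(dir, "toy_genome.gbk-loc"))
  expect_length(locs, 3L)
  gff <- readLines(file.path(dir, "toy_genome.gff3"))
  expect_identical(sum(!startsWith(gff, "#")), 3L)
})

test_that("GFF3 records encode to conformant features", {
  gff <- system.file("extdata", "toy_genome.gff3", package = "ontogen")
  sch <- build_demo_schema()
  store <- new_instance_store(sch)
  seqi <- store_create(store, "Sequence", "http://gbol.life/0.1/chr1")
  store_set(store, seqi, "sequence", "ACGT")
  store_set(store, seqi, "strandType", "DoubleStrandedDNA")
  feats <- encode_gff3(gff, store, seqi)
  expect_length(feats, 3L)
  g <- turtle_parse(export_graph(store))
  expect_true(validate_graph(g, sch)$conforms)
  # the reverse-strand CDS got a reverse-strand region
  t <- g$triples
  cds <- t$s[t$p == "http://gbol.life/0.1/featureType" & t$o == "CDS"]
  loc <- t$o[t$s == cds & t$p == "http://gbol.life/0.1/location"]
  expect_identical(t$o[t$s == loc & t$p == "http://gbol.life/0.1/strand"],
                   "http://gbol.life/0.1/ReverseStrandPosition")
})
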