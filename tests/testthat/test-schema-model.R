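test_that("only the four multiplicity forms are legal", {
  expect_identical(format(multiplicity(0, 1)), "0..1")
  expect_identical(format(multiplicity(1, Inf)), "1..N")
  expect_identical(format(multiplicity(0, Inf, "ordered")), "=0..N")
  expect_identical(format(multiplicity(1, Inf, "numbered")), "~1..N")
  expect_error(multiplicity(2, 1), class = "ontogen_syntax_error")
  expect_error(multiplicity(0, 2), class = "ontogen_syntax_error")
  expect_error(multiplicity(1, 1, "ordered"), class = "ontogen_syntax_error")
})

test_that("name conventions are enforced at construction", {
  expect_error(class_def("http://x/", "exactPosition"),
               class = "ontogen_invalid_name")
  expect_error(class_def("http://x/", "Exact Position"),
               class = "ontogen_invalid_name")
  expect_error(property_def("Position", "http://x/p",
                            target_primitive("string"), multiplicity(0, 1)),
               class = "ontogen_invalid_name")
  expect_silent(class_def("http://x/E", "ExactPosition"))
})

test_that("schema stats count owned properties and value sets separately", {
  empty <- schema("http://e.org/")
  expect_identical(unclass(schema_stats(empty)),
                   list(classes = 0L, properties = 0L, value_sets = 0L))
  base <- "http://e.org/"
  one <- schema(base,
    classes = list(class_def(paste0(base, "A"), "A", properties = list(
      property_def("x", paste0(base, "x"), target_primitive("string"),
                   multiplicity(0, 1)),
      property_def("y", paste0(base, "y"), target_primitive("integer"),
                   multiplicity(1, 1))))),
    value_sets = list(value_set_def(paste0(base, "V"), "V",
                                    members = paste0(base, c("M1", "M2",
                                                             "M3")))))
  st <- schema_stats(one)
  expect_identical(unclass(st),
                   list(classes = 1L, properties = 2L, value_sets = 1L))
})

test_that("stats are additive over disjoint schema unions", {
  a <- random_schema(2, n_classes = 5, n_value_sets = 1)
  b <- protein_schema()
  c3 <- regulation_schema()
  for (other in list(b, c3)) {
    u <- schema_merge(a, other)
    expect_identical(schema_stats(u)$classes,
                     schema_stats(a)$classes + schema_stats(other)$classes)
    expect_identical(schema_stats(u)$properties,
                     schema_stats(a)$properties +
                       schema_stats(other)$properties)
    expect_identical(schema_stats(u)$value_sets,
                     schema_stats(a)$value_sets +
                       schema_stats(other)$value_sets)
  }
})

test_that("effective_properties flattens the parent chain ancestor-first", {
  base <- "http://e.org/"
  mk <- function(nm, parent, pname) {
    class_def(paste0(base, nm), nm,
              parent = if (!is.null(parent)) paste0(base, parent) else NULL,
              properties = list(property_def(
                pname, paste0(base, pname), target_primitive("string"),
                multiplicity(0, 1))))
  }
  sch <- schema(base, classes = list(mk("A", NULL, "aProp"),
                                     mk("B", "A", "bProp"),
                                     mk("C", "B", "cProp")))
  # independent oracle: brute-force walk of the parent chain
  brute <- function(sch, iri) {
    chain <- character(0)
    while (!is.null(iri)) {
      chain <- c(iri, chain)
      iri <- sch$classes[[iri]]$parent
    }
    unlist(lapply(chain, function(i) names(sch$classes[[i]]$properties)))
  }
  got <- names(effective_properties(sch, paste0(base, "C")))
  expect_identical(got, c("aProp", "bProp", "cProp"))
  expect_identical(got, brute(sch, paste0(base, "C")))
  expect_identical(names(effective_properties(sch, paste0(base, "A"))),
                   "aProp")
  expect_error(effective_properties(sch, paste0(base, "Nope")),
               class = "ontogen_unknown_class")
})

test_that("effective_properties agrees with brute force on random schemas", {
  brute <- function(sch, iri) {
    chain <- character(0)
    while (!is.null(iri)) {
      chain <- c(iri, chain)
      iri <- sch$classes[[iri]]$parent
    }
    unlist(lapply(chain, function(i) names(sch$classes[[i]]$properties)))
  }
  for (seed in 1:10) {
    sch <- random_schema(seed, n_classes = sample(1:20, 1), n_value_sets = 1)
    for (iri in names(sch$classes)) {
      eff <- effective_properties(sch, iri)
      expect_identical(names(eff) %||% character(0),
                       brute(sch, iri) %||% character(0), info = iri)
      # idempotence: no duplicates
      expect_false(anyDuplicated(names(eff)) > 0L)
    }
  }
})

test_that("fuzzy-position subclasses inherit the location chain", {
  loc <- build_locations_schema()
  before <- class_by_name_iri(loc, "BeforePosition")
  eff <- effective_properties(loc, before)
  expect_true("position" %in% names(eff))
  expect_identical(names(eff)[length(names(eff))], "position")
})

test_that("value_set_members includes transitive sub-members", {
  base <- "http://e.org/"
  vs <- value_set_def(paste0(base, "FileType"), "FileType",
                      members = paste0(base, c("CSV", "TXT", "TSV")))
  sch <- schema(base, value_sets = list(vs))
  expect_setequal(value_set_members(sch, paste0(base, "FileType")),
                  paste0(base, c("CSV", "TXT", "TSV")))

  nested <- value_set_def(
    paste0(base, "NucleicAcid"), "NucleicAcid",
    members = structure(
      c(rep(paste0(base, "NucleicAcid"), 5L), paste0(base, "adenine")),
      names = paste0(base, c("adenine", "cytosine", "guanine", "thiamine",
                             "uracil", "inosine"))))
  sch2 <- schema(base, value_sets = list(nested))
  expect_setequal(value_set_members(sch2, paste0(base, "NucleicAcid")),
                  paste0(base, c("adenine", "cytosine", "guanine", "thiamine",
                                 "uracil", "inosine")))
  expect_error(value_set_members(sch2, paste0(base, "Nope")),
               class = "ontogen_unknown_value_set")
})

test_that("structural invariants are rejected at assembly", {
  base <- "http://e.org/"
  p <- function(nm) property_def(nm, paste0(base, nm),
                                 target_primitive("string"),
                                 multiplicity(0, 1))
  # property redefinition along the chain
  expect_error(schema(base, classes = list(
    class_def(paste0(base, "A"), "A", properties = list(p("x"))),
    class_def(paste0(base, "B"), "B", parent = paste0(base, "A"),
              properties = list(p("x"))))),
    class = "ontogen_duplicate_property")
  # subClassOf cycle
  expect_error(schema(base, classes = list(
    class_def(paste0(base, "A"), "A", parent = paste0(base, "B")),
    class_def(paste0(base, "B"), "B", parent = paste0(base, "A")))),
    class = "ontogen_cyclic_hierarchy")
  # dangling class reference
  expect_error(schema(base, classes = list(
    class_def(paste0(base, "A"), "A", properties = list(
      property_def("ref", paste0(base, "ref"),
                   target_class(paste0(base, "Protien")),
                   multiplicity(0, 1)))))),
    class = "ontogen_unresolved_reference")
  # class/value-set IRI overlap
  expect_error(schema(base,
    classes = list(class_def(paste0(base, "V"), "V")),
    value_sets = list(value_set_def(paste0(base, "V"), "V",
                                    members = paste0(base, "M")))),
    class = "ontogen_unresolved_reference")
})
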