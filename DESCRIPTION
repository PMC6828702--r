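Package: ontogen
Title: Ontology-Driven Schema Compiler and Closed-World RDF Validator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compiles a combined OWL + simplified-ShEx schema definition into
    the four artifacts a semantic data resource needs: an OWL ontology file,
    a full ShEx schema, a typed R data-binding API, and browsable Markdown
    documentation. Validates RDF instance graphs against the schema under
    closed-world semantics, reporting missing required properties, cardinality
    violations, predicate typos, untyped nodes and value-set violations.
    Bundles a genome-annotation locations sub-ontology (FALDO-derived, with a
    GenBank location-string encoder) and a miniature feature/provenance schema
    as executable fixtures, plus a seeded generator of random schemas,
    conforming instance graphs and single-fault mutations for conformance
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
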