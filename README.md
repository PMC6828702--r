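# ontogen

`ontogen` is an ontology-driven schema compiler and closed-world RDF validator
for the R ecosystem, built for groups that maintain semantic data resources —
in particular genome-annotation resources — where an OWL ontology doubles as
the database schema.

RDF graphs have no enforced structure: an OWL ontology *describes* the
intended shape of the data but, under OWL's open-world assumption, an instance
missing a required link is never reported — the link is simply assumed to
exist unstated. In practice, converting heterogeneous data into RDF produces
predicate typos, instances with missing attributes, untyped nodes and values
outside their controlled vocabularies, and none of this is caught by an OWL
reasoner. `ontogen` closes that gap with a single source of truth: one
definition file that combines OWL class declarations with a simplified
ShEx-style property dialect, compiled into everything the resource needs,
plus a gate-keeping validator that checks instance data under **closed-world
semantics** (the absence of an obligatory link is an error).

## What it does

From one schema-definition file (Turtle or RDF/XML), `ontogen` generates:

1. **An OWL ontology** — per property an `owl:allValuesFrom` restriction with
   optional min/max cardinality 1; `someValuesFrom` is never used, so every
   referenced object is forced to the expected type.
2. **A full ShEx schema** (ShExC) — one `CLOSED EXTRA rdf:type` shape per
   class with flattened inherited properties; multiplicities `0..1`, `1..1`,
   `0..N`, `1..N` map to `?`, (none), `*`, `+`.
3. **A typed R data-binding API** — one constructor per class with
   `set`/`get` accessors for single-valued and `add`/`remove`/`get` accessors
   for multi-valued properties; setters type-check at call time and export
   refuses to serialise incomplete data, so graphs built through the API are
   correct by construction.
4. **Markdown documentation** — one page per class/value set laid out so that
   a static site rooted at the namespace makes the term IRIs resolvable, plus
   a mkdocs site configuration.

The **validator** checks any RDF instance graph against the schema and
reports eight violation kinds: `UNKNOWN_PREDICATE`, `MISSING_REQUIRED`,
`CARDINALITY_EXCEEDED`, `WRONG_TARGET_TYPE`, `UNTYPED_NODE`,
`VALUE_SET_VIOLATION`, `MALFORMED_LIST`, `NON_SCHEMA_TYPE`.

Property definitions use a one-line-per-property dialect stored in the
`propertyDefinitions` annotation of each class:

```
# the amino acid sequence
sequence xsd:string 1..1
domain ProteinDomain =0..N
fileType @FileType 1..1
xref IRI 0..N
```

Targets are a primitive datatype, another class, a value set (`@`, a
controlled vocabulary modelled as a class subtree under `EnumeratedValue`),
or an external IRI. A leading `=` or `~` on the multiplicity stores the
values as an ordered RDF collection or a numbered (`rdf:_1`, `rdf:_2`, ...)
container.

The package bundles a genome-annotation fixture: the FALDO-derived
genomic-locations sub-ontology (16 classes, 17 properties, 1 strand value
set) with a GenBank location-string codec (`100..400`,
`complement(join(...))`, `102^103`, `<5..10`, `one-of(5,8)..20`, ...), a
miniature feature/document/provenance schema, and a three-gene toy annotation
graph. A seeded conformance testkit generates random schemas, conforming
instance graphs, and minimal single-fault mutations for each violation kind.

## Worked example

```r
library(ontogen)

# the bundled genomic-locations schema
loc <- read_schema(system.file("extdata", "gbol_locations.ttl",
                               package = "ontogen"))
schema_stats(loc)
#> {"classes":16,"properties":17,"value_sets":1}

# compile it
write_artifact(emit_owl(loc), "out")     # out/ontology.ttl
write_artifact(emit_shex(loc), "out")    # out/shapes.shex
generate_api(loc, "out/api")             # typed R bindings + manifest
generate_docs(loc, "out/docs")           # Markdown pages + mkdocs.yml

# encode a GenBank location string through the binding runtime
demo <- build_demo_schema()
store <- new_instance_store(demo)
chr <- store_create(store, "Sequence", "http://gbol.life/0.1/chr1")
store_set(store, chr, "sequence", "ACGTACGTACGT")
store_set(store, chr, "strandType", "DoubleStrandedDNA")
cds <- encode_location("complement(join(10..20,30..40))", chr, store)
decode_location(store, cds)
#> [1] "complement(join(10..20,30..40))"

# graphs built through the runtime validate cleanly
validate_graph(turtle_parse(export_graph(store)), demo)
#> <validation_report> 8 instance(s) checked: conforms

# seed a predicate typo into the toy annotation graph and catch it
g <- turtle_parse(export_graph(build_toy_annotation_store()))
res <- mutate_graph(g, demo, "UNKNOWN_PREDICATE", seed = 4)
validate_graph(res$graph, demo)
#> <validation_report> 26 instance(s) checked: 1 violation(s)
#>   kind              subject
#> 1 UNKNOWN_PREDICATE http://gbol.life/0.1/FeatureProvenance_7
#>   detail
#> 1 predicate <http://gbol.life/0.1/origiz> is not defined for c
```

A command-line interface wraps the same functions
(`inst/cli/ontogen generate|validate|stats|fixture`); `validate` exits 0 iff
the data conforms.

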