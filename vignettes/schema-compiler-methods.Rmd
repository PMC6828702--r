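---
title: "Closed-world schema compilation: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-world schema compilation: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why it is
built the way it is. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The schema model

A schema is a set of classes in a single-inheritance tree, each carrying an
ordered list of *direct* properties, plus value sets (controlled vocabularies
modelled as class subtrees under `EnumeratedValue`, so that a vocabulary can
later evolve into a full class hierarchy without changing the data). Every
property has exactly one target — a primitive XSD datatype, another class, a
value set, or an external IRI — and one of four multiplicities: `0..1`,
`1..1`, `0..N`, `1..N`. Unbounded properties may additionally be *ordered*
(`=`, serialised as an RDF collection) or *numbered* (`~`, serialised with
`rdf:_1`, `rdf:_2`, ... container membership); these are the two standard RDF
idioms for the two words, and the distinction matters because a collection
encodes order structurally while a container encodes it in the predicate
names.

Assumptions baked into the model, all enforced at construction time:

* **Single inheritance.** Multiple parents would make property flattening
  ambiguous (which ancestor's ordering wins?), and nothing in the bundled
  domains needs it.
* **No property redefinition.** A subclass may not re-declare an inherited
  property name; overriding would silently change the contract of every
  consumer of the ancestor shape.
* **Naming conventions are invariants, not style.** Classes are
  UpperCamelCase, properties lowerCamelCase, no whitespace. The generated
  artifacts (accessor names, page URLs, shape labels) rely on this.
* **Class and value-set IRI spaces are disjoint.** A term is either
  instantiable or a vocabulary entry, never both.

## Closed-world validation

OWL makes the open-world assumption: a missing obligatory link is not an
error, because it might exist unstated. For a database schema this is the
wrong default — the whole point is to reject incomplete records. The
validator therefore interprets the schema closed-world: every subject with an
`rdf:type` in the schema is checked against its class's flattened property
list, and

* a required property with no value is `MISSING_REQUIRED`;
* more values than the multiplicity admits is `CARDINALITY_EXCEEDED`;
* a predicate outside the flattened list (other than `rdf:type`) is
  `UNKNOWN_PREDICATE` — this is what catches typos in predicates;
* an object of a class-typed property must carry the target class or one of
  its descendants (`WRONG_TARGET_TYPE` otherwise, `UNTYPED_NODE` when it has
  no type at all);
* a value-set value must be a member IRI of the set, including transitive
  sub-members (`VALUE_SET_VIOLATION`);
* ordered/numbered list values must be structurally well-formed
  (`MALFORMED_LIST`: broken or cyclic `rdf:rest` chains, non-contiguous
  `rdf:_n` indices);
* a type outside the schema is `NON_SCHEMA_TYPE`.

Decisions where the design was genuinely open:

* **Literal leniency.** A plain (untyped) literal is accepted for a numeric
  target when its lexical form is valid; requiring explicit `^^xsd:integer`
  everywhere would reject most hand-written Turtle for no safety gain. A
  lexically invalid value is always a violation.
* **Multiple `rdf:type` values.** The node is validated against each schema
  type independently; closed-world semantics are per shape.
* **External IRI targets** are checked syntactically (absolute IRI) only.
  They point into foreign ontologies that cannot be closed-world checked
  locally.
* **Blank nodes** are legal subjects and objects everywhere except as
  value-set members (a vocabulary entry without a stable IRI is useless).
* **Duplicate IRIs** are prevented at the source: the binding runtime
  collision-checks minted IRIs against the store. The validator cannot detect
  a "duplicate" inside one graph (RDF merges identical subjects), so the
  check belongs to data production, not validation.

## The emitted artifacts

**OWL.** Per property one restriction bnode: `owl:allValuesFrom` the target,
`owl:minCardinality 1` iff the minimum is 1, `owl:maxCardinality 1` iff the
maximum is 1. `someValuesFrom` is never emitted, because it does not force
*all* referenced objects to the expected type. Unconstrained external targets
get `rdfs:Resource`. Classes, properties and value sets are sorted by IRI, so
the output is deterministic and re-serialising the parsed file reproduces it
byte for byte.

**ShEx.** One shape per class, `CLOSED` with `rdf:type` in an `EXTRA` clause:
closed shapes are what detect unknown predicates, and `rdf:type` must be
exempt so instances can carry their own type. Inheritance is realised by
flattening rather than shape inclusion, so every shape is self-contained and
engine-portable. A class-typed property is emitted as a *disjunction* of
shape references over the target class and all its descendants: a subclass
instance carries its own (wider) closed shape, so a bare reference to the
ancestor shape would wrongly reject it. Ordered lists reference a generated
recursive list shape (`rdf:first`/`rdf:rest`); numbered containers have no
ShExC equivalent, so the container node is emitted unconstrained and
deep-checked only by the package validator — this is one of the two
documented divergence categories between the validator and a ShEx engine
(the other is that the validator names `UNTYPED_NODE` as its own kind where
ShEx reports a generic shape failure).

**Bindings.** Accessor kinds are determined solely by multiplicity (`set`
overwrites for max 1; `add`/`remove` append for unbounded). Value-set
membership is enforced twice: at set time for fast failure and again at
export as a backstop. Export refuses to serialise while any instance misses a
required property or references an object absent from the store, and reports
the complete list of offenders — partial exports are how inconsistent
resources are born. Subject order on export is insertion order, making export
deterministic.

**Documentation.** Pages live at `<ClassName>/index.md`, mirroring the IRI
fragment, so a static server rooted at the namespace makes every class IRI
resolvable. Inherited properties are shown in a separate section from own
properties, and per-property anchors are emitted as `#propertyName`.

## The genomic-locations fixture

The bundled locations sub-ontology fixes 16 classes, 17 owned properties and
one value set. The enumeration (recorded in
`inst/extdata/gbol_locations_manifest.json`) is: a property-less `Sequence`
anchor; `Location` carrying the `reference` to its sequence — on the
location, not the position, so a collection of regions can span sequences;
`Region`, `BaseLocation` and `InBetweenLocation` as direct children of
`Location`, each with an optional `strand`; `CollectionOfRegions` with
ordered, numbered and unordered variants (the three list encodings the
dialect offers); and the position tree `Position` / `ExactPosition` /
`FuzzyPosition` with `BeforePosition`, `AfterPosition`, `InRangePosition`,
`OneOfPosition`. Fuzzy positions hold plain integers rather than nested
position objects, which forbids arbitrarily deep location expressions. The
strand (`forward`/`reverse`/`both`) is a value set, deliberately not a
`Position` subclass, because a region carries both an index position and a
strand. There are no N-/C-terminal position classes (indexes count from the
N-terminal side) and no reflective `beginOf`/`endOf` properties.

Coordinates are 1-based and fully closed, the GenBank convention; GFF3 input
(also 1-based closed) maps identically. `a^b` denotes the site between two
adjacent bases identified by the preceding base, so `b = a + 1` is enforced
for same-sequence strings. `complement(...)` maps to the reverse strand.
`join(...)` becomes an ordered collection, `order(...)` an unordered one.
The strand rule — no strand on a location whose sequence is single-stranded
or a protein — needs a strandedness kind per sequence; the demo schema
models it as the value set `{DoubleStrandedDNA, SingleStrandedDNA, RNA,
Protein}` with RNA treated as single-stranded, and only double-stranded DNA
admits stranded locations.

## The conformance testkit and what passing means

The generator emulates the data this toolchain is built for: small typed
graphs (a handful of instances per run) over random schemas that cover all
four target kinds, all four multiplicities and both list encodings, with
short ASCII strings and integers in `[0, 10^6]` so failures stay
human-inspectable. Instances are allocated first and linked afterwards, so
mutually required classes never deadlock. All randomness flows through one
seeded generator that saves and restores the session RNG state.

Mutations are minimal seeded edits, one per violation kind — delete the only
value of a required property, append a second value to a single-valued one,
perturb one predicate character, repoint a reference at an incompatible
instance, delete an object's type, swap in a non-member IRI, break one
`rdf:rest` link or renumber one `rdf:_n`, retype an unreferenced instance.
Each is constructed so that it induces *exactly* its kind, which is what
makes 100% detection with kind-exactness a meaningful statement rather than
"the validator fires on broken input".

What passing does **not** show about real data: the generated graphs are
small and clean apart from the seeded fault; they contain no encoding noise,
no namespace drift between producers, no triple-store-scale volumes, no
multi-typed instances, and the single-fault model cannot exhibit interacting
faults whose symptoms mask each other. The suite validates the machinery,
not any particular biological resource.

Problem sizes used by the test suite and the acceptance script — the
package's chosen study conditions: 20 random schemas x 8 violation kinds x
50 mutation seeds (detection study); 200 generated/mutated graphs for the
validator-vs-ShEx-oracle agreement; 100 random schemas for the definition
round trip; 100 runtime-built stores for the correct-by-construction study;
16 GenBank location strings covering every location class.

## Numerical and encoding choices

* Doubles serialise with `%.15g` (shortest round-trippable form at double
  precision); integers with `%d`; booleans as `true`/`false`.
* Turtle output is deterministic: prefixes in map order, subjects in
  first-appearance (or caller-fixed) order, `rdf:type` first within a
  subject. Long (triple-quoted) literals are used exactly when the value
  contains a newline, which keeps `propertyDefinitions` blocks readable in
  the emitted files.
* Minted IRIs are `<base><ClassName>_<n>` with a monotone counter,
  collision-checked against the store.
* Generated binding units are plain R closures over the store runtime rather
  than generated S4/R6, so the templates stay host-language-light and further
  target languages can be added by swapping templates only.

## Known limitations

* No OWL reasoning: subsumption is taken from the declared tree; no
  consistency checking, no inference of missing types.
* No SHACL emission; ShEx (plus the built-in validator) is the conformance
  path.
* ShEx cannot express `rdf:_n` container structure, so numbered-list checks
  exist only in the built-in validator (documented divergence).
* The input dialect has no per-property facets (regular expressions, numeric
  ranges); value constraints beyond datatype and value-set membership are out
  of scope.
* OWL imports are not resolved over the network; external ontologies appear
  as opaque IRI targets only.
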