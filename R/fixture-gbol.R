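# Bundled genome-annotation fixtures: the genomic-locations sub-ontology
# (FALDO-derived, redefined in its own namespace), a reduced
# feature/document/provenance demo schema, and a GenBank location-string
# encoder/decoder that exercises the data-binding runtime.
#
# Locations model: a Location on a Sequence is either a Region (begin/end
# positions), a collection of Regions (ordered, numbered or unordered; members
# may sit on different sequences), a single base (BaseLocation), or an
# in-between location (between two adjacent bases, identified by the
# preceding base). Positions are exact or fuzzy (before/after/in-range/
# one-of); fuzzy positions hold plain integers rather than nested position
# objects. Strand is a value set, deliberately not a Position subclass, and
# sits on Region/BaseLocation/InBetweenLocation; the reference to the
# Sequence sits on the Location (not the Position), so that collections can
# span sequences. There are no N-/C-terminal position classes (indexes count
# from the N-terminal side) and no reflective beginOf/endOf properties.

GBOL_BASE <- "http://gbol.life/0.1/"
FALDO <- "http://biohackathon.org/resource/faldo#"

gbol_iri <- function(name) paste0(GBOL_BASE, name)

strand_value_set <- function() {
  value_set_def(
    gbol_iri("StrandPosition"), "StrandPosition",
    members = c(gbol_iri("ForwardStrandPosition"),
                gbol_iri("ReverseStrandPosition"),
                gbol_iri("BothStrandsPosition")),
    annotations = annotation_set(
      "Strand on which a location lies: forward, reverse or both.",
      usage_comment = "No strand may be given when the referenced sequence is single-stranded or a protein.",
      exact_matches = paste0(FALDO, c("ForwardStrandPosition",
                                      "ReverseStrandPosition",
                                      "BothStrandsPosition"))))
}

gbol_prop <- function(name, target, mult, description = NULL) {
  property_def(name, gbol_iri(name), target, mult, description)
}

gbol_class <- function(name, parent = NULL, properties = list(),
                       definition = NULL, exact_match = NULL,
                       ddbj_label = NULL) {
  class_def(gbol_iri(name), name,
            parent = if (!is.null(parent)) gbol_iri(parent) else NULL,
            properties = properties,
            annotations = annotation_set(
              definition = if (is.null(definition)) name else definition,
              ddbj_label = ddbj_label,
              exact_matches = if (!is.null(exact_match)) {
                paste0(FALDO, exact_match)
              } else character()))
}

location_classes <- function() {
  int1 <- function(name, desc) {
    gbol_prop(name, target_primitive("integer"), multiplicity(1, 1), desc)
  }
  pos1 <- function(name, desc) {
    gbol_prop(name, target_class(gbol_iri("Position")), multiplicity(1, 1),
              desc)
  }
  strand0 <- function() {
    gbol_prop("strand", target_value_set(gbol_iri("StrandPosition")),
              multiplicity(0, 1), "strand the location lies on")
  }
  regions <- function(name, ordered, desc) {
    gbol_prop(name, target_class(gbol_iri("Region")),
              multiplicity(1, Inf, ordered), desc)
  }
  list(
    gbol_class("Sequence",
               definition = "A biological sequence a location can refer to."),
    gbol_class("Location", properties = list(
      gbol_prop("reference", target_class(gbol_iri("Sequence")),
                multiplicity(0, 1),
                "sequence the location is defined on")),
      definition = "An extent on a sequence; the reference lives here, not on the positions, so a location may span sequences."),
    gbol_class("Region", parent = "Location", properties = list(
      pos1("begin", "first base of the region"),
      pos1("end", "last base of the region"),
      strand0()),
      definition = "A contiguous stretch with begin and end positions.",
      exact_match = "Region", ddbj_label = "location"),
    gbol_class("BaseLocation", parent = "Location", properties = list(
      pos1("at", "the single base"),
      strand0()),
      definition = "A single base at a given position."),
    gbol_class("InBetweenLocation", parent = "Location", properties = list(
      pos1("after", "the base after which the in-between site lies"),
      strand0()),
      definition = "A site between two adjacent bases, identified by the preceding base.",
      exact_match = "InBetweenPosition"),
    gbol_class("CollectionOfRegions", parent = "Location",
      definition = "A location made of several regions, possibly on different sequences.",
      exact_match = "CollectionOfRegions"),
    gbol_class("OrderedCollectionOfRegions", parent = "CollectionOfRegions",
      properties = list(regions("memberRegions", "ordered",
                                "member regions in biological order")),
      definition = "Region collection whose member order is meaningful (a GenBank join)."),
    gbol_class("NumberedCollectionOfRegions", parent = "CollectionOfRegions",
      properties = list(regions("numberedRegions", "numbered",
                                "member regions with explicit numbering")),
      definition = "Region collection whose members carry explicit numbers."),
    gbol_class("UnorderedCollectionOfRegions", parent = "CollectionOfRegions",
      properties = list(gbol_prop(
        "members", target_class(gbol_iri("Region")), multiplicity(1, Inf),
        "member regions, unordered")),
      definition = "Region collection without ordering (a GenBank order)."),
    gbol_class("Position",
      definition = "A single coordinate on a sequence (1-based).",
      exact_match = "Position"),
    gbol_class("ExactPosition", parent = "Position", properties = list(
      int1("position", "the exactly known coordinate")),
      definition = "An exactly known coordinate.",
      exact_match = "ExactPosition"),
    gbol_class("FuzzyPosition", parent = "Position",
      definition = "A coordinate that is not exactly known; subclasses hold plain integers, never nested position objects.",
      exact_match = "FuzzyPosition"),
    gbol_class("BeforePosition", parent = "FuzzyPosition", properties = list(
      int1("position", "the coordinate the true position lies before")),
      definition = "A coordinate known to lie before a given base.",
      exact_match = "BeforePosition"),
    gbol_class("AfterPosition", parent = "FuzzyPosition", properties = list(
      int1("position", "the coordinate the true position lies after")),
      definition = "A coordinate known to lie after a given base.",
      exact_match = "AfterPosition"),
    gbol_class("InRangePosition", parent = "FuzzyPosition", properties = list(
      int1("beginPosition", "lowest possible coordinate"),
      int1("endPosition", "highest possible coordinate")),
      definition = "A coordinate known to lie within a closed range.",
      exact_match = "InRangePosition"),
    gbol_class("OneOfPosition", parent = "FuzzyPosition", properties = list(
      gbol_prop("position", target_primitive("integer"),
                multiplicity(1, Inf), "the candidate coordinates")),
      definition = "A coordinate known to be one of several candidates.",
      exact_match = "OneOfPosition"))
}

#' The genomic-locations fixture schema
#'
#' Sixteen classes, seventeen owned properties and one value set (the strand),
#' mirroring the genomic-locations sub-domain of a genome-annotation ontology.
#'
#' @return An `og_schema`.
#' @export
build_locations_schema <- function() {
  schema(GBOL_BASE,
         classes = location_classes(),
         value_sets = list(strand_value_set()),
         prefixes = c(gbol = GBOL_BASE, faldo = FALDO),
         base_prefix = "gbol")
}

#' The miniature feature/document/provenance demo schema
#'
#' Extends the locations fixture with sequences that carry features, documents
#' and data sets that package them, and the two provenance layers: dataset-wise
#' (annotation activities: automatic ones must name a software agent,
#' parameters and input/output files; manual ones a curator) and element-wise
#' (per-feature-property evidence through `FeatureProvenance`, with
#' tool-specific scores in extensible `ProvenanceAnnotation` subclasses).
#'
#' @return An `og_schema`.
#' @export
build_demo_schema <- function() {
  base <- location_classes()
  # enrich the anchor Sequence class with the demo properties
  seq_idx <- which(vapply(base, function(c) c$name, "") == "Sequence")
  base[[seq_idx]] <- gbol_class("Sequence", properties = list(
    gbol_prop("sequence", target_primitive("string"), multiplicity(1, 1),
              "the residue string"),
    gbol_prop("strandType", target_value_set(gbol_iri("StrandType")),
              multiplicity(1, 1), "strandedness kind of the molecule"),
    gbol_prop("feature", target_class(gbol_iri("Feature")),
              multiplicity(0, Inf), "features annotated on this sequence")),
    definition = "A biological sequence with its features.")
  strand_type <- value_set_def(
    gbol_iri("StrandType"), "StrandType",
    members = c(gbol_iri("DoubleStrandedDNA"), gbol_iri("SingleStrandedDNA"),
                gbol_iri("RNA"), gbol_iri("Protein")),
    annotations = annotation_set(
      "Strandedness kind of a sequence; only double-stranded DNA admits stranded locations."))
  demo <- list(
    gbol_class("Feature", properties = list(
      gbol_prop("locus", target_primitive("string"), multiplicity(1, 1),
                "locus tag of the feature"),
      gbol_prop("featureType", target_primitive("string"),
                multiplicity(1, 1), "feature kind, e.g. gene, CDS, tRNA"),
      gbol_prop("location", target_class(gbol_iri("Location")),
                multiplicity(1, 1), "genomic location on the sequence"),
      gbol_prop("provenance", target_class(gbol_iri("FeatureProvenance")),
                multiplicity(0, Inf),
                "element-wise provenance of the feature's properties")),
      definition = "An annotated element located on a sequence.",
      ddbj_label = "feature"),
    gbol_class("Document", properties = list(
      gbol_prop("sequence", target_class(gbol_iri("Sequence")),
                multiplicity(1, 1),
                "the sequence whose annotations this document packages")),
      definition = "Packaging entity holding all annotations for one sequence."),
    gbol_class("GBOLDataSet", properties = list(
      gbol_prop("name", target_primitive("string"), multiplicity(1, 1),
                "data-set name"),
      gbol_prop("document", target_class(gbol_iri("Document")),
                multiplicity(0, Inf), "documents in the collection"),
      gbol_prop("activity", target_class(gbol_iri("AnnotationActivity")),
                multiplicity(0, Inf),
                "annotation activities run for this data set")),
      definition = "Data collection holding metadata and references to all documents and activities."),
    gbol_class("AnnotationActivity",
      definition = "An annotation run; dataset-wise provenance."),
    gbol_class("AutomaticAnnotationActivity", parent = "AnnotationActivity",
      properties = list(
        gbol_prop("softwareAgent", target_external(), multiplicity(1, 1),
                  "the tool that produced the annotations"),
        gbol_prop("parameters", target_primitive("string"),
                  multiplicity(1, 1), "full parameter string of the run"),
        gbol_prop("inputFile", target_primitive("anyURI"),
                  multiplicity(0, Inf), "input files of the run"),
        gbol_prop("outputFile", target_primitive("anyURI"),
                  multiplicity(0, Inf), "output files of the run")),
      definition = "Automatic annotation: requires the software agent and its parameters plus the run's files."),
    gbol_class("ManualAnnotationActivity", parent = "AnnotationActivity",
      properties = list(
        gbol_prop("curator", target_external(), multiplicity(1, 1),
                  "the person who curated the annotation")),
      definition = "Manual curation: requires a curator."),
    gbol_class("FeatureProvenance", properties = list(
      gbol_prop("onProperty", target_external(), multiplicity(1, 1),
                "the feature property this evidence concerns"),
      gbol_prop("annotation", target_class(gbol_iri("ProvenanceAnnotation")),
                multiplicity(1, 1), "the evidence record"),
      gbol_prop("origin", target_class(gbol_iri("AnnotationActivity")),
                multiplicity(0, 1), "the activity that produced the evidence")),
      definition = "Binds evidence to one property of one feature (element-wise provenance)."),
    gbol_class("ProvenanceAnnotation", properties = list(
      gbol_prop("experiment", target_external(), multiplicity(0, 1),
                "evidence-ontology term the annotation is based on")),
      definition = "Base class for tool-specific evidence; extend it with per-tool subclasses."))
  schema(GBOL_BASE,
         classes = c(base, demo),
         value_sets = list(strand_value_set(), strand_type),
         prefixes = c(gbol = GBOL_BASE, faldo = FALDO),
         base_prefix = "gbol")
}

#' Extend a schema with a tool-specific provenance subclass
#'
#' Evidence classes for individual tools are not part of the bundled schema;
#' they are added per deployment as subclasses of `ProvenanceAnnotation`.
#'
#' @param schema An `og_schema` containing `ProvenanceAnnotation`.
#' @param subclass_def A [class_def()] whose `parent` is the
#'   `ProvenanceAnnotation` IRI.
#' @return A new `og_schema`; the input schema is unchanged.
#' @export
extend_with_provenance_subclass <- function(schema, subclass_def) {
  pa <- schema$classes[[gbol_iri("ProvenanceAnnotation")]]
  if (is.null(pa)) {
    og_stop("schema has no ProvenanceAnnotation class", "extension_error")
  }
  if (is.null(subclass_def$parent) || subclass_def$parent != pa$iri) {
    og_stop("provenance extensions must subclass ProvenanceAnnotation",
            "extension_error")
  }
  schema(schema$base_iri,
         classes = c(unname(schema$classes), list(subclass_def)),
         value_sets = unname(schema$value_sets),
         prefixes = schema$prefixes[names(schema$prefixes) != "gbol"],
         base_prefix = "gbol")
}

# ---- GenBank location strings ------------------------------------------

split_top_level <- function(s, sep = ",") {
  depth <- 0L
  parts <- character(0)
  cur <- ""
  for (ch in strsplit(s, "", fixed = TRUE)[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == sep && depth == 0L) {
      parts <- c(parts, cur)
      cur <- ""
    } else cur <- paste0(cur, ch)
  }
  c(parts, cur)
}

gbk_parse_error <- function(s, why) {
  og_stop(paste0("malformed location string '", s, "': ", why),
          "parse_error")
}

parse_gbk_position <- function(tok, full) {
  if (grepl("^[0-9]+$", tok)) {
    return(list(kind = "exact", n = as.integer(tok)))
  }
  if (grepl("^<[0-9]+$", tok)) {
    return(list(kind = "before", n = as.integer(substring(tok, 2L))))
  }
  if (grepl("^>[0-9]+$", tok)) {
    return(list(kind = "after", n = as.integer(substring(tok, 2L))))
  }
  if (grepl("^\\([0-9]+\\.[0-9]+\\)$", tok)) {
    ns <- as.integer(strsplit(gsub("[()]", "", tok), ".", fixed = TRUE)[[1]])
    if (ns[1] > ns[2]) gbk_parse_error(full, "in-range bounds reversed")
    return(list(kind = "range", a = ns[1], b = ns[2]))
  }
  if (grepl("^one-of\\([0-9,]+\\)$", tok)) {
    ns <- as.integer(strsplit(sub("^one-of\\(", "",
                                  sub("\\)$", "", tok)), ",")[[1]])
    if (length(ns) < 2L) gbk_parse_error(full, "one-of needs >= 2 candidates")
    return(list(kind = "oneof", ns = ns))
  }
  gbk_parse_error(full, paste0("bad position token '", tok, "'"))
}

parse_gbk_location <- function(s, full = s) {
  s <- gsub("[ \t]", "", s)
  if (!nzchar(s)) gbk_parse_error(full, "empty location")
  if (grepl("^complement\\(.*\\)$", s)) {
    inner <- parse_gbk_location(substr(s, 12L, nchar(s) - 1L), full)
    inner$complement <- TRUE
    return(inner)
  }
  m <- regmatches(s, regexec("^(join|order)\\((.*)\\)$", s))[[1]]
  if (length(m)) {
    parts <- split_top_level(m[3])
    if (length(parts) < 2L) gbk_parse_error(full, "collection needs >= 2 members")
    return(list(kind = m[2], complement = FALSE,
                members = lapply(parts, parse_gbk_location, full = full)))
  }
  if (grepl("^[0-9]+\\^[0-9]+$", s)) {
    ab <- as.integer(strsplit(s, "^", fixed = TRUE)[[1]])
    if (ab[2] != ab[1] + 1L) {
      gbk_parse_error(full,
                      "in-between site must lie between adjacent bases")
    }
    return(list(kind = "between", complement = FALSE, a = ab[1], b = ab[2]))
  }
  if (grepl("^[0-9]+$", s)) {
    return(list(kind = "point", complement = FALSE, n = as.integer(s)))
  }
  halves <- split_top_level(s, sep = ".")
  # '..' splits into tokens with one empty string between the two dots
  dots <- which(halves == "")
  if (length(halves) == 3L && length(dots) == 1L && dots == 2L) {
    return(list(kind = "region", complement = FALSE,
                begin = parse_gbk_position(halves[1], full),
                end = parse_gbk_position(halves[3], full)))
  }
  gbk_parse_error(full, "unrecognised syntax")
}

make_position <- function(store, ast) {
  switch(ast$kind,
    exact = {
      p <- store_create(store, "ExactPosition")
      store_set(store, p, "position", ast$n)
      p
    },
    before = {
      p <- store_create(store, "BeforePosition")
      store_set(store, p, "position", ast$n)
      p
    },
    after = {
      p <- store_create(store, "AfterPosition")
      store_set(store, p, "position", ast$n)
      p
    },
    range = {
      p <- store_create(store, "InRangePosition")
      store_set(store, p, "beginPosition", ast$a)
      store_set(store, p, "endPosition", ast$b)
      p
    },
    oneof = {
      p <- store_create(store, "OneOfPosition")
      for (n in ast$ns) store_add(store, p, "position", n)
      p
    })
}

build_location <- function(store, ast, sequence) {
  rev_strand <- gbol_iri("ReverseStrandPosition")
  loc <- switch(ast$kind,
    region = {
      r <- store_create(store, "Region")
      store_set(store, r, "begin", make_position(store, ast$begin))
      store_set(store, r, "end", make_position(store, ast$end))
      if (isTRUE(ast$complement)) store_set(store, r, "strand", rev_strand)
      r
    },
    point = {
      b <- store_create(store, "BaseLocation")
      store_set(store, b, "at",
                make_position(store, list(kind = "exact", n = ast$n)))
      if (isTRUE(ast$complement)) store_set(store, b, "strand", rev_strand)
      b
    },
    between = {
      ib <- store_create(store, "InBetweenLocation")
      store_set(store, ib, "after",
                make_position(store, list(kind = "exact", n = ast$a)))
      if (isTRUE(ast$complement)) store_set(store, ib, "strand", rev_strand)
      ib
    },
    join = ,
    order = {
      cls <- if (ast$kind == "join") "OrderedCollectionOfRegions"
      else "UnorderedCollectionOfRegions"
      prop <- if (ast$kind == "join") "memberRegions" else "members"
      coll <- store_create(store, cls)
      for (mast in ast$members) {
        if (isTRUE(ast$complement)) mast$complement <- TRUE
        if (mast$kind != "region") {
          gbk_parse_error(ast$kind, "collections may only contain regions")
        }
        store_add(store, coll, prop, build_location(store, mast, sequence))
      }
      coll
    })
  store_set(store, loc, "reference", sequence)
  loc
}

#' Encode a GenBank location string as location instances
#'
#' Builds the location (regions, collections, single bases, in-between sites,
#' exact and fuzzy positions) in the store via the binding runtime and returns
#' the top-level instance. Coordinates are 1-based, fully closed;
#' `complement(...)` sets the reverse strand; `a^b` requires `b = a + 1`.
#'
#' @param loc GenBank location string, e.g. `"join(10..20,30..40)"`,
#'   `"complement(<5..10)"`, `"102^103"`.
#' @param sequence The referenced sequence: an `og_instance` (or IRI)
#'   registered in the store.
#' @param store An [new_instance_store()] on a schema containing the locations
#'   classes.
#' @return The `og_instance` of the created location.
#' @export
encode_location <- function(loc, sequence, store) {
  ast <- parse_gbk_location(loc)
  build_location(store, ast, sequence)
}

decode_position <- function(store, iri) {
  inst <- store$instances[[iri]]
  name <- local_name(inst$class_iri, GBOL_BASE)
  g <- function(p) store_get(store, iri, p)
  switch(name,
    ExactPosition = g("position"),
    BeforePosition = paste0("<", g("position")),
    AfterPosition = paste0(">", g("position")),
    InRangePosition = paste0("(", g("beginPosition"), ".",
                             g("endPosition"), ")"),
    OneOfPosition = paste0("one-of(", paste(g("position"), collapse = ","),
                           ")"))
}

#' Decode a location instance back to its GenBank string
#'
#' Exact inverse of [encode_location()] on its output.
#'
#' @param store The instance store holding the location.
#' @param location An `og_instance` (or IRI) of a location.
#' @return GenBank location string.
#' @export
decode_location <- function(store, location) {
  iri <- instance_iri(location)
  inst <- store$instances[[iri]]
  name <- local_name(inst$class_iri, GBOL_BASE)
  comp <- function(s) {
    strand <- store_get(store, iri, "strand")
    if (length(strand) && strand == gbol_iri("ReverseStrandPosition")) {
      paste0("complement(", s, ")")
    } else s
  }
  switch(name,
    Region = comp(paste0(decode_position(store, store_get(store, iri, "begin")),
                         "..",
                         decode_position(store, store_get(store, iri, "end")))),
    BaseLocation = comp(decode_position(store, store_get(store, iri, "at"))),
    InBetweenLocation = {
      a <- as.integer(store_get(
        store, store_get(store, iri, "after"), "position"))
      comp(paste0(a, "^", a + 1L))
    },
    OrderedCollectionOfRegions = ,
    UnorderedCollectionOfRegions = {
      prop <- if (name == "OrderedCollectionOfRegions") "memberRegions"
      else "members"
      word <- if (name == "OrderedCollectionOfRegions") "join" else "order"
      members <- store_get(store, iri, prop)
      strs <- vapply(members, function(m) decode_location(store, m), "")
      all_comp <- all(startsWith(strs, "complement("))
      if (all_comp && length(strs)) {
        strs <- substr(strs, 12L, nchar(strs) - 1L)
        paste0("complement(", word, "(", paste(strs, collapse = ","), "))")
      } else {
        paste0(word, "(", paste(strs, collapse = ","), ")")
      }
    },
    og_stop(paste0("not a location instance: ", iri), "parse_error"))
}

#' Check the strand rule over a store
#'
#' No strand may be specified on a location whose referenced sequence is
#' single-stranded (single-stranded DNA or RNA) or a protein.
#'
#' @param store An [new_instance_store()] on the demo schema (sequences carry
#'   a `strandType`).
#' @return A data frame of violations (kind `STRAND_RULE_VIOLATION`), empty
#'   when the rule holds.
#' @export
strand_rule_check <- function(store) {
  unstranded <- c(gbol_iri("SingleStrandedDNA"), gbol_iri("RNA"),
                  gbol_iri("Protein"))
  out <- list()
  for (iri in store$order) {
    inst <- store$instances[[iri]]
    strand <- inst$props[["strand"]]
    if (is.null(strand)) next
    ref <- inst$props[["reference"]]
    if (is.null(ref)) {
      og_stop(paste0("stranded location <", iri,
                     "> has no sequence reference"), "dangling_reference")
    }
    seq_inst <- store$instances[[ref[[1]]$o]]
    if (is.null(seq_inst)) {
      og_stop(paste0("stranded location <", iri,
                     "> references a sequence absent from the store"),
              "dangling_reference")
    }
    st <- seq_inst$props[["strandType"]]
    if (!is.null(st) && st[[1]]$o %in% unstranded) {
      out[[length(out) + 1L]] <- violation_row(
        "STRAND_RULE_VIOLATION", iri, gbol_iri("strand"),
        sprintf("stranded location on %s sequence <%s>",
                local_name(st[[1]]$o, GBOL_BASE), ref[[1]]$o))
    }
  }
  if (length(out)) do.call(rbind, out)
  else violation_row(character(0), character(0), character(0), character(0))
}

# ---- toy annotation graph ----------------------------------------------

toy_gff3_lines <- function() {
  c("##gff-version 3",
    "##sequence-region chr1 1 5000",
    "chr1\ttoytool\tgene\t100\t400\t.\t+\t.\tID=gene001;locus_tag=TOY_0001",
    "chr1\ttoytool\tCDS\t500\t800\t.\t-\t.\tID=cds001;locus_tag=TOY_0002",
    "chr1\ttoytool\ttRNA\t900\t1000\t.\t+\t.\tID=trna001;locus_tag=TOY_0003")
}

toy_location_strings <- function() {
  c("100..400", "complement(500..800)", "join(900..950,960..1000)")
}

#' Build the bundled three-gene toy annotation store
#'
#' A double-stranded sequence with three features (gene, CDS on the reverse
#' strand, a joined tRNA), each carrying element-wise provenance bound to an
#' automatic annotation activity, packaged into a document and data set.
#'
#' @return An `instance_store` on [build_demo_schema()].
#' @export
build_toy_annotation_store <- function() {
  sch <- build_demo_schema()
  store <- new_instance_store(sch)
  seq <- store_create(store, "Sequence", gbol_iri("chr1"))
  store_set(store, seq, "sequence",
            paste(rep("ACGT", 25L), collapse = ""))
  store_set(store, seq, "strandType", gbol_iri("DoubleStrandedDNA"))
  activity <- store_create(store, "AutomaticAnnotationActivity")
  store_set(store, activity, "softwareAgent", "http://example.org/tool/toytool")
  store_set(store, activity, "parameters", "--mode fast --toy")
  store_add(store, activity, "inputFile", "file:///data/toy_genome.fasta")
  store_add(store, activity, "outputFile", "file:///data/toy_genome.gff3")
  info <- list(c("TOY_0001", "gene"), c("TOY_0002", "CDS"),
               c("TOY_0003", "tRNA"))
  locs <- toy_location_strings()
  for (k in seq_along(info)) {
    feat <- store_create(store, "Feature")
    store_set(store, feat, "locus", info[[k]][1])
    store_set(store, feat, "featureType", info[[k]][2])
    store_set(store, feat, "location", encode_location(locs[k], seq, store))
    ann <- store_create(store, "ProvenanceAnnotation")
    store_set(store, ann, "experiment", "http://purl.obolibrary.org/obo/ECO_0000203")
    prov <- store_create(store, "FeatureProvenance")
    store_set(store, prov, "onProperty", gbol_iri("featureType"))
    store_set(store, prov, "annotation", ann)
    store_set(store, prov, "origin", activity)
    store_add(store, feat, "provenance", prov)
    store_add(store, seq, "feature", feat)
  }
  doc <- store_create(store, "Document")
  store_set(store, doc, "sequence", seq)
  ds <- store_create(store, "GBOLDataSet")
  store_set(store, ds, "name", "toy genome annotation")
  store_add(store, ds, "document", doc)
  store_add(store, ds, "activity", activity)
  store
}

#' Read features from a GFF3 file into an annotation store
#'
#' Uses `rtracklayer` to read the records; each becomes a `Feature` whose
#' location is a `Region` on the named sequence (1-based, fully closed, like
#' GenBank strings), reverse-strand records map to the reverse strand value.
#'
#' @param path GFF3 file path.
#' @param store An `instance_store` on the demo schema.
#' @param sequence The `og_instance` of the sequence the records annotate.
#' @return List of created `Feature` instances, invisibly.
#' @export
encode_gff3 <- function(path, store, sequence) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("encode_gff3() needs the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  feats <- lapply(seq_along(gr), function(i) {
    rec <- gr[i]
    feat <- store_create(store, "Feature")
    lt <- rec$locus_tag
    store_set(store, feat, "locus",
              if (!is.null(lt) && !is.na(lt)) as.character(lt)
              else as.character(rec$ID))
    store_set(store, feat, "featureType", as.character(rec$type))
    loc <- sprintf("%d..%d", GenomicRanges::start(rec),
                   GenomicRanges::end(rec))
    if (as.character(GenomicRanges::strand(rec)) == "-") {
      loc <- paste0("complement(", loc, ")")
    }
    store_set(store, feat, "location", encode_location(loc, sequence, store))
    store_add(store, sequence, "feature", feat)
    feat
  })
  invisible(feats)
}

#' Materialise the bundled fixture files
#'
#' Writes the locations schema, the demo schema, the toy GFF3 + location
#' strings, the toy instance graph, and a manifest recording the exact class
#' and property enumeration of the locations fixture.
#'
#' @param out_dir Output directory.
#' @return Written paths, invisibly.
#' @export
materialize_fixtures <- function(out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  loc <- build_locations_schema()
  demo <- build_demo_schema()
  paths <- c(
    write_artifact(emit_definition(loc, "gbol_locations.ttl"), out_dir),
    write_artifact(emit_definition(demo, "demo_annotation.ttl"), out_dir))
  gff <- file.path(out_dir, "toy_genome.gff3")
  writeLines(toy_gff3_lines(), gff)
  loc_strings <- file.path(out_dir, "toy_genome.gbk-loc")
  writeLines(toy_location_strings(), loc_strings)
  toy <- file.path(out_dir, "toy_instances.ttl")
  writeLines(export_graph(build_toy_annotation_store()), toy, useBytes = TRUE)
  st <- schema_stats(loc)
  manifest <- file.path(out_dir, "gbol_locations_manifest.json")
  writeLines(as.character(jsonlite::toJSON(list(
    classes = vapply(loc$classes, function(c) c$name, "", USE.NAMES = FALSE),
    properties = unlist(lapply(loc$classes, function(c) {
      if (length(c$properties)) paste0(c$name, ".", names(c$properties))
    }), use.names = FALSE),
    value_sets = vapply(loc$value_sets, function(v) v$name, "",
                        USE.NAMES = FALSE),
    stats = unclass(st)), auto_unbox = TRUE, pretty = TRUE)), manifest)
  invisible(c(paths, gff, loc_strings, toy, manifest))
}
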