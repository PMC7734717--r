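# Knowledge-base model: ontology loading, the three assertion families, and
# structural type inference (asserted types + transitive subclass closure).
# The closure stands in for a DL reasoner; it covers every behavior the
# dialogue and QA pipelines exercise on named classes.

RESERVED_PREDICATES <- c(IRI_TYPE, IRI_SUBCLASS, IRI_LABEL)
RESERVED_TYPES <- c(IRI_CLASS, IRI_OBJPROP, IRI_DATAPROP, IRI_NAMED_IND,
                    IRI_ONTOLOGY, IRI_ANNPROP)

#' Load an ontology into a knowledge base
#'
#' Reads an RDF/XML or Turtle ontology and extracts the three assertion
#' families used for question answering: object-property assertions
#' (instance-to-instance), data-property assertions (instance-to-literal),
#' and class assertions (triples whose subject and object are both declared
#' classes), together with the subclass graph, individual types, and labels.
#'
#' @param path Path to an `.owl`/`.rdf` (RDF/XML) or `.ttl` (Turtle) file.
#' @param format Serialization; `"auto"` resolves by extension.
#' @return An object of class `cooqa_kb`: a list with elements `assertions`
#'   (data.frame `domain`, `property`, `range`, `range_is_literal`, `kind`),
#'   `subclass` (data.frame `subclass`, `superclass`), `types` (data.frame
#'   `individual`, `class`), `labels` (named character), `classes`,
#'   `entities`, and `source`.
#' @examples
#' kb <- load_ontology(generate_toy_kb(file.path(tempdir(), "kb.owl")))
#' nrow(kb_assertions(kb, "object"))
#' @export
load_ontology <- function(path, format = c("auto", "rdfxml", "turtle")) {
  triples <- read_rdf(path, format = match.arg(format))
  kb_from_triples(triples, source = path)
}

kb_from_triples <- function(triples, source = NA_character_) {
  is_type <- triples$predicate == IRI_TYPE & !triples$is_literal
  classes <- unique(c(
    triples$subject[is_type & triples$object == IRI_CLASS],
    triples$subject[triples$predicate == IRI_SUBCLASS],
    triples$object[triples$predicate == IRI_SUBCLASS & !triples$is_literal]
  ))
  obj_props  <- triples$subject[is_type & triples$object == IRI_OBJPROP]
  data_props <- triples$subject[is_type & triples$object == IRI_DATAPROP]

  subclass <- triples[triples$predicate == IRI_SUBCLASS & !triples$is_literal,
                      c("subject", "object")]
  names(subclass) <- c("subclass", "superclass")

  types <- triples[is_type & !(triples$object %in% RESERVED_TYPES),
                   c("subject", "object")]
  names(types) <- c("individual", "class")
  classes <- unique(c(classes, types$class))

  label_rows <- triples$predicate == IRI_LABEL & triples$is_literal
  explicit <- triples$object[label_rows]
  names(explicit) <- triples$subject[label_rows]

  plain <- triples[!(triples$predicate %in% RESERVED_PREDICATES) &
                     !(is_type), , drop = FALSE]
  # literal ranges are data assertions; triples between two declared classes
  # are class assertions; everything else is an object assertion
  kind <- ifelse(plain$is_literal, "data",
          ifelse(plain$subject %in% classes & plain$object %in% classes,
                 "class", "object"))
  assertions <- data.frame(domain = plain$subject, property = plain$predicate,
                           range = plain$object,
                           range_is_literal = plain$is_literal,
                           kind = kind, stringsAsFactors = FALSE)
  rownames(assertions) <- NULL

  entities <- unique(c(triples$subject, triples$predicate,
                       triples$object[!triples$is_literal]))
  kb <- list(assertions = assertions, subclass = unique(subclass),
             types = unique(types), labels = explicit, classes = classes,
             object_properties = unique(obj_props),
             data_properties = unique(data_props),
             entities = entities, source = source)
  class(kb) <- "cooqa_kb"
  kb
}

#' @export
print.cooqa_kb <- function(x, ...) {
  n <- table(factor(x$assertions$kind, levels = c("object", "data", "class")))
  cat("<cooqa_kb> ", length(x$entities), " entities | assertions: ",
      n[["object"]], " object, ", n[["data"]], " data, ", n[["class"]],
      " class | ", nrow(x$subclass), " subclass edges\n", sep = "")
  invisible(x)
}

#' Extract one assertion family
#'
#' @param kb A `cooqa_kb`.
#' @param kind `"object"`, `"data"`, or `"class"`.
#' @return The matching rows of `kb$assertions`.
#' @export
kb_assertions <- function(kb, kind = c("object", "data", "class")) {
  kind <- match.arg(kind)
  out <- kb$assertions[kb$assertions$kind == kind, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Human-readable label for an entity IRI
#'
#' An explicit `rdfs:label` wins; otherwise the IRI local name with
#' underscores replaced by spaces, lowercased. Literal values are returned
#' as-is.
#'
#' @param kb A `cooqa_kb`.
#' @param iri Character vector of IRIs (or literal values).
#' @param is_literal Logical vector: which elements are literals.
#' @return Character vector of labels.
#' @export
kb_label <- function(kb, iri, is_literal = FALSE) {
  is_literal <- rep_len(is_literal, length(iri))
  out <- character(length(iri))
  for (i in seq_along(iri)) {
    if (is_literal[i]) {
      out[i] <- iri[i]
    } else if (iri[i] %in% names(kb$labels)) {
      out[i] <- kb$labels[[iri[i]]]
    } else {
      out[i] <- tolower(gsub("_", " ", iri_local(iri[i]), fixed = TRUE))
    }
  }
  out
}

# Transitive closure of a class set under the subclass relation, by fixpoint
# expansion (the independent test oracle uses graph reachability instead).
class_closure <- function(kb, classes) {
  seen <- unique(classes)
  repeat {
    nxt <- kb$subclass$superclass[kb$subclass$subclass %in% seen]
    add <- setdiff(nxt, seen)
    if (!length(add)) break
    seen <- c(seen, add)
  }
  seen
}

#' Inferred classes of an individual
#'
#' Asserted types plus their transitive superclass closure — the structural
#' stand-in for reasoner-derived classification.
#'
#' @param kb A `cooqa_kb`.
#' @param individual IRI of an individual with at least one asserted type.
#' @return Character vector of class IRIs.
#' @export
infer_classes <- function(kb, individual) {
  asserted <- kb$types$class[kb$types$individual == individual]
  if (!length(asserted)) {
    stop("unknown individual (no asserted type): ", individual)
  }
  class_closure(kb, asserted)
}

#' Class assertions instantiated by an instance-level triple
#'
#' For an object- or data-property assertion, returns every class assertion
#' `(D, P, R)` in the knowledge base with `D` among the inferred classes of
#' the triple's domain, `P` equal to the triple's property, and (for object
#' assertions) `R` among the inferred classes of the range. Data-property
#' ranges are literals and carry no classes, so they match on domain and
#' property only.
#'
#' @param kb A `cooqa_kb`.
#' @param triple A one-row assertion data.frame (columns `domain`,
#'   `property`, `range`, `range_is_literal`, `kind`) or a list with those
#'   fields.
#' @return Data.frame of matching class assertions (possibly empty).
#' @export
tbox_assertions_of <- function(kb, triple) {
  triple <- as.list(triple)
  if (identical(triple$kind, "class")) {
    stop("tbox_assertions_of expects an object- or data-property assertion")
  }
  cls <- kb_assertions(kb, "class")
  dom_types <- kb$types$class[kb$types$individual == triple$domain]
  if (!length(dom_types) || !nrow(cls)) return(cls[0, , drop = FALSE])
  dom_closure <- class_closure(kb, dom_types)
  keep <- cls$domain %in% dom_closure & cls$property == triple$property
  if (identical(triple$kind, "object")) {
    rng_types <- kb$types$class[kb$types$individual == triple$range]
    if (!length(rng_types)) return(cls[0, , drop = FALSE])
    keep <- keep & cls$range %in% class_closure(kb, rng_types)
  }
  out <- cls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Re-serialize a knowledge base to a flat triple table (round-trip support).
kb_to_triples <- function(kb) {
  rows <- list()
  if (nrow(kb$types)) {
    rows[[length(rows) + 1L]] <- triple_df(kb$types$individual, IRI_TYPE,
                                           kb$types$class)
  }
  for (cl in kb$classes) {
    rows[[length(rows) + 1L]] <- triple_df(cl, IRI_TYPE, IRI_CLASS)
  }
  for (p in kb$object_properties) {
    rows[[length(rows) + 1L]] <- triple_df(p, IRI_TYPE, IRI_OBJPROP)
  }
  for (p in kb$data_properties) {
    rows[[length(rows) + 1L]] <- triple_df(p, IRI_TYPE, IRI_DATAPROP)
  }
  if (nrow(kb$subclass)) {
    rows[[length(rows) + 1L]] <- triple_df(kb$subclass$subclass, IRI_SUBCLASS,
                                           kb$subclass$superclass)
  }
  if (length(kb$labels)) {
    rows[[length(rows) + 1L]] <- triple_df(names(kb$labels), IRI_LABEL,
                                           unname(kb$labels), is_literal = TRUE)
  }
  if (nrow(kb$assertions)) {
    rows[[length(rows) + 1L]] <- triple_df(kb$assertions$domain,
                                           kb$assertions$property,
                                           kb$assertions$range,
                                           kb$assertions$range_is_literal)
  }
  do.call(rbind, rows)
}

#' Serialize a knowledge base back to an ontology file
#'
#' @param kb A `cooqa_kb`.
#' @param path Output path (`.ttl` for Turtle, anything else for RDF/XML).
#' @param format Serialization; `"auto"` resolves by extension.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(kb, path, format = c("auto", "rdfxml", "turtle")) {
  write_rdf(kb_to_triples(kb), path, format = match.arg(format))
}
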