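#' The seven-type clinical information model
#'
#' Radiology reports are structured around two *concept* entity types --
#' observations (directly observed imaging features such as "nodule") and
#' clinical findings (interpretations such as "cancer") -- and five
#' *modifier* entity types that attach attributes to a concept: anatomical
#' location, certainty, change, characteristics, and size.
#'
#' @return A data frame with columns `name` and `category`
#'   (`"concept"` or `"modifier"`), one row per entity type.
#' @examples
#' entity_types()
#' @export
entity_types <- function() {
  data.frame(
    name = c("Observation", "ClinicalFinding", "AnatomicalLocation",
             "Certainty", "Change", "Characteristics", "Size"),
    category = c("concept", "concept", rep("modifier", 5L)),
    stringsAsFactors = FALSE
  )
}

concept_types <- function() {
  et <- entity_types()
  et$name[et$category == "concept"]
}

modifier_types <- function() {
  et <- entity_types()
  et$name[et$category == "modifier"]
}

#' Relation types and their endpoint constraints
#'
#' Two directed relation types are defined. A `Modifier` relation runs from
#' an observation or clinical-finding entity to a modifier entity. An
#' `Evidence` relation runs from an observation entity to the clinical
#' finding it supports.
#'
#' @return A named list; each element has `head_types` and `tail_types`
#'   character vectors of admissible endpoint entity types.
#' @examples
#' relation_types()
#' @export
relation_types <- function() {
  list(
    Modifier = list(head_types = concept_types(),
                    tail_types = modifier_types()),
    Evidence = list(head_types = "Observation",
                    tail_types = "ClinicalFinding")
  )
}

check_entity_type <- function(type) {
  bad <- setdiff(type, entity_types()$name)
  if (length(bad) > 0) {
    stop("unknown entity type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(type)
}

check_relation_type <- function(type) {
  bad <- setdiff(type, names(relation_types()))
  if (length(bad) > 0) {
    stop("unknown relation type: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(type)
}

#' Is a (head, tail) entity-type pair admissible for a relation type?
#'
#' @param head_type,tail_type Entity type names (see [entity_types()]).
#' @param rel_type Relation type name, `"Modifier"` or `"Evidence"`.
#' @return `TRUE` iff the directed pair satisfies the schema constraints.
#' @examples
#' validate_relation("Observation", "AnatomicalLocation", "Modifier")  # TRUE
#' validate_relation("ClinicalFinding", "Observation", "Evidence")     # FALSE
#' @export
validate_relation <- function(head_type, tail_type, rel_type) {
  check_entity_type(c(head_type, tail_type))
  check_relation_type(rel_type)
  rt <- relation_types()[[rel_type]]
  head_type %in% rt$head_types && tail_type %in% rt$tail_types
}

#' Construct an annotated report
#'
#' The unit of I/O, training and evaluation: report text plus (optionally)
#' sentence segmentation, typed entity spans and typed binary relations.
#' Character offsets are 0-based and half-open throughout.
#'
#' @param id Report identifier.
#' @param text Report text (UTF-8).
#' @param entities Data frame with columns `id`, `type`, `start`, `end`,
#'   `text`; may be `NULL` for an unannotated report.
#' @param relations Data frame with columns `id`, `type`, `head`, `tail`
#'   (entity ids); may be `NULL`.
#' @param source Optional source/stratum tag (e.g. `"chest"`).
#' @param tokenize If `TRUE`, segment and tokenize the text immediately.
#' @param validate If `TRUE`, check all schema invariants.
#' @return An object of class `rad_report`.
#' @export
rad_report <- function(id, text, entities = NULL, relations = NULL,
                       source = NA_character_, tokenize = TRUE,
                       validate = TRUE) {
  if (is.null(entities)) entities <- empty_entities()
  if (is.null(relations)) relations <- empty_relations()
  r <- structure(
    list(id = id, text = text, sentences = NULL, entities = entities,
         relations = relations, oos = NULL, source = source),
    class = "rad_report"
  )
  if (tokenize) r <- tokenize_report(r)
  if (validate) validate_report(r)
  r
}

empty_entities <- function() {
  data.frame(id = character(), type = character(), start = integer(),
             end = integer(), text = character(), stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(id = character(), type = character(), head = character(),
             tail = character(), stringsAsFactors = FALSE)
}

#' Validate the schema invariants of a report
#'
#' Checks entity offsets against the text, entity text against the
#' corresponding substring, relation endpoints against the entity table,
#' and relation type constraints.
#'
#' @param report A [rad_report()].
#' @return The report, invisibly; errors on the first violation.
#' @export
validate_report <- function(report) {
  ent <- report$entities
  n <- nchar(report$text)
  if (nrow(ent) > 0) {
    check_entity_type(ent$type)
    if (anyDuplicated(ent$id) > 0) {
      stop("duplicate entity id in report ", report$id, call. = FALSE)
    }
    bad <- ent$start < 0 | ent$start >= ent$end | ent$end > n
    if (any(bad)) {
      stop("entity offsets outside text in report ", report$id, ": ",
           paste(ent$id[bad], collapse = ", "), call. = FALSE)
    }
    sub <- substring(report$text, ent$start + 1L, ent$end)
    if (any(sub != ent$text)) {
      stop("entity text does not match report substring in report ",
           report$id, call. = FALSE)
    }
  }
  rel <- report$relations
  if (nrow(rel) > 0) {
    check_relation_type(rel$type)
    miss <- !(rel$head %in% ent$id) | !(rel$tail %in% ent$id)
    if (any(miss)) {
      stop("relation endpoint not among entities in report ", report$id,
           call. = FALSE)
    }
    if (any(rel$head == rel$tail)) {
      stop("self-relation in report ", report$id, call. = FALSE)
    }
    ht <- ent$type[match(rel$head, ent$id)]
    tt <- ent$type[match(rel$tail, ent$id)]
    ok <- mapply(validate_relation, ht, tt, rel$type)
    if (!all(ok)) {
      stop("relation violates type constraints in report ", report$id, ": ",
           paste(rel$id[!ok], collapse = ", "), call. = FALSE)
    }
  }
  invisible(report)
}

#' @export
print.rad_report <- function(x, ...) {
  cat(sprintf("<rad_report %s: %d chars, %d sentences, %d entities, %d relations>\n",
              x$id, nchar(x$text),
              if (is.null(x$sentences)) 0L else length(x$sentences),
              nrow(x$entities), nrow(x$relations)))
  invisible(x)
}

#' Serialize the information model as a human-readable configuration block
#'
#' The type names emitted here are exactly the names expected in BRAT `.ann`
#' files, so a schema block can be pasted into annotation-tool configs.
#'
#' @return A character vector of configuration lines.
#' @export
schema_config <- function() {
  et <- entity_types()
  rt <- relation_types()
  c("[entities]", et$name,
    "[relations]",
    vapply(names(rt), function(nm) {
      sprintf("%s\tArg1:%s, Arg2:%s", nm,
              paste(rt[[nm]]$head_types, collapse = "|"),
              paste(rt[[nm]]$tail_types, collapse = "|"))
    }, character(1)))
}
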