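# In-memory typed knowledge base: entities, relations, is-a closure,
# layer classification and context-dependent role assignments.

#' @importFrom stats setNames
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# CURIE grammar: uppercase alphanumeric prefix, local id of digits or a
# fixture-scoped token (letters, digits, "_", ".", "-").
CURIE_RE <- "^[A-Z][A-Z0-9]*:[A-Za-z0-9][A-Za-z0-9_.-]*$"

PREDICATES <- c("is_a", "has_part", "part_of", "has_result",
                "occurs_in", "has_role", "has_participant")

KIND_TAGS <- c("object", "role", "quality", "primitive_process",
               "process_sequence", "toxic_course", "functioning_process",
               "meta_functioning_process", "molecule",
               "biological_structure", "finding")

LAYERS <- c("top", "intermediate", "lower", "unassigned")
CATEGORIES <- c("continuant", "occurrent", "unassigned")

.process_kinds <- c("primitive_process", "process_sequence", "toxic_course",
                    "functioning_process", "meta_functioning_process")
.continuant_kinds <- c("object", "role", "quality", "molecule",
                       "biological_structure")

#' Create an ontology entity
#'
#' An entity is a named class, either a continuant (objects, roles,
#' qualities -- things that persist through time) or an occurrent
#' (processes -- things that unfold in time). Entities carry a layer
#' annotation recording whether they belong to the domain-independent top
#' layer, the biomedical intermediate layer, or the toxicology-specific
#' lower layer of the three-layer is-a model.
#'
#' A `toxic_course` kind tag implies `process_sequence`, and any process
#' kind implies the occurrent category; continuant kind tags likewise imply
#' the continuant category when no category is given explicitly.
#'
#' @param id CURIE identifier, e.g. `"TXPO:0001964"` or
#'   `"TXPOX:lysosome"`. Fixture entities use the reserved `TXPOX` prefix so
#'   they can never collide with released TXPO identifiers.
#' @param label human-readable name; defaults to the id.
#' @param category `"continuant"`, `"occurrent"` or `"unassigned"`.
#' @param layer `"top"`, `"intermediate"`, `"lower"` or `"unassigned"`.
#'   Layer provenance is an annotation assigned at construction time.
#' @param kind character vector of kind tags, a subset of
#'   `c("object","role","quality","primitive_process","process_sequence",`
#'   `"toxic_course","functioning_process","meta_functioning_process",`
#'   `"molecule","biological_structure","finding")`.
#' @param definition free-text definition.
#' @param xrefs character vector of cross-reference CURIEs (e.g. GO ids).
#' @return An object of class `tox_entity`.
#' @export
entity <- function(id, label = id, category = "unassigned",
                   layer = "unassigned", kind = character(),
                   definition = "", xrefs = character()) {
  if (!is.character(id) || length(id) != 1L || !grepl(CURIE_RE, id))
    stop("malformed CURIE id: '", paste(id, collapse = ","), "'", call. = FALSE)
  category <- match.arg(category, CATEGORIES)
  layer <- match.arg(layer, LAYERS)
  bad <- setdiff(kind, KIND_TAGS)
  if (length(bad))
    stop("unknown kind tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if ("toxic_course" %in% kind) kind <- union(kind, "process_sequence")
  if (category == "unassigned") {
    if (any(kind %in% .process_kinds)) category <- "occurrent"
    else if (any(kind %in% .continuant_kinds)) category <- "continuant"
  }
  if (any(kind %in% .process_kinds) && category == "continuant")
    stop("entity '", id, "' has a process kind but continuant category",
         call. = FALSE)
  structure(
    list(id = id, label = label, category = category, layer = layer,
         kind = sort(unique(kind)), definition = definition,
         xrefs = sort(unique(xrefs))),
    class = "tox_entity")
}

#' @export
print.tox_entity <- function(x, ...) {
  cat(sprintf("<%s> %s  [%s/%s]%s\n", x$id, x$label, x$category, x$layer,
              if (length(x$kind)) paste0(" {", paste(x$kind, collapse = ","), "}") else ""))
  invisible(x)
}

.empty_relations <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), context = character(),
             stringsAsFactors = FALSE)
}

#' Create an empty knowledge base
#'
#' A knowledge base holds entities, typed relation triples, course
#' specialization (substitution) maps, finding annotations and the ids of
#' the category roots. It has reference semantics: mutating functions such
#' as [kb_add_entity()] modify it in place and return invisibly.
#'
#' @return An object of class `tox_kb`.
#' @export
#' @examples
#' kb <- kb_new()
#' kb_add_entity(kb, entity("TXPOX:lysosome", "lysosome",
#'                          kind = "biological_structure"))
#' kb_size(kb)
kb_new <- function() {
  kb <- new.env(parent = emptyenv())
  kb$entities <- list()
  kb$relations <- .empty_relations()
  kb$substitutions <- list()      # course id -> named chr (source id -> target id)
  kb$findings <- data.frame(process = character(), finding = character(),
                            stringsAsFactors = FALSE)
  kb$roots <- character()         # named: continuant / occurrent / process / toxic_course
  kb$extra <- data.frame(subject = character(), predicate = character(),
                         object = character(), literal = logical(),
                         stringsAsFactors = FALSE)
  kb$warnings <- character()
  kb$import_report <- NULL
  class(kb) <- "tox_kb"
  kb
}

#' @export
print.tox_kb <- function(x, ...) {
  cat(sprintf("<tox_kb> %d entities, %d relations\n",
              length(x$entities), nrow(x$relations)))
  invisible(x)
}

#' @rdname kb_new
#' @param kb a `tox_kb`.
#' @export
kb_size <- function(kb) length(kb$entities)

kb_has_entity <- function(kb, id) !is.null(kb$entities[[id]])

#' Retrieve an entity by id
#' @param kb a `tox_kb`.
#' @param id entity CURIE.
#' @return the `tox_entity`; error if absent.
#' @export
kb_entity <- function(kb, id) {
  e <- kb$entities[[id]]
  if (is.null(e)) stop("unknown entity id: '", id, "'", call. = FALSE)
  e
}

#' @rdname kb_entity
#' @export
kb_entity_ids <- function(kb) sort(names(kb$entities))

#' Look up entity ids by exact label
#' @inheritParams kb_entity
#' @param label label string to match exactly.
#' @return character vector of matching ids (possibly empty), sorted.
#' @export
kb_find_label <- function(kb, label) {
  hits <- vapply(kb$entities, function(e) identical(e$label, label), logical(1))
  sort(names(kb$entities)[hits])
}

#' Declare the category roots of a knowledge base
#'
#' Records which entities act as the continuant and occurrent top-layer
#' roots (and optionally the generic process and toxic-course roots used by
#' [kb_stats()]).
#'
#' @inheritParams kb_entity
#' @param ... named root ids, e.g. `continuant = "TXPOX:continuant"`.
#' @export
kb_set_roots <- function(kb, ...) {
  roots <- c(...)
  for (id in roots) kb_entity(kb, id)
  kb$roots[names(roots)] <- roots
  invisible(kb)
}

#' Add an entity to a knowledge base
#'
#' @inheritParams kb_entity
#' @param e a `tox_entity` built with [entity()].
#' @return the entity id, invisibly. Errors on a duplicate id or a
#'   malformed CURIE.
#' @export
kb_add_entity <- function(kb, e) {
  stopifnot(inherits(kb, "tox_kb"), inherits(e, "tox_entity"))
  if (kb_has_entity(kb, e$id))
    stop("duplicate entity id: '", e$id, "'", call. = FALSE)
  kb$entities[[e$id]] <- e
  invisible(e$id)
}

# Effective category: the explicit field, else inferred from an is_a path
# to a declared category root.
kb_category <- function(kb, id) {
  e <- kb_entity(kb, id)
  if (e$category != "unassigned") return(e$category)
  anc <- kb_ancestors(kb, id, "is_a")
  for (cat in c("continuant", "occurrent")) {
    r <- kb$roots[cat]
    if (!is.na(r) && (identical(unname(r), id) || unname(r) %in% anc))
      return(cat)
  }
  "unassigned"
}

#' Add a typed relation triple
#'
#' Predicate domain/range constraints are enforced at insertion:
#' `has_result` connects occurrents only; `occurs_in` connects an occurrent
#' to a continuant (biological structure); `has_role` connects a continuant
#' to a role-kind continuant and its optional `context` (the process within
#' which the role holds) must be an occurrent; `has_participant` connects
#' an occurrent to a continuant. `part_of(a, b)` is stored canonically as
#' `has_part(b, a)`. An `is_a` edge that would create a cycle is rejected.
#' Entities whose category cannot (yet) be resolved are not constrained.
#'
#' Re-adding an identical triple is a no-op, so import is idempotent.
#'
#' @inheritParams kb_entity
#' @param subject,object entity ids; must exist in `kb`.
#' @param predicate one of `is_a`, `has_part`, `part_of`, `has_result`,
#'   `occurs_in`, `has_role`, `has_participant`.
#' @param context optional entity id scoping a `has_role` assertion.
#' @return the stored triple as a one-row data frame, invisibly.
#' @export
kb_add_relation <- function(kb, subject, predicate, object,
                            context = NA_character_) {
  stopifnot(inherits(kb, "tox_kb"))
  if (!predicate %in% PREDICATES)
    stop("unknown predicate: '", predicate, "'", call. = FALSE)
  for (id in c(subject, object)) {
    if (!kb_has_entity(kb, id))
      stop("unknown entity id: '", id, "'", call. = FALSE)
  }
  if (predicate == "part_of") {   # canonical storage: has_part
    tmp <- subject; subject <- object; object <- tmp
    predicate <- "has_part"
  }
  cs <- kb_category(kb, subject)
  co <- kb_category(kb, object)
  .need <- function(actual, wanted, endpoint, id) {
    if (actual != "unassigned" && actual != wanted)
      stop("typed-constraint violation: ", predicate, " requires ", wanted,
           " ", endpoint, " but '", id, "' is ", actual, call. = FALSE)
  }
  if (predicate == "has_result") {
    .need(cs, "occurrent", "subject", subject)
    .need(co, "occurrent", "object", object)
  } else if (predicate == "occurs_in") {
    .need(cs, "occurrent", "subject", subject)
    .need(co, "continuant", "object", object)
  } else if (predicate == "has_role") {
    .need(cs, "continuant", "subject", subject)
    .need(co, "continuant", "object", object)
    if (!"role" %in% kb_entity(kb, object)$kind)
      stop("typed-constraint violation: has_role object '", object,
           "' is not a role-kind entity", call. = FALSE)
    if (!is.na(context)) {
      if (!kb_has_entity(kb, context))
        stop("unknown entity id: '", context, "'", call. = FALSE)
      .need(kb_category(kb, context), "occurrent", "context", context)
    }
  } else if (predicate == "has_participant") {
    .need(cs, "occurrent", "subject", subject)
    .need(co, "continuant", "object", object)
  } else if (predicate == "is_a") {
    if (identical(subject, object) ||
        subject %in% kb_ancestors(kb, object, "is_a"))
      stop("is_a cycle: adding '", subject, "' is_a '", object,
           "' would close a loop", call. = FALSE)
  }
  row <- data.frame(subject = subject, predicate = predicate,
                    object = object, context = context,
                    stringsAsFactors = FALSE)
  rel <- kb$relations
  dup <- rel$subject == subject & rel$predicate == predicate &
    rel$object == object &
    (is.na(rel$context) & is.na(context) |
       (!is.na(rel$context) & !is.na(context) & rel$context == context))
  if (!any(dup)) kb$relations <- rbind(rel, row)
  invisible(row)
}

#' Relations of a knowledge base
#'
#' Returns the relation table. `part_of` is a view: canonical storage is
#' `has_part`, and requesting `part_of` returns the inverse triples.
#'
#' @inheritParams kb_entity
#' @param predicate optional predicate filter.
#' @return data frame with columns subject, predicate, object, context.
#' @export
kb_relations <- function(kb, predicate = NULL) {
  rel <- kb$relations
  if (is.null(predicate)) return(rel)
  if (!predicate %in% PREDICATES)
    stop("unknown predicate: '", predicate, "'", call. = FALSE)
  if (predicate == "part_of") {
    hp <- rel[rel$predicate == "has_part", , drop = FALSE]
    return(data.frame(subject = hp$object, predicate = "part_of",
                      object = hp$subject, context = hp$context,
                      stringsAsFactors = FALSE))
  }
  rel[rel$predicate == predicate, , drop = FALSE]
}

#' Transitive ancestors along a transitive predicate
#'
#' For `is_a` the ancestors are the (transitive) superclasses; for
#' `has_part` they are the transitive wholes, i.e. every entity that has
#' the query entity as a direct or indirect part. The entity itself is
#' excluded. Results are a set, returned in lexicographic id order.
#'
#' @inheritParams kb_entity
#' @param predicate `"is_a"` or `"has_part"` (the transitive predicates).
#' @return character vector of ancestor ids.
#' @export
kb_ancestors <- function(kb, id, predicate = "is_a") {
  if (!kb_has_entity(kb, id)) stop("unknown entity id: '", id, "'", call. = FALSE)
  if (!predicate %in% c("is_a", "has_part"))
    stop("unsupported predicate for ancestor query: '", predicate, "'",
         call. = FALSE)
  rel <- kb$relations[kb$relations$predicate == predicate, , drop = FALSE]
  if (predicate == "is_a") { from <- rel$subject; to <- rel$object }
  else { from <- rel$object; to <- rel$subject }   # upward = whole
  seen <- character()
  frontier <- id
  while (length(frontier)) {
    nxt <- setdiff(unique(to[from %in% frontier]), c(seen, id))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

#' @rdname kb_ancestors
#' @export
kb_descendants <- function(kb, id, predicate = "is_a") {
  if (!kb_has_entity(kb, id)) stop("unknown entity id: '", id, "'", call. = FALSE)
  if (!predicate %in% c("is_a", "has_part"))
    stop("unsupported predicate for descendant query: '", predicate, "'",
         call. = FALSE)
  rel <- kb$relations[kb$relations$predicate == predicate, , drop = FALSE]
  if (predicate == "is_a") { from <- rel$object; to <- rel$subject }
  else { from <- rel$subject; to <- rel$object }
  seen <- character()
  frontier <- id
  while (length(frontier)) {
    nxt <- setdiff(unique(to[from %in% frontier]), c(seen, id))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

kb_connected <- function(kb, id) {
  roots <- unname(kb$roots[c("continuant", "occurrent")])
  roots <- roots[!is.na(roots)]
  if (!length(roots)) return(FALSE)
  id %in% roots || any(roots %in% kb_ancestors(kb, id, "is_a"))
}

#' Classify the layer of an entity
#'
#' Layer provenance is an annotation stored on each entity at construction
#' time (the fixture builders and the RDF importer tag it). An entity
#' without a layer tag but connected to a category root by is-a falls back
#' to `"intermediate"`; a disconnected entity is `"unassigned"` and a
#' warning is recorded on the knowledge base.
#'
#' @inheritParams kb_entity
#' @return one of `"top"`, `"intermediate"`, `"lower"`, `"unassigned"`.
#' @export
kb_classify_layer <- function(kb, id) {
  e <- kb_entity(kb, id)
  if (e$layer != "unassigned") return(e$layer)
  if (kb_connected(kb, id)) return("intermediate")
  kb$warnings <- c(kb$warnings,
                   paste0("entity '", id, "' is not connected to a root; ",
                          "layer unassigned"))
  "unassigned"
}

#' Roles of a molecule within a process context
#'
#' Returns the role entities asserted with `has_role` whose context equals
#' `process_id`, plus context-free role assertions (which hold in any
#' process).
#'
#' @inheritParams kb_entity
#' @param molecule_id continuant (molecule) id.
#' @param process_id occurrent (process) id.
#' @return character vector of role entity ids (possibly empty), sorted.
#' @export
kb_roles_of <- function(kb, molecule_id, process_id) {
  kb_entity(kb, molecule_id); kb_entity(kb, process_id)
  rel <- kb$relations
  hit <- rel$predicate == "has_role" & rel$subject == molecule_id &
    (is.na(rel$context) | rel$context == process_id)
  sort(unique(rel$object[hit]))
}

#' Annotate a process with a pathological finding
#'
#' Findings attach to processes as annotations (not causal participants)
#' and are carried along in course graphs and route results.
#'
#' @inheritParams kb_entity
#' @param process occurrent id.
#' @param finding id of a finding-kind entity.
#' @export
kb_add_finding <- function(kb, process, finding) {
  kb_entity(kb, process); kb_entity(kb, finding)
  f <- kb$findings
  if (!any(f$process == process & f$finding == finding))
    kb$findings <- rbind(f, data.frame(process = process, finding = finding,
                                       stringsAsFactors = FALSE))
  invisible(kb)
}

#' Structural validation of a knowledge base
#'
#' Checks the class invariants: the is-a graph is acyclic, every entity
#' carrying both a process and a continuant kind is flagged, and every
#' lower-layer entity has an is-a path to a root.
#'
#' @inheritParams kb_entity
#' @return data frame of violations with columns `type` and `detail`
#'   (zero rows when valid).
#' @export
kb_validate <- function(kb) {
  out <- data.frame(type = character(), detail = character(),
                    stringsAsFactors = FALSE)
  isa <- kb$relations[kb$relations$predicate == "is_a", , drop = FALSE]
  if (nrow(isa)) {
    g <- igraph::graph_from_data_frame(isa[, c("subject", "object")],
                                       directed = TRUE)
    if (!igraph::is_dag(g))
      out <- rbind(out, data.frame(type = "cycle",
                                   detail = "is_a graph contains a cycle"))
  }
  for (id in names(kb$entities)) {
    e <- kb$entities[[id]]
    if (any(e$kind %in% .process_kinds) && any(e$kind %in% .continuant_kinds))
      out <- rbind(out, data.frame(
        type = "category",
        detail = paste0("entity '", id, "' has both continuant and occurrent kinds")))
    if (e$layer == "lower" && !kb_connected(kb, id))
      out <- rbind(out, data.frame(
        type = "disconnected",
        detail = paste0("lower-layer entity '", id, "' has no is_a path to a root")))
  }
  out
}
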