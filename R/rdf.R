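# RDF import/export (Turtle and RDF/XML), OBO PURL <-> CURIE mapping and
# knowledge-base statistics.
#
# No RDF triple-store binding is available to R here, so the Turtle side is
# a deliberately constrained codec: documents are written one triple per
# line with prefixed names and plain literals, and the reader accepts
# exactly that subset (plus comments and <full-IRI> terms). RDF/XML goes
# through xml2 using the striped rdf:Description syntax. Both dialects
# round-trip every knowledge base this package builds; unrecognized
# predicates are preserved verbatim in a side channel, never dropped.

OBO_BASE <- "http://purl.obolibrary.org/obo/"

.ns <- list(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl  = "http://www.w3.org/2002/07/owl#",
  obo  = OBO_BASE,
  txv  = "http://purl.obolibrary.org/obo/txpo/vocab#"
)

# predicate vocabulary: English relation labels -> IRIs. has_result has no
# OBO Relations Ontology counterpart, so it lives in the fallback vocab
# namespace together with the engine's annotation properties.
.pred_iri <- c(
  is_a            = paste0(.ns$rdfs, "subClassOf"),
  has_part        = paste0(.ns$obo, "BFO_0000051"),
  occurs_in       = paste0(.ns$obo, "BFO_0000066"),
  has_role        = paste0(.ns$obo, "RO_0000087"),
  has_participant = paste0(.ns$obo, "RO_0000057"),
  has_result      = paste0(.ns$txv, "has_result")
)
.iri_pred <- setNames(names(.pred_iri), unname(.pred_iri))

.ann_iri <- c(
  type       = paste0(.ns$rdf, "type"),
  label      = paste0(.ns$rdfs, "label"),
  definition = paste0(.ns$obo, "IAO_0000115"),
  layer      = paste0(.ns$txv, "layer"),
  category   = paste0(.ns$txv, "category"),
  kind       = paste0(.ns$txv, "kind"),
  xref       = paste0(.ns$txv, "xref"),
  root       = paste0(.ns$txv, "root"),
  has_finding = paste0(.ns$txv, "has_finding"),
  context    = paste0(.ns$txv, "context"),
  subject    = paste0(.ns$rdf, "subject"),
  predicate  = paste0(.ns$rdf, "predicate"),
  object     = paste0(.ns$rdf, "object"),
  Statement  = paste0(.ns$rdf, "Statement"),
  Substitution = paste0(.ns$txv, "Substitution"),
  subst_course = paste0(.ns$txv, "subst_course"),
  subst_source = paste0(.ns$txv, "subst_source"),
  subst_target = paste0(.ns$txv, "subst_target"),
  owl_class  = paste0(.ns$owl, "Class")
)

#' Map between CURIEs and OBO-style PURL IRIs
#'
#' `curie_to_iri("TXPO:0001964")` gives
#' `"http://purl.obolibrary.org/obo/TXPO_0001964"`; `iri_to_curie()` is its
#' inverse under the same base, so the round trip is the identity for every
#' id using the base. An IRI outside the base is passed through unchanged
#' and flagged with attribute `external = TRUE`.
#'
#' @param id a CURIE (`prefix:local`).
#' @param iri an IRI string.
#' @param base base IRI (default the OBO PURL base).
#' @return the mapped string.
#' @export
curie_to_iri <- function(id, base = OBO_BASE) {
  if (!grepl(CURIE_RE, id))
    stop("malformed CURIE: '", id, "'", call. = FALSE)
  paste0(base, sub(":", "_", id, fixed = TRUE))
}

#' @rdname curie_to_iri
#' @export
iri_to_curie <- function(iri, base = OBO_BASE) {
  if (!startsWith(iri, base)) {
    attr(iri, "external") <- TRUE
    return(iri)
  }
  local <- substring(iri, nchar(base) + 1L)
  m <- regexpr("^[A-Z][A-Z0-9]*_", local)
  if (m == -1L) {
    attr(iri, "external") <- TRUE
    return(iri)
  }
  prefix <- substring(local, 1L, attr(m, "match.length") - 1L)
  rest <- substring(local, attr(m, "match.length") + 1L)
  out <- paste0(prefix, ":", rest)
  if (!grepl(CURIE_RE, out)) {
    attr(iri, "external") <- TRUE
    return(iri)
  }
  out
}

# ---- triple assembly ------------------------------------------------------

# Flatten a kb into an ordered data frame of IRI triples
# (subject, predicate, object, literal). Ordering is fully deterministic so
# serialization is byte-stable.
kb_to_triples <- function(kb, base = OBO_BASE) {
  tr <- list()
  add <- function(s, p, o, lit = FALSE)
    tr[[length(tr) + 1L]] <<- list(s = s, p = p, o = o, lit = lit)
  ent_iri <- function(id) curie_to_iri(id, base)

  root_names <- sort(names(kb$roots))
  for (id in kb_entity_ids(kb)) {
    e <- kb$entities[[id]]
    s <- ent_iri(id)
    add(s, .ann_iri["type"], .ann_iri["owl_class"])
    add(s, .ann_iri["label"], e$label, lit = TRUE)
    if (e$layer != "unassigned") add(s, .ann_iri["layer"], e$layer, lit = TRUE)
    if (e$category != "unassigned")
      add(s, .ann_iri["category"], e$category, lit = TRUE)
    for (k in e$kind) add(s, .ann_iri["kind"], k, lit = TRUE)
    if (nzchar(e$definition))
      add(s, .ann_iri["definition"], e$definition, lit = TRUE)
    for (x in e$xrefs) add(s, .ann_iri["xref"], x, lit = TRUE)
    for (rn in root_names)
      if (identical(unname(kb$roots[rn]), id))
        add(s, .ann_iri["root"], rn, lit = TRUE)
  }

  rel <- kb$relations
  ord <- order(rel$predicate, rel$subject, rel$object,
               ifelse(is.na(rel$context), "", rel$context))
  rel <- rel[ord, , drop = FALSE]
  k <- 0L
  for (i in seq_len(nrow(rel))) {
    r <- rel[i, ]
    if (r$predicate == "has_role" && !is.na(r$context)) {
      k <- k + 1L
      stmt <- paste0(.ns$txv, "stmt_role_", k)
      add(stmt, .ann_iri["type"], .ann_iri["Statement"])
      add(stmt, .ann_iri["subject"], ent_iri(r$subject))
      add(stmt, .ann_iri["predicate"], .pred_iri["has_role"])
      add(stmt, .ann_iri["object"], ent_iri(r$object))
      add(stmt, .ann_iri["context"], ent_iri(r$context))
    } else {
      add(ent_iri(r$subject), unname(.pred_iri[r$predicate]), ent_iri(r$object))
    }
  }

  f <- kb$findings
  if (nrow(f)) {
    f <- f[order(f$process, f$finding), , drop = FALSE]
    for (i in seq_len(nrow(f)))
      add(ent_iri(f$process[i]), .ann_iri["has_finding"], ent_iri(f$finding[i]))
  }

  k <- 0L
  for (course in sort(names(kb$substitutions))) {
    sub <- kb$substitutions[[course]]
    for (src in sort(names(sub))) {
      k <- k + 1L
      stmt <- paste0(.ns$txv, "stmt_subst_", k)
      add(stmt, .ann_iri["type"], .ann_iri["Substitution"])
      add(stmt, .ann_iri["subst_course"], ent_iri(course))
      add(stmt, .ann_iri["subst_source"], ent_iri(src))
      add(stmt, .ann_iri["subst_target"], ent_iri(unname(sub[src])))
    }
  }

  ex <- kb$extra
  if (nrow(ex)) {
    ex <- ex[order(ex$subject, ex$predicate, ex$object), , drop = FALSE]
    for (i in seq_len(nrow(ex)))
      add(ex$subject[i], ex$predicate[i], ex$object[i], lit = ex$literal[i])
  }

  data.frame(subject = vapply(tr, `[[`, "", "s"),
             predicate = vapply(tr, `[[`, "", "p"),
             object = vapply(tr, `[[`, "", "o"),
             literal = vapply(tr, `[[`, TRUE, "lit"),
             stringsAsFactors = FALSE)
}

# Rebuild a kb from IRI triples. Violating triples are collected into the
# import report and the import continues.
triples_to_kb <- function(tr, base = OBO_BASE) {
  kb <- kb_new()
  report <- list(violations = character(), unknown_predicates = character(),
                 undeclared = character(),
                 membership_predicate = "has_part")
  cur <- function(iri) iri_to_curie(iri, base)

  is_class <- tr$predicate == .ann_iri["type"] & tr$object == .ann_iri["owl_class"]
  class_subjects <- unique(tr$subject[is_class])
  stmt_subjects <- unique(tr$subject[
    tr$predicate == .ann_iri["type"] &
      tr$object %in% c(.ann_iri["Statement"], .ann_iri["Substitution"])])

  ann_of <- function(s, p) tr$object[tr$subject == s & tr$predicate == p]
  for (s in sort(class_subjects)) {
    id <- cur(s)
    if (isTRUE(attr(id, "external"))) next
    lab <- ann_of(s, .ann_iri["label"])
    lay <- ann_of(s, .ann_iri["layer"])
    cat_ <- ann_of(s, .ann_iri["category"])
    kb_add_entity(kb, entity(
      id,
      label = if (length(lab)) lab[1] else id,
      layer = if (length(lay)) lay[1] else "unassigned",
      category = if (length(cat_)) cat_[1] else "unassigned",
      kind = ann_of(s, .ann_iri["kind"]),
      definition = paste(ann_of(s, .ann_iri["definition"]), collapse = " "),
      xrefs = ann_of(s, .ann_iri["xref"])))
    roots <- ann_of(s, .ann_iri["root"])
    if (length(roots)) kb$roots[roots] <- as.character(id)
  }

  ensure <- function(id) {
    if (!kb_has_entity(kb, id)) {
      report$undeclared <<- c(report$undeclared, id)
      kb_add_entity(kb, entity(id))
    }
    id
  }
  add_rel <- function(s, p, o, ctx = NA_character_) {
    tryCatch(kb_add_relation(kb, s, p, o, ctx),
             error = function(e) {
               report$violations <<- c(report$violations, conditionMessage(e))
               NULL
             })
  }

  handled_ann <- unname(.ann_iri[c("type", "label", "layer", "category",
                                   "kind", "definition", "xref", "root")])
  for (i in seq_len(nrow(tr))) {
    s <- tr$subject[i]; p <- tr$predicate[i]; o <- tr$object[i]
    if (s %in% stmt_subjects) next
    if (p %in% names(.iri_pred)) {
      cs <- cur(s); co <- cur(o)
      if (isTRUE(attr(cs, "external")) || isTRUE(attr(co, "external"))) {
        kb$extra <- rbind(kb$extra, data.frame(
          subject = s, predicate = p, object = o, literal = tr$literal[i],
          stringsAsFactors = FALSE))
        next
      }
      add_rel(ensure(as.character(cs)), .iri_pred[[p]], ensure(as.character(co)))
    } else if (p == .ann_iri["has_finding"]) {
      kb_add_finding(kb, ensure(as.character(cur(s))),
                     ensure(as.character(cur(o))))
    } else if (!(p %in% handled_ann)) {
      report$unknown_predicates <- union(report$unknown_predicates, p)
      kb$extra <- rbind(kb$extra, data.frame(
        subject = s, predicate = p, object = o, literal = tr$literal[i],
        stringsAsFactors = FALSE))
    }
  }

  # reified contextual role assertions and substitution records
  for (s in sort(stmt_subjects)) {
    types <- ann_of(s, .ann_iri["type"])
    if (.ann_iri["Statement"] %in% types) {
      subj <- cur(ann_of(s, .ann_iri["subject"])[1])
      obj <- cur(ann_of(s, .ann_iri["object"])[1])
      ctx <- cur(ann_of(s, .ann_iri["context"])[1])
      add_rel(ensure(as.character(subj)), "has_role",
              ensure(as.character(obj)), as.character(ctx))
    } else if (.ann_iri["Substitution"] %in% types) {
      course <- as.character(cur(ann_of(s, .ann_iri["subst_course"])[1]))
      src <- as.character(cur(ann_of(s, .ann_iri["subst_source"])[1]))
      tgt <- as.character(cur(ann_of(s, .ann_iri["subst_target"])[1]))
      sub <- kb$substitutions[[course]] %||% character()
      sub[src] <- tgt
      kb$substitutions[[course]] <- sub
    }
  }

  kb$import_report <- report
  kb
}

# ---- Turtle codec ---------------------------------------------------------

.ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}
.ttl_unescape <- function(x) {
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

.qname <- function(iri, prefixes) {
  for (p in names(prefixes)) {
    ns <- prefixes[[p]]
    if (startsWith(iri, ns)) {
      local <- substring(iri, nchar(ns) + 1L)
      if (grepl("^[A-Za-z0-9_.-]+$", local)) return(paste0(p, ":", local))
    }
  }
  paste0("<", iri, ">")
}

.term_order <- c("txv", "obo", "rdf", "rdfs", "owl")

serialize_turtle <- function(tr, base = OBO_BASE) {
  prefixes <- .ns[.term_order]
  lines <- vapply(names(prefixes), function(p)
    sprintf("@prefix %s: <%s> .", p, prefixes[[p]]), "")
  # longest namespaces first so txv wins over its obo prefix
  body <- vapply(seq_len(nrow(tr)), function(i) {
    o <- if (tr$literal[i]) paste0("\"", .ttl_escape(tr$object[i]), "\"")
    else .qname(tr$object[i], prefixes)
    sprintf("%s %s %s .", .qname(tr$subject[i], prefixes),
            .qname(tr$predicate[i], prefixes), o)
  }, "")
  paste0(paste(c(lines, "", body), collapse = "\n"), "\n")
}

parse_turtle <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  prefixes <- list()
  tr <- list()
  for (ln in lines) {
    if (grepl("^@prefix", ln)) {
      m <- regmatches(ln, regexec("^@prefix\\s+([A-Za-z][A-Za-z0-9_-]*):\\s+<([^>]*)>\\s*\\.$", ln))[[1]]
      if (length(m) != 3)
        stop("Turtle parse error in prefix declaration: ", ln, call. = FALSE)
      prefixes[[m[2]]] <- m[3]
      next
    }
    m <- regmatches(ln, regexec("^(<[^>]*>|[^\\s<\"]+)\\s+(<[^>]*>|[^\\s<\"]+)\\s+(.*\\S)\\s*\\.$", ln, perl = TRUE))[[1]]
    if (length(m) != 4)
      stop("Turtle parse error (unsupported syntax): ", ln, call. = FALSE)
    expand <- function(term) {
      if (startsWith(term, "<")) return(substring(term, 2L, nchar(term) - 1L))
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      if (length(parts) < 2 || is.null(prefixes[[parts[1]]]))
        stop("Turtle parse error: undeclared prefix in '", term, "'",
             call. = FALSE)
      paste0(prefixes[[parts[1]]], paste(parts[-1], collapse = ":"))
    }
    obj <- m[4]
    if (startsWith(obj, "\"")) {
      if (!grepl('^".*"$', obj))
        stop("Turtle parse error in literal: ", ln, call. = FALSE)
      tr[[length(tr) + 1L]] <- list(s = expand(m[2]), p = expand(m[3]),
                                    o = .ttl_unescape(substring(obj, 2L, nchar(obj) - 1L)),
                                    lit = TRUE)
    } else {
      tr[[length(tr) + 1L]] <- list(s = expand(m[2]), p = expand(m[3]),
                                    o = expand(obj), lit = FALSE)
    }
  }
  data.frame(subject = vapply(tr, `[[`, "", "s"),
             predicate = vapply(tr, `[[`, "", "p"),
             object = vapply(tr, `[[`, "", "o"),
             literal = vapply(tr, `[[`, TRUE, "lit"),
             stringsAsFactors = FALSE)
}

# ---- RDF/XML codec --------------------------------------------------------

serialize_rdfxml <- function(tr, base = OBO_BASE) {
  # collect namespaces (standard + any foreign predicate namespaces)
  prefixes <- .ns
  split_iri <- function(iri) {
    cut <- max(c(regexpr("#[^#/]*$", iri), regexpr("/[^#/]*$", iri)))
    if (cut < 1) return(NULL)
    c(ns = substring(iri, 1L, cut), local = substring(iri, cut + 1L))
  }
  extra_ns <- character()
  for (p in unique(tr$predicate)) {
    sp <- split_iri(p)
    if (is.null(sp) || sp["ns"] %in% unlist(prefixes)) next
    extra_ns <- union(extra_ns, unname(sp["ns"]))
  }
  if (length(extra_ns))
    for (i in seq_along(sort(extra_ns)))
      prefixes[[paste0("ns", i)]] <- sort(extra_ns)[i]

  pred_qname <- function(iri) {
    for (p in names(prefixes))
      if (startsWith(iri, prefixes[[p]]) &&
          grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", substring(iri, nchar(prefixes[[p]]) + 1L)))
        return(paste0(p, ":", substring(iri, nchar(prefixes[[p]]) + 1L)))
    stop("cannot express predicate as XML QName: ", iri, call. = FALSE)
  }

  attrs <- paste(sprintf('xmlns:%s="%s"', names(prefixes), unlist(prefixes)),
                 collapse = " ")
  doc <- xml2::read_xml(sprintf("<rdf:RDF %s></rdf:RDF>", attrs))
  for (s in unique(tr$subject)) {
    node <- xml2::xml_add_child(doc, "rdf:Description", "rdf:about" = s)
    rows <- which(tr$subject == s)
    for (i in rows) {
      child <- xml2::xml_add_child(node, pred_qname(tr$predicate[i]))
      if (tr$literal[i]) xml2::xml_set_text(child, tr$object[i])
      else xml2::xml_set_attr(child, "rdf:resource", tr$object[i])
    }
  }
  as.character(doc)
}

parse_rdfxml <- function(text) {
  doc <- xml2::read_xml(text)
  nsmap <- xml2::xml_ns(doc)
  expand_name <- function(node) {
    nm <- xml2::xml_name(node, nsmap)   # "prefix:local" or "local"
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2 && parts[1] %in% names(nsmap))
      paste0(nsmap[[parts[1]]], parts[2])
    else nm
  }
  get_attr <- function(node, name) {
    a <- xml2::xml_attr(node, name)
    if (is.na(a)) a <- xml2::xml_attr(node, paste0("rdf:", name))
    a
  }
  tr <- list()
  for (node in xml2::xml_children(doc)) {
    about <- get_attr(node, "about")
    if (is.na(about)) next
    nname <- expand_name(node)
    if (nname != paste0(.ns$rdf, "Description"))
      tr[[length(tr) + 1L]] <- list(s = about, p = .ann_iri[["type"]],
                                    o = nname, lit = FALSE)
    for (child in xml2::xml_children(node)) {
      p <- expand_name(child)
      res <- get_attr(child, "resource")
      if (!is.na(res))
        tr[[length(tr) + 1L]] <- list(s = about, p = p, o = res, lit = FALSE)
      else
        tr[[length(tr) + 1L]] <- list(s = about, p = p,
                                      o = xml2::xml_text(child), lit = TRUE)
    }
  }
  data.frame(subject = vapply(tr, `[[`, "", "s"),
             predicate = vapply(tr, `[[`, "", "p"),
             object = vapply(tr, `[[`, "", "o"),
             literal = vapply(tr, `[[`, TRUE, "lit"),
             stringsAsFactors = FALSE)
}

# ---- public surface -------------------------------------------------------

.guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("turtle", "rdfxml")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ttl", "turtle")) "turtle"
  else if (ext %in% c("owl", "rdf", "xml")) "rdfxml"
  else stop("cannot guess RDF dialect from extension: ", path, call. = FALSE)
}

#' Serialize a knowledge base to RDF
#'
#' Output is deterministic (stable triple ordering) for a fixed knowledge
#' base and dialect, and re-parses to an isomorphic knowledge base. An
#' invalid knowledge base is refused with the violation list.
#'
#' @inheritParams kb_entity
#' @param path optional output file; when `NULL` the document is returned
#'   as a character string.
#' @param format `"turtle"` or `"rdfxml"`; guessed from the file extension
#'   when `path` is given (.ttl vs .owl/.rdf/.xml).
#' @param base base IRI for CURIE expansion.
#' @return the serialized document as a single string (invisibly when
#'   written to `path`).
#' @export
write_rdf <- function(kb, path = NULL, format = NULL, base = OBO_BASE) {
  v <- kb_validate(kb)
  if (nrow(v))
    stop("refusing to serialize an invalid knowledge base:\n  ",
         paste(v$detail, collapse = "\n  "), call. = FALSE)
  format <- if (is.null(path) && is.null(format)) "turtle"
  else .guess_format(path %||% "", format)
  tr <- kb_to_triples(kb, base)
  out <- if (format == "turtle") serialize_turtle(tr, base)
  else serialize_rdfxml(tr, base)
  if (!is.null(path)) {
    writeLines(out, path, sep = "")
    return(invisible(out))
  }
  out
}

#' Parse an RDF document into a knowledge base
#'
#' Every recognized triple becomes an entity or a typed relation;
#' unrecognized predicates are retained verbatim in the `extra` side
#' channel and listed in the import report. Triples violating the typed
#' constraints are collected into the report's `violations` and the import
#' continues.
#'
#' @param source file path, or a character string containing the document
#'   (when `text = TRUE`).
#' @param format `"turtle"` or `"rdfxml"`; guessed from the extension when
#'   reading a file.
#' @param base base IRI for CURIE contraction.
#' @param text set `TRUE` when `source` is document text, not a path.
#' @return a `tox_kb`; the import report is available as
#'   `kb$import_report`.
#' @export
read_rdf <- function(source, format = NULL, base = OBO_BASE, text = FALSE) {
  if (!text) {
    if (!file.exists(source))
      stop("file not found: ", source, call. = FALSE)
    format <- .guess_format(source, format)
    source <- paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    format <- match.arg(format %||% "turtle", c("turtle", "rdfxml"))
  }
  tr <- if (format == "turtle") parse_turtle(source) else parse_rdfxml(source)
  triples_to_kb(tr, base)
}

#' Knowledge-base statistics
#'
#' Counts entities, toxic courses (is-a descendants of the toxic-course
#' root), processes (is-a descendants of the process root) and relations by
#' predicate. Counts are invariant under serialization round-trips.
#'
#' @inheritParams kb_entity
#' @return a list of class `tox_kb_stats` with elements `n_entities`,
#'   `n_toxic_courses`, `n_processes`, `n_relations_by_predicate`.
#' @export
kb_stats <- function(kb) {
  n_desc <- function(root_name) {
    r <- kb$roots[root_name]
    if (is.na(r)) return(0L)
    length(kb_descendants(kb, unname(r), "is_a"))
  }
  by_pred <- table(kb$relations$predicate)
  structure(list(
    n_entities = length(kb$entities),
    n_toxic_courses = n_desc("toxic_course"),
    n_processes = n_desc("process"),
    n_relations_by_predicate = setNames(as.integer(by_pred), names(by_pred))
  ), class = "tox_kb_stats")
}

#' @export
print.tox_kb_stats <- function(x, ...) {
  cat(sprintf("entities: %d  toxic courses: %d  processes: %d\n",
              x$n_entities, x$n_toxic_courses, x$n_processes))
  for (p in names(x$n_relations_by_predicate))
    cat(sprintf("  %-16s %d\n", p, x$n_relations_by_predicate[[p]]))
  invisible(x)
}

#' @rdname kb_stats
#' @export
kb_stats_json <- function(kb) {
  s <- kb_stats(kb)
  jsonlite::toJSON(list(
    n_entities = s$n_entities,
    n_toxic_courses = s$n_toxic_courses,
    n_processes = s$n_processes,
    n_relations_by_predicate = as.list(s$n_relations_by_predicate)),
    auto_unbox = TRUE)
}
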