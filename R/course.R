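# Toxic courses as causal graphs: materialization with parent-to-child
# process inheritance, term-substitution specialization, and validation.

slug_id <- function(label, prefix = "TXPOX") {
  s <- tolower(label)
  s <- gsub("[^a-z0-9]+", "_", s)
  s <- gsub("^_+|_+$", "", s)
  paste0(prefix, ":", s)
}

#' Materialize a toxic course as a causal graph
#'
#' The node set is the course's own processes (those related to the course
#' by `has_part`) unioned with every ancestor course's processes after the
#' course's substitution map has been applied; inheritance is computed at
#' materialization time, keeping the knowledge base normalized. The edge
#' set is every asserted `has_result` pair among the materialized nodes,
#' plus the substitution image of inherited edges. Edge direction follows
#' the causal arrow: `(cause, effect)`.
#'
#' Asserted `has_result` edges touching exactly one node of the course
#' (dangling references into other courses) are recorded as validation
#' warnings on the result (attribute `warnings`) and excluded from the
#' materialized edge set, which keeps every edge endpoint inside the node
#' set.
#'
#' @inheritParams kb_entity
#' @param course_id id of a toxic-course entity.
#' @return an object of class `tox_course_graph`: list with `course_id`,
#'   `nodes` (sorted ids), `edges` (data frame `from`,`to`),
#'   `inherited_from` (named character: node -> ancestor course id),
#'   `findings` (named list: node -> finding ids), `labels`.
#' @export
build_course_graph <- function(kb, course_id) {
  e <- kb_entity(kb, course_id)
  if (!"toxic_course" %in% e$kind)
    stop("not a toxic course: '", course_id, "'", call. = FALSE)
  rel <- kb$relations
  own <- sort(unique(rel$object[rel$predicate == "has_part" &
                                  rel$subject == course_id]))
  parents <- rel$object[rel$predicate == "is_a" & rel$subject == course_id]
  parents <- parents[vapply(parents, function(p)
    "toxic_course" %in% kb_entity(kb, p)$kind, logical(1))]
  sub <- kb$substitutions[[course_id]] %||% character()
  map1 <- function(x) ifelse(x %in% names(sub), unname(sub[x]), x)

  nodes <- own
  edges <- data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE)
  inherited <- character()

  for (p in sort(parents)) {
    pg <- build_course_graph(kb, p)
    pn <- map1(pg$nodes)
    origin <- ifelse(pg$nodes %in% names(pg$inherited_from),
                     unname(pg$inherited_from[pg$nodes]), p)
    for (i in seq_along(pn)) {
      if (!(pn[i] %in% own) && !(pn[i] %in% names(inherited)))
        inherited[pn[i]] <- origin[i]
    }
    nodes <- union(nodes, pn)
    if (nrow(pg$edges))
      edges <- rbind(edges, data.frame(from = map1(pg$edges$from),
                                       to = map1(pg$edges$to),
                                       stringsAsFactors = FALSE))
  }

  hr <- rel[rel$predicate == "has_result", , drop = FALSE]
  both <- hr$subject %in% nodes & hr$object %in% nodes
  dangling <- xor(hr$subject %in% nodes, hr$object %in% nodes)
  if (any(both))
    edges <- rbind(edges, data.frame(from = hr$subject[both],
                                     to = hr$object[both],
                                     stringsAsFactors = FALSE))
  edges <- unique(edges)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(nodes))

  findings <- lapply(setNames(nodes, nodes), function(n)
    sort(kb$findings$finding[kb$findings$process == n]))
  labels <- vapply(nodes, function(n) kb_entity(kb, n)$label, "")

  g <- structure(list(course_id = course_id, nodes = nodes, edges = edges,
                      inherited_from = inherited, findings = findings,
                      labels = labels),
                 class = "tox_course_graph")
  if (any(dangling))
    attr(g, "warnings") <- sprintf(
      "dangling has_result edge (%s -> %s) references a process outside course '%s'",
      hr$subject[dangling], hr$object[dangling], course_id)
  g
}

#' @export
print.tox_course_graph <- function(x, ...) {
  cat(sprintf("<tox_course_graph> %s: %d processes, %d causal edges (%d inherited nodes)\n",
              x$course_id, length(x$nodes), nrow(x$edges),
              length(x$inherited_from)))
  invisible(x)
}

#' Specialize a parent course into a child course
#'
#' Creates a child toxic course (`is_a` parent) whose materialized graph
#' contains every parent process with the substitution applied, plus the
#' added causal chain. The substitution is an explicit id-level mapping
#' (curator action), not free-text label surgery: each source is a process
#' id of the parent's graph; each target is either an existing entity id or
#' a new label, in which case a specialized entity is created (`is_a` its
#' source, lower layer). A target label equal to the label of an existing
#' unrelated process is a collision error. The parent course is unchanged.
#'
#' @inheritParams kb_entity
#' @param parent_course_id id of the parent toxic course.
#' @param child_label label for the new course; must be non-empty.
#' @param substitution named character vector, source process id ->
#'   target id or new label (e.g. phospholipid -> sphingomyelin terms).
#' @param added_chain list of `c(cause, effect)` pairs; elements are
#'   entity ids, existing labels, or new labels (created as lower-layer
#'   primitive processes).
#' @param child_id optional explicit CURIE for the new course (defaults to
#'   a `TXPOX` slug of the label).
#' @return the new course id, invisibly.
#' @export
specialize_course <- function(kb, parent_course_id, child_label,
                              substitution = character(),
                              added_chain = list(), child_id = NULL) {
  pe <- kb_entity(kb, parent_course_id)
  if (!"toxic_course" %in% pe$kind)
    stop("not a toxic course: '", parent_course_id, "'", call. = FALSE)
  if (!is.character(child_label) || length(child_label) != 1L ||
      !nzchar(trimws(child_label)))
    stop("child_label must be a non-empty string", call. = FALSE)

  parent_graph <- build_course_graph(kb, parent_course_id)

  resolve_target <- function(src, tgt) {
    if (grepl(CURIE_RE, tgt) && kb_has_entity(kb, tgt)) return(tgt)
    hits <- kb_find_label(kb, tgt)
    if (length(hits))
      stop("substitution target label '", tgt,
           "' collides with existing process ", hits[1], call. = FALSE)
    id <- slug_id(tgt)
    if (kb_has_entity(kb, id))
      stop("substitution target '", tgt, "' collides with existing id ", id,
           call. = FALSE)
    se <- kb_entity(kb, src)
    k <- intersect(se$kind, .process_kinds)
    if (!length(k)) k <- "primitive_process"
    kb_add_entity(kb, entity(id, label = tgt, category = "occurrent",
                             layer = "lower", kind = k))
    kb_add_relation(kb, id, "is_a", src)   # target specializes its source
    id
  }
  sub <- character()
  for (src in names(substitution)) {
    if (!src %in% parent_graph$nodes)
      stop("substitution source '", src, "' is not a process of course '",
           parent_course_id, "'", call. = FALSE)
    sub[src] <- resolve_target(src, unname(substitution[src]))
  }

  cid <- child_id %||% slug_id(child_label)
  kb_add_entity(kb, entity(cid, label = child_label, category = "occurrent",
                           layer = "lower", kind = "toxic_course"))
  kb_add_relation(kb, cid, "is_a", parent_course_id)
  if (length(sub)) kb$substitutions[[cid]] <- sub

  resolve_node <- function(x) {
    if (grepl(CURIE_RE, x) && kb_has_entity(kb, x)) return(x)
    hits <- kb_find_label(kb, x)
    if (length(hits) == 1L) return(hits)
    if (length(hits) > 1L)
      stop("ambiguous label '", x, "' matches: ",
           paste(hits, collapse = ", "), call. = FALSE)
    id <- slug_id(x)
    kb_add_entity(kb, entity(id, label = x, category = "occurrent",
                             layer = "lower", kind = "primitive_process"))
    proc_root <- kb$roots["process"]
    if (!is.na(proc_root)) kb_add_relation(kb, id, "is_a", unname(proc_root))
    id
  }
  for (pair in added_chain) {
    if (length(pair) != 2L)
      stop("added_chain entries must be (cause, effect) pairs", call. = FALSE)
    a <- resolve_node(pair[[1]]); b <- resolve_node(pair[[2]])
    kb_add_relation(kb, cid, "has_part", a)
    kb_add_relation(kb, cid, "has_part", b)
    kb_add_relation(kb, a, "has_result", b)
  }
  invisible(cid)
}

#' Validate a materialized course graph
#'
#' Reports causal cycles (errors unless `allow_cycles` -- toxic courses
#' are progressions, with an escape hatch for feedback loops), isolated
#' nodes (warnings) and, when the knowledge base is supplied, edges with
#' non-occurrent endpoints (errors).
#'
#' @param graph a `tox_course_graph`.
#' @param allow_cycles tolerate causal cycles.
#' @param kb optional `tox_kb` for endpoint category checks.
#' @return data frame of findings with columns `severity`
#'   (`"error"`/`"warning"`), `type`, `detail`; zero rows means valid.
#' @export
validate_course <- function(graph, allow_cycles = FALSE, kb = NULL) {
  stopifnot(inherits(graph, "tox_course_graph"))
  out <- data.frame(severity = character(), type = character(),
                    detail = character(), stringsAsFactors = FALSE)
  add <- function(severity, type, detail)
    out <<- rbind(out, data.frame(severity = severity, type = type,
                                  detail = detail, stringsAsFactors = FALSE))
  if (nrow(graph$edges)) {
    g <- igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                       vertices = graph$nodes)
    if (!igraph::is_dag(g) && !allow_cycles) {
      comp <- igraph::components(g, mode = "strong")
      cyc <- names(comp$membership)[comp$membership %in%
                                      which(comp$csize > 1)]
      loops <- igraph::which_loop(g)
      self <- unique(igraph::as_edgelist(g)[loops, 1])
      for (grp in sort(unique(comp$membership[cyc])))
        add("error", "cycle",
            paste0("causal cycle among: ",
                   paste(sort(names(comp$membership)[comp$membership == grp]),
                         collapse = " -> ")))
      for (s in self) add("error", "cycle", paste0("self-loop at ", s))
    }
    deg <- igraph::degree(g, mode = "all")
    iso <- names(deg)[deg == 0]
  } else {
    iso <- graph$nodes
  }
  for (n in sort(iso))
    add("warning", "isolated", paste0("process '", n,
                                      "' has no causal edges"))
  if (!is.null(kb)) {
    for (n in graph$nodes) {
      if (kb_has_entity(kb, n) && kb_category(kb, n) == "continuant")
        add("error", "category",
            paste0("course node '", n, "' is a continuant"))
    }
  }
  for (w in attr(graph, "warnings") %||% character())
    add("warning", "dangling", w)
  rownames(out) <- NULL
  out
}

#' Export a course graph as node-link JSON
#'
#' Produces `{"course", "nodes":[{"id","label","inherited_from",`
#' `"findings"}], "links":[{"source","target"}]}`, suitable for
#' force-directed rendering.
#'
#' @param graph a `tox_course_graph`.
#' @return a JSON string.
#' @export
course_graph_json <- function(graph) {
  nodes <- lapply(graph$nodes, function(n) list(
    id = n,
    label = unname(graph$labels[n]),
    inherited_from = if (n %in% names(graph$inherited_from))
      unname(graph$inherited_from[n]) else NULL,
    findings = as.list(graph$findings[[n]] %||% character())))
  links <- lapply(seq_len(nrow(graph$edges)), function(i)
    list(source = graph$edges$from[i], target = graph$edges$to[i]))
  jsonlite::toJSON(list(course = graph$course_id, nodes = nodes,
                        links = links),
                   auto_unbox = TRUE, null = "null")
}
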