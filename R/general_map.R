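# General course map: merge multiple course graphs, detect processes
# common to several courses, and group causes by is-a generalization.

#' Merge course graphs into a general course map
#'
#' The node set is the union of the input graphs' nodes; each node records
#' the courses it belongs to, and is flagged `common` when its membership
#' reaches the commonality threshold (default 2 courses). Edges likewise
#' record the courses asserting them. Matching is by process id or by
#' normalized label (for courses whose ids differ). The merge is
#' order-invariant: permuting the inputs yields an identical map.
#'
#' @param graphs list of `tox_course_graph` objects with distinct course
#'   ids.
#' @param match_mode `"by_id"` or `"by_label"`.
#' @param threshold minimum number of member courses for a node to count
#'   as common (default 2).
#' @return an object of class `tox_general_map`: list with `nodes` (data
#'   frame `key`,`label`,`common`,`n_courses` plus list columns
#'   `courses` and `ids`), `edges` (data frame `from`,`to` with list
#'   column `courses`), `match_mode`, `threshold`.
#' @export
merge_courses <- function(graphs, match_mode = c("by_id", "by_label"),
                          threshold = 2L) {
  match_mode <- match.arg(match_mode)
  stopifnot(length(graphs) >= 1L,
            all(vapply(graphs, inherits, TRUE, "tox_course_graph")))
  cids <- vapply(graphs, `[[`, "", "course_id")
  if (anyDuplicated(cids))
    stop("duplicate course ids in input: ",
         paste(unique(cids[duplicated(cids)]), collapse = ", "),
         call. = FALSE)
  key_fun <- function(g, ids) {
    if (match_mode == "by_id") ids else normalize_label(unname(g$labels[ids]))
  }

  node_courses <- list(); node_ids <- list(); node_label <- character()
  edge_courses <- list()
  for (g in graphs[order(cids)]) {
    keys <- key_fun(g, g$nodes)
    for (i in seq_along(g$nodes)) {
      k <- keys[i]
      node_courses[[k]] <- sort(union(node_courses[[k]], g$course_id))
      node_ids[[k]] <- sort(union(node_ids[[k]], g$nodes[i]))
      if (!k %in% names(node_label) || is.na(node_label[k]))
        node_label[k] <- unname(g$labels[g$nodes[i]])
    }
    if (nrow(g$edges)) {
      ek_from <- key_fun(g, g$edges$from); ek_to <- key_fun(g, g$edges$to)
      for (i in seq_len(nrow(g$edges))) {
        ek <- paste0(ek_from[i], "\r", ek_to[i])
        edge_courses[[ek]] <- sort(union(edge_courses[[ek]], g$course_id))
      }
    }
  }

  keys <- sort(names(node_courses))
  nodes <- data.frame(key = keys,
                      label = unname(node_label[keys]),
                      n_courses = vapply(node_courses[keys], length, 0L),
                      stringsAsFactors = FALSE)
  nodes$common <- nodes$n_courses >= threshold
  nodes$courses <- unname(node_courses[keys])
  nodes$ids <- unname(node_ids[keys])

  ekeys <- if (length(edge_courses)) sort(names(edge_courses)) else character()
  parts <- strsplit(ekeys, "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[`, "", 1),
                      to = vapply(parts, `[`, "", 2),
                      stringsAsFactors = FALSE)
  edges$courses <- unname(edge_courses[ekeys])

  structure(list(nodes = nodes, edges = edges, match_mode = match_mode,
                 threshold = as.integer(threshold)),
            class = "tox_general_map")
}

#' @export
print.tox_general_map <- function(x, ...) {
  cat(sprintf("<tox_general_map> %d processes (%d common at threshold %d), %d edges\n",
              nrow(x$nodes), sum(x$nodes$common), x$threshold, nrow(x$edges)))
  invisible(x)
}

.map_key <- function(map, node) {
  if (node %in% map$nodes$key) return(node)
  if (map$match_mode == "by_label") {
    k <- normalize_label(node)
    if (k %in% map$nodes$key) return(k)
  }
  # allow an entity id when the map is keyed by label
  hit <- which(vapply(map$nodes$ids, function(ids) node %in% ids, TRUE))
  if (length(hit)) return(map$nodes$key[hit[1]])
  stop("node '", node, "' is not in the general map", call. = FALSE)
}

# most specific informative common is-a ancestor of a set of entity ids;
# informative = proper ancestor whose layer is not "top" (the generality
# ceiling) and which is not a category root. NULL when none exists.
.lca_informative <- function(kb, ids, ceiling_layers = "top") {
  anc_sets <- lapply(ids, function(id) kb_ancestors(kb, id, "is_a"))
  common <- Reduce(intersect, anc_sets)
  common <- setdiff(common, unname(kb$roots))
  if (!length(common)) return(NULL)
  informative <- common[vapply(common, function(a)
    !(kb_entity(kb, a)$layer %in% ceiling_layers), TRUE)]
  if (!length(informative)) return(NULL)
  depth <- vapply(informative, function(a)
    length(kb_ancestors(kb, a, "is_a")), 0L)
  informative[order(-depth, informative)][1]
}

#' Group the causes of a map node by is-a generalization
#'
#' The causes of `target_node` are its upstream neighbours across the
#' merged courses. Causes are partitioned by their nearest shared is-a
#' ancestor in the ontology: groups are grown greedily by merging causes
#' whose common ancestor lies below the generality ceiling (by default,
#' anything in the domain-independent top layer is too general to group
#' by). Causes sharing no informative ancestor form singleton groups,
#' labelled by their own most specific informative ancestor (or
#' themselves).
#'
#' @inheritParams kb_entity
#' @param map a `tox_general_map` built from graphs over `kb`.
#' @param target_node a node key, label or member entity id in the map.
#' @param ceiling_layers layers considered too general to label a group
#'   (default `"top"`).
#' @return list of groups, each a list with `ancestor` (the labelling
#'   entity id), `label`, and `causes` (sorted member entity ids). Groups
#'   are sorted by ancestor id.
#' @export
generalize_causes <- function(kb, map, target_node,
                              ceiling_layers = "top") {
  stopifnot(inherits(map, "tox_general_map"))
  key <- .map_key(map, target_node)
  in_edges <- map$edges[map$edges$to == key, , drop = FALSE]
  cause_keys <- sort(unique(in_edges$from))
  # representative entity id per merged node: lexicographically first member
  rep_id <- vapply(cause_keys, function(k)
    map$nodes$ids[[match(k, map$nodes$key)]][1], "")
  if (!length(cause_keys)) return(list())

  members <- lapply(seq_along(cause_keys), function(i) i)
  repeat {
    merged <- FALSE
    for (i in seq_along(members)) {
      if (merged) break
      for (j in seq_along(members)) {
        if (j <= i) next
        cand <- c(members[[i]], members[[j]])
        if (!is.null(.lca_informative(kb, rep_id[cand], ceiling_layers))) {
          members[[i]] <- cand
          members[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }

  out <- lapply(members, function(idx) {
    ids <- sort(rep_id[idx])
    if (length(ids) > 1L) {
      anc <- .lca_informative(kb, ids, ceiling_layers)
    } else {
      anc <- .lca_informative(kb, c(ids, ids), ceiling_layers)
    }
    anc <- anc %||% ids[1]
    list(ancestor = unname(anc),
         label = kb_entity(kb, unname(anc))$label,
         causes = unname(ids))
  })
  out[order(vapply(out, `[[`, "", "ancestor"))]
}

#' Export a general course map as node-link JSON
#'
#' Nodes carry a `size` field proportional to the number of member
#' courses (rendering metadata for the "large common node" display).
#'
#' @param map a `tox_general_map`.
#' @return a JSON string.
#' @export
general_map_json <- function(map) {
  nodes <- lapply(seq_len(nrow(map$nodes)), function(i) list(
    id = map$nodes$key[i],
    label = map$nodes$label[i],
    courses = as.list(map$nodes$courses[[i]]),
    common = map$nodes$common[i],
    size = map$nodes$n_courses[i]))
  links <- lapply(seq_len(nrow(map$edges)), function(i) list(
    source = map$edges$from[i],
    target = map$edges$to[i],
    courses = as.list(map$edges$courses[[i]])))
  jsonlite::toJSON(list(nodes = nodes, links = links), auto_unbox = TRUE)
}
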