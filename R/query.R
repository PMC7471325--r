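# Route search over causal graphs, cross-course route comparison,
# functional decomposition trees and bottom-up dysfunction propagation.

.course_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = graph$nodes)
}

# label normalization for cross-course matching: case-fold, strip a
# trailing "[course]" bracket suffix, squeeze whitespace
normalize_label <- function(x) {
  x <- sub("\\s*\\[[^]]*\\]\\s*$", "", x)
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Upstream/downstream route search from a process
#'
#' `direction = "downstream"` returns every process reachable from the
#' origin along causal (`has_result`) edges -- the forward course of
#' toxicity; `"upstream"` returns every process with a directed path *to*
#' the origin -- the retrospective causes. Depths are shortest hop
#' distances from the origin (0 at the origin), optionally truncated at
#' `max_depth`. Findings annotations of the selected processes are carried
#' along.
#'
#' @param graph a `tox_course_graph`.
#' @param origin a process id in the graph.
#' @param direction `"upstream"` or `"downstream"`.
#' @param max_depth optional non-negative truncation depth (default
#'   unlimited).
#' @return an object of class `tox_route`: list with `origin`,
#'   `direction`, `nodes` (sorted), `edges` (induced edge set), `depth`
#'   (named integer) and `findings`.
#' @export
route <- function(graph, origin, direction = c("downstream", "upstream"),
                  max_depth = Inf) {
  stopifnot(inherits(graph, "tox_course_graph"))
  direction <- match.arg(direction)
  if (!origin %in% graph$nodes)
    stop("origin '", origin, "' is not a node of course '",
         graph$course_id, "'", call. = FALSE)
  if (max_depth < 0) stop("max_depth must be >= 0", call. = FALSE)
  g <- .course_igraph(graph)
  mode <- if (direction == "downstream") "out" else "in"
  dm <- igraph::distances(g, v = origin, mode = mode)
  d <- setNames(dm[1, ], colnames(dm))
  keep <- names(d)[is.finite(d) & d <= max_depth]
  depth <- setNames(as.integer(d[keep]), keep)
  nodes <- sort(keep)
  sub <- igraph::induced_subgraph(g, nodes)
  el <- igraph::as_edgelist(sub)
  edges <- data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(origin = origin, direction = direction, nodes = nodes,
                 edges = edges, depth = depth[nodes],
                 findings = graph$findings[nodes],
                 labels = graph$labels[nodes]),
            class = "tox_route")
}

#' @export
print.tox_route <- function(x, ...) {
  cat(sprintf("<tox_route> %s of %s: %d processes\n", x$direction, x$origin,
              length(x$nodes)))
  invisible(x)
}

#' Compare routes from a shared process across two courses
#'
#' Runs [route()] from the matched node in both graphs and partitions the
#' results into common, a-only and b-only processes -- e.g. comparing the
#' downstream consequences of one common finding between two toxic
#' courses. Matching defaults to id equality; `match_mode = "by_label"`
#' uses case-folded labels with the course bracket suffix stripped, for
#' courses whose process ids differ.
#'
#' @param graph_a,graph_b `tox_course_graph` objects.
#' @param shared_node a process id (or, under `by_label`, a label) present
#'   in both graphs.
#' @param direction `"upstream"` or `"downstream"`.
#' @param match_mode `"by_id"` or `"by_label"`.
#' @param max_depth optional truncation passed to [route()].
#' @return list with elements `common`, `a_only`, `b_only` (sorted match
#'   keys), and `route_a`, `route_b`.
#' @export
compare_routes <- function(graph_a, graph_b, shared_node,
                           direction = c("downstream", "upstream"),
                           match_mode = c("by_id", "by_label"),
                           max_depth = Inf) {
  direction <- match.arg(direction)
  match_mode <- match.arg(match_mode)
  key_of <- function(graph) {
    if (match_mode == "by_id") setNames(graph$nodes, graph$nodes)
    else setNames(normalize_label(unname(graph$labels[graph$nodes])),
                  graph$nodes)
  }
  resolve <- function(graph, which) {
    keys <- key_of(graph)
    target <- if (match_mode == "by_id") shared_node
    else normalize_label(shared_node)
    hit <- names(keys)[keys == target]
    if (!length(hit)) {
      # allow passing an id even under by_label
      if (shared_node %in% graph$nodes) return(shared_node)
      stop("node '", shared_node, "' is missing from graph ", which,
           " (course '", graph$course_id, "')", call. = FALSE)
    }
    hit[1]
  }
  ra <- route(graph_a, resolve(graph_a, "a"), direction, max_depth)
  rb <- route(graph_b, resolve(graph_b, "b"), direction, max_depth)
  ka <- unique(unname(key_of(graph_a)[ra$nodes]))
  kb_ <- unique(unname(key_of(graph_b)[rb$nodes]))
  list(common = sort(intersect(ka, kb_)),
       a_only = sort(setdiff(ka, kb_)),
       b_only = sort(setdiff(kb_, ka)),
       route_a = ra, route_b = rb)
}

#' Functional decomposition tree of a functioning process
#'
#' In the functional-decomposition view, the overall function of a system
#' (e.g. a cell keeping phospholipid levels in range) is achieved by
#' sub-functions performed by the system's parts (organelles), encoded as
#' `has_part` relations between processes; each sub-process is annotated
#' with the biological structure it `occurs_in`. Recursion bottoms out at
#' processes with no parts; a `has_part` cycle is an error naming the
#' loop.
#'
#' @inheritParams kb_entity
#' @param root_process id of the functioning process at the root.
#' @return an object of class `tox_decomposition`: nested list with
#'   `id`, `label`, `structure` (the `occurs_in` target or `NA`) and
#'   `children`.
#' @export
decomposition_tree <- function(kb, root_process) {
  kb_entity(kb, root_process)
  rel <- kb$relations
  build <- function(id, path) {
    if (id %in% path)
      stop("has_part cycle detected: ",
           paste(c(path[which(path == id):length(path)], id),
                 collapse = " -> "), call. = FALSE)
    parts <- sort(unique(rel$object[rel$predicate == "has_part" &
                                      rel$subject == id]))
    parts <- parts[vapply(parts, function(p)
      kb_category(kb, p) != "continuant", logical(1))]
    struct <- rel$object[rel$predicate == "occurs_in" & rel$subject == id]
    list(id = id,
         label = kb_entity(kb, id)$label,
         structure = if (length(struct)) sort(struct)[1] else NA_character_,
         children = lapply(parts, build, path = c(path, id)))
  }
  structure(build(root_process, character()), class = "tox_decomposition")
}

#' @export
print.tox_decomposition <- function(x, ...) {
  show <- function(node, indent) {
    cat(strrep("  ", indent), node$label,
        if (!is.na(node$structure)) paste0("  @", node$structure) else "",
        "\n", sep = "")
    for (ch in node$children) show(ch, indent + 1L)
  }
  show(x, 0L)
  invisible(x)
}

.tree_nodes <- function(tree) {
  out <- tree$id
  for (ch in tree$children) out <- c(out, .tree_nodes(ch))
  out
}

#' Bottom-up dysfunction propagation in a decomposition tree
#'
#' A dysfunction in one sub-process affects, from the bottom up, every
#' whole-function whose achievement depends on the failed part: the
#' ancestors of the failed node in the decomposition tree. Unrelated
#' branches are not affected; failing the root affects nothing above it.
#'
#' @param tree a `tox_decomposition`.
#' @param failed_node id of the failed process; must be in the tree.
#' @return sorted character vector of affected process ids.
#' @export
propagate_dysfunction <- function(tree, failed_node) {
  stopifnot(inherits(tree, "tox_decomposition"))
  path_to <- function(node, target, above) {
    if (identical(node$id, target)) return(above)
    for (ch in node$children) {
      r <- path_to(ch, target, c(above, node$id))
      if (!is.null(r)) return(r)
    }
    NULL
  }
  res <- path_to(tree, failed_node, character())
  if (is.null(res))
    stop("node '", failed_node, "' is not in the decomposition tree",
         call. = FALSE)
  sort(unique(res))
}

#' Export a route result as node-link JSON
#'
#' Produces `{"origin","direction","nodes":[{"id","depth","findings"}],`
#' `"links":[...]}`.
#'
#' @param r a `tox_route`.
#' @return a JSON string.
#' @export
route_json <- function(r) {
  nodes <- lapply(r$nodes, function(n) list(
    id = n, depth = unname(r$depth[n]),
    findings = as.list(r$findings[[n]] %||% character())))
  links <- lapply(seq_len(nrow(r$edges)), function(i)
    list(source = r$edges$from[i], target = r$edges$to[i]))
  jsonlite::toJSON(list(origin = r$origin, direction = r$direction,
                        nodes = nodes, links = links), auto_unbox = TRUE)
}
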