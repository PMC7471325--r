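# Independent oracles: deliberately naive implementations (fixpoint
# iteration, recursive DFS, exhaustive set intersection) that the engine's
# results are compared against. They never call the code paths they check.

# transitive closure by repeated relational join until no change
oracle_closure <- function(from, to, start) {
  anc <- character()
  repeat {
    step <- unique(to[from %in% c(start, anc)])
    new <- setdiff(step, c(anc, start))
    if (!length(new)) break
    anc <- c(anc, new)
  }
  sort(anc)
}

# reachability by plain recursive DFS over an edge list
oracle_reachable <- function(edges, origin, mode = c("out", "in")) {
  mode <- match.arg(mode)
  if (mode == "in") edges <- data.frame(from = edges$to, to = edges$from)
  seen <- new.env(parent = emptyenv())
  visit <- function(v) {
    if (!is.null(seen[[v]])) return(invisible())
    seen[[v]] <- TRUE
    for (w in edges$to[edges$from == v]) visit(w)
  }
  visit(origin)
  sort(ls(seen))
}

# exhaustive enumeration of all simple paths; returns nodes on any cycle
oracle_cycle_nodes <- function(nodes, edges) {
  on_cycle <- character()
  walk <- function(v, path) {
    for (w in edges$to[edges$from == v]) {
      if (w == path[1]) on_cycle <<- union(on_cycle, path)
      else if (!w %in% path) walk(w, c(path, w))
    }
  }
  for (n in nodes) walk(n, n)
  sort(on_cycle)
}

# build a random DAG edge list over node names (edges only i -> j, i < j)
random_dag <- function(n, p) {
  ids <- sprintf("N%02d", seq_len(n))
  from <- character(); to <- character()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (stats::runif(1) < p) {
          from <- c(from, ids[i]); to <- c(to, ids[j])
        }
      }
    }
  }
  list(nodes = ids, edges = data.frame(from = from, to = to,
                                       stringsAsFactors = FALSE))
}

# wrap a raw node/edge list as a course graph for route-search tests
mk_graph <- function(nodes, edges, course_id = "TXPOX:test_course") {
  structure(list(course_id = course_id, nodes = sort(nodes),
                 edges = edges,
                 inherited_from = character(),
                 findings = setNames(vector("list", length(nodes)), nodes),
                 labels = setNames(nodes, nodes)),
            class = "tox_course_graph")
}

# canonical forms for isomorphism checks after serialization round-trips
canon_relations <- function(kb) {
  r <- kb$relations
  r <- r[order(r$subject, r$predicate, r$object,
               ifelse(is.na(r$context), "", r$context)), ]
  rownames(r) <- NULL
  r
}
canon_subst <- function(kb) {
  if (!length(kb$substitutions)) return(list())
  s <- kb$substitutions[order(names(kb$substitutions))]
  lapply(s, function(m) m[order(names(m))])
}
canon_findings <- function(kb) {
  f <- kb$findings[order(kb$findings$process, kb$findings$finding), ]
  rownames(f) <- NULL
  f
}
expect_kb_isomorphic <- function(a, b) {
  expect_identical(kb_entity_ids(a), kb_entity_ids(b))
  for (id in kb_entity_ids(a))
    expect_identical(unclass(kb_entity(a, id)), unclass(kb_entity(b, id)))
  expect_identical(canon_relations(a), canon_relations(b))
  expect_identical(canon_subst(a), canon_subst(b))
  expect_identical(canon_findings(a), canon_findings(b))
  expect_identical(a$roots[order(names(a$roots))],
                   b$roots[order(names(b$roots))])
}
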