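# Course materialization, inheritance, specialization and validation.

test_that("the phospholipidosis graph contains the printed 5-node chain", {
  kb <- published_fixture()$kb
  g <- build_course_graph(kb, tx("phospholipidosis"))
  chain <- c(tx("compound_accumulation_in_lysosome"),
             tx("negative_regulation_of_phospholipid_degradation"),
             tx("hypofunction_of_phospholipid_degradation"),
             tx("phospholipid_metabolism_imbalance"),
             tx("phospholipid_accumulation_in_lysosome"))
  expect_true(all(chain %in% g$nodes))
  for (i in seq_len(length(chain) - 1))
    expect_true(any(g$edges$from == chain[i] & g$edges$to == chain[i + 1]))
  expect_error(build_course_graph(kb, tx("lysosome")), "not a toxic course")
})

test_that("a course with no parent and no processes is an empty graph", {
  kb <- kb_new()
  kb_add_entity(kb, entity("TXPOX:bare", "bare course",
                           kind = "toxic_course"))
  g <- build_course_graph(kb, "TXPOX:bare")
  expect_length(g$nodes, 0)
  expect_equal(nrow(g$edges), 0L)
})

test_that("inherited node sets equal a recursive-union oracle", {
  for (seed in c(9, 23, 31)) {
    built <- build_random_kb(seed, n_processes = 40, n_courses = 6,
                             edge_density = 0.2)
    kb <- built$kb
    rep_ <- built$report
    own <- rep_$course_processes
    parent <- rep_$course_parent
    oracle_nodes <- function(k) {       # naive recursion up the parent chain
      out <- own[[k]]
      if (!is.na(parent[k])) out <- union(out, oracle_nodes(parent[k]))
      sort(out)
    }
    for (k in seq_along(rep_$created_courses)) {
      cid <- sprintf("TXPOX:rc_%02d", k)
      expect_identical(build_course_graph(kb, cid)$nodes, oracle_nodes(k))
    }
  }
})

test_that("specialization yields the sphingomyelin chains with provenance", {
  kb <- published_fixture()$kb
  g <- build_course_graph(kb, tx("sphingomyelin_disorder"))
  chain <- c(tx("compound_accumulation_in_lysosome"),
             tx("negative_regulation_of_sphingomyelin_catabolic_process"),
             tx("hypofunction_of_sphingomyelin_degradation"),
             tx("sphingomyelin_metabolism_imbalance"),
             tx("sphingomyelin_accumulation_in_lysosome"))
  for (i in seq_len(length(chain) - 1))
    expect_true(any(g$edges$from == chain[i] & g$edges$to == chain[i + 1]))
  # course-specific ceramide additions
  expect_true(any(g$edges$from == tx("hypofunction_of_sphingomyelin_degradation") &
                    g$edges$to == tx("decreasing_ceramide")))
  expect_true(any(g$edges$from == tx("decreasing_ceramide") &
                    g$edges$to == tx("negative_regulation_of_apoptotic_process")))
  # inherited processes carry their origin course
  expect_equal(unname(g$inherited_from[tx("compound_accumulation_in_lysosome")]),
               tx("phospholipidosis"))
  # the parent graph does not see the substituted terms
  pg <- build_course_graph(kb, tx("phospholipidosis"))
  expect_false(tx("sphingomyelin_metabolism_imbalance") %in% pg$nodes)
})

test_that("inheritance invariant: substituted parent processes are kept", {
  kb <- published_fixture()$kb
  for (child in c(tx("sphingomyelin_disorder"), "TXPO:0001964",
                  "TXPO:0003369", "TXPO:0000949", "TXPO:0001468")) {
    g <- build_course_graph(kb, child)
    parent <- kb_relations(kb, "is_a")
    pid <- parent$object[parent$subject == child][1]
    pg <- build_course_graph(kb, pid)
    sub <- kb$substitutions[[child]]
    mapped <- ifelse(pg$nodes %in% names(sub), sub[pg$nodes], pg$nodes)
    expect_true(all(mapped %in% g$nodes), info = child)
  }
})

test_that("identity specialization copies the parent graph", {
  built <- build_published_kb()   # fresh: this test mutates the kb
  kb <- built$kb
  cid <- specialize_course(kb, tx("phospholipidosis"), "plain copy course")
  g <- build_course_graph(kb, cid)
  pg <- build_course_graph(kb, tx("phospholipidosis"))
  expect_identical(g$nodes, pg$nodes)
  expect_identical(g$edges, pg$edges)
  expect_setequal(unique(unname(g$inherited_from)), tx("phospholipidosis"))
})

test_that("injective substitution preserves edge counts plus additions", {
  set.seed(77)
  for (rep_i in 1:5) {
    built <- build_random_kb(100 + rep_i, n_processes = 15, n_courses = 1,
                             edge_density = 0.3)
    kb <- built$kb
    pg <- build_course_graph(kb, "TXPOX:rc_01")
    srcs <- sample(pg$nodes, min(4, length(pg$nodes)))
    sub <- setNames(paste0("specialized variant ", seq_along(srcs)), srcs)
    cid <- specialize_course(kb, "TXPOX:rc_01", paste0("child ", rep_i),
                             substitution = sub,
                             added_chain = list(c("extra cause A", "extra effect B")),
                             child_id = sprintf("TXPOX:child_%d", rep_i))
    cg <- build_course_graph(kb, cid)
    expect_equal(nrow(cg$edges), nrow(pg$edges) + 1L)
    expect_equal(length(cg$nodes), length(pg$nodes) + 2L)
  }
})

test_that("specialization rejects collisions and empty labels", {
  kb <- build_published_kb()$kb
  expect_error(
    specialize_course(kb, tx("phospholipidosis"), "bad",
                      substitution = c("TXPOX:phospholipid_metabolism_imbalance" =
                                         "lipid accumulation")),
    "collides")
  expect_error(specialize_course(kb, tx("phospholipidosis"), "  "),
               "non-empty")
  expect_error(specialize_course(kb, tx("lysosome"), "x"),
               "not a toxic course")
})

test_that("course validation flags cycles and isolated nodes", {
  kb <- published_fixture()$kb
  for (cid in published_fixture()$report$created_courses) {
    v <- validate_course(build_course_graph(kb, cid), kb = kb)
    expect_equal(sum(v$severity == "error"), 0L, info = cid)
  }
  g <- mk_graph(c("A", "B"), data.frame(from = c("A", "B"), to = c("B", "A")))
  v <- validate_course(g)
  expect_equal(sum(v$type == "cycle"), 1L)
  expect_equal(nrow(validate_course(g, allow_cycles = TRUE)), 0L)
})

test_that("cycle reporting matches an exhaustive path-search oracle", {
  set.seed(13)
  for (rep_i in 1:10) {
    d <- random_dag(10, 0.25)
    expect_equal(sum(validate_course(mk_graph(d$nodes, d$edges))$type == "cycle"),
                 0L)
    # plant a back edge to close a cycle (when any edge exists)
    if (nrow(d$edges)) {
      e <- d$edges[sample(nrow(d$edges), 1), ]
      planted <- rbind(d$edges, data.frame(from = e$to, to = e$from))
      v <- validate_course(mk_graph(d$nodes, planted))
      cyc_oracle <- oracle_cycle_nodes(d$nodes, planted)
      expect_gt(length(cyc_oracle), 0)
      expect_equal(sum(v$type == "cycle") > 0, TRUE)
      reported <- sort(unique(unlist(
        strsplit(gsub("causal cycle among: |self-loop at ", "",
                      v$detail[v$type == "cycle"]), " -> "))))
      expect_true(all(reported %in% cyc_oracle))
    }
  }
})

test_that("materialization is pure: repeated calls are identical", {
  kb <- published_fixture()$kb
  g1 <- build_course_graph(kb, tx("sphingomyelin_disorder"))
  g2 <- build_course_graph(kb, tx("sphingomyelin_disorder"))
  expect_identical(g1, g2)
})

test_that("course JSON export carries nodes, links and provenance", {
  kb <- published_fixture()$kb
  j <- jsonlite::fromJSON(
    course_graph_json(build_course_graph(kb, tx("sphingomyelin_disorder"))),
    simplifyVector = FALSE)
  expect_equal(j$course, tx("sphingomyelin_disorder"))
  ids <- vapply(j$nodes, `[[`, "", "id")
  expect_true(tx("sphingomyelin_accumulation_in_lysosome") %in% ids)
  inh <- j$nodes[[which(ids == tx("compound_accumulation_in_lysosome"))]]
  expect_equal(inh$inherited_from, tx("phospholipidosis"))
})
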