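# Route search, route comparison, decomposition trees, dysfunction
# propagation.

test_that("retrospective route from vacuolation reaches the drug regulation", {
  kb <- published_fixture()$kb
  g <- build_course_graph(kb, tx("phospholipidosis"))
  up <- route(g, tx("lipid_vacuolation"), "upstream")
  expect_true(tx("negative_regulation_of_phospholipid_degradation") %in%
                up$nodes)
  expect_true(tx("phospholipid_metabolism_imbalance") %in% up$nodes)
  expect_equal(unname(up$depth[up$origin]), 0L)
  expect_error(route(g, "TXPOX:nope", "upstream"), "not a node")
})

test_that("a source node has only itself upstream", {
  kb <- published_fixture()$kb
  g <- build_course_graph(kb, tx("phospholipidosis"))
  up <- route(g, tx("compound_accumulation_in_lysosome"), "upstream")
  expect_identical(up$nodes, tx("compound_accumulation_in_lysosome"))
})

test_that("max_depth truncates at hop distance", {
  kb <- published_fixture()$kb
  g <- build_course_graph(kb, tx("phospholipidosis"))
  r <- route(g, tx("compound_accumulation_in_lysosome"), "downstream",
             max_depth = 2)
  expect_true(all(r$depth <= 2))
  expect_length(r$nodes, 3)
})

test_that("route equals the exhaustive DFS reachability oracle", {
  set.seed(101)
  for (rep_i in 1:60) {
    d <- random_dag(sample(50, 1), runif(1, 0.02, 0.3))
    g <- mk_graph(d$nodes, d$edges)
    origin <- sample(d$nodes, 1)
    expect_identical(route(g, origin, "downstream")$nodes,
                     oracle_reachable(d$edges, origin, "out"))
    expect_identical(route(g, origin, "upstream")$nodes,
                     oracle_reachable(d$edges, origin, "in"))
  }
})

test_that("upstream equals downstream on the edge-reversed graph", {
  set.seed(55)
  for (rep_i in 1:20) {
    d <- random_dag(30, 0.12)
    g <- mk_graph(d$nodes, d$edges)
    rg <- mk_graph(d$nodes, data.frame(from = d$edges$to, to = d$edges$from))
    origin <- sample(d$nodes, 1)
    a <- route(g, origin, "upstream")
    b <- route(rg, origin, "downstream")
    expect_identical(a$nodes, b$nodes)
    expect_identical(a$depth, b$depth)
  }
})

test_that("depths satisfy the triangle property on traversed edges", {
  set.seed(56)
  d <- random_dag(40, 0.15)
  g <- mk_graph(d$nodes, d$edges)
  r <- route(g, d$nodes[1], "downstream")
  for (i in seq_len(nrow(r$edges)))
    expect_lte(r$depth[r$edges$to[i]], r$depth[r$edges$from[i]] + 1)
})

test_that("route comparison separates course-specific findings", {
  kb <- published_fixture()$kb
  nash <- build_course_graph(kb, tx("nash_fragment"))
  pl <- build_course_graph(kb, tx("phospholipidosis"))
  cmp <- compare_routes(nash, pl, tx("increasing_hepatocyte_volume"),
                        "downstream")
  expect_true(tx("ballooning") %in% cmp$a_only)
  expect_true(tx("myelin_figure_in_lysosome") %in% cmp$b_only)
  expect_true(tx("increasing_hepatocyte_volume") %in% cmp$common)
  # the same works matching on normalized labels
  cmp2 <- compare_routes(nash, pl, "Increasing Hepatocyte Volume",
                         "downstream", match_mode = "by_label")
  expect_true("ballooning" %in% cmp2$a_only)
  expect_error(compare_routes(nash, pl, tx("bile_acid_accumulation"),
                              "downstream"),
               "missing from graph a")
})

test_that("comparing a graph with itself leaves no asymmetric nodes", {
  kb <- published_fixture()$kb
  g <- build_course_graph(kb, tx("phospholipidosis"))
  cmp <- compare_routes(g, g, tx("lipid_vacuolation"), "upstream")
  expect_length(cmp$a_only, 0)
  expect_length(cmp$b_only, 0)
  expect_identical(cmp$common, cmp$route_a$nodes)
})

test_that("route comparison is symmetric up to swapping sides", {
  set.seed(60)
  d1 <- random_dag(20, 0.2); d2 <- random_dag(20, 0.2)
  shared <- d1$nodes[1]
  g1 <- mk_graph(d1$nodes, d1$edges, "TXPOX:c1")
  g2 <- mk_graph(d2$nodes, d2$edges, "TXPOX:c2")
  ab <- compare_routes(g1, g2, shared, "downstream")
  ba <- compare_routes(g2, g1, shared, "downstream")
  expect_identical(ab$a_only, ba$b_only)
  expect_identical(ab$b_only, ba$a_only)
  expect_identical(ab$common, ba$common)
  # common set equals the oracle intersection of reachability sets
  expect_identical(ab$common,
                   sort(intersect(oracle_reachable(d1$edges, shared, "out"),
                                  oracle_reachable(d2$edges, shared, "out"))))
})

test_that("the decomposition of decreasing phospholipid spans the organelles", {
  kb <- published_fixture()$kb
  tree <- decomposition_tree(kb, tx("decreasing_phospholipid"))
  got <- setNames(vapply(tree$children, `[[`, "", "structure"),
                  vapply(tree$children, `[[`, "", "id"))
  expect_equal(unname(got[tx("phospholipid_catabolic_process")]), tx("lysosome"))
  expect_equal(unname(got[tx("phospholipid_transport_from_lysosome_into_cytosol")]),
               tx("lysosome"))
  expect_equal(unname(got[tx("lysosomal_enzyme_transport")]), tx("late_endosome"))
  expect_equal(unname(got[tx("phospholipase_gene_expression")]), tx("nucleus"))
})

test_that("a leaf process decomposes to a bare root", {
  kb <- published_fixture()$kb
  tree <- decomposition_tree(kb, tx("phospholipase_gene_expression"))
  expect_length(tree$children, 0)
  expect_equal(tree$id, tx("phospholipase_gene_expression"))
})

test_that("random part-forests have the leaf count the generator recorded", {
  set.seed(71)
  for (rep_i in 1:5) {
    kb <- kb_new()
    n <- sample(10:25, 1)
    ids <- sprintf("TXPOX:t%02d", seq_len(n))
    for (id in ids) kb_add_entity(kb, entity(id, kind = "primitive_process"))
    parent <- c(NA, vapply(2:n, function(i) sample(i - 1, 1), 0L))
    for (i in 2:n) kb_add_relation(kb, ids[parent[i]], "has_part", ids[i])
    n_leaves <- sum(!(seq_len(n) %in% parent))
    count_leaves <- function(node)
      if (!length(node$children)) 1L
      else sum(vapply(node$children, count_leaves, 0L))
    tree <- decomposition_tree(kb, ids[1])
    expect_equal(count_leaves(tree), n_leaves)
  }
})

test_that("has_part cycles in decomposition are reported with the loop", {
  kb <- kb_new()
  for (id in c("TXPOX:a", "TXPOX:b")) kb_add_entity(kb, entity(id, kind = "primitive_process"))
  kb_add_relation(kb, "TXPOX:a", "has_part", "TXPOX:b")
  kb_add_relation(kb, "TXPOX:b", "has_part", "TXPOX:a")
  expect_error(decomposition_tree(kb, "TXPOX:a"), "cycle.*TXPOX:a")
})

test_that("dysfunction propagates bottom-up to the whole functions only", {
  kb <- published_fixture()$kb
  tree <- decomposition_tree(kb, tx("decreasing_phospholipid"))
  expect_identical(propagate_dysfunction(tree, tx("phospholipase_gene_expression")),
                   tx("decreasing_phospholipid"))
  expect_identical(propagate_dysfunction(tree, tx("decreasing_phospholipid")),
                   character(0))
  expect_error(propagate_dysfunction(tree, "TXPOX:nope"), "not in the")
})

test_that("propagation equals the parent-pointer walk oracle", {
  set.seed(81)
  kb <- kb_new()
  n <- 20
  ids <- sprintf("TXPOX:w%02d", seq_len(n))
  for (id in ids) kb_add_entity(kb, entity(id, kind = "primitive_process"))
  parent <- c(NA, vapply(2:n, function(i) sample(i - 1, 1), 0L))
  for (i in 2:n) kb_add_relation(kb, ids[parent[i]], "has_part", ids[i])
  tree <- decomposition_tree(kb, ids[1])
  for (probe in sample(2:n, 8)) {
    walk <- integer(); at <- probe
    while (!is.na(parent[at])) { at <- parent[at]; walk <- c(walk, at) }
    expect_identical(propagate_dysfunction(tree, ids[probe]),
                     sort(ids[walk]))
  }
})

test_that("route JSON carries depths and findings annotations", {
  kb <- published_fixture()$kb
  g <- build_course_graph(kb, tx("phospholipidosis"))
  j <- jsonlite::fromJSON(route_json(route(
    g, tx("phospholipid_accumulation_in_lysosome"), "downstream")),
    simplifyVector = FALSE)
  ids <- vapply(j$nodes, `[[`, "", "id")
  self <- j$nodes[[which(ids == tx("phospholipid_accumulation_in_lysosome"))]]
  expect_equal(self$depth, 0L)
  expect_true(tx("myelin_figure_in_lysosome") %in% unlist(self$findings))
})
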