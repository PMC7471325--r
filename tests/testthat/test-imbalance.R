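# Qualitative demand-supply imbalance model.

test_that("level shifts are ordinal with clamping", {
  expect_equal(names(shift_level("medium", 1)), "high")
  expect_equal(names(shift_level("very_high", 3)), "very_high")
  expect_equal(names(shift_level("very_low", -2)), "very_low")
  expect_error(fl_level("extreme"), "unknown level")
  # random (level, steps) against a plain integer-clamp oracle
  set.seed(21)
  for (i in 1:200) {
    lv <- sample(0:4, 1); st <- sample(-6:6, 1)
    expect_equal(unname(unclass(shift_level(fl_level(lv), st))),
                 max(0L, min(4L, lv + st)))
  }
})

test_that("level resolution reflects homeostasis, caps and adaptation", {
  # no modifiers: medium demand met at medium (homeostasis)
  lv <- resolve_levels(scenario("TXPOX:d", "TXPOX:s"))
  expect_equal(names(lv$effective_demand), "medium")
  expect_equal(names(lv$effective_supply), "medium")
  # supply adapts upward to meet raised demand when uncapped
  lv <- resolve_levels(scenario("TXPOX:d", "TXPOX:s", modifiers = list(
    modifier("demand", "raise", 1))))
  expect_equal(names(lv$effective_supply), "high")
  # a cap at medium holds supply below raised demand
  lv <- resolve_levels(scenario("TXPOX:d", "TXPOX:s", modifiers = list(
    modifier("supply_cap", "cap", level = "medium"),
    modifier("demand", "raise", 1))))
  expect_equal(names(lv$effective_demand), "high")
  expect_equal(names(lv$effective_supply), "medium")
  # a gene-defect cap at very low dominates (caps min-combine)
  lv <- resolve_levels(scenario("TXPOX:d", "TXPOX:s", modifiers = list(
    modifier("supply_cap", "cap", level = "very_low"),
    modifier("supply_cap", "cap", level = "medium"))))
  expect_equal(names(lv$effective_supply), "very_low")
})

test_that("the four published scenarios evaluate to their printed states", {
  kb <- published_fixture()$kb
  a <- evaluate_imbalance(published_scenario(kb, "latent"))
  expect_equal(a$state, "balanced_latent")
  expect_length(a$outcomes, 0)
  expect_equal(a$reserve, 0L)

  b <- evaluate_imbalance(published_scenario(kb, "moderate"))
  expect_equal(b$state, "imbalanced_demand")
  expect_identical(b$outcomes, tx("phospholipid_accumulation_in_lysosome"))

  c_ <- evaluate_imbalance(published_scenario(kb, "obese"))
  expect_equal(c_$state, "imbalanced_demand")
  expect_identical(c_$outcomes, tx("phospholipid_accumulation_in_lysosome"))

  d0 <- evaluate_imbalance(published_scenario(kb, "niemann_pick"))
  d1 <- evaluate_imbalance(published_scenario(kb, "niemann_pick", with_cad = TRUE))
  expect_equal(d0$state, "imbalanced_demand")
  expect_identical(d0$outcomes, tx("sphingomyelin_accumulation_in_lysosome"))
  expect_equal(d0$state, d1$state)
  expect_identical(d0$outcomes, d1$outcomes)
})

test_that("a forced very-high defence above demand is itself damaging", {
  sc <- scenario("TXPOX:d", "TXPOX:s", outcome_process = "TXPOX:o",
                 damage_process = "TXPOX:fibrosis",
                 modifiers = list(modifier("supply_cap", "raise",
                                           magnitude = 2)))
  a <- evaluate_imbalance(sc)
  expect_equal(a$state, "imbalanced_supply")
  expect_identical(a$outcomes, "TXPOX:fibrosis")
  # one step above demand is ordinary adaptation headroom, not damage
  sc2 <- scenario("TXPOX:d", "TXPOX:s", outcome_process = "TXPOX:o",
                  baseline_demand = "high",
                  modifiers = list(modifier("supply_cap", "raise",
                                            magnitude = 2)))
  expect_equal(evaluate_imbalance(sc2)$state, "balanced")
})

test_that("an imbalanced scenario without an outcome is a config error", {
  sc <- scenario("TXPOX:d", "TXPOX:s", modifiers = list(
    modifier("supply_cap", "cap", level = "very_low")))
  expect_error(evaluate_imbalance(sc), "no outcome_process")
})

test_that("raising demand never restores balance (monotonicity)", {
  set.seed(31)
  for (i in 1:100) {
    mods <- list()
    if (runif(1) < 0.7)
      mods <- c(mods, list(modifier("supply_cap", "cap",
                                    level = fl_level(sample(0:4, 1)))))
    raise0 <- sample(0:2, 1)
    base <- scenario("TXPOX:d", "TXPOX:s", outcome_process = "TXPOX:o",
                     baseline_demand = fl_level(sample(0:4, 1)),
                     modifiers = mods)
    raised <- base
    raised$modifiers <- c(raised$modifiers,
                          list(modifier("demand", "raise", sample(1:3, 1))))
    s0 <- evaluate_imbalance(base)$state
    s1 <- evaluate_imbalance(raised)$state
    if (s0 == "imbalanced_demand") expect_equal(s1, "imbalanced_demand")
  }
})

test_that("lowering the supply cap never increases the reserve", {
  set.seed(32)
  for (i in 1:50) {
    base <- scenario("TXPOX:d", "TXPOX:s", outcome_process = "TXPOX:o",
                     baseline_demand = fl_level(sample(0:4, 1)))
    capped <- base
    capped$modifiers <- list(modifier("supply_cap", "cap",
                                      level = fl_level(sample(0:4, 1))))
    expect_lte(evaluate_imbalance(capped)$reserve,
               evaluate_imbalance(base)$reserve)
  }
})

test_that("no modifiers is the homeostasis fixed point, deterministically", {
  sc <- scenario("TXPOX:d", "TXPOX:s", outcome_process = "TXPOX:o")
  a1 <- evaluate_imbalance(sc)
  a2 <- evaluate_imbalance(sc)
  expect_equal(a1$state, "balanced")
  expect_length(a1$outcomes, 0)
  expect_identical(a1, a2)
})

test_that("scenarios bind to course processes and reject outsiders", {
  kb <- published_fixture()$kb
  sc <- scenario_from_course(kb, tx("phospholipidosis"), list(
    demand = tx("increasing_phospholipid"),
    supply = tx("decreasing_phospholipid"),
    outcome = tx("phospholipid_accumulation_in_lysosome")))
  expect_s3_class(sc, "tox_scenario")
  expect_error(
    scenario_from_course(kb, tx("phospholipidosis"), list(
      demand = tx("bile_acid_accumulation"),
      supply = tx("decreasing_phospholipid"),
      outcome = tx("phospholipid_accumulation_in_lysosome"))),
    "outside course")
  expect_error(
    scenario_from_course(kb, tx("cholestasis_fragment"), list(
      demand = tx("bile_acid_accumulation"),
      supply = tx("increasing_hepatocyte_volume"),
      outcome = tx("increasing_hepatocyte_volume"),
      modifiers = list(modifier("supply_cap", "cap", level = "medium",
                                cause_process = tx("ballooning"))))),
    "outside course")
})

test_that("scenarios round-trip through YAML and JSON files", {
  kb <- published_fixture()$kb
  sc <- published_scenario(kb, "moderate")
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("scenario.", ext))
    write_scenario(sc, path)
    sc2 <- read_scenario(path)
    expect_identical(evaluate_imbalance(sc), evaluate_imbalance(sc2))
    expect_identical(sc2$demand_process, sc$demand_process)
    expect_length(sc2$modifiers, length(sc$modifiers))
    unlink(path)
  }
})
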