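# Deterministic fixtures: the published course fragments (phospholipidosis
# family, NASH, cholestasis, ground glass appearance) and random knowledge
# bases for property tests. All worked-example tests run on these fixtures;
# nothing is downloaded.

# minimal upper-level scaffold shared by both builders
.kb_scaffold <- function(kb, add) {
  add(entity("TXPOX:continuant", "continuant", "continuant", "top"))
  add(entity("TXPOX:occurrent", "occurrent", "occurrent", "top"))
  add(entity("TXPOX:object", "object", "continuant", "top", "object"))
  add(entity("TXPOX:role", "role", "continuant", "top", "role"))
  add(entity("TXPOX:quality", "quality", "continuant", "top", "quality"))
  add(entity("TXPOX:process", "process", "occurrent", "top"))
  add(entity("TXPOX:primitive_process", "primitive process", "occurrent",
             "top", "primitive_process"))
  add(entity("TXPOX:process_sequence", "process sequence", "occurrent",
             "top", "process_sequence"))
  add(entity("TXPOX:toxic_course", "toxic course", "occurrent", "lower",
             "toxic_course"))
  kb_set_roots(kb, continuant = "TXPOX:continuant",
               occurrent = "TXPOX:occurrent",
               process = "TXPOX:process",
               toxic_course = "TXPOX:toxic_course")
  isa <- function(a, b) kb_add_relation(kb, a, "is_a", b)
  isa("TXPOX:object", "TXPOX:continuant")
  isa("TXPOX:role", "TXPOX:continuant")
  isa("TXPOX:quality", "TXPOX:continuant")
  isa("TXPOX:process", "TXPOX:occurrent")
  isa("TXPOX:primitive_process", "TXPOX:process")
  isa("TXPOX:process_sequence", "TXPOX:process")
  isa("TXPOX:toxic_course", "TXPOX:process_sequence")
  invisible(kb)
}

#' Build the published-course knowledge base
#'
#' Constructs, deterministically and offline, the knowledge base encoding
#' the printed course fragments: the functioning-process is-a hierarchy
#' (receiving / making existence / generating, with sifting, transmitting,
#' separating, decomposing, splitting, detaching, and the meta-functioning
#' controlling branch); the functional decomposition of "decreasing
#' phospholipid" over the cell's organelles; the phospholipidosis causal
#' chain and its specialization into sphingomyelin disorder (phospholipid
#' to sphingomyelin substitution plus the ceramide chain); the latent,
#' moderate, obese and Niemann-Pick course variants under their published
#' PURL-style ids; NASH, cholestasis and ground-glass fragments; and role
#' assignments for amiodarone, PLA2G15, desipramine/imipramine and ASAH1.
#'
#' Only explicitly printed processes are encoded; the fixtures are
#' fragments, not complete representations of the released courses.
#' Fixture entities use the reserved `TXPOX` prefix except the four course
#' variants whose PURL ids are printed.
#'
#' @return list with elements `kb` (a `tox_kb`) and `report` (a
#'   `FixtureReport`-style list: `created_entities`, `created_courses`,
#'   `created_relations_by_predicate`, `seed`).
#' @export
build_published_kb <- function() {
  kb <- kb_new()
  add <- function(e) kb_add_entity(kb, e)
  rel <- function(s, p, o, ctx = NA_character_) kb_add_relation(kb, s, p, o, ctx)
  px <- function(x) paste0("TXPOX:", x)
  .kb_scaffold(kb, add)

  # -- functioning-process hierarchy (top layer, functional-ontology terms)
  fp <- function(local, label, parent, layer = "top",
                 kind = "functioning_process") {
    add(entity(px(local), label, "occurrent", layer, kind))
    rel(px(local), "is_a", parent)
    px(local)
  }
  fproot <- fp("functioning_process", "functioning process", "TXPOX:process")
  fp("receiving", "receiving", fproot)
  mex <- fp("making_existence", "making existence", fproot)
  cop <- fp("changing_an_operand", "changing an operand", mex)
  crel <- fp("changing_relationship_between_operands",
             "changing relationship between operands", mex)
  sift <- fp("sifting", "sifting", crel)
  trans <- fp("transmitting", "transmitting", sift)
  sep <- fp("separating", "separating", crel)
  dec <- fp("decomposing", "decomposing", sep)
  spl <- fp("splitting", "splitting", sep)
  det <- fp("detaching", "detaching", sep)
  fp("generating", "generating", fproot)
  mfp <- fp("meta_functioning_process", "meta-functioning process",
            "TXPOX:process", kind = "meta_functioning_process")
  ctrl <- fp("controlling", "controlling", mfp,
             kind = "meta_functioning_process")
  regapo <- fp("regulation_of_apoptosis", "regulation of apoptosis", ctrl,
               layer = "intermediate", kind = "meta_functioning_process")
  fp("cell_cycle_control", "cell cycle control", ctrl,
     layer = "intermediate", kind = "meta_functioning_process")

  # -- intermediate biomedical processes
  ip <- function(local, label, parent, kind = "primitive_process",
                 layer = "intermediate", xrefs = character()) {
    add(entity(px(local), label, "occurrent", layer, kind, xrefs = xrefs))
    rel(px(local), "is_a", parent)
    px(local)
  }
  biotrans <- ip("biological_transport", "biological transport", trans)
  lipt <- ip("lipid_transport", "lipid transport", biotrans)
  plt <- ip("phospholipid_transport", "phospholipid transport", lipt,
            xrefs = "GO:0015914")
  biodeg <- ip("biochemical_degradation", "biochemical degradation", dec)
  pldeg <- ip("phospholipid_degradation", "phospholipid degradation", biodeg)
  plcat <- ip("phospholipid_catabolic_process",
              "phospholipid catabolic process", biodeg)
  ip("cell_division", "cell division", spl)
  ip("complex_dissociation", "complex dissociation", det)
  accum <- ip("accumulation_of_intracellular_substances",
              "accumulation of intracellular substances", cop)
  orgup <- ip("increase_in_number_of_organelles",
              "increase in number of organelles", cop)
  imbal <- ip("homeostasis_imbalance", "homeostasis imbalance",
              "TXPOX:process")
  inflam <- ip("inflammatory_response", "inflammatory response",
               "TXPOX:process")

  # -- biological structures
  add(entity(px("biological_structure"), "biological structure",
             "continuant", "intermediate", "biological_structure"))
  rel(px("biological_structure"), "is_a", "TXPOX:object")
  st <- function(local, label) {
    add(entity(px(local), label, "continuant", "intermediate",
               "biological_structure"))
    rel(px(local), "is_a", px("biological_structure"))
    px(local)
  }
  cell <- st("cell", "cell")
  lys <- st("lysosome", "lysosome")
  lysmem <- st("lysosomal_membrane", "lysosomal membrane")
  lend <- st("late_endosome", "late endosome")
  nuc <- st("nucleus", "nucleus")
  ser <- st("smooth_endoplasmic_reticulum", "smooth endoplasmic reticulum")
  st("liver", "liver")
  add(entity(px("hepatocyte"), "hepatocyte", "continuant", "intermediate",
             "biological_structure"))
  rel(px("hepatocyte"), "is_a", cell)
  rel(lys, "has_part", lysmem)
  for (p in c(lys, lend, nuc, ser)) rel(cell, "has_part", p)
  rel(px("liver"), "has_part", px("hepatocyte"))

  # -- molecules and roles
  add(entity(px("molecule"), "molecule", "continuant", "intermediate",
             "molecule"))
  rel(px("molecule"), "is_a", "TXPOX:object")
  mol <- function(local, label, parent = px("molecule")) {
    add(entity(px(local), label, "continuant", "intermediate", "molecule"))
    rel(px(local), "is_a", parent)
    px(local)
  }
  amio <- mol("amiodarone", "amiodarone")
  desi <- mol("desipramine", "desipramine")
  imip <- mol("imipramine", "imipramine")
  pl <- mol("phospholipid", "phospholipid")
  mol("sphingomyelin", "sphingomyelin", parent = pl)
  mol("ceramide", "ceramide")
  mol("bile_acid", "bile acid")
  mol("fatty_acid", "fatty acid")
  pla2 <- mol("PLA2G15", "PLA2G15")
  asah1 <- mol("ASAH1", "ASAH1")
  rol <- function(local, label) {
    add(entity(px(local), label, "continuant", "intermediate", "role"))
    rel(px(local), "is_a", "TXPOX:role")
    px(local)
  }
  cad_role <- rol("cationic_amphiphilic_drug", "cationic amphiphilic drug")
  cip <- rol("competitive_inhibitor_of_phospholipase",
             "competitive inhibitor of phospholipase")
  mri <- rol("mitochondrial_respiratory_chain_inhibitor",
             "mitochondrial respiratory-chain inhibitor")
  pri <- rol("positive_regulator_of_immune_response",
             "positive regulator of immune response")
  fiasma <- rol("functional_inhibitor_of_acid_sphingomyelinase",
                "functional inhibitor of acid sphingomyelinase")

  # -- toxicology-specific (lower layer) processes
  lp <- function(local, label, parent, kind = "primitive_process") {
    add(entity(px(local), label, "occurrent", "lower", kind))
    rel(px(local), "is_a", parent)
    px(local)
  }
  cmp_acc <- lp("compound_accumulation_in_lysosome",
                "compound accumulation in lysosome", accum)
  cad_acc <- lp("cad_accumulation_in_lysosome",
                "CAD accumulation in lysosome", cmp_acc)
  negreg <- lp("negative_regulation_of_phospholipid_degradation",
               "negative regulation of phospholipid degradation", ctrl)
  hypo <- lp("hypofunction_of_phospholipid_degradation",
             "hypofunction of phospholipid degradation", pldeg)
  plimb <- lp("phospholipid_metabolism_imbalance",
              "phospholipid metabolism imbalance", imbal)
  placc <- lp("phospholipid_accumulation_in_lysosome",
              "phospholipid accumulation in lysosome", accum)
  vol <- lp("increasing_hepatocyte_volume", "increasing hepatocyte volume",
            cop)
  incpl <- lp("increasing_phospholipid", "increasing phospholipid", cop)
  decpl <- ip("decreasing_phospholipid", "decreasing phospholipid", cop,
              kind = "functioning_process")
  posreg <- lp("positive_regulation_of_phospholipid_biosynthetic_process",
               "positive regulation of phospholipid biosynthetic process",
               ctrl)
  inflow <- lp("increase_in_fatty_acid_inflow_into_hepatocyte",
               "increase in fatty acid inflow into hepatocyte", biotrans)
  negretc <- lp("negative_regulation_of_respiratory_electron_transport_chain",
                "negative regulation of the respiratory electron transport chain",
                ctrl)
  negapo <- lp("negative_regulation_of_apoptotic_process",
               "negative regulation of apoptotic process", regapo)
  deccer <- lp("decreasing_ceramide", "decreasing ceramide", cop)
  hypocer <- lp("hypofunction_of_ceramide_degradation",
                "hypofunction of ceramide degradation", biodeg)
  mut <- lp("sphingomyelinase_gene_mutation", "sphingomyelinase gene mutation",
            "TXPOX:process")
  dyssph <- lp("dysfunction_of_sphingomyelin_degradation",
               "dysfunction of sphingomyelin degradation", biodeg)
  dysfat <- lp("dysfunction_of_fatty_acid_degradation",
               "dysfunction of fatty acid degradation", biodeg)
  lipacc <- lp("lipid_accumulation", "lipid accumulation", accum)
  bileacc <- lp("bile_acid_accumulation", "bile acid accumulation", accum)
  serp <- lp("smooth_endoplasmic_reticulum_proliferation",
             "smooth endoplasmic reticulum proliferation", orgup)
  # findings printed inside the causal chains
  vac <- lp("lipid_vacuolation", "lipid vacuolation", "TXPOX:process",
            kind = c("primitive_process", "finding"))
  ball <- lp("ballooning", "ballooning", "TXPOX:process",
             kind = c("primitive_process", "finding"))
  myel <- lp("myelin_figure_in_lysosome", "myelin figure in lysosome",
             "TXPOX:process", kind = c("primitive_process", "finding"))
  magg <- lp("macrophage_aggregation", "macrophage aggregation",
             "TXPOX:process", kind = c("primitive_process", "finding"))

  # -- functional decomposition of "decreasing phospholipid" (cell system)
  pltl <- lp("phospholipid_transport_from_lysosome_into_cytosol",
             "phospholipid transport from lysosome into cytosol [Phospholipidosis]",
             plt)
  lyst <- ip("lysosomal_enzyme_transport", "lysosomal enzyme transport",
             biotrans)
  plge <- ip("phospholipase_gene_expression", "phospholipase gene expression",
             px("generating"))
  rel(decpl, "occurs_in", cell)
  for (part in c(plcat, pltl, lyst, plge)) rel(decpl, "has_part", part)
  rel(plcat, "occurs_in", lys)
  rel(pltl, "occurs_in", lys)
  rel(lyst, "occurs_in", lend)
  rel(plge, "occurs_in", nuc)

  # -- localization and participation
  rel(cmp_acc, "occurs_in", lys)
  rel(cad_acc, "occurs_in", lys)
  rel(placc, "occurs_in", lys)
  rel(negreg, "has_participant", amio)
  rel(hypocer, "has_participant", asah1)

  # -- context-dependent roles
  rel(amio, "has_role", cad_role, negreg)
  rel(amio, "has_role", cip, negreg)
  rel(amio, "has_role", mri, negretc)
  rel(pla2, "has_role", pri, inflam)
  rel(desi, "has_role", fiasma, dyssph)
  rel(imip, "has_role", fiasma, dyssph)

  # -- phospholipidosis course and its causal chain
  plosis <- px("phospholipidosis")
  add(entity(plosis, "phospholipidosis", "occurrent", "lower",
             "toxic_course"))
  rel(plosis, "is_a", "TXPOX:toxic_course")
  members <- c(cmp_acc, negreg, hypo, plimb, placc, vac, vol, myel,
               incpl, decpl)
  for (m in members) rel(plosis, "has_part", m)
  chain <- function(...) {
    ids <- c(...)
    for (i in seq_len(length(ids) - 1L))
      rel(ids[i], "has_result", ids[i + 1L])
  }
  chain(cmp_acc, negreg, hypo, plimb, placc)
  rel(placc, "has_result", vac)
  rel(placc, "has_result", vol)
  rel(vol, "has_result", myel)

  # -- sphingomyelin disorder: phospholipid -> sphingomyelin specialization
  sphd <- specialize_course(
    kb, plosis, "sphingomyelin disorder",
    substitution = c(
      "TXPOX:negative_regulation_of_phospholipid_degradation" =
        "negative regulation of sphingomyelin catabolic process",
      "TXPOX:hypofunction_of_phospholipid_degradation" =
        "hypofunction of sphingomyelin degradation",
      "TXPOX:phospholipid_metabolism_imbalance" =
        "sphingomyelin metabolism imbalance",
      "TXPOX:phospholipid_accumulation_in_lysosome" =
        "sphingomyelin accumulation in lysosome",
      "TXPOX:increasing_phospholipid" = "increasing sphingomyelin",
      "TXPOX:decreasing_phospholipid" = "decreasing sphingomyelin"),
    added_chain = list(
      c("hypofunction of sphingomyelin degradation", "decreasing ceramide"),
      c("decreasing ceramide", "negative regulation of apoptotic process"),
      c("decreasing ceramide", "hypofunction of ceramide degradation")),
    child_id = px("sphingomyelin_disorder"))
  sphacc <- px("sphingomyelin_accumulation_in_lysosome")

  # -- imbalance course variants (published PURL ids)
  latent <- specialize_course(kb, plosis, "phospholipidosis (latent)",
                              child_id = "TXPO:0001964")
  moderate <- specialize_course(
    kb, plosis, "phospholipidosis (moderate)",
    added_chain = list(c(posreg, incpl)),
    child_id = "TXPO:0003369")
  obese <- specialize_course(
    kb, plosis, "phospholipidosis via obese",
    added_chain = list(c(inflow, posreg), c(posreg, incpl)),
    child_id = "TXPO:0000949")
  np <- specialize_course(
    kb, sphd, "course of Niemann-Pick disease type A",
    added_chain = list(c(mut, dyssph), c(dyssph, sphacc)),
    child_id = "TXPO:0001468")

  # -- NASH, cholestasis and ground-glass fragments
  course <- function(local, label, members) {
    id <- px(local)
    add(entity(id, label, "occurrent", "lower", "toxic_course"))
    rel(id, "is_a", "TXPOX:toxic_course")
    for (m in members) rel(id, "has_part", m)
    id
  }
  nash <- course("nash_fragment", "NASH fragment",
                 c(dysfat, lipacc, vac, vol, ball))
  chain(dysfat, lipacc, vac)
  rel(lipacc, "has_result", vol)
  rel(vol, "has_result", ball)
  chole <- course("cholestasis_fragment", "cholestasis fragment",
                  c(bileacc, vol))
  rel(bileacc, "has_result", vol)
  gga <- course("ground_glass_fragment", "ground glass appearance fragment",
                c(serp, vol))
  rel(serp, "has_result", vol)

  # -- finding annotations (electron-microscopy observations)
  kb_add_finding(kb, placc, myel)
  kb_add_finding(kb, sphacc, myel)
  kb_add_finding(kb, sphacc, magg)

  report <- list(
    created_entities = kb_size(kb),
    created_courses = sort(c(plosis, sphd, latent, moderate, obese, np,
                             nash, chole, gga)),
    created_relations_by_predicate =
      setNames(as.integer(table(kb$relations$predicate)),
               names(table(kb$relations$predicate))),
    seed = NA_integer_)
  list(kb = kb, report = report)
}

#' Canned imbalance scenarios for the published course variants
#'
#' Builds the demand-supply scenario printed for each course variant:
#' \describe{
#'   \item{latent}{a cationic amphiphilic drug caps phospholipid
#'     degradation at medium while demand stays at medium: balance holds
#'     but the adaptation reserve is exhausted.}
#'   \item{moderate}{the same cap plus a demand raise through positive
#'     regulation of phospholipid biosynthesis: demand exceeds supply and
#'     phospholipid accumulation manifests.}
#'   \item{obese}{the demand raise is caused by increased fatty-acid
#'     inflow into hepatocytes (obesity).}
#'   \item{niemann_pick}{a sphingomyelinase gene mutation caps the
#'     defence at very low, so the imbalance occurs with or without a
#'     drug modifier (`with_cad` toggles one).}
#' }
#'
#' @param kb the knowledge base from [build_published_kb()].
#' @param which scenario name.
#' @param with_cad for `niemann_pick`: also include the drug capping
#'   modifier (the assessment does not depend on it).
#' @return a `tox_scenario`.
#' @export
published_scenario <- function(kb, which = c("latent", "moderate", "obese",
                                         "niemann_pick"),
                           with_cad = FALSE) {
  which <- match.arg(which)
  px <- function(x) paste0("TXPOX:", x)
  cad_cap <- modifier("supply_cap", "cap", level = "medium",
                      cause_process = px("negative_regulation_of_phospholipid_degradation"))
  demand_raise <- function(cause)
    modifier("demand", "raise", magnitude = 1L, cause_process = cause)
  pl_bindings <- function(mods) list(
    demand = px("increasing_phospholipid"),
    supply = px("decreasing_phospholipid"),
    outcome = px("phospholipid_accumulation_in_lysosome"),
    modifiers = mods)
  switch(which,
    latent = scenario_from_course(kb, "TXPO:0001964",
                                  pl_bindings(list(cad_cap))),
    moderate = scenario_from_course(
      kb, "TXPO:0003369",
      pl_bindings(list(cad_cap, demand_raise(
        px("positive_regulation_of_phospholipid_biosynthetic_process"))))),
    obese = scenario_from_course(
      kb, "TXPO:0000949",
      pl_bindings(list(cad_cap, demand_raise(
        px("increase_in_fatty_acid_inflow_into_hepatocyte"))))),
    niemann_pick = {
      mods <- list(modifier("supply_cap", "cap", level = "very_low",
                            cause_process = px("dysfunction_of_sphingomyelin_degradation")))
      if (with_cad)
        mods <- c(mods, list(modifier(
          "supply_cap", "cap", level = "medium",
          cause_process = px("negative_regulation_of_sphingomyelin_catabolic_process"))))
      scenario_from_course(kb, "TXPO:0001468", list(
        demand = px("increasing_sphingomyelin"),
        supply = px("decreasing_sphingomyelin"),
        outcome = px("sphingomyelin_accumulation_in_lysosome"),
        modifiers = mods))
    })
}

#' Build a random knowledge base for property testing
#'
#' Generates a random DAG of causal (`has_result`) edges over processes
#' partitioned into toxic courses with a random course hierarchy. Edges
#' run only forward along a global topological order and only within a
#' course, so every course graph is acyclic by construction. Reproducible
#' from the seed; the RNG state of the caller is left untouched. The
#' report carries the builder's own construction tallies as ground truth.
#'
#' @param seed integer seed.
#' @param n_processes number of processes (>= 1).
#' @param n_courses number of courses (>= 1, <= `n_processes`).
#' @param edge_density probability in (0, 1] of each forward within-course
#'   edge.
#' @return list with elements `kb` and `report` (includes
#'   `course_processes`, the per-course own process sets).
#' @export
build_random_kb <- function(seed, n_processes = 30L, n_courses = 3L,
                            edge_density = 0.15) {
  n_processes <- as.integer(n_processes); n_courses <- as.integer(n_courses)
  if (n_processes < 1L || n_courses < 1L || n_courses > n_processes)
    stop("infeasible sizes: need 1 <= n_courses <= n_processes",
         call. = FALSE)
  if (!(edge_density > 0 && edge_density <= 1))
    stop("edge_density must be in (0, 1]", call. = FALSE)

  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)

  kb <- kb_new()
  tally <- new.env(parent = emptyenv())
  tally$entities <- 0L
  tally$rel <- c(is_a = 0L, has_part = 0L, has_result = 0L)
  add <- function(e) { tally$entities <- tally$entities + 1L; kb_add_entity(kb, e) }
  rel <- function(s, p, o) {
    tally$rel[p] <- tally$rel[p] + 1L
    kb_add_relation(kb, s, p, o)
  }
  .kb_scaffold(kb, add)
  tally$rel["is_a"] <- tally$rel["is_a"] + 7L   # scaffold is_a edges

  pid <- sprintf("TXPOX:rp_%03d", seq_len(n_processes))
  for (i in seq_len(n_processes)) {
    add(entity(pid[i], sprintf("random process %d", i), "occurrent",
               "lower", "primitive_process"))
    rel(pid[i], "is_a", "TXPOX:process")
  }
  # course assignment: each course gets at least one process
  course_of <- c(seq_len(n_courses),
                 if (n_processes > n_courses)
                   sample(n_courses, n_processes - n_courses, replace = TRUE))
  cid <- sprintf("TXPOX:rc_%02d", seq_len(n_courses))
  parent_of <- rep(NA_integer_, n_courses)
  for (k in seq_len(n_courses)) {
    add(entity(cid[k], sprintf("random course %d", k), "occurrent", "lower",
               "toxic_course"))
    if (k > 1L && stats::runif(1) < 0.5) {
      parent_of[k] <- sample(k - 1L, 1L)
      rel(cid[k], "is_a", cid[parent_of[k]])
    } else {
      rel(cid[k], "is_a", "TXPOX:toxic_course")
    }
  }
  for (i in seq_len(n_processes)) rel(cid[course_of[i]], "has_part", pid[i])

  n_edges <- 0L
  if (n_processes > 1L) {
    for (i in seq_len(n_processes - 1L)) {
      for (j in seq((i + 1L), n_processes)) {
        if (course_of[i] == course_of[j] && stats::runif(1) < edge_density) {
          rel(pid[i], "has_result", pid[j])
          n_edges <- n_edges + 1L
        }
      }
    }
  }

  report <- list(
    created_entities = tally$entities,
    created_courses = sort(cid),
    created_relations_by_predicate = as.list(tally$rel),
    seed = as.integer(seed),
    n_edges = n_edges,
    course_parent = parent_of,
    course_processes = lapply(setNames(seq_len(n_courses), cid), function(k)
      sort(pid[course_of == k])))
  list(kb = kb, report = report)
}
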