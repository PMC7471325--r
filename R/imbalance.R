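# Qualitative demand-supply imbalance model: ordinal performance levels,
# modifier application, adaptation, and classification into balanced /
# latent / imbalanced states with outcomes.
#
# Supply is a biological defence functioning process; demand is toxic
# activity. Cells hold homeostasis at "medium"; the defence adapts upward
# to meet rising demand but cannot exceed its cap. A capping modifier that
# exhausts the adaptation reserve puts the system in the latent stage;
# demand above supply manifests the outcome; a forced very-high defence
# well above demand is itself damaging (hyperfunction).

LEVELS <- c(very_low = 0L, low = 1L, medium = 2L, high = 3L, very_high = 4L)

#' Ordinal functioning levels
#'
#' The five-level ordinal scale of functional performance:
#' `very_low < low < medium < high < very_high`. `fl_level()` builds a
#' level from its name (or passes an existing level through);
#' [shift_level()] performs ordinal addition clamped to the range.
#'
#' @param x a level name, an integer in 0..4, or a `tox_level`.
#' @return an object of class `tox_level` (a named integer).
#' @export
#' @examples
#' shift_level(fl_level("medium"), 1)    # high
#' shift_level(fl_level("very_high"), 3) # clamps at very_high
fl_level <- function(x) {
  if (inherits(x, "tox_level")) return(x)
  if (is.character(x)) {
    if (!x %in% names(LEVELS)) stop("unknown level: '", x, "'", call. = FALSE)
    v <- LEVELS[x]
  } else if (is.numeric(x)) {
    if (x < 0 || x > 4 || x != round(x))
      stop("level index out of range: ", x, call. = FALSE)
    v <- LEVELS[as.integer(x) + 1L]
  } else stop("cannot interpret as a level", call. = FALSE)
  structure(unname(v), names = names(LEVELS)[unname(v) + 1L],
            class = "tox_level")
}

#' @export
print.tox_level <- function(x, ...) {
  cat(names(x), "\n")
  invisible(x)
}

#' @export
format.tox_level <- function(x, ...) names(x)

#' @rdname fl_level
#' @param level a `tox_level` (or level name).
#' @param steps signed integer number of ordinal steps.
#' @export
shift_level <- function(level, steps) {
  level <- fl_level(level)
  fl_level(max(0L, min(4L, unclass(level) + as.integer(steps))))
}

#' Build an imbalance modifier
#'
#' Modifiers describe how a process perturbs the scenario: raising or
#' lowering the functional demand, capping the defence's attainable level
#' (e.g. a drug preventing high-level degradation, or a gene mutation
#' reducing it to very low), or forcing the defence above demand
#' (`effect = "raise"` on `target = "supply_cap"`, a floor at
#' medium + `magnitude`, the hyperfunction case).
#'
#' @param target `"demand"` or `"supply_cap"`.
#' @param effect `"raise"`, `"lower"` or `"cap"`.
#' @param magnitude level steps (>= 1) for raise/lower.
#' @param level for `effect = "cap"`: the cap level (name or
#'   `tox_level`); multiple caps combine by minimum.
#' @param cause_process id of the process causing the modification.
#' @return a list of class `tox_modifier`.
#' @export
modifier <- function(target = c("demand", "supply_cap"),
                     effect = c("raise", "lower", "cap"),
                     magnitude = 1L, level = NULL,
                     cause_process = NA_character_) {
  target <- match.arg(target)
  effect <- match.arg(effect)
  if (effect == "cap") {
    if (target != "supply_cap")
      stop("cap modifiers must target supply_cap", call. = FALSE)
    if (is.null(level)) stop("cap modifiers need a level", call. = FALSE)
    level <- fl_level(level)
  } else {
    magnitude <- as.integer(magnitude)
    if (magnitude < 1L) stop("magnitude must be >= 1", call. = FALSE)
  }
  structure(list(target = target, effect = effect, magnitude = magnitude,
                 level = level, cause_process = cause_process),
            class = "tox_modifier")
}

#' Build an imbalance scenario
#'
#' @param demand_process process id of the toxic activity (functional
#'   demand).
#' @param supply_process process id of the biological defence
#'   (functioning process).
#' @param outcome_process process id emitted when demand exceeds supply.
#' @param baseline_demand demand level before modifiers (default
#'   `"medium"`, homeostasis).
#' @param supply_cap highest level the defence can reach by adaptation
#'   (default `"very_high"`).
#' @param modifiers list of [modifier()] objects.
#' @param damage_process optional process emitted on hyperfunction damage
#'   (defaults to `outcome_process`).
#' @param over_supply_threshold level steps by which a forced very-high
#'   supply must exceed demand to count as damaging (default 2).
#' @return a list of class `tox_scenario`.
#' @export
scenario <- function(demand_process, supply_process, outcome_process = NULL,
                     baseline_demand = "medium", supply_cap = "very_high",
                     modifiers = list(), damage_process = NULL,
                     over_supply_threshold = 2L) {
  stopifnot(all(vapply(modifiers, inherits, TRUE, "tox_modifier")))
  structure(list(demand_process = demand_process,
                 supply_process = supply_process,
                 outcome_process = outcome_process,
                 baseline_demand = fl_level(baseline_demand),
                 supply_cap = fl_level(supply_cap),
                 modifiers = modifiers,
                 damage_process = damage_process,
                 over_supply_threshold = as.integer(over_supply_threshold)),
            class = "tox_scenario")
}

#' Resolve the effective levels of a scenario
#'
#' Modifier application order is fixed for determinism: raises and lowers
#' first, then caps (combined by minimum). The effective demand is the
#' baseline after demand modifiers; the effective supply adapts upward to
#' meet demand but cannot exceed the (possibly capped) supply cap. A
#' forced-supply floor (raise on `supply_cap`) may set the supply above
#' demand.
#'
#' @param sc a `tox_scenario`.
#' @return list with `effective_demand`, `effective_supply`,
#'   `supply_cap` (all `tox_level`), `forced_floor` (`tox_level` or
#'   `NULL`) and `capped` (logical: any cap modifier applied).
#' @export
resolve_levels <- function(sc) {
  stopifnot(inherits(sc, "tox_scenario"))
  demand <- sc$baseline_demand
  cap <- sc$supply_cap
  forced <- NULL
  capped <- FALSE
  # pass 1: raises/lowers
  for (m in sc$modifiers) {
    if (m$effect == "cap") next
    step <- if (m$effect == "raise") m$magnitude else -m$magnitude
    if (m$target == "demand") demand <- shift_level(demand, step)
    else {
      floor_ <- shift_level(fl_level("medium"), step)
      forced <- if (is.null(forced)) floor_
      else fl_level(max(unclass(forced), unclass(floor_)))
    }
  }
  # pass 2: caps (min-combine)
  for (m in sc$modifiers) {
    if (m$effect != "cap") next
    cap <- fl_level(min(unclass(cap), unclass(m$level)))
    capped <- TRUE
  }
  supply <- fl_level(min(unclass(demand), unclass(cap)))
  if (!is.null(forced))
    supply <- fl_level(max(unclass(supply), unclass(forced)))
  list(effective_demand = demand, effective_supply = supply,
       supply_cap = cap, forced_floor = forced, capped = capped)
}

#' Evaluate a demand-supply imbalance scenario
#'
#' Classifies the scenario into one of four states:
#' \describe{
#'   \item{balanced}{supply meets demand with adaptation reserve left.}
#'   \item{balanced_latent}{balance is maintained but a capping modifier
#'     has exhausted the adaptation reserve -- the latent stage: no
#'     outcome yet, but the system cannot adapt to any further demand.}
#'   \item{imbalanced_demand}{demand exceeds the attainable supply; the
#'     outcome process manifests.}
#'   \item{imbalanced_supply}{a forced defence at very high level exceeds
#'     demand by at least the over-supply threshold; hyperfunction itself
#'     causes damage (e.g. fibrosis).}
#' }
#' The reserve is `supply_cap - effective_demand` in level steps.
#'
#' @param sc a `tox_scenario`.
#' @return an object of class `tox_assessment`: list with
#'   `effective_demand`, `effective_supply`, `state`, `outcomes`
#'   (character vector of process ids, empty unless imbalanced) and
#'   `reserve`.
#' @export
evaluate_imbalance <- function(sc) {
  lv <- resolve_levels(sc)
  d <- unclass(lv$effective_demand)
  s <- unclass(lv$effective_supply)
  reserve <- unclass(lv$supply_cap) - d
  if (d > s) {
    if (is.null(sc$outcome_process))
      stop("scenario is imbalanced but has no outcome_process", call. = FALSE)
    state <- "imbalanced_demand"
    outcomes <- sc$outcome_process
  } else if (!is.null(lv$forced_floor) && s == 4L &&
             (s - d) >= sc$over_supply_threshold) {
    dmg <- sc$damage_process %||% sc$outcome_process
    if (is.null(dmg))
      stop("scenario is imbalanced but has no damage/outcome process",
           call. = FALSE)
    state <- "imbalanced_supply"
    outcomes <- dmg
  } else if (reserve <= 0L && lv$capped) {
    state <- "balanced_latent"
    outcomes <- character()
  } else {
    state <- "balanced"
    outcomes <- character()
  }
  structure(list(effective_demand = lv$effective_demand,
                 effective_supply = lv$effective_supply,
                 state = state, outcomes = outcomes,
                 reserve = as.integer(reserve)),
            class = "tox_assessment")
}

#' @export
print.tox_assessment <- function(x, ...) {
  cat(sprintf("<tox_assessment> %s (demand %s, supply %s, reserve %+d)%s\n",
              x$state, names(x$effective_demand), names(x$effective_supply),
              x$reserve,
              if (length(x$outcomes))
                paste0("\n  outcomes: ", paste(x$outcomes, collapse = ", "))
              else ""))
  invisible(x)
}

#' Build a scenario from a course's processes
#'
#' Bindings name which processes of the course fill the demand, supply and
#' outcome slots, and which act as modifier causes; every bound process
#' must exist in the materialized course graph.
#'
#' @inheritParams kb_entity
#' @param course_id a toxic-course id.
#' @param bindings list with elements `demand`, `supply`, `outcome`
#'   (process ids) and optional `modifiers` (list of [modifier()] whose
#'   `cause_process`, when set, must be in the course), plus optional
#'   `baseline_demand`, `supply_cap`, `damage`.
#' @return a `tox_scenario`.
#' @export
scenario_from_course <- function(kb, course_id, bindings) {
  graph <- build_course_graph(kb, course_id)
  check <- function(id, slot) {
    if (is.null(id)) return(NULL)
    if (!id %in% graph$nodes)
      stop("binding '", slot, "' references process '", id,
           "' outside course '", course_id, "'", call. = FALSE)
    id
  }
  mods <- bindings$modifiers %||% list()
  for (m in mods) {
    if (!is.na(m$cause_process)) check(m$cause_process, "modifier cause")
  }
  scenario(demand_process = check(bindings$demand, "demand"),
           supply_process = check(bindings$supply, "supply"),
           outcome_process = check(bindings$outcome, "outcome"),
           baseline_demand = bindings$baseline_demand %||% "medium",
           supply_cap = bindings$supply_cap %||% "very_high",
           modifiers = mods,
           damage_process = check(bindings$damage, "damage"))
}

#' Read/write imbalance scenarios as YAML or JSON
#'
#' The file mirrors the [scenario()] fields; modifiers are a list of
#' mappings with `target`, `effect`, `magnitude` or `level`, and
#' `cause_process`. Format is chosen by extension (.yaml/.yml vs .json).
#'
#' @param path file path.
#' @return `read_scenario()` returns a `tox_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
  else stop("unknown scenario format: .", ext, call. = FALSE)
  mods <- lapply(x$modifiers %||% list(), function(m)
    modifier(target = m$target, effect = m$effect,
             magnitude = m$magnitude %||% 1L,
             level = m$level,
             cause_process = m$cause_process %||% NA_character_))
  scenario(demand_process = x$demand_process,
           supply_process = x$supply_process,
           outcome_process = x$outcome_process,
           baseline_demand = x$baseline_demand %||% "medium",
           supply_cap = x$supply_cap %||% "very_high",
           modifiers = mods,
           damage_process = x$damage_process,
           over_supply_threshold = x$over_supply_threshold %||% 2L)
}

#' @rdname read_scenario
#' @param sc a `tox_scenario`.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "tox_scenario"))
  x <- list(demand_process = sc$demand_process,
            supply_process = sc$supply_process,
            outcome_process = sc$outcome_process,
            baseline_demand = names(sc$baseline_demand),
            supply_cap = names(sc$supply_cap),
            over_supply_threshold = sc$over_supply_threshold,
            damage_process = sc$damage_process,
            modifiers = lapply(sc$modifiers, function(m) {
              out <- list(target = m$target, effect = m$effect)
              if (m$effect == "cap") out$level <- names(m$level)
              else out$magnitude <- m$magnitude
              if (!is.na(m$cause_process)) out$cause_process <- m$cause_process
              out
            }))
  x <- Filter(Negate(is.null), x)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Serialize an assessment as JSON
#' @param a a `tox_assessment`.
#' @return a JSON string.
#' @export
assessment_json <- function(a) {
  jsonlite::toJSON(list(
    state = a$state,
    effective_demand = names(a$effective_demand),
    effective_supply = names(a$effective_supply),
    reserve = a$reserve,
    outcomes = as.list(a$outcomes)), auto_unbox = TRUE)
}
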