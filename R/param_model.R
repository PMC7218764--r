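# Parameter model: domain types, validation, and the parameter-bundle format.
#
# A bundle is a directory with a config.yaml naming the states, scalar
# settings and the CSV tables it references:
#   transitions:   from,to,probability,dist
#   economics:     state,cost,cost_dist,daly_weight,daly_lo,daly_hi
#   lifetable:     age,expectancy
#   allowed_edges: from,to

#' Define a health-state space
#'
#' @param ids Character vector of unique state identifiers (e.g. the letters
#'   `A`..`Z` of the canonical RHD model).
#' @param labels Human-readable labels, same length as `ids`.
#' @param death_state Identifier of the absorbing death state.
#' @param tunnel_states Identifiers of single-cycle pass-through states (the
#'   Surgery state in the canonical model): their self-transition is forced
#'   to zero, so their outgoing probabilities must sum to 1.
#' @return An object of class `rhd_state_space`.
#' @export
state_space <- function(ids, labels = ids, death_state,
                        tunnel_states = character()) {
  ids <- as.character(ids)
  if (length(ids) == 0) stop("state space must contain at least one state")
  if (anyDuplicated(ids))
    stop("duplicate state identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(labels) != length(ids))
    stop("labels must match ids in length")
  if (!death_state %in% ids)
    stop("death_state '", death_state, "' is not a member of the state space")
  bad <- setdiff(tunnel_states, ids)
  if (length(bad))
    stop("tunnel states not in state space: ", paste(bad, collapse = ", "))
  structure(list(states = data.frame(id = ids, label = as.character(labels),
                                     stringsAsFactors = FALSE),
                 death_state = death_state,
                 tunnel_states = as.character(tunnel_states)),
            class = "rhd_state_space")
}

state_ids <- function(ss) ss$states$id

#' @export
print.rhd_state_space <- function(x, ...) {
  cat(sprintf("State space: %d states, death = %s%s\n",
              nrow(x$states), x$death_state,
              if (length(x$tunnel_states))
                paste0(", tunnel = ", paste(x$tunnel_states, collapse = ","))
              else ""))
  invisible(x)
}

#' Assemble a parameter set
#'
#' Bundles every input of one scenario: the state space, transition entries
#' with uncertainty descriptors, per-state economics (annual cost and DALY
#' weight with its 95% uncertainty interval), a life table, the cycle-0
#' distribution, cohort constants, screening test characteristics and the
#' secondary-prophylaxis effect sizes. All invariants are checked on
#' construction.
#'
#' @param state_space An [state_space()] object.
#' @param transitions Data frame `from,to,probability` plus a list column
#'   `dist` of [rhd_dist] descriptors (or a character column parsed with the
#'   bundle descriptor syntax).
#' @param economics Data frame `state,cost,daly_weight,daly_lo,daly_hi` plus
#'   a `cost_dist` descriptor column.
#' @param life_table Data frame `age,expectancy`; ages strictly increasing,
#'   expectancies positive and non-increasing (within `1e-6`).
#' @param initial_distribution Named per-state proportions summing to 1
#'   within `1e-9` (missing states are zero).
#' @param cohort_size Persons in the closed cohort.
#' @param n_cycles Number of one-year cycles.
#' @param start_age Age in years at cycle 0.
#' @param discount_rate Annual discount rate for costs and outcomes.
#' @param threshold Willingness-to-pay threshold, USD per DALY averted.
#' @param screening List with `cost_per_scan`, `sensitivity_borderline`,
#'   `sensitivity_definite`, `specificity`, `false_positive_followup_cost`,
#'   `screened_fraction`, and optionally `owsa` (named list of
#'   `c(lower, upper)` sweep endpoints).
#' @param prophylaxis List with `effect_definite`, `effect_mild` (fractional
#'   hazard reductions), `definite_from`, `definite_to`, `mild_from`,
#'   `mild_to` (state ids the reductions act on).
#' @param roles Named list mapping model roles to state ids:
#'   `disease_free`, `undiagnosed_borderline`, `diagnosed_borderline`,
#'   `undiagnosed_definite`, `treated_definite`, plus `borderline_states` /
#'   `definite_states` used by external validation. Roles may be `NA` for
#'   reduced models.
#' @param allowed_edges Data frame `from,to` of permitted directed edges
#'   (the transcription of the model diagram); self-loops need not be listed.
#' @param shared_cost_variance Variance applied to every gamma cost
#'   descriptor written as `gamma_shared` in a bundle.
#' @return An object of class `rhd_params`.
#' @export
parameter_set <- function(state_space, transitions, economics, life_table,
                          initial_distribution, cohort_size = 1000,
                          n_cycles = 30, start_age = 11,
                          discount_rate = 0.03, threshold = 25949.85,
                          screening, prophylaxis, roles,
                          allowed_edges = NULL,
                          shared_cost_variance = 0) {
  p <- structure(list(
    state_space = state_space,
    transitions = transitions,
    economics = economics,
    life_table = life_table,
    initial_distribution = initial_distribution,
    cohort_size = cohort_size,
    n_cycles = n_cycles,
    start_age = start_age,
    discount_rate = discount_rate,
    threshold = threshold,
    screening = screening,
    prophylaxis = prophylaxis,
    roles = roles,
    allowed_edges = allowed_edges,
    shared_cost_variance = shared_cost_variance
  ), class = "rhd_params")
  # canonical column order, so bundles round-trip identically
  tr_cols <- c("from", "to", "probability", "dist")
  if (all(tr_cols %in% names(p$transitions)))
    p$transitions <- p$transitions[tr_cols]
  ec_cols <- c("state", "cost", "cost_dist", "daly_weight", "daly_lo", "daly_hi")
  if (all(ec_cols %in% names(p$economics)))
    p$economics <- p$economics[ec_cols]
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks every structural invariant of an `rhd_params` object and stops
#' with an informative message naming the offending field on the first
#' violation. Returns the object invisibly so it can be chained.
#'
#' @param p An `rhd_params` object.
#' @return `p`, invisibly.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "rhd_params"))
  ss <- p$state_space
  if (!inherits(ss, "rhd_state_space")) stop("state_space is not an rhd_state_space")
  ids <- state_ids(ss)

  tr <- p$transitions
  need <- c("from", "to", "probability", "dist")
  if (!all(need %in% names(tr)))
    stop("transitions must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(c(tr$from, tr$to)), ids)
  if (length(bad))
    stop("transition references unknown state(s): ", paste(bad, collapse = ", "))
  key <- paste(tr$from, tr$to, sep = "->")
  if (anyDuplicated(key))
    stop("duplicate transition entries: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (any(tr$probability < 0 | tr$probability > 1))
    stop("transition probabilities outside [0,1]: ",
         paste(key[tr$probability < 0 | tr$probability > 1], collapse = ", "))
  for (i in seq_len(nrow(tr)))
    if (!inherits(tr$dist[[i]], "rhd_dist"))
      stop("transition ", key[i], " carries no uncertainty descriptor")
  # outgoing mass per state (self-loops count toward the row total)
  for (s in ids) {
    out <- sum(tr$probability[tr$from == s & tr$to != s])
    if (out > 1 + 1e-9)
      stop(sprintf("outgoing probabilities of state %s sum to %.12g > 1", s, out))
  }
  if (!is.null(p$allowed_edges)) {
    v <- validate_edges(tr, p$allowed_edges)
    if (nrow(v))
      stop("transitions not permitted by the model diagram: ",
           paste(paste(v$from, v$to, sep = "->"), collapse = ", "))
  }

  ec <- p$economics
  need <- c("state", "cost", "cost_dist", "daly_weight", "daly_lo", "daly_hi")
  if (!all(need %in% names(ec)))
    stop("economics must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(ec$state, ids)
  if (length(bad))
    stop("economics references unknown state(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(ec$state))
    stop("duplicate economics rows for state(s): ",
         paste(unique(ec$state[duplicated(ec$state)]), collapse = ", "))
  missing_ec <- setdiff(ids, ec$state)
  if (length(missing_ec))
    stop("states without economics entry: ", paste(missing_ec, collapse = ", "))
  if (any(ec$cost < 0)) stop("negative annual cost for state(s): ",
                             paste(ec$state[ec$cost < 0], collapse = ", "))
  okw <- function(x) all(x >= 0 & x <= 1)
  if (!okw(ec$daly_weight) || !okw(ec$daly_lo) || !okw(ec$daly_hi))
    stop("DALY weights and their intervals must lie in [0,1]")
  if (any(!(ec$daly_lo <= ec$daly_weight & ec$daly_weight <= ec$daly_hi)))
    stop("DALY weight interval must satisfy lo <= weight <= hi for state(s): ",
         paste(ec$state[!(ec$daly_lo <= ec$daly_weight &
                          ec$daly_weight <= ec$daly_hi)], collapse = ", "))
  dz <- ec[ec$state == ss$death_state, ]
  if (dz$cost != 0 || dz$daly_weight != 0)
    stop("death state must have zero annual cost and zero DALY weight ",
         "(mortality contributes through years of life lost)")

  lt <- p$life_table
  if (!all(c("age", "expectancy") %in% names(lt)))
    stop("life_table must have columns age, expectancy")
  if (is.unsorted(lt$age, strictly = TRUE))
    stop("life_table ages must be strictly increasing")
  if (any(lt$expectancy <= 0))
    stop("life expectancies must be positive")
  if (any(diff(lt$expectancy) > 1e-6))
    stop("life expectancy must be non-increasing with age")

  init <- p$initial_distribution
  if (is.null(names(init)) || any(!nzchar(names(init))))
    stop("initial_distribution must be a named vector")
  bad <- setdiff(names(init), ids)
  if (length(bad))
    stop("initial_distribution references unknown state(s): ",
         paste(bad, collapse = ", "))
  if (any(init < 0)) stop("initial_distribution has negative entries")
  if (abs(sum(init) - 1) > 1e-9)
    stop(sprintf("initial_distribution sums to %.12g, expected 1", sum(init)))

  if (p$cohort_size <= 0) stop("cohort_size must be positive")
  if (p$n_cycles < 1) stop("n_cycles must be >= 1")
  if (p$discount_rate < 0) stop("discount_rate must be >= 0")
  if (p$threshold < 0) stop("threshold must be >= 0")
  if (p$start_age < 0) stop("start_age must be >= 0")

  sc <- p$screening
  for (f in c("sensitivity_borderline", "sensitivity_definite", "specificity",
              "screened_fraction"))
    if (is.null(sc[[f]]) || sc[[f]] < 0 || sc[[f]] > 1)
      stop("screening$", f, " must be a probability in [0,1]")
  for (f in c("cost_per_scan", "false_positive_followup_cost"))
    if (is.null(sc[[f]]) || sc[[f]] < 0)
      stop("screening$", f, " must be a cost >= 0")

  pr <- p$prophylaxis
  for (f in c("effect_definite", "effect_mild"))
    if (is.null(pr[[f]]) || pr[[f]] < 0 || pr[[f]] > 1)
      stop("prophylaxis$", f, " must be a fraction in [0,1]")
  for (f in c("definite_from", "mild_from")) {
    s <- pr[[f]]
    if (length(s) && !is.na(s) && !s %in% ids)
      stop("prophylaxis$", f, " names unknown state ", s)
  }

  for (r in names(p$roles)) {
    s <- p$roles[[r]]
    bad <- setdiff(s[!is.na(s)], ids)
    if (length(bad))
      stop("role '", r, "' names unknown state(s): ", paste(bad, collapse = ", "))
  }
  invisible(p)
}

#' Check transitions against the permitted edge list
#'
#' Self-loops are always permitted; any other `(from, to)` pair must appear
#' in `allowed_edges`. Violations are returned as data, not raised.
#'
#' @param transitions Data frame with `from` and `to` columns.
#' @param allowed_edges Data frame with `from` and `to` columns.
#' @return The subset of `transitions` rows (columns `from`, `to`) that are
#'   not permitted; zero rows when all edges are legal.
#' @export
validate_edges <- function(transitions, allowed_edges) {
  if (nrow(transitions) == 0)
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  key <- paste(transitions$from, transitions$to, sep = "->")
  okay <- paste(allowed_edges$from, allowed_edges$to, sep = "->")
  bad <- transitions$from != transitions$to & !(key %in% okay)
  transitions[bad, c("from", "to"), drop = FALSE]
}

#' @export
print.rhd_params <- function(x, ...) {
  cat(sprintf(paste0(
    "Parameter set: %d states, %d transitions\n",
    "  cohort %d, %d cycles from age %g, discount %.1f%%, threshold $%.2f/DALY\n"),
    nrow(x$state_space$states), nrow(x$transitions),
    x$cohort_size, x$n_cycles, x$start_age,
    100 * x$discount_rate, x$threshold))
  invisible(x)
}

# ---- bundle I/O -------------------------------------------------------------

# scalar config keys accepted in config.yaml (unknown keys are rejected)
.bundle_keys <- c("states", "death_state", "tunnel_states",
                  "initial_distribution", "cohort_size", "n_cycles",
                  "start_age", "discount_rate", "threshold", "screening",
                  "prophylaxis", "roles", "shared_cost_variance", "files")
.screening_keys <- c("cost_per_scan", "sensitivity_borderline",
                     "sensitivity_definite", "specificity",
                     "false_positive_followup_cost", "screened_fraction",
                     "owsa")
.prophylaxis_keys <- c("effect_definite", "effect_mild", "definite_from",
                       "definite_to", "mild_from", "mild_to")

read_bundle_csv <- function(path, what) {
  if (!file.exists(path))
    stop("bundle ", what, " table not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

parse_dist_column <- function(x, shared_cost_variance = NULL, means = NULL) {
  lapply(seq_along(x), function(i) {
    s <- trimws(x[[i]])
    if (identical(s, "gamma_shared")) {
      if (is.null(shared_cost_variance))
        stop("'gamma_shared' descriptor used but no shared_cost_variance set")
      dist_gamma_mean_var(means[[i]], shared_cost_variance)
    } else dist_from_string(s)
  })
}

#' Read a parameter bundle from disk
#'
#' @param path Bundle directory (containing `config.yaml`) or the path of the
#'   config file itself.
#' @param transitions_overlay Optional path to an alternative transitions CSV
#'   (same columns) substituted for the bundled one — the hook for dropping
#'   in externally sourced transition probabilities without editing the
#'   bundle.
#' @return A validated `rhd_params` object.
#' @export
load_parameter_bundle <- function(path, transitions_overlay = NULL) {
  cfg_path <- if (dir.exists(path)) file.path(path, "config.yaml") else path
  if (!file.exists(cfg_path)) stop("bundle config not found: ", cfg_path)
  root <- dirname(cfg_path)
  cfg <- yaml::read_yaml(cfg_path)

  unknown <- setdiff(names(cfg), .bundle_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(setdiff(.bundle_keys, "tunnel_states"), names(cfg))
  if (length(missing))
    stop("missing config key(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(cfg$screening), .screening_keys)
  if (length(unknown))
    stop("unknown screening key(s): ", paste(unknown, collapse = ", "))
  unknown <- setdiff(names(cfg$prophylaxis), .prophylaxis_keys)
  if (length(unknown))
    stop("unknown prophylaxis key(s): ", paste(unknown, collapse = ", "))

  ss <- state_space(ids = vapply(cfg$states, `[[`, "", "id"),
                    labels = vapply(cfg$states, `[[`, "", "label"),
                    death_state = cfg$death_state,
                    tunnel_states = unlist(cfg$tunnel_states) %||% character())

  tr_path <- if (!is.null(transitions_overlay)) transitions_overlay
             else file.path(root, cfg$files$transitions)
  tr <- read_bundle_csv(tr_path, "transitions")
  tr$dist <- parse_dist_column(tr$dist)
  tr <- tr[c("from", "to", "probability", "dist")]

  ec <- read_bundle_csv(file.path(root, cfg$files$economics), "economics")
  ec$cost_dist <- parse_dist_column(ec$cost_dist,
                                    shared_cost_variance = cfg$shared_cost_variance,
                                    means = ec$cost)
  lt <- read_bundle_csv(file.path(root, cfg$files$lifetable), "lifetable")
  ae <- read_bundle_csv(file.path(root, cfg$files$allowed_edges), "allowed_edges")

  init <- unlist(cfg$initial_distribution)
  roles <- lapply(cfg$roles, function(x) { x <- unlist(x); x[x == ""] <- NA; x })
  screening <- cfg$screening
  if (!is.null(screening$owsa))
    screening$owsa <- lapply(screening$owsa, unlist)
  prophylaxis <- cfg$prophylaxis
  prophylaxis$definite_to <- as.character(unlist(prophylaxis$definite_to))
  prophylaxis$mild_to <- as.character(unlist(prophylaxis$mild_to))

  parameter_set(
    state_space = ss, transitions = tr, economics = ec, life_table = lt,
    initial_distribution = init,
    cohort_size = cfg$cohort_size, n_cycles = cfg$n_cycles,
    start_age = cfg$start_age, discount_rate = cfg$discount_rate,
    threshold = cfg$threshold, screening = screening,
    prophylaxis = prophylaxis, roles = roles, allowed_edges = ae,
    shared_cost_variance = cfg$shared_cost_variance
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a parameter bundle to disk
#'
#' Writes the bundle dialect read by [load_parameter_bundle()]; numeric
#' values are serialized at full precision so that load -> save -> load is
#' the identity.
#'
#' @param p An `rhd_params` object.
#' @param path Target directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_parameter_bundle <- function(p, path) {
  validate_params(p)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)

  tr <- data.frame(from = p$transitions$from, to = p$transitions$to,
                   probability = fmt_num(p$transitions$probability),
                   dist = vapply(p$transitions$dist, dist_to_string, ""),
                   stringsAsFactors = FALSE)
  utils::write.csv(tr, file.path(path, "transitions.csv"), row.names = FALSE)

  ec <- p$economics
  eco <- data.frame(state = ec$state, cost = fmt_num(ec$cost),
                    cost_dist = vapply(ec$cost_dist, dist_to_string, ""),
                    daly_weight = fmt_num(ec$daly_weight),
                    daly_lo = fmt_num(ec$daly_lo), daly_hi = fmt_num(ec$daly_hi),
                    stringsAsFactors = FALSE)
  utils::write.csv(eco, file.path(path, "economics.csv"), row.names = FALSE)

  lt <- data.frame(age = fmt_num(p$life_table$age),
                   expectancy = fmt_num(p$life_table$expectancy))
  utils::write.csv(lt, file.path(path, "lifetable.csv"), row.names = FALSE)
  utils::write.csv(p$allowed_edges, file.path(path, "allowed_edges.csv"),
                   row.names = FALSE)

  cfg <- list(
    states = lapply(seq_len(nrow(p$state_space$states)), function(i)
      list(id = p$state_space$states$id[i],
           label = p$state_space$states$label[i])),
    death_state = p$state_space$death_state,
    tunnel_states = as.list(p$state_space$tunnel_states),
    initial_distribution = as.list(p$initial_distribution),
    cohort_size = p$cohort_size, n_cycles = p$n_cycles,
    start_age = p$start_age, discount_rate = p$discount_rate,
    threshold = p$threshold,
    screening = lapply(p$screening, function(x)
      if (is.list(x)) lapply(x, as.list) else x),
    prophylaxis = lapply(p$prophylaxis, function(x)
      if (length(x) > 1) as.list(x) else x),
    roles = lapply(p$roles, function(x) {
      x <- as.character(x); x[is.na(x)] <- ""; as.list(x)
    }),
    shared_cost_variance = p$shared_cost_variance,
    files = list(transitions = "transitions.csv",
                 economics = "economics.csv",
                 lifetable = "lifetable.csv",
                 allowed_edges = "allowed_edges.csv")
  )
  yaml::write_yaml(cfg, file.path(path, "config.yaml"), precision = 17)
  invisible(path)
}

#' The canonical 15-state RHD parameter bundle
#'
#' Loads the parameter bundle shipped with the package: the 15 health states
#' of the Brazilian RHD screening model with their published 2017-USD annual
#' costs (No RHD and all untreated states $0; Diagnosed Borderline $25.84;
#' Treated Asymptomatic Definite and Resolved-G $93.93; Treated Mild Clinical
#' and Resolved-H $337.47; Treated Severe Clinical, Resolved-I and
#' Post-Surgery $854.00; Surgery $4,120.51), cohort size 1,000, 30 one-year
#' cycles from age 11, 3% annual discounting, a $25,949.85/DALY threshold and
#' a $6.60 cost per screening scan.
#'
#' Transition probabilities, DALY weights, the life table, the initial
#' distribution split and baseline screening accuracies are *synthetic
#' placeholders* (files marked `_synthetic`): structurally faithful to the
#' model diagram but not estimates of the study's supplementary values.
#' Substitute externally sourced transitions with the
#' `transitions_overlay` argument of [load_parameter_bundle()].
#'
#' @param transitions_overlay Optional transitions CSV path, passed through
#'   to [load_parameter_bundle()].
#' @return A validated `rhd_params` object.
#' @export
paper_fixture <- function(transitions_overlay = NULL) {
  load_parameter_bundle(
    system.file("extdata", "rhd_brazil", package = "rhdcea", mustWork = TRUE),
    transitions_overlay = transitions_overlay)
}
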