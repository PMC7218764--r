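# Strategy construction (standard care vs one-time screening) and the
# deterministic cost-effectiveness pipeline.

#' Halve (or otherwise reduce) treated-state progression
#'
#' Applies the secondary-prophylaxis effect to a transition matrix:
#' progression probabilities out of the treated asymptomatic-definite state
#' toward clinical/surgical states are multiplied by
#' `(1 - reduction_definite)`, treated mild-to-severe progression by
#' `(1 - reduction_mild)`, and the freed probability mass is returned to each
#' source state's self-transition so rows stay stochastic.
#'
#' @param matrix Row-stochastic transition matrix.
#' @param reduction_definite,reduction_mild Fractional reductions in `[0,1]`.
#' @param definite_from,mild_from Source state ids (`NA` disables the arm).
#' @param definite_to,mild_to Target state ids the reductions act on.
#' @return The adjusted matrix.
#' @export
apply_prophylaxis_effect <- function(matrix, reduction_definite,
                                     reduction_mild,
                                     definite_from, definite_to,
                                     mild_from, mild_to) {
  if (reduction_definite < 0 || reduction_definite > 1 ||
      reduction_mild < 0 || reduction_mild > 1)
    stop("prophylaxis reductions must lie in [0,1]")
  scale_row <- function(m, from, to, reduction) {
    if (length(from) != 1 || is.na(from) || reduction == 0) return(m)
    to <- intersect(to, colnames(m))
    freed <- sum(m[from, to]) * reduction
    m[from, to] <- m[from, to] * (1 - reduction)
    m[from, from] <- m[from, from] + freed
    m
  }
  m <- scale_row(matrix, definite_from, definite_to, reduction_definite)
  m <- scale_row(m, mild_from, mild_to, reduction_mild)
  check_stochastic(m)
  m
}

base_matrix <- function(params) {
  pr <- params$prophylaxis
  m <- assemble_matrix(params$transitions, params$state_space)
  apply_prophylaxis_effect(m, pr$effect_definite, pr$effect_mild,
                           pr$definite_from, pr$definite_to,
                           pr$mild_from, pr$mild_to)
}

new_strategy <- function(name, initial, matrix, one_time_costs) {
  structure(list(name = name, initial = initial, matrix = matrix,
                 one_time_costs = one_time_costs),
            class = "rhd_strategy")
}

#' Standard-care strategy
#'
#' The cycle-0 distribution is the parameter set's initial distribution
#' (screening-study-derived prevalences) scaled to the cohort size; there are
#' no one-time costs. Treated states carry the prophylaxis-reduced
#' progression in both strategies, so the strategies differ only through the
#' cycle-0 reallocation and screening costs.
#'
#' @param params An `rhd_params`.
#' @return An `rhd_strategy`.
#' @export
build_standard_care <- function(params) {
  ids <- state_ids(params$state_space)
  init <- setNames(numeric(length(ids)), ids)
  init[names(params$initial_distribution)] <-
    params$initial_distribution * params$cohort_size
  new_strategy("standard_care", init, base_matrix(params),
               data.frame(cycle = numeric(), amount = numeric(),
                          label = character()))
}

#' One-time screening strategy
#'
#' Everyone in the screened fraction is scanned at cycle 0 (cost
#' `cohort_size * screened_fraction * cost_per_scan`). Of the screened
#' undiagnosed-borderline occupants, `sensitivity_borderline` move to the
#' diagnosed-borderline state; of the screened untreated
#' asymptomatic-definite occupants, `sensitivity_definite` move to the
#' treated-definite state. Screened disease-free children test falsely
#' positive with probability `1 - specificity`, incurring the one-time
#' follow-up cost while remaining disease-free.
#'
#' @param params An `rhd_params`.
#' @return An `rhd_strategy`.
#' @export
build_screening <- function(params) {
  sc <- params$screening
  for (f in c("sensitivity_borderline", "sensitivity_definite", "specificity"))
    if (sc[[f]] < 0 || sc[[f]] > 1)
      stop("screening$", f, " must lie in [0,1]")
  std <- build_standard_care(params)
  init <- std$initial
  r <- params$roles
  f <- sc$screened_fraction

  move <- function(init, from, to, prob) {
    if (length(from) != 1 || is.na(from) || is.na(to)) return(init)
    moved <- init[from] * f * prob
    init[from] <- init[from] - moved
    init[to] <- init[to] + moved
    init
  }
  init <- move(init, r$undiagnosed_borderline, r$diagnosed_borderline,
               sc$sensitivity_borderline)
  init <- move(init, r$undiagnosed_definite, r$treated_definite,
               sc$sensitivity_definite)

  fp <- if (length(r$disease_free) == 1 && !is.na(r$disease_free))
    std$initial[r$disease_free] * f * (1 - sc$specificity) else 0
  one_time <- data.frame(
    cycle = c(0, 0),
    amount = c(params$cohort_size * f * sc$cost_per_scan,
               fp * sc$false_positive_followup_cost),
    label = c("screening_scans", "false_positive_followup"))

  new_strategy("screening", init, std$matrix, one_time)
}

#' Evaluate one strategy
#'
#' Runs the cohort and accrues discounted costs and DALYs.
#'
#' @param strategy An `rhd_strategy`.
#' @param params The `rhd_params` it was built from.
#' @param accrual Cycle accrual timing, `"end"` (default) or `"begin"`.
#' @param yll_mode `"stream"` (default) or `"lump"`.
#' @return An `rhd_scenario` with `total_cost`, `total_dalys`, `yld`, `yll`,
#'   `one_time_costs`, the per-cycle breakdowns and the `trace`.
#' @export
run_strategy <- function(strategy, params, accrual = c("end", "begin"),
                         yll_mode = c("stream", "lump")) {
  accrual <- match.arg(accrual)
  yll_mode <- match.arg(yll_mode)
  trace <- run_cohort(strategy$matrix, strategy$initial, params$n_cycles)
  costs <- accrue_costs(trace, params$economics, strategy$one_time_costs,
                        params$discount_rate, accrual)
  dalys <- accrue_dalys(trace, params$economics, params$life_table,
                        params$start_age, params$discount_rate,
                        params$state_space$death_state, accrual, yll_mode)
  structure(list(name = strategy$name,
                 total_cost = costs$total, total_dalys = dalys$total,
                 yld = dalys$yld, yll = dalys$yll,
                 one_time_costs = costs$one_time,
                 cost_per_cycle = costs$per_cycle,
                 daly_per_cycle = dalys$per_cycle,
                 trace = trace),
            class = "rhd_scenario")
}

#' @export
print.rhd_scenario <- function(x, ...) {
  cat(sprintf("%s: cost $%.2f (one-time $%.2f), DALYs %.2f (YLD %.2f, YLL %.2f)\n",
              x$name, x$total_cost, x$one_time_costs, x$total_dalys,
              x$yld, x$yll))
  invisible(x)
}

#' Deterministic cost-effectiveness analysis
#'
#' Builds and evaluates the standard-care and screening strategies and
#' compares them at the parameter set's threshold.
#'
#' @inheritParams run_strategy
#' @param params An `rhd_params`.
#' @return An `rhd_cea`: list with `standard`, `screening` (both
#'   `rhd_scenario`) and `comparison` (`rhd_comparison`).
#' @export
run_cea <- function(params, accrual = c("end", "begin"),
                    yll_mode = c("stream", "lump")) {
  accrual <- match.arg(accrual)
  yll_mode <- match.arg(yll_mode)
  std <- run_strategy(build_standard_care(params), params, accrual, yll_mode)
  scr <- run_strategy(build_screening(params), params, accrual, yll_mode)
  structure(list(standard = std, screening = scr,
                 comparison = compare_strategies(std, scr, params$threshold)),
            class = "rhd_cea")
}

#' @export
print.rhd_cea <- function(x, ...) {
  print(x$standard); print(x$screening); print(x$comparison)
  invisible(x)
}
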