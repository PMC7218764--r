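# Discounted cost and DALY accrual, and incremental comparison (ICER / NMB).

#' Present-value discount factor
#'
#' @param rate Annual discount rate (>= 0).
#' @param cycle Cycle index (>= 0); cycle 0 is undiscounted.
#' @return `(1 + rate)^(-cycle)`.
#' @export
discount_factor <- function(rate, cycle) {
  if (any(rate < 0)) stop("discount rate must be >= 0")
  if (any(cycle < 0)) stop("cycle must be >= 0")
  (1 + rate)^(-cycle)
}

accrual_rows <- function(trace, accrual) {
  n <- nrow(trace) - 1
  # end-of-cycle: state occupied during cycle t is trace row t, discounted
  # by t; begin-of-cycle uses row t-1 discounted by t-1.
  if (accrual == "end") list(rows = 2:(n + 1), cycles = 1:n)
  else list(rows = 1:n, cycles = 0:(n - 1))
}

#' Accrue discounted costs over a cohort trace
#'
#' Per-cycle state costs are occupancy times annual cost, discounted at the
#' cycle's factor; one-time amounts are discounted at their own cycle.
#'
#' @param trace An `rhd_trace`.
#' @param economics Data frame with `state` and `cost` columns covering every
#'   trace state with positive occupancy.
#' @param one_time Data frame with `cycle` and `amount` columns (may have
#'   zero rows).
#' @param rate Annual discount rate.
#' @param accrual `"end"` (default: cycle-t occupancy discounted by t) or
#'   `"begin"`.
#' @return A list with `total`, `state_cost` (discounted recurring costs),
#'   `one_time` and the `per_cycle` breakdown.
#' @export
accrue_costs <- function(trace, economics, one_time = NULL, rate = 0,
                         accrual = c("end", "begin")) {
  accrual <- match.arg(accrual)
  ids <- colnames(trace)
  cost <- setNames(rep(NA_real_, length(ids)), ids)
  cost[economics$state] <- economics$cost
  occupied <- ids[colSums(trace) > 0]
  if (anyNA(cost[occupied]))
    stop("no cost entry for occupied state(s): ",
         paste(occupied[is.na(cost[occupied])], collapse = ", "))
  cost[is.na(cost)] <- 0
  a <- accrual_rows(trace, accrual)
  df <- discount_factor(rate, a$cycles)
  per_cycle <- as.numeric(trace[a$rows, , drop = FALSE] %*% cost) * df
  one_time_total <- 0
  if (!is.null(one_time) && nrow(one_time))
    one_time_total <- sum(one_time$amount * discount_factor(rate, one_time$cycle))
  list(total = sum(per_cycle) + one_time_total,
       state_cost = sum(per_cycle),
       one_time = one_time_total,
       per_cycle = data.frame(cycle = a$cycles, cost = per_cycle))
}

# Linear interpolation into the life table; errors outside its range.
life_expectancy_at <- function(life_table, age) {
  if (any(age < min(life_table$age)) || any(age > max(life_table$age)))
    stop(sprintf("attained age %g outside life table range [%g, %g]",
                 age[which(age < min(life_table$age) |
                           age > max(life_table$age))][1],
                 min(life_table$age), max(life_table$age)))
  stats::approx(life_table$age, life_table$expectancy, xout = age)$y
}

# Present value (at the death cycle's origin, time 0) of L years of life
# starting the year after a death at cycle t: sum_{k=1..ceil(L)} w_k
# (1+r)^-(t+k), with the final fractional year pro-rated.
yll_stream_pv <- function(L, t, rate) {
  if (L <= 0) return(0)
  k <- seq_len(ceiling(L))
  w <- pmin(1, L - (k - 1))
  sum(w * discount_factor(rate, t + k))
}

#' Accrue discounted DALYs over a cohort trace
#'
#' Years lived with disability (YLD) accrue as occupancy times DALY weight
#' per cycle, discounted like costs. Years of life lost (YLL) accrue for the
#' new entrants to the death state each cycle, valued by the remaining life
#' expectancy at the attained age; with `yll_mode = "stream"` (default) the
#' expectancy is spread over whole years starting the year after death and
#' each year discounted back to time 0, with `"lump"` it is taken as a lump
#' sum at the death cycle.
#'
#' @param trace An `rhd_trace`.
#' @param economics Data frame with `state` and `daly_weight` columns.
#' @param life_table Data frame `age,expectancy` covering all attained ages.
#' @param start_age Age at cycle 0.
#' @param rate Annual discount rate.
#' @param death_state Id of the absorbing death state.
#' @param accrual Cost/YLD accrual timing, `"end"` or `"begin"`.
#' @param yll_mode `"stream"` or `"lump"`.
#' @return A list with `total`, `yld`, `yll` and `per_cycle` breakdown.
#' @export
accrue_dalys <- function(trace, economics, life_table, start_age, rate = 0,
                         death_state, accrual = c("end", "begin"),
                         yll_mode = c("stream", "lump")) {
  accrual <- match.arg(accrual)
  yll_mode <- match.arg(yll_mode)
  ids <- colnames(trace)
  w <- setNames(rep(0, length(ids)), ids)
  w[economics$state] <- economics$daly_weight
  w[death_state] <- 0

  a <- accrual_rows(trace, accrual)
  df <- discount_factor(rate, a$cycles)
  yld_cycle <- as.numeric(trace[a$rows, , drop = FALSE] %*% w) * df

  n <- nrow(trace) - 1
  deaths <- diff(trace[, death_state])            # new deaths in cycles 1..n
  if (any(deaths < -1e-9)) stop("death-state occupancy decreased over a cycle")
  yll_cycle <- numeric(n)
  for (t in seq_len(n)) {
    if (deaths[t] <= 0) next
    L <- life_expectancy_at(life_table, start_age + t)
    yll_cycle[t] <- deaths[t] *
      if (yll_mode == "stream") yll_stream_pv(L, t, rate)
      else L * discount_factor(rate, t)
  }
  list(total = sum(yld_cycle) + sum(yll_cycle),
       yld = sum(yld_cycle), yll = sum(yll_cycle),
       per_cycle = data.frame(cycle = a$cycles, yld = yld_cycle),
       yll_per_cycle = data.frame(cycle = seq_len(n), yll = yll_cycle))
}

#' Incremental comparison of two strategies
#'
#' @param standard,intervention `rhd_scenario` results (see [run_strategy()])
#'   or any lists with `total_cost` and `total_dalys` fields, computed under
#'   identical horizon and discounting.
#' @param threshold Willingness-to-pay, USD per DALY averted.
#' @return An `rhd_comparison`: `delta_cost` (intervention minus standard),
#'   `delta_effect` (DALYs averted, standard minus intervention), `icer`
#'   (`NA` when `delta_effect` is 0), a `label` among `"icer"`, `"dominant"`
#'   (cheaper and more effective), `"dominated"` (costlier and less
#'   effective), `"less_effective_cheaper"` and `"equal_effect"`, and
#'   `nmb = threshold * delta_effect - delta_cost`.
#' @export
compare_strategies <- function(standard, intervention, threshold) {
  dc <- intervention$total_cost - standard$total_cost
  de <- standard$total_dalys - intervention$total_dalys
  if (de > 0) {
    label <- if (dc <= 0) "dominant" else "icer"
    icer <- dc / de
  } else if (de < 0) {
    label <- if (dc >= 0) "dominated" else "less_effective_cheaper"
    icer <- dc / de
  } else {
    label <- "equal_effect"
    icer <- NA_real_
  }
  structure(list(delta_cost = dc, delta_effect = de, icer = icer,
                 label = label, threshold = threshold,
                 nmb = threshold * de - dc),
            class = "rhd_comparison")
}

#' @export
print.rhd_comparison <- function(x, ...) {
  cat(sprintf("Incremental cost:   $%.2f\n", x$delta_cost))
  cat(sprintf("DALYs averted:      %.2f\n", x$delta_effect))
  if (is.na(x$icer)) cat(sprintf("ICER:               undefined (%s)\n", x$label))
  else cat(sprintf("ICER:               $%.2f per DALY averted%s\n", x$icer,
                   if (x$label != "icer") paste0(" [", x$label, "]") else ""))
  cat(sprintf("NMB at $%.2f: $%.2f\n", x$threshold, x$nmb))
  invisible(x)
}
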