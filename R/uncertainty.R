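# Probabilistic sensitivity analysis (parameter sampling, CE pairs, CEAC)
# and one-way deterministic sensitivity analysis (tornado).

# One probabilistic realization of a parameter set: draws every transition
# probability, state cost and DALY weight from its descriptor. Transition
# rows whose sampled off-diagonal mass exceeds 1 are renormalized so the
# self-loop remainder is 0; otherwise the remainder goes to the self-loop as
# in the deterministic model.
sample_params <- function(params) {
  p <- params
  tr <- p$transitions
  tr$probability <- vapply(tr$dist, sample_parameter, 0)
  tr$probability <- pmin(1, pmax(0, tr$probability))
  tunnels <- p$state_space$tunnel_states
  for (s in unique(tr$from)) {
    i <- which(tr$from == s & tr$to != s)
    out <- sum(tr$probability[i])
    # tunnel rows have no self-loop remainder: renormalize to exactly 1
    if (s %in% tunnels) {
      if (out <= 0) stop("tunnel state ", s, " sampled zero outgoing mass")
      tr$probability[i] <- tr$probability[i] / out
    } else if (out > 1) {
      tr$probability[i] <- tr$probability[i] / out
    }
  }
  p$transitions <- tr

  ec <- p$economics
  ec$cost <- vapply(ec$cost_dist, sample_parameter, 0)
  dw <- mapply(function(lo, mode, hi) {
    if (lo == hi) mode else sample_parameter(dist_triangular_95ui(lo, mode, hi))
  }, ec$daly_lo, ec$daly_weight, ec$daly_hi)
  ec$daly_weight <- pmin(1, pmax(0, dw))
  # the death state contributes via YLL only
  ec$daly_weight[ec$state == p$state_space$death_state] <- 0
  ec$cost[ec$state == p$state_space$death_state] <- 0
  p$economics <- ec
  p
}

#' Probabilistic sensitivity analysis
#'
#' Re-runs the full two-strategy model `n_iterations` times with every
#' uncertain parameter drawn from its descriptor (gamma costs, triangular
#' DALY weights, per-transition descriptors with row renormalization), and
#' records the incremental cost and DALYs averted of screening versus
#' standard care. Fully reproducible given `seed`. Iterations yielding an
#' invalid transition matrix are redrawn (at most 100 attempts each).
#'
#' @param params An `rhd_params`.
#' @param n_iterations Number of iterations (>= 1).
#' @param seed Integer seed.
#' @param accrual,yll_mode Passed to [run_strategy()].
#' @return An `rhd_psa`: `iterations` data frame with columns
#'   `delta_cost`, `delta_effect`, `cost_standard`, `cost_screening`,
#'   `dalys_standard`, `dalys_screening`; plus `seed`, `n_iterations`,
#'   `n_redraws` and the base-case `threshold`.
#' @export
run_psa <- function(params, n_iterations = 10000, seed = 1,
                    accrual = c("end", "begin"),
                    yll_mode = c("stream", "lump")) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  accrual <- match.arg(accrual)
  yll_mode <- match.arg(yll_mode)
  set.seed(seed)
  out <- base::matrix(NA_real_, n_iterations, 6,
                      dimnames = list(NULL,
                        c("delta_cost", "delta_effect", "cost_standard",
                          "cost_screening", "dalys_standard",
                          "dalys_screening")))
  n_redraws <- 0L
  for (i in seq_len(n_iterations)) {
    for (attempt in seq_len(100)) {
      res <- tryCatch(run_cea(sample_params(params), accrual, yll_mode),
                      error = function(e) NULL)
      if (!is.null(res)) break
      n_redraws <- n_redraws + 1L
      if (attempt == 100)
        stop("iteration ", i, " rejected 100 times; bundle descriptors ",
             "generate invalid transition matrices")
    }
    out[i, ] <- c(res$comparison$delta_cost, res$comparison$delta_effect,
                  res$standard$total_cost, res$screening$total_cost,
                  res$standard$total_dalys, res$screening$total_dalys)
  }
  if (any(!is.finite(out))) stop("non-finite PSA results")
  structure(list(iterations = as.data.frame(out), seed = seed,
                 n_iterations = n_iterations, n_redraws = n_redraws,
                 threshold = params$threshold),
            class = "rhd_psa")
}

#' @export
print.rhd_psa <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %d, %d redraws)\n",
              x$n_iterations, x$seed, x$n_redraws))
  cat(sprintf("  mean incremental cost $%.2f, mean DALYs averted %.2f\n",
              mean(x$iterations$delta_cost), mean(x$iterations$delta_effect)))
  cat(sprintf("  P(cost-effective at $%.2f/DALY) = %.3f\n", x$threshold,
              acceptance_probability(x, x$threshold)))
  invisible(x)
}

#' Probability of cost-effectiveness at a threshold
#'
#' Fraction of PSA iterations with positive net monetary benefit,
#' `lambda * delta_effect - delta_cost > 0`.
#'
#' @param psa An `rhd_psa`.
#' @param lambda Willingness-to-pay threshold(s).
#' @return Numeric vector of probabilities, one per `lambda`.
#' @export
acceptance_probability <- function(psa, lambda) {
  vapply(lambda, function(l)
    mean(l * psa$iterations$delta_effect - psa$iterations$delta_cost > 0), 0)
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa An `rhd_psa`.
#' @param thresholds Strictly increasing grid of willingness-to-pay values;
#'   defaults to 0 to twice the base-case threshold in 200 steps.
#' @return An `rhd_ceac` data frame with columns `threshold`, `probability`.
#' @export
ceac <- function(psa, thresholds = NULL) {
  if (is.null(thresholds))
    thresholds <- seq(0, 2 * psa$threshold, length.out = 201)
  if (!length(thresholds)) stop("threshold grid is empty")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("threshold grid must be strictly increasing")
  structure(data.frame(threshold = thresholds,
                       probability = acceptance_probability(psa, thresholds)),
            class = c("rhd_ceac", "data.frame"))
}

# ---- one-way sensitivity ---------------------------------------------------

#' Set one addressable parameter
#'
#' Parameter ids: `discount_rate`, `threshold`, `cohort_size`, `start_age`,
#' `prophylaxis_effect_definite`, `prophylaxis_effect_mild`,
#' `cost:<state>`, `daly:<state>`, `trans:<from>-><to>`,
#' `screening:<field>`.
#'
#' @param params An `rhd_params`.
#' @param parameter_id Address string.
#' @param value New value; invariants are re-checked and violations raised
#'   with the parameter named.
#' @return The modified `rhd_params`.
#' @export
set_parameter <- function(params, parameter_id, value) {
  p <- params
  fail <- function(msg) stop("parameter '", parameter_id, "': ", msg)
  prob_ok <- function(v) if (v < 0 || v > 1) fail("value outside [0,1]")
  if (parameter_id %in% c("discount_rate", "threshold", "cohort_size",
                          "start_age")) {
    if (value < 0) fail("value must be >= 0")
    p[[parameter_id]] <- value
  } else if (parameter_id == "prophylaxis_effect_definite") {
    prob_ok(value); p$prophylaxis$effect_definite <- value
  } else if (parameter_id == "prophylaxis_effect_mild") {
    prob_ok(value); p$prophylaxis$effect_mild <- value
  } else if (grepl("^cost:", parameter_id)) {
    s <- sub("^cost:", "", parameter_id)
    i <- match(s, p$economics$state)
    if (is.na(i)) fail("unknown state")
    if (value < 0) fail("cost must be >= 0")
    p$economics$cost[i] <- value
  } else if (grepl("^daly:", parameter_id)) {
    s <- sub("^daly:", "", parameter_id)
    i <- match(s, p$economics$state)
    if (is.na(i)) fail("unknown state")
    prob_ok(value)
    p$economics$daly_weight[i] <- value
    p$economics$daly_lo[i] <- min(p$economics$daly_lo[i], value)
    p$economics$daly_hi[i] <- max(p$economics$daly_hi[i], value)
  } else if (grepl("^trans:", parameter_id)) {
    key <- sub("^trans:", "", parameter_id)
    ft <- strsplit(key, "->", fixed = TRUE)[[1]]
    if (length(ft) != 2) fail("expected trans:<from>-><to>")
    i <- which(p$transitions$from == ft[1] & p$transitions$to == ft[2])
    if (!length(i)) fail("no such transition entry")
    prob_ok(value)
    p$transitions$probability[i] <- value
    # tunnel rows carry no self-loop: rebalance the sibling destinations so
    # the row still allocates its full mass
    if (ft[1] %in% p$state_space$tunnel_states) {
      j <- which(p$transitions$from == ft[1] & p$transitions$to != ft[2])
      rest <- sum(p$transitions$probability[j])
      if (rest > 0)
        p$transitions$probability[j] <-
          p$transitions$probability[j] * (1 - value) / rest
      else if (length(j))
        p$transitions$probability[j[1]] <- 1 - value
    }
  } else if (grepl("^screening:", parameter_id)) {
    f <- sub("^screening:", "", parameter_id)
    if (!f %in% setdiff(.screening_keys, "owsa")) fail("unknown screening field")
    if (grepl("cost", f)) { if (value < 0) fail("cost must be >= 0") }
    else prob_ok(value)
    p$screening[[f]] <- value
  } else fail("unknown parameter id")
  validate_params(p)
  p
}

base_icer <- function(params, accrual = "end", yll_mode = "stream") {
  run_cea(params, accrual, yll_mode)$comparison$icer
}

#' One-way sweep of a single parameter
#'
#' Evaluates the deterministic model with the parameter at its low and high
#' bound, everything else at base, and reports the two ICERs and their
#' absolute spread.
#'
#' @param params An `rhd_params`.
#' @param parameter_id Address accepted by [set_parameter()].
#' @param low,high Sweep endpoints, `low <= high`.
#' @param accrual,yll_mode Passed to [run_strategy()].
#' @return One-row data frame: `parameter`, `low`, `high`, `icer_low`,
#'   `icer_high`, `spread`.
#' @export
one_way_sweep <- function(params, parameter_id, low, high,
                          accrual = "end", yll_mode = "stream") {
  if (low > high) stop("low must be <= high")
  icer_lo <- base_icer(set_parameter(params, parameter_id, low),
                       accrual, yll_mode)
  icer_hi <- base_icer(set_parameter(params, parameter_id, high),
                       accrual, yll_mode)
  data.frame(parameter = parameter_id, low = low, high = high,
             icer_low = icer_lo, icer_high = icer_hi,
             spread = abs(icer_hi - icer_lo),
             stringsAsFactors = FALSE)
}

# Enumerate sweepable parameters with bounds derived from their descriptors.
sweep_registry <- function(params) {
  rows <- list()
  add <- function(id, lo, hi)
    rows[[length(rows) + 1]] <<- data.frame(parameter = id, low = lo, high = hi,
                                            stringsAsFactors = FALSE)
  add("discount_rate", 0, 0.05)      # 0% to 5%
  tr <- params$transitions
  out_mass <- vapply(tr$from, function(s)
    sum(tr$probability[tr$from == s & tr$to != s]), 0)
  for (i in seq_len(nrow(tr))) {
    ci <- dist_interval(tr$dist[[i]])
    if (ci[2] <= ci[1]) next
    # cap the upper endpoint so the source row stays sub-stochastic
    hi_cap <- if (tr$from[i] == tr$to[i]) 1
              else tr$probability[i] + (1 - out_mass[i])
    lo <- max(0, ci[1]); hi <- min(1, ci[2], hi_cap)
    if (hi > lo) add(sprintf("trans:%s->%s", tr$from[i], tr$to[i]), lo, hi)
  }
  ec <- params$economics
  for (i in seq_len(nrow(ec))) {
    ci <- dist_interval(ec$cost_dist[[i]])
    if (ci[2] > ci[1]) add(paste0("cost:", ec$state[i]), ci[1], ci[2])
    if (ec$daly_hi[i] > ec$daly_lo[i])
      add(paste0("daly:", ec$state[i]), ec$daly_lo[i], ec$daly_hi[i])
  }
  for (f in names(params$screening$owsa)) {
    b <- params$screening$owsa[[f]]
    add(paste0("screening:", f), b[1], b[2])
  }
  add("prophylaxis_effect_definite", 0, params$prophylaxis$effect_definite)
  add("prophylaxis_effect_mild",
      max(0, params$prophylaxis$effect_mild - 0.25),
      min(1, params$prophylaxis$effect_mild + 0.25))
  do.call(rbind, rows)
}

#' One-way (tornado) sensitivity analysis over all bounded parameters
#'
#' Sweeps every parameter that carries usable bounds — each transition and
#' cost over its descriptor's 95% interval, each DALY weight over its
#' uncertainty interval, screening accuracies over their configured sweep
#' endpoints, the prophylaxis effects, and always the discount rate over
#' 0–5% — and returns the rows sorted by decreasing ICER spread. Parameters
#' without bounds (point descriptors) are skipped with a message.
#'
#' @param params An `rhd_params`.
#' @param accrual,yll_mode Passed to [run_strategy()].
#' @return An `rhd_tornado` data frame: `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `spread`, plus attribute `base_icer`.
#' @export
tornado_analysis <- function(params, accrual = "end", yll_mode = "stream") {
  reg <- sweep_registry(params)
  skipped <- setdiff(
    c(sprintf("trans:%s->%s", params$transitions$from, params$transitions$to),
      paste0("cost:", params$economics$state),
      paste0("daly:", params$economics$state)),
    reg$parameter)
  if (length(skipped))
    message("skipped ", length(skipped),
            " parameter(s) without uncertainty bounds")
  rows <- lapply(seq_len(nrow(reg)), function(i)
    one_way_sweep(params, reg$parameter[i], reg$low[i], reg$high[i],
                  accrual, yll_mode))
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  structure(out, class = c("rhd_tornado", "data.frame"),
            base_icer = base_icer(params, accrual, yll_mode))
}
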