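# Shared fixtures built in code.

# Random row-stochastic matrix over k states, last state absorbing death.
random_stochastic_matrix <- function(k, ids = paste0("S", seq_len(k))) {
  m <- matrix(stats::rexp(k * k), k, k, dimnames = list(ids, ids))
  m <- m / rowSums(m)
  m[k, ] <- 0
  m[k, k] <- 1
  m
}

# Independent matrix-power oracle (repeated squaring not needed at n <= 30).
mat_power <- function(m, t) {
  out <- diag(nrow(m))
  for (i in seq_len(t)) out <- out %*% m
  out
}

# Replace every uncertainty descriptor by a point mass at its current value,
# so PSA iterations degenerate to the deterministic run.
degenerate_params <- function(p) {
  p$transitions$dist <- lapply(p$transitions$probability, dist_point)
  p$economics$cost_dist <- lapply(p$economics$cost, dist_point)
  p$economics$daly_lo <- p$economics$daly_weight
  p$economics$daly_hi <- p$economics$daly_weight
  p
}

# Small 4-state screening model (healthy A, undiagnosed sick B, diagnosed
# sick Fd, dead Z) plus an unreachable state O. Screening moves part of B to
# the cheaper-progressing Fd at cycle 0, so the strategies genuinely differ
# (positive DALYs averted, positive incremental cost).
make_screen_toy <- function(sens = 0.8, spec = 1, scan_cost = 5,
                            fp_cost = 0, discount = 0.03, n_cycles = 20) {
  ss <- state_space(c("A", "B", "Fd", "O", "Z"),
                    c("Healthy", "Undiagnosed sick", "Diagnosed sick",
                      "Orphan", "Dead"),
                    death_state = "Z")
  tr <- data.frame(from = c("A", "B", "Fd"),
                   to = c("Z", "Z", "Z"),
                   probability = c(0.005, 0.20, 0.05),
                   stringsAsFactors = FALSE)
  tr$dist <- lapply(tr$probability, function(x) dist_beta_mean_n(x, 50))
  ec <- data.frame(state = c("A", "B", "Fd", "O", "Z"),
                   cost = c(0, 0, 50, 100, 0),
                   daly_weight = c(0, 0.10, 0.05, 0, 0),
                   daly_lo = c(0, 0.05, 0.02, 0, 0),
                   daly_hi = c(0, 0.15, 0.08, 0, 0),
                   stringsAsFactors = FALSE)
  ec$cost_dist <- list(dist_point(0), dist_point(0),
                       dist_gamma_mean_var(50, 100),
                       dist_gamma_mean_var(100, 400), dist_point(0))
  parameter_set(
    state_space = ss, transitions = tr, economics = ec,
    life_table = data.frame(age = 0:100,
                            expectancy = pmax(2, 70 - 0.7 * (0:100))),
    initial_distribution = c(A = 0.9, B = 0.1),
    cohort_size = 1000, n_cycles = n_cycles, start_age = 11,
    discount_rate = discount, threshold = 5000,
    screening = list(cost_per_scan = scan_cost,
                     sensitivity_borderline = sens,
                     sensitivity_definite = 0, specificity = spec,
                     false_positive_followup_cost = fp_cost,
                     screened_fraction = 1,
                     owsa = list(sensitivity_borderline = c(0.5, 0.9))),
    prophylaxis = list(effect_definite = 0, effect_mild = 0,
                       definite_from = NA, definite_to = character(),
                       mild_from = NA, mild_to = character()),
    roles = list(disease_free = "A", undiagnosed_borderline = "B",
                 diagnosed_borderline = "Fd", undiagnosed_definite = NA,
                 treated_definite = NA,
                 borderline_states = c("B", "Fd"), definite_states = NA),
    allowed_edges = data.frame(from = c("A", "B", "Fd", "O"),
                               to = c("Z", "Z", "Z", "Z"),
                               stringsAsFactors = FALSE))
}
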