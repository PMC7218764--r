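# Synthetic parameter-bundle generator.
#
# The generator's job is structural fidelity: complete bundles with the
# canonical 15-state topology, valid stochastic rows, gamma cost
# descriptors anchored on the published per-state cost means, triangular
# DALY-weight descriptors and a monotone life table — so that every pipeline
# stage is exercisable without external inputs. Transition magnitudes are
# drawn from broad documented ranges and are not estimates of any study's
# values.

# Canonical 15-state space: No RHD (A); undiagnosed/diagnosed asymptomatic
# borderline (B/F); untreated/treated asymptomatic definite (C/G);
# untreated/treated mild clinical (D/H); untreated/treated severe clinical
# (E/I); resolved-after-treatment states (RG/RH/RI); surgery tunnel (X);
# post-surgery (K); death (Z).
canonical_states <- function() {
  data.frame(
    id = c("A", "B", "C", "D", "E", "F", "G", "H", "I",
           "RG", "RH", "RI", "K", "X", "Z"),
    label = c("No RHD",
              "Undiagnosed Asymptomatic Borderline RHD",
              "Untreated Asymptomatic Definite RHD",
              "Untreated Mild Clinical RHD",
              "Untreated Severe Clinical RHD",
              "Diagnosed Borderline RHD",
              "Treated Asymptomatic Definite RHD",
              "Treated Mild Clinical RHD",
              "Treated Severe Clinical RHD",
              "Resolved RHD (from treated asymptomatic definite)",
              "Resolved RHD (from treated mild clinical)",
              "Resolved RHD (from treated severe clinical)",
              "Post Surgery", "Surgery", "Death"),
    stringsAsFactors = FALSE)
}

# Directed edges of the model diagram with the generator's sampling ranges
# (annual probabilities). Progression edges advance disease, care edges move
# untreated symptomatic patients into treated states, mortality edges go to
# Z. The surgery tunnel X fully allocates its mass (K gets the draw, Z the
# remainder).
canonical_edges <- function() {
  e <- function(from, to, lo, hi, class)
    data.frame(from = from, to = to, lo = lo, hi = hi, class = class,
               stringsAsFactors = FALSE)
  rbind(
    e("A", "B", 0.002, 0.008, "incidence"),
    e("A", "C", 0.0005, 0.002, "incidence"),
    e("A", "Z", 0.0005, 0.0015, "mortality"),
    e("B", "A", 0.10, 0.30, "regression"),
    e("B", "C", 0.05, 0.15, "progression"),
    e("B", "Z", 0.0005, 0.0015, "mortality"),
    e("C", "D", 0.05, 0.12, "progression"),
    e("C", "X", 0.01, 0.03, "progression"),
    e("C", "Z", 0.01, 0.03, "mortality"),
    e("D", "E", 0.08, 0.15, "progression"),
    e("D", "H", 0.10, 0.20, "care"),
    e("D", "X", 0.02, 0.05, "progression"),
    e("D", "Z", 0.02, 0.04, "mortality"),
    e("E", "I", 0.10, 0.20, "care"),
    e("E", "X", 0.10, 0.20, "progression"),
    e("E", "Z", 0.10, 0.20, "mortality"),
    e("F", "A", 0.10, 0.30, "regression"),
    e("F", "G", 0.05, 0.15, "progression"),
    e("F", "Z", 0.0005, 0.0015, "mortality"),
    e("G", "H", 0.05, 0.12, "progression"),
    e("G", "RG", 0.02, 0.08, "regression"),
    e("G", "X", 0.005, 0.02, "progression"),
    e("G", "Z", 0.005, 0.02, "mortality"),
    e("H", "I", 0.08, 0.15, "progression"),
    e("H", "RH", 0.02, 0.08, "regression"),
    e("H", "X", 0.02, 0.06, "progression"),
    e("H", "Z", 0.01, 0.03, "mortality"),
    e("I", "X", 0.10, 0.20, "progression"),
    e("I", "RI", 0.01, 0.05, "regression"),
    e("I", "Z", 0.05, 0.15, "mortality"),
    e("RG", "Z", 0.0005, 0.0015, "mortality"),
    e("RH", "Z", 0.001, 0.003, "mortality"),
    e("RI", "Z", 0.005, 0.015, "mortality"),
    e("K", "X", 0.01, 0.03, "progression"),
    e("K", "Z", 0.01, 0.03, "mortality"),
    e("X", "K", 0.85, 0.95, "tunnel"),
    e("X", "Z", 0.05, 0.15, "mortality")
  )
}

# Published 2017-USD annual cost means per state; zero-cost states carry a
# point descriptor, costed states a shared-variance gamma.
canonical_costs <- function() {
  c(A = 0, B = 0, C = 0, D = 0, E = 0,
    F = 25.84, G = 93.93, H = 337.47, I = 854.00,
    RG = 93.93, RH = 337.47, RI = 854.00,
    K = 854.00, X = 4120.51, Z = 0)
}

# Synthetic DALY weights (mode, lo, hi): asymptomatic states carry no
# disability apart from the "knowing" disutility of a borderline or treated
# diagnosis; clinical states use mild/severe valvular-disease-tier weights.
canonical_daly <- function() {
  w <- function(state, mode, lo, hi)
    data.frame(state = state, daly_weight = mode, daly_lo = lo, daly_hi = hi,
               stringsAsFactors = FALSE)
  rbind(
    w("A", 0, 0, 0), w("B", 0, 0, 0), w("C", 0, 0, 0),
    w("D", 0.041, 0.026, 0.062), w("E", 0.179, 0.122, 0.251),
    w("F", 0.012, 0.004, 0.020),          # disutility of knowing, borderline
    w("G", 0.006, 0.002, 0.012),
    w("H", 0.041, 0.026, 0.062), w("I", 0.179, 0.122, 0.251),
    w("RG", 0, 0, 0), w("RH", 0, 0, 0), w("RI", 0, 0, 0),
    w("K", 0.049, 0.031, 0.072), w("X", 0.080, 0.050, 0.110),
    w("Z", 0, 0, 0))
}

canonical_roles <- function() {
  list(disease_free = "A",
       undiagnosed_borderline = "B",
       diagnosed_borderline = "F",
       undiagnosed_definite = "C",
       treated_definite = "G",
       borderline_states = c("B", "F"),
       definite_states = c("C", "G"))
}

canonical_screening <- function() {
  list(cost_per_scan = 6.60,
       sensitivity_borderline = 0.65,
       sensitivity_definite = 0.90,
       specificity = 0.95,
       false_positive_followup_cost = 30.00,
       screened_fraction = 1.0,
       owsa = list(sensitivity_borderline = c(0.50, 0.80),
                   sensitivity_definite = c(0.80, 1.00),
                   specificity = c(0.90, 0.99)))
}

canonical_prophylaxis <- function() {
  list(effect_definite = 0.50, effect_mild = 0.50,
       definite_from = "G", definite_to = c("H", "X"),
       mild_from = "H", mild_to = "I")
}

make_life_table <- function(start_expectancy = 71.5, decline = 0.8,
                            floor = 2.5, max_age = 100) {
  age <- 0:max_age
  data.frame(age = age,
             expectancy = pmax(floor, start_expectancy - decline * age))
}

#' Configuration for the synthetic bundle generator
#'
#' @param seed Integer seed; the bundle is a deterministic function of the
#'   full configuration.
#' @param disease_prevalence Fraction of the cohort with latent RHD at cycle
#'   0 (default 0.042, the screening-study prevalence of asymptomatic RHD).
#' @param borderline_definite_ratio How the prevalent cases split between
#'   borderline and definite lesions (default 3:1, typical of screening
#'   series; synthetic).
#' @param progression_scale,mortality_scale,cost_scale Positive multipliers
#'   applied to progression probabilities, mortality probabilities and cost
#'   means.
#' @param life_table_shape Numeric `c(start_expectancy, decline_per_year)`.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1, disease_prevalence = 0.042,
                             borderline_definite_ratio = 3,
                             progression_scale = 1, mortality_scale = 1,
                             cost_scale = 1,
                             life_table_shape = c(71.5, 0.8)) {
  if (disease_prevalence < 0 || disease_prevalence > 1)
    stop("disease_prevalence must lie in [0,1]")
  if (progression_scale <= 0 || mortality_scale <= 0 || cost_scale <= 0)
    stop("scales must be positive")
  if (borderline_definite_ratio < 0)
    stop("borderline_definite_ratio must be >= 0")
  structure(list(seed = seed, disease_prevalence = disease_prevalence,
                 borderline_definite_ratio = borderline_definite_ratio,
                 progression_scale = progression_scale,
                 mortality_scale = mortality_scale,
                 cost_scale = cost_scale,
                 life_table_shape = life_table_shape),
            class = "generator_config")
}

#' Generate a complete synthetic parameter bundle
#'
#' Emits a fully validated `rhd_params` on the canonical 15-state topology:
#' transition probabilities drawn uniformly from the documented per-edge
#' ranges (then scaled and, if needed, row-renormalized), shared-variance
#' gamma cost descriptors on the published cost means, triangular DALY
#' descriptors, a linear-decline life table and an initial distribution
#' placing `disease_prevalence` of the cohort in the undiagnosed latent
#' states. Deterministic given the configuration (the global RNG seed is set
#' from `config$seed`).
#'
#' @param config A [generator_config()].
#' @return An `rhd_params`.
#' @export
generate_bundle <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  states <- canonical_states()
  ss <- state_space(states$id, states$label, death_state = "Z",
                    tunnel_states = "X")
  edges <- canonical_edges()
  prob <- stats::runif(nrow(edges), edges$lo, edges$hi)
  scale <- ifelse(edges$class %in% c("progression", "incidence"),
                  config$progression_scale,
                  ifelse(edges$class == "mortality",
                         config$mortality_scale, 1))
  prob <- pmin(1, prob * scale)
  # tunnel row must allocate exactly: X->Z takes the complement of X->K
  k <- which(edges$from == "X" & edges$to == "K")
  z <- which(edges$from == "X" & edges$to == "Z")
  prob[z] <- 1 - prob[k]
  # renormalize any over-full non-tunnel row
  for (s in setdiff(unique(edges$from), "X")) {
    i <- which(edges$from == s)
    if (sum(prob[i]) > 1) prob[i] <- prob[i] / sum(prob[i])
  }
  tr <- data.frame(from = edges$from, to = edges$to, probability = prob,
                   stringsAsFactors = FALSE)
  tr$dist <- lapply(prob, function(p)
    if (p %in% c(0, 1)) dist_point(p) else dist_beta_mean_n(p, 100))

  costs <- canonical_costs() * config$cost_scale
  shared_var <- (0.30 * costs[["X"]])^2
  ec <- canonical_daly()
  ec$cost <- costs[ec$state]
  ec$cost_dist <- lapply(ec$cost, function(cst)
    if (cst == 0) dist_point(0) else dist_gamma_mean_var(cst, shared_var))
  ec <- ec[c("state", "cost", "cost_dist", "daly_weight", "daly_lo", "daly_hi")]

  prev <- config$disease_prevalence
  r <- config$borderline_definite_ratio
  fb <- if (prev == 0) 0 else r / (1 + r)
  init <- c(A = 1 - prev, B = prev * fb, C = prev * (1 - fb))

  parameter_set(
    state_space = ss, transitions = tr, economics = ec,
    life_table = make_life_table(config$life_table_shape[1],
                                 config$life_table_shape[2]),
    initial_distribution = init,
    cohort_size = 1000, n_cycles = 30, start_age = 11,
    discount_rate = 0.03, threshold = 25949.85,
    screening = canonical_screening(),
    prophylaxis = canonical_prophylaxis(),
    roles = canonical_roles(),
    allowed_edges = canonical_edges()[c("from", "to")],
    shared_cost_variance = shared_var)
}

#' Generate the 3-state toy bundle
#'
#' A reduced healthy/sick/dead model whose discounted outcomes have closed
#' geometric-series forms, used as independent oracles for the accrual
#' engine: with stay-sick probability `p = 1 - p_recover - p_die` and a
#' cohort starting entirely sick, the discounted sick-years after `n` cycles
#' are `sum_{t=1..n} p^t (1+r)^(-t)`.
#'
#' @param p_recover Annual sick-to-healthy probability.
#' @param p_die Annual sick-to-dead probability.
#' @param sick_cost Annual cost of the sick state (point descriptor).
#' @param sick_weight Disability weight of the sick state.
#' @param n_cycles,discount_rate,cohort_size Cohort settings.
#' @return An `rhd_params`.
#' @export
generate_toy_bundle <- function(p_recover = 0.4, p_die = 0,
                                sick_cost = 100, sick_weight = 0.2,
                                n_cycles = 30, discount_rate = 0.03,
                                cohort_size = 1) {
  if (p_recover + p_die > 1) stop("p_recover + p_die must be <= 1")
  ss <- state_space(c("healthy", "sick", "dead"),
                    c("Healthy", "Sick", "Dead"), death_state = "dead")
  tr <- data.frame(from = c("sick", "sick"), to = c("healthy", "dead"),
                   probability = c(p_recover, p_die),
                   stringsAsFactors = FALSE)
  tr$dist <- list(dist_point(p_recover), dist_point(p_die))
  ec <- data.frame(state = c("healthy", "sick", "dead"),
                   cost = c(0, sick_cost, 0),
                   daly_weight = c(0, sick_weight, 0),
                   daly_lo = c(0, sick_weight, 0),
                   daly_hi = c(0, sick_weight, 0),
                   stringsAsFactors = FALSE)
  ec$cost_dist <- list(dist_point(0), dist_point(sick_cost), dist_point(0))
  parameter_set(
    state_space = ss, transitions = tr, economics = ec,
    life_table = make_life_table(), initial_distribution = c(sick = 1),
    cohort_size = cohort_size, n_cycles = n_cycles, start_age = 11,
    discount_rate = discount_rate, threshold = 1000,
    screening = list(cost_per_scan = 0, sensitivity_borderline = 0,
                     sensitivity_definite = 0, specificity = 1,
                     false_positive_followup_cost = 0,
                     screened_fraction = 1),
    prophylaxis = list(effect_definite = 0, effect_mild = 0,
                       definite_from = NA, definite_to = character(),
                       mild_from = NA, mild_to = character()),
    roles = list(disease_free = "healthy",
                 undiagnosed_borderline = NA, diagnosed_borderline = NA,
                 undiagnosed_definite = NA, treated_definite = NA,
                 borderline_states = NA, definite_states = NA),
    allowed_edges = data.frame(from = c("sick", "sick", "healthy"),
                               to = c("healthy", "dead", "dead"),
                               stringsAsFactors = FALSE))
}
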