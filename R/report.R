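# Orchestration and reporting: deterministic run, PSA, tornado and external
# validation, each optionally writing CSV/JSON outputs plus a run manifest
# into an output directory.

resolve_params <- function(bundle) {
  if (inherits(bundle, "rhd_params")) return(list(params = bundle, path = NA))
  list(params = load_parameter_bundle(bundle), path = bundle)
}

bundle_hash <- function(path) {
  if (is.na(path)) return(NA_character_)
  cfg <- if (dir.exists(path)) file.path(path, "config.yaml") else path
  files <- c(cfg, file.path(dirname(cfg),
                            unlist(yaml::read_yaml(cfg)$files)))
  paste(unname(tools::md5sum(files)), collapse = "")
}

write_manifest <- function(out_dir, subcommand, bundle_path, seed, files) {
  manifest <- list(
    subcommand = subcommand,
    bundle = if (is.na(bundle_path)) "in-memory" else bundle_path,
    bundle_md5 = bundle_hash(bundle_path),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    tool = paste0("rhdcea ", as.character(utils::packageVersion("rhdcea"))),
    outputs = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

ensure_dir <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_dir
}

#' Deterministic analysis with file outputs
#'
#' Runs [run_cea()] and, when `out_dir` is given, writes `results.json`,
#' `results.csv`, the two cohort traces and a run manifest.
#'
#' @param bundle An `rhd_params` or a bundle path.
#' @param out_dir Optional output directory.
#' @param discount_rate,threshold Optional overrides of the bundle values.
#' @param accrual,yll_mode Passed to [run_strategy()].
#' @return The `rhd_cea` result, invisibly when writing files.
#' @export
cmd_run <- function(bundle, out_dir = NULL, discount_rate = NULL,
                    threshold = NULL, accrual = "end", yll_mode = "stream") {
  b <- resolve_params(bundle)
  params <- b$params
  if (!is.null(discount_rate))
    params <- set_parameter(params, "discount_rate", discount_rate)
  if (!is.null(threshold))
    params <- set_parameter(params, "threshold", threshold)
  res <- run_cea(params, accrual, yll_mode)
  if (is.null(out_dir)) return(res)
  ensure_dir(out_dir)
  cmp <- res$comparison
  tab <- data.frame(
    strategy = c("standard_care", "screening"),
    total_cost = round(c(res$standard$total_cost, res$screening$total_cost), 2),
    total_dalys = round(c(res$standard$total_dalys, res$screening$total_dalys), 2),
    yld = round(c(res$standard$yld, res$screening$yld), 2),
    yll = round(c(res$standard$yll, res$screening$yll), 2),
    one_time_costs = round(c(res$standard$one_time_costs,
                             res$screening$one_time_costs), 2))
  utils::write.csv(tab, file.path(out_dir, "results.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(standard_care = list(total_cost = res$standard$total_cost,
                              total_dalys = res$standard$total_dalys),
         screening = list(total_cost = res$screening$total_cost,
                          total_dalys = res$screening$total_dalys),
         comparison = list(delta_cost = cmp$delta_cost,
                           dalys_averted = cmp$delta_effect,
                           icer = cmp$icer, label = cmp$label,
                           nmb = cmp$nmb, threshold = cmp$threshold)),
    file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  export_trace(res$standard$trace, file.path(out_dir, "trace_standard.csv"),
               params$start_age)
  export_trace(res$screening$trace, file.path(out_dir, "trace_screening.csv"),
               params$start_age)
  write_manifest(out_dir, "run", b$path, NA,
                 c("results.csv", "results.json", "trace_standard.csv",
                   "trace_screening.csv"))
  invisible(res)
}

#' Probabilistic analysis with file outputs
#'
#' Runs [run_psa()] and [ceac()]; when `out_dir` is given, writes
#' `psa_iterations.csv`, `ceac.csv`, a summary JSON with the acceptance
#' probability at the bundle threshold, and a manifest.
#'
#' @param bundle An `rhd_params` or a bundle path.
#' @param n_iterations,seed Passed to [run_psa()].
#' @param thresholds Optional CEAC grid.
#' @param out_dir Optional output directory.
#' @return List with `psa`, `ceac` and `acceptance_at_threshold`.
#' @export
cmd_psa <- function(bundle, n_iterations = 10000, seed = 1,
                    thresholds = NULL, out_dir = NULL) {
  b <- resolve_params(bundle)
  psa <- run_psa(b$params, n_iterations, seed)
  curve <- ceac(psa, thresholds)
  acc <- acceptance_probability(psa, b$params$threshold)
  if (!is.null(out_dir)) {
    ensure_dir(out_dir)
    it <- cbind(iteration = seq_len(nrow(psa$iterations)), psa$iterations)
    utils::write.csv(it, file.path(out_dir, "psa_iterations.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(curve), file.path(out_dir, "ceac.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(n_iterations = n_iterations, seed = seed,
           threshold = b$params$threshold,
           acceptance_at_threshold = acc,
           n_redraws = psa$n_redraws),
      file.path(out_dir, "psa_summary.json"), auto_unbox = TRUE, digits = NA)
    write_manifest(out_dir, "psa", b$path, seed,
                   c("psa_iterations.csv", "ceac.csv", "psa_summary.json"))
  }
  list(psa = psa, ceac = curve, acceptance_at_threshold = acc)
}

#' Tornado analysis with file outputs
#'
#' Runs [tornado_analysis()]; when `out_dir` is given writes `tornado.csv`
#' (rows sorted by decreasing ICER spread; the 0–5% discount-rate sweep is
#' always among them) and a manifest.
#'
#' @param bundle An `rhd_params` or a bundle path.
#' @param out_dir Optional output directory.
#' @return The `rhd_tornado` data frame.
#' @export
cmd_tornado <- function(bundle, out_dir = NULL) {
  b <- resolve_params(bundle)
  tor <- tornado_analysis(b$params)
  if (!is.null(out_dir)) {
    ensure_dir(out_dir)
    out <- as.data.frame(tor)
    out[c("icer_low", "icer_high", "spread")] <-
      round(out[c("icer_low", "icer_high", "spread")], 2)
    utils::write.csv(out, file.path(out_dir, "tornado.csv"), row.names = FALSE)
    write_manifest(out_dir, "tornado", b$path, NA, "tornado.csv")
  }
  tor
}

#' External validation against observed age-band prevalences
#'
#' Runs the standard-care cohort and compares the model-predicted prevalence
#' of a state class (borderline or definite latent RHD, per the bundle's
#' role mapping) in each observed age band with the observed prevalence.
#'
#' @param bundle An `rhd_params` or a bundle path.
#' @param observed Data frame with columns `age_lo`, `age_hi`,
#'   `state_class` (a role name ending in `_states`, e.g.
#'   `"borderline_states"`) and `observed` (proportion).
#' @param out_dir Optional output directory for `validation.csv`.
#' @return Data frame with `predicted`, `observed`, `abs_diff` and
#'   `rel_diff` (`(predicted - observed) / observed`) per band.
#' @export
cmd_validate <- function(bundle, observed, out_dir = NULL) {
  b <- resolve_params(bundle)
  params <- b$params
  out <- observed
  out$predicted <- rep(NA_real_, nrow(out))
  if (nrow(observed)) {
    trace <- run_strategy(build_standard_care(params), params)$trace
    for (i in seq_len(nrow(observed))) {
      cls <- observed$state_class[i]
      states <- params$roles[[cls]]
      if (is.null(states) || all(is.na(states)))
        stop("unknown state class '", cls, "' in observed table")
      out$predicted[i] <- prevalence_by_ageband(
        trace, params$start_age, states,
        observed$age_lo[i], observed$age_hi[i],
        params$state_space$death_state)
    }
  }
  out$abs_diff <- out$predicted - out$observed
  out$rel_diff <- ifelse(out$observed == 0, NA, out$abs_diff / out$observed)
  if (!is.null(out_dir)) {
    ensure_dir(out_dir)
    utils::write.csv(out, file.path(out_dir, "validation.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, "validate", b$path, NA, "validation.csv")
  }
  out
}
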