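# Cohort state-transition engine: matrix assembly, trace propagation and
# age-band prevalence summaries.

#' Assemble a transition matrix from transition entries
#'
#' Builds the row-stochastic annual transition matrix: unspecified diagonal
#' entries are set to the complement of the specified outgoing mass, the
#' death row is forced absorbing, and tunnel states (single-cycle
#' pass-through) must have their outgoing mass fully specified since their
#' self-transition is zero by construction.
#'
#' @param transitions Data frame with `from`, `to`, `probability` columns.
#' @param state_space An [state_space()] object.
#' @return A square numeric matrix with state ids as dimnames, class
#'   `rhd_matrix`.
#' @export
assemble_matrix <- function(transitions, state_space) {
  ids <- state_ids(state_space)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(transitions)) {
    if (any(transitions$probability < 0 | transitions$probability > 1))
      stop("transition probabilities must lie in [0,1]")
    m[cbind(match(transitions$from, ids), match(transitions$to, ids))] <-
      transitions$probability
  }
  self_specified <- ids %in% transitions$from[transitions$from == transitions$to]
  for (i in seq_len(n)) {
    out <- sum(m[i, -i])
    if (out > 1 + 1e-9)
      stop(sprintf("outgoing probabilities of state %s sum to %.12g > 1",
                   ids[i], out))
    if (ids[i] %in% state_space$tunnel_states) {
      if (self_specified[i] && m[i, i] != 0)
        stop("tunnel state ", ids[i], " cannot have a self-transition")
      if (abs(out - 1) > 1e-9)
        stop(sprintf(
          "tunnel state %s must have fully specified outgoing probabilities (sum %.12g, expected 1)",
          ids[i], out))
      m[i, i] <- 0
    } else if (!self_specified[i]) {
      m[i, i] <- 1 - out
    } else if (abs(sum(m[i, ]) - 1) > 1e-9) {
      stop(sprintf("row of state %s sums to %.12g, expected 1",
                   ids[i], sum(m[i, ])))
    }
  }
  # absorbing death
  d <- match(state_space$death_state, ids)
  m[d, ] <- 0
  m[d, d] <- 1
  structure(m, class = c("rhd_matrix", "matrix", "array"))
}

check_stochastic <- function(m, tol = 1e-9) {
  if (any(m < -tol) || any(m > 1 + tol))
    stop("transition matrix entries must lie in [0,1]")
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad))
    stop("transition matrix rows do not sum to 1: ",
         paste(sprintf("%s (%.12g)", rownames(m)[bad], rs[bad]), collapse = ", "))
  invisible(TRUE)
}

#' Run a closed cohort through the model
#'
#' Propagates the cycle-0 occupancy through `n_cycles` applications of the
#' transition matrix. Mass is conserved at every cycle. The base model is
#' cycle-constant; a list of `n_cycles` matrices (one per cycle, identical
#' dimnames) is also accepted for age-dependent extensions.
#'
#' @param matrix Row-stochastic transition matrix (states as dimnames), or a
#'   list of `n_cycles` such matrices.
#' @param initial Named per-state occupancy at cycle 0 (persons); missing
#'   states are zero.
#' @param n_cycles Number of cycles (>= 1).
#' @return An `rhd_trace`: an `(n_cycles + 1) x n_states` matrix of
#'   occupancies, rows named by cycle `0..n_cycles`.
#' @export
run_cohort <- function(matrix, initial, n_cycles) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (is.list(matrix)) {
    if (length(matrix) != n_cycles)
      stop("per-cycle matrix list must have one matrix per cycle (",
           n_cycles, ")")
    mats <- matrix
    matrix <- mats[[1]]
    for (m in mats) {
      check_stochastic(m)
      if (!identical(dimnames(m), dimnames(matrix)))
        stop("per-cycle matrices must share identical state dimnames")
    }
  } else {
    check_stochastic(matrix)
    mats <- NULL
  }
  ids <- rownames(matrix)
  x <- setNames(numeric(length(ids)), ids)
  if (is.null(names(initial)) && length(initial) == length(ids))
    names(initial) <- ids
  bad <- setdiff(names(initial), ids)
  if (length(bad)) stop("initial occupancy names unknown state(s): ",
                        paste(bad, collapse = ", "))
  x[names(initial)] <- initial
  if (any(x < 0)) stop("initial occupancies must be >= 0")
  trace <- base::matrix(0, n_cycles + 1, length(ids),
                        dimnames = list(0:n_cycles, ids))
  trace[1, ] <- x
  for (t in seq_len(n_cycles))
    trace[t + 1, ] <- trace[t, ] %*% (if (is.null(mats)) matrix else mats[[t]])
  structure(trace, class = c("rhd_trace", "matrix", "array"),
            cohort_size = sum(x))
}

#' Mean prevalence of selected states over an age band
#'
#' Averages, over the cycles whose attained age (`start_age + cycle`) lies in
#' `[age_lo, age_hi)`, the occupancy of `states_of_interest` divided by the
#' occupancy of all alive states.
#'
#' @param trace An `rhd_trace`.
#' @param start_age Age at cycle 0.
#' @param states_of_interest State ids in the numerator.
#' @param age_lo,age_hi Age band, inclusive of `age_lo`, exclusive of
#'   `age_hi`.
#' @param death_state Id of the state excluded from the alive denominator.
#' @return A proportion in `[0, 1]`.
#' @export
prevalence_by_ageband <- function(trace, start_age, states_of_interest,
                                  age_lo, age_hi, death_state) {
  ages <- start_age + as.numeric(rownames(trace))
  rows <- which(ages >= age_lo & ages < age_hi)
  if (!length(rows))
    stop(sprintf("age band [%g, %g) contains no model cycle", age_lo, age_hi))
  bad <- setdiff(states_of_interest, colnames(trace))
  if (length(bad)) stop("unknown state(s): ", paste(bad, collapse = ", "))
  alive <- setdiff(colnames(trace), death_state)
  num <- rowSums(trace[rows, states_of_interest, drop = FALSE])
  den <- rowSums(trace[rows, alive, drop = FALSE])
  if (any(den <= 0)) stop("no alive occupancy in the requested age band")
  mean(num / den)
}

#' Export a cohort trace as CSV
#'
#' @param trace An `rhd_trace`.
#' @param path Output file.
#' @param start_age Age at cycle 0, used for the `age` column.
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, path, start_age = 0) {
  cyc <- as.numeric(rownames(trace))
  out <- data.frame(cycle = cyc, age = start_age + cyc,
                    as.data.frame(unclass(trace), check.names = FALSE),
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
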