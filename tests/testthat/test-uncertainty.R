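test_that("degenerate PSA equals the deterministic run in every iteration", {
  p <- degenerate_params(make_screen_toy())
  det <- run_cea(p)$comparison
  psa <- run_psa(p, n_iterations = 5, seed = 99)
  expect_identical(psa$n_redraws, 0L)
  expect_true(all(psa$iterations$delta_cost == det$delta_cost))
  expect_true(all(psa$iterations$delta_effect == det$delta_effect))
})

test_that("the PSA is reproducible from its seed", {
  p <- make_screen_toy()
  a <- run_psa(p, 25, seed = 7)
  b <- run_psa(p, 25, seed = 7)
  expect_identical(a, b)
  c <- run_psa(p, 25, seed = 8)
  expect_false(identical(a$iterations, c$iterations))
})

test_that("sampled transition rows remain stochastic after renormalization", {
  p <- paper_fixture()
  set.seed(11)
  for (rep in 1:20) {
    q <- rhdcea:::sample_params(p)
    m <- assemble_matrix(q$transitions, q$state_space)
    expect_true(all(abs(rowSums(m) - 1) < 1e-12))
  }
})

test_that("CEAC is the NMB exceedance curve with a step at the ICER", {
  p <- degenerate_params(make_screen_toy())
  det <- run_cea(p)$comparison
  expect_gt(det$delta_effect, 0)
  expect_gt(det$delta_cost, 0)
  psa <- run_psa(p, 4, seed = 1)
  grid <- sort(unique(c(det$icer * c(0.5, 0.99, 1.01, 2), 1, det$icer)))
  curve <- ceac(psa, grid)
  # degenerate PSA: acceptance jumps 0 -> 1 exactly above the ICER
  expect_equal(curve$probability, as.numeric(grid * det$delta_effect -
                                             det$delta_cost > 0))
  expect_identical(curve$probability[curve$threshold == det$icer], 0)

  expect_equal(acceptance_probability(psa, 0), 0)       # costs always positive
  expect_equal(acceptance_probability(psa, 1e12), 1)    # effect always positive

  expect_error(ceac(psa, numeric()), "empty")
  expect_error(ceac(psa, c(2, 1)), "strictly increasing")
})

test_that("CEAC probabilities are monotone when every iteration averts DALYs", {
  p <- make_screen_toy()
  psa <- run_psa(p, 60, seed = 3)
  curve <- ceac(psa)
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  if (all(psa$iterations$delta_effect >= 0))
    expect_true(all(diff(curve$probability) >= 0))
})

test_that("acceptance probability is Monte-Carlo self-consistent across seeds", {
  p <- make_screen_toy()
  n <- 150
  p1 <- acceptance_probability(run_psa(p, n, seed = 21), p$threshold)
  p2 <- acceptance_probability(run_psa(p, n, seed = 22), p$threshold)
  pbar <- (p1 + p2) / 2
  se <- sqrt(pbar * (1 - pbar) * 2 / n)
  expect_lt(abs(p1 - p2), 2.58 * se + 1e-9)
})

test_that("set_parameter addresses every parameter family and validates", {
  p <- paper_fixture()
  expect_equal(set_parameter(p, "discount_rate", 0)$discount_rate, 0)
  expect_equal(set_parameter(p, "cost:K", 900)$economics$cost[
    p$economics$state == "K"], 900)
  expect_equal(set_parameter(p, "daly:F", 0.02)$economics$daly_weight[
    p$economics$state == "F"], 0.02)
  q <- set_parameter(p, "trans:B->C", 0.2)
  expect_equal(q$transitions$probability[q$transitions$from == "B" &
                                         q$transitions$to == "C"], 0.2)
  expect_equal(set_parameter(p, "screening:specificity", 0.8)$
                 screening$specificity, 0.8)
  expect_equal(set_parameter(p, "prophylaxis_effect_definite", 0.25)$
                 prophylaxis$effect_definite, 0.25)

  expect_error(set_parameter(p, "trans:B->C", 1.4), "trans:B->C")
  expect_error(set_parameter(p, "daly:F", -0.1), "daly:F")
  expect_error(set_parameter(p, "cost:NOPE", 5), "cost:NOPE")
  expect_error(set_parameter(p, "bogus", 1), "bogus")

  # tunnel rows rebalance their siblings so the row still allocates fully
  q <- set_parameter(p, "trans:X->K", 0.7)
  xk <- q$transitions$from == "X"
  expect_equal(sum(q$transitions$probability[xk]), 1)
})

test_that("one-way sweeps bracket the base case and degenerate to zero spread", {
  p <- make_screen_toy()
  row <- one_way_sweep(p, "cost:Fd", 50, 50)
  expect_identical(row$spread, 0)

  base <- run_cea(p)$comparison$icer
  r0 <- run_cea(set_parameter(p, "discount_rate", 0))$comparison$icer
  r5 <- run_cea(set_parameter(p, "discount_rate", 0.05))$comparison$icer
  sw <- one_way_sweep(p, "discount_rate", 0, 0.05)
  expect_equal(sw$icer_low, r0)
  expect_equal(sw$icer_high, r5)
  # monotone along the sweep: base ICER lies between the endpoints
  expect_true((r0 - base) * (r5 - base) <= 0)
  expect_true(min(r0, r5) <= base && base <= max(r0, r5))

  # a state never occupied under either strategy cannot move the ICER
  orphan <- one_way_sweep(p, "cost:O", 0, 1e6)
  expect_identical(orphan$spread, 0)

  expect_error(one_way_sweep(p, "trans:B->Z", 0.9, 1.4), "trans:B->Z")
  expect_error(one_way_sweep(p, "cost:Fd", 60, 50), "low")
})

test_that("tornado rows are sorted by spread and recomputable independently", {
  p <- make_screen_toy()
  tor <- suppressMessages(tornado_analysis(p))
  expect_true(all(diff(tor$spread) <= 1e-12))
  expect_identical(sum(tor$parameter == "discount_rate"), 1L)
  expect_true("screening:sensitivity_borderline" %in% tor$parameter)
  # orphan-state cost has bounds (gamma) but zero influence
  expect_equal(tor$spread[tor$parameter == "cost:O"], 0)
  # endpoint recomputation matches the reported rows
  for (i in 1:3) {
    lo <- run_cea(set_parameter(p, tor$parameter[i], tor$low[i]))$comparison$icer
    hi <- run_cea(set_parameter(p, tor$parameter[i], tor$high[i]))$comparison$icer
    expect_equal(tor$icer_low[i], lo)
    expect_equal(tor$icer_high[i], hi)
    expect_equal(tor$spread[i], abs(hi - lo))
  }
})

test_that("point-only bundles produce zero spread for descriptor parameters", {
  p <- degenerate_params(make_screen_toy())
  tor <- suppressMessages(tornado_analysis(p))
  swept <- grepl("^(trans|cost|daly):", tor$parameter)
  expect_identical(sum(swept), 0L)  # all skipped: no bounds
  expect_true("discount_rate" %in% tor$parameter)
})
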