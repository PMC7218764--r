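# minimal two-state trace builders used throughout
trace_of <- function(rows, ids) {
  structure(rows, dimnames = list(0:(nrow(rows) - 1), ids),
            class = c("rhd_trace", "matrix", "array"))
}

test_that("discount factors follow the compound-interest closed form", {
  expect_identical(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03)
  expect_identical(discount_factor(0, 30), 1)
  expect_error(discount_factor(-0.01, 1), ">= 0")
})

test_that("cost accrual matches hand-computed sums", {
  ids <- c("K", "Z")
  ec <- data.frame(state = ids, cost = c(854, 0))

  tr <- trace_of(rbind(c(1, 0), c(1, 0)), ids)
  expect_equal(accrue_costs(tr, data.frame(state = ids, cost = c(0, 0)),
                            rate = 0)$total, 0)
  expect_equal(accrue_costs(tr, ec, rate = 0)$total, 854)

  tr2 <- trace_of(rbind(c(1, 0), c(1, 0), c(1, 0)), ids)
  expect_equal(accrue_costs(tr2, ec, rate = 0.03)$total,
               854 * (1 / 1.03 + 1 / 1.03^2))

  one <- data.frame(cycle = c(0, 1), amount = c(100, 103))
  got <- accrue_costs(tr2, ec, one_time = one, rate = 0.03)
  expect_equal(got$one_time, 100 + 103 / 1.03)
  expect_equal(got$total, got$state_cost + got$one_time)

  # occupied state without a cost entry is an error
  expect_error(accrue_costs(tr, data.frame(state = "Z", cost = 0), rate = 0),
               "K")
})

test_that("begin-of-cycle accrual discounts one cycle earlier", {
  ids <- c("K", "Z")
  ec <- data.frame(state = ids, cost = c(854, 0))
  tr2 <- trace_of(rbind(c(1, 0), c(1, 0), c(1, 0)), ids)
  expect_equal(accrue_costs(tr2, ec, rate = 0.03, accrual = "begin")$total,
               854 * (1 + 1 / 1.03))
})

test_that("DALY accrual decomposes into YLD and life-table YLL", {
  ids <- c("sick", "dead")
  lt <- data.frame(age = c(0, 120), expectancy = c(2, 2))
  ec0 <- data.frame(state = ids, daly_weight = c(0, 0))

  alive <- trace_of(rbind(c(1, 0), c(1, 0)), ids)
  expect_equal(accrue_dalys(alive, ec0, lt, 11, 0, "dead")$total, 0)

  dies <- trace_of(rbind(c(1, 0), c(0, 1)), ids)
  expect_equal(accrue_dalys(dies, ec0, lt, 11, 0, "dead")$yll, 2)
  expect_equal(accrue_dalys(dies, ec0, lt, 11, 0.03, "dead")$yll,
               1.03^-2 + 1.03^-3)
  expect_equal(accrue_dalys(dies, ec0, lt, 11, 0.03, "dead",
                            yll_mode = "lump")$yll, 2 / 1.03)

  # fractional final year is pro-rated in the stream convention
  lt25 <- data.frame(age = c(0, 120), expectancy = c(2.5, 2.5))
  expect_equal(accrue_dalys(dies, ec0, lt25, 11, 0.03, "dead")$yll,
               1.03^-2 + 1.03^-3 + 0.5 * 1.03^-4)

  ecw <- data.frame(state = ids, daly_weight = c(0.2, 0))
  expect_equal(accrue_dalys(alive, ecw, lt, 11, 0, "dead")$yld, 0.2)
  expect_error(accrue_dalys(dies, ec0,
                            data.frame(age = c(0, 10), expectancy = c(5, 5)),
                            11, 0, "dead"), "outside life table")
})

test_that("a dead cohort accrues no YLD and an immortal one no YLL", {
  p <- generate_toy_bundle(p_recover = 0, p_die = 1)
  res <- run_strategy(build_standard_care(p), p)
  expect_equal(res$yld, 0, tolerance = 1e-12)
  p2 <- generate_toy_bundle(p_die = 0)
  res2 <- run_strategy(build_standard_care(p2), p2)
  expect_identical(res2$yll, 0)
})

test_that("discounted totals decrease with the rate and match raw sums at 0", {
  set.seed(202)
  ids <- c("S1", "S2", "Z")
  ec <- data.frame(state = ids, cost = c(120, 30, 0),
                   daly_weight = c(0.1, 0.02, 0))
  lt <- data.frame(age = 0:100, expectancy = pmax(2, 70 - 0.7 * (0:100)))
  for (rep in 1:5) {
    m <- random_stochastic_matrix(3, ids)
    tr <- run_cohort(m, c(S1 = 600, S2 = 400, Z = 0), 15)
    costs <- vapply(c(0, 0.02, 0.05, 0.1),
                    function(r) accrue_costs(tr, ec, rate = r)$total, 0)
    expect_true(all(diff(costs) < 1e-9))
    dalys <- vapply(c(0, 0.02, 0.05, 0.1),
                    function(r) accrue_dalys(tr, ec, lt, 11, r, "Z")$total, 0)
    expect_true(all(diff(dalys) < 1e-9))
    # r = 0 reproduces the undiscounted sums exactly
    raw <- sum(tr[-1, ] %*% ec$cost)
    expect_equal(accrue_costs(tr, ec, rate = 0)$total, raw)
  }
})

test_that("incremental comparison handles ratios, dominance and NMB", {
  std <- list(total_cost = 34249.72, total_dalys = 726.63)
  scr <- list(total_cost = 49828.52, total_dalys = 725.09)
  cmp <- compare_strategies(std, scr, 25949.85)
  expect_equal(cmp$delta_cost, 15578.80)
  expect_equal(cmp$delta_effect, 1.54)
  expect_equal(cmp$icer, 15578.80 / 1.54)
  expect_identical(cmp$label, "icer")
  expect_equal(cmp$nmb, 25949.85 * 1.54 - 15578.80)

  dom <- compare_strategies(list(total_cost = 10, total_dalys = 5),
                            list(total_cost = 8, total_dalys = 4), 100)
  expect_identical(dom$label, "dominant")
  dtd <- compare_strategies(list(total_cost = 8, total_dalys = 4),
                            list(total_cost = 10, total_dalys = 5), 100)
  expect_identical(dtd$label, "dominated")
  eq <- compare_strategies(list(total_cost = 5, total_dalys = 2),
                           list(total_cost = 5, total_dalys = 2), 1e6)
  expect_identical(eq$label, "equal_effect")
  expect_true(is.na(eq$icer))
  expect_identical(eq$nmb, 0)
})

test_that("NMB sign agrees with the ICER/threshold comparison when DALYs are averted", {
  set.seed(303)
  for (rep in 1:20) {
    std <- list(total_cost = stats::runif(1, 1e4, 1e5),
                total_dalys = stats::runif(1, 500, 800))
    scr <- list(total_cost = std$total_cost + stats::runif(1, -2e4, 4e4),
                total_dalys = std$total_dalys - stats::runif(1, 0.1, 50))
    lambda <- stats::runif(1, 0, 5e4)
    cmp <- compare_strategies(std, scr, lambda)
    expect_gt(cmp$delta_effect, 0)
    expect_identical(cmp$nmb > 0, cmp$icer < lambda)
  }
})

test_that("the ICER is invariant under cohort rescaling", {
  p <- make_screen_toy()
  base <- run_cea(p)$comparison$icer
  for (k in c(1 / 4, 10, 373)) {
    q <- set_parameter(p, "cohort_size", 1000 * k)
    expect_equal(run_cea(q)$comparison$icer, base, tolerance = 1e-9)
  }
})
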