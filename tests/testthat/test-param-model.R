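test_that("packaged bundle carries the published constants", {
  p <- paper_fixture()
  cost <- function(s) p$economics$cost[p$economics$state == s]
  expect_identical(cost("A"), 0)
  expect_identical(cost("F"), 25.84)
  expect_identical(cost("G"), 93.93)
  expect_identical(cost("H"), 337.47)
  expect_identical(cost("I"), 854.00)
  expect_identical(cost("RG"), 93.93)
  expect_identical(cost("RH"), 337.47)
  expect_identical(cost("RI"), 854.00)
  expect_identical(cost("K"), 854.00)
  expect_identical(cost("X"), 4120.51)
  expect_identical(cost("Z"), 0)
  expect_identical(p$cohort_size, 1000L)
  expect_identical(p$n_cycles, 30L)
  expect_identical(p$discount_rate, 0.03)
  expect_identical(p$threshold, 25949.85)
  expect_identical(p$screening$cost_per_scan, 6.6)
  expect_equal(p$start_age, 11)
  expect_identical(nrow(p$state_space$states), 15L)
  expect_identical(p$state_space$death_state, "Z")
  expect_identical(p$state_space$tunnel_states, "X")
})

test_that("load -> save -> load is the identity on valid bundles", {
  for (p in list(paper_fixture(), generate_toy_bundle())) {
    dir <- withr::local_tempdir()
    save_parameter_bundle(p, dir)
    q <- load_parameter_bundle(dir)
    # file names inside the bundle differ; compare content field by field
    expect_equal(q$transitions, p$transitions)
    expect_equal(q$economics, p$economics)
    expect_equal(q$life_table, p$life_table)
    expect_equal(q$initial_distribution, p$initial_distribution)
    expect_equal(q$screening, p$screening)
    expect_equal(q$prophylaxis, p$prophylaxis)
    expect_equal(q$state_space, p$state_space)
    expect_equal(q$cohort_size, p$cohort_size)
    expect_equal(q$discount_rate, p$discount_rate)
    # and saving the reloaded bundle reproduces the files byte for byte
    dir2 <- withr::local_tempdir()
    save_parameter_bundle(q, dir2)
    for (f in list.files(dir))
      expect_identical(readLines(file.path(dir2, f)),
                       readLines(file.path(dir, f)), label = f)
  }
})

test_that("validation rejects malformed bundles with named diagnostics", {
  p <- paper_fixture()

  bad <- p
  bad$initial_distribution <- c(A = 0.938, B = 0.0315, C = 0.0105)  # 0.98
  expect_error(validate_params(bad), "sums to 0.98")

  bad <- p
  bad$transitions$to[1] <- "NOPE"
  expect_error(validate_params(bad), "NOPE")

  bad <- p
  i <- which(bad$transitions$from == "E")[1]
  bad$transitions$probability[i] <- 0.99   # E's row already carries ~0.45
  expect_error(validate_params(bad), "state E")

  bad <- p
  bad$economics <- p$economics[p$economics$state != "K", ]
  expect_error(validate_params(bad), "K")

  bad <- p
  bad$life_table$expectancy[5] <- bad$life_table$expectancy[4] + 1
  expect_error(validate_params(bad), "non-increasing")
})

test_that("unknown config keys are rejected by name", {
  dir <- withr::local_tempdir()
  save_parameter_bundle(paper_fixture(), dir)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$typo_key <- 1
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  expect_error(load_parameter_bundle(dir), "typo_key")
})

test_that("edge validation flags departures from the model diagram", {
  p <- paper_fixture()
  # death is absorbing: an explicit resurrection edge is a violation
  tr <- data.frame(from = "Z", to = "A", probability = 0.1,
                   stringsAsFactors = FALSE)
  v <- validate_edges(tr, p$allowed_edges)
  expect_identical(nrow(v), 1L)
  expect_identical(v$from, "Z")

  empty <- tr[0, ]
  expect_identical(nrow(validate_edges(empty, p$allowed_edges)), 0L)

  # the packaged transitions themselves are all permitted
  expect_identical(nrow(validate_edges(p$transitions, p$allowed_edges)), 0L)

  # self-loops are always allowed even if unlisted
  self <- data.frame(from = "A", to = "A", probability = 0.5,
                     stringsAsFactors = FALSE)
  expect_identical(nrow(validate_edges(self, p$allowed_edges)), 0L)
})

test_that("state space constructor enforces its invariants", {
  expect_error(state_space(character(), death_state = "Z"), "at least one")
  expect_error(state_space(c("A", "A"), death_state = "A"), "duplicate")
  expect_error(state_space(c("A", "B"), death_state = "Z"), "not a member")
  expect_error(state_space(c("A", "Z"), death_state = "Z",
                           tunnel_states = "Q"), "Q")
})

test_that("transitions overlay substitutes the transition table", {
  p0 <- paper_fixture()
  dir <- withr::local_tempdir()
  tr <- data.frame(from = p0$transitions$from, to = p0$transitions$to,
                   probability = sprintf("%.17g", p0$transitions$probability),
                   dist = vapply(p0$transitions$dist,
                                 rhdcea:::dist_to_string, ""),
                   stringsAsFactors = FALSE)
  tr$probability[tr$from == "B" & tr$to == "C"] <- "0.123"
  f <- file.path(dir, "overlay.csv")
  utils::write.csv(tr, f, row.names = FALSE)
  p1 <- paper_fixture(transitions_overlay = f)
  expect_equal(
    p1$transitions$probability[p1$transitions$from == "B" &
                               p1$transitions$to == "C"], 0.123)
})
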