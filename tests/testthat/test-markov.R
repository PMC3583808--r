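test_that("cycle schedules follow the quarterly-then-annual design", {
  p <- thal_params()
  sh <- build_cycle_schedule(p, "hsct", terminal_age = 120)
  expect_equal(sh$length_years[1:4], rep(0.25, 4))
  expect_true(all(sh$length_years[-(1:4)] == 1))
  expect_equal(sh$start_age[1], 13.7)
  expect_equal(sh$start_age[5], 14.7)            # first annual cycle
  expect_equal(sh$phase[1:7], c("Q1", "Q2", "Q3", "Q4", "IRON_CHELATION",
                                "IRON_CHELATION", "POST_HSCT"))
  expect_equal(sum(sh$length_years), p$horizon_years)

  sb <- build_cycle_schedule(p, "btict", terminal_age = 120)
  expect_equal(nrow(sb), 99)                     # 99 annual cycles
  expect_true(all(sb$length_years == 1))

  # a 100-year table caps the horizon at the terminal age
  sb100 <- build_cycle_schedule(p, "btict", terminal_age = 100)
  expect_true(all(floor(sb100$start_age) <= 100))
  expect_equal(floor(sb100$start_age[nrow(sb100)]), 100)

  expect_error(build_cycle_schedule(thal_params(horizon_years = 0.5), "hsct"),
               "horizon")
})

test_that("transition matrices are row-stochastic with absorbing death", {
  p <- thal_params()
  lt <- default_table()
  for (arm in c("hsct", "btict")) {
    sh <- build_cycle_schedule(p, arm, terminal_age = 100)
    for (i in c(1:5, 20, nrow(sh))) {
      M <- build_transition_matrix(p, sh[i, ], lt, arm)
      expect_equal(unname(rowSums(M)), rep(1, 9), tolerance = 1e-12)
      expect_true(all(M >= 0 & M <= 1))
      expect_equal(unname(M["DEATH", ]), c(rep(0, 8), 1))
    }
  }
  # no graft failure possible from Q3 onward
  sh <- build_cycle_schedule(p, "hsct", terminal_age = 100)
  M3 <- build_transition_matrix(p, sh[3, ], lt, "hsct")
  expect_equal(unname(M3["Q2", "BTICT_NO_CARDIAC"]), 0)
})

test_that("over-unit competing exits are reported, not clipped", {
  p <- thal_params(q_fail_q1 = 0.9)
  lt <- flat_table(0.5)
  sh <- build_cycle_schedule(p, "hsct", terminal_age = 100)
  expect_error(build_transition_matrix(p, sh[1, ], lt, "hsct"), "sum to")
})

test_that("cohort traces conserve mass, absorb death and respect tunnels", {
  p <- thal_params()
  lt <- default_table()
  for (arm in c("hsct", "btict")) {
    tr <- run_cohort(arm, p, lt)
    expect_equal(unname(rowSums(tr)), rep(1, nrow(tr)), tolerance = 1e-9)
    expect_true(all(diff(tr[, "DEATH"]) >= -1e-12))
    expect_equal(unname(tr[nrow(tr), "DEATH"]), 1, tolerance = 1e-9)  # terminal row
  }
  tr <- run_cohort("hsct", p, lt)
  # tunnel: Q_k occupied only at its scheduled row (Q1 also at entry)
  for (k in 1:4) {
    col <- tr[, paste0("Q", k)]
    occupied <- which(col > 0) - 1L   # cycle index of each occupied row
    expect_true(all(occupied %in% if (k == 1) c(0L, 1L) else k))
  }
  # transplant mortality and failure drain Q-state mass monotonically
  expect_true(tr[2, "Q1"] < 1)
  expect_true(tr[5, "Q4"] <= tr[4, "Q3"])
})

test_that("with all risks off the cohort never dies", {
  p0 <- no_excess_params()
  lt0 <- flat_table(0)
  tr <- run_cohort("hsct", p0, lt0)
  expect_equal(unname(max(tr[-nrow(tr), "DEATH"])), 0)   # alive until the terminal row
  expect_equal(sum(tr[, "DEATH"] == 1), 1)       # qx = 1 terminal absorption
})

test_that("certain background mortality kills the cohort in one cycle", {
  lt <- flat_table(0.001)
  lt$qx[lt$age == 20] <- 1
  tr <- run_cohort("btict", thal_params(), lt)
  sh <- attr(tr, "schedule")
  k <- which(floor(sh$start_age) == 20)[1]
  expect_equal(unname(tr[k + 1, "DEATH"]), 1, tolerance = 1e-12)
})

test_that("transfusion-arm decay matches the closed-form geometric oracle", {
  p <- thal_params(p_cardiac_annual = 0, rr_btict_death = 3.9)
  lt <- flat_table(0.01)
  tr <- run_cohort("btict", p, lt)
  alive <- rowSums(tr[, setdiff(colnames(tr), "DEATH")])
  n <- 0:30
  expect_equal(unname(alive[n + 1]), 0.99^(3.9 * n), tolerance = 1e-9)

  # brute-force two-state simulation oracle
  a <- 1; brute <- 1
  q <- 1 - 0.99^3.9
  for (i in 1:30) { a <- a * (1 - q); brute <- c(brute, a) }
  expect_equal(unname(alive[1:31]), brute, tolerance = 1e-12)
})

test_that("with no excess risk both arms track life-table survivorship", {
  p0 <- no_excess_params()
  lt <- default_table()

  # comparator arm: annual cycles from age 13.7 read q13, q14, ...
  tr_b <- run_cohort("btict", p0, lt)
  alive_b <- rowSums(tr_b[, setdiff(colnames(tr_b), "DEATH")])
  n_check <- 40
  oracle_b <- cumprod(c(1, 1 - annual_death_probability(
    lt, 13.7 + 0:(n_check - 1))))
  expect_equal(unname(alive_b[1:(n_check + 1)]), oracle_b, tolerance = 1e-9)

  # transplant arm: four quarter-scaled cycles, then annual
  tr_h <- run_cohort("hsct", p0, lt)
  alive_h <- rowSums(tr_h[, setdiff(colnames(tr_h), "DEATH")])
  q_quarters <- annual_death_probability(lt, c(13.7, 13.95, 14.2, 14.45))
  oracle_y1 <- cumprod((1 - q_quarters)^0.25)
  expect_equal(unname(alive_h[2:5]), oracle_y1, tolerance = 1e-9)
  oracle_rest <- oracle_y1[4] * cumprod(
    1 - annual_death_probability(lt, 14.7 + 0:(n_check - 1)))
  expect_equal(unname(alive_h[6:(n_check + 5)]), oracle_rest, tolerance = 1e-9)
})

test_that("raising the transfusion-arm relative risk never extends its life expectancy", {
  lt <- default_table()
  le <- vapply(c(1, 2, 3.9, 6), function(rr) {
    tr <- run_cohort("btict", thal_params(rr_btict_death = rr), lt)
    sh <- attr(tr, "schedule")
    sum(rowSums(tr[-1, setdiff(colnames(tr), "DEATH")]) * sh$length_years)
  }, numeric(1))
  expect_true(all(diff(le) < 0))
})

test_that("fitted survival models can drive the failure schedule", {
  rec <- read_cohort(system.file("extdata", "hsct_cohort_synthetic.csv",
                                 package = "thalcea"))
  models <- list(failure = fit_parametric(rec, "graft_failure"),
                 death = fit_parametric(rec, "death"))
  p <- thal_params(failure_source = "fitted")
  lt <- default_table()
  tr <- run_cohort("hsct", p, lt, models = models)
  # fitted failure rate moves far more mass to the transfusion path than the
  # tabulated base-case probabilities do
  tr_base <- run_cohort("hsct", thal_params(), lt)
  expect_gt(tr[6, "BTICT_NO_CARDIAC"], tr_base[6, "BTICT_NO_CARDIAC"])
  expect_equal(unname(rowSums(tr)), rep(1, nrow(tr)), tolerance = 1e-9)
})

test_that("traces serialize to the documented CSV layout", {
  tr <- run_cohort("btict", thal_params(), default_table())
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  d <- utils::read.csv(path)
  expect_equal(names(d)[1:3], c("cycle", "start_age", "length_years"))
  expect_true("death" %in% names(d))
  expect_equal(nrow(d), nrow(tr))
})
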