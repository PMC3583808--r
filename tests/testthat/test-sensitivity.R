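test_that("moment matching recovers means and variances exactly", {
  b <- param_spec("u", 0.5, family = "beta", mean = 0.5, se = 0.25)
  mb <- moment_match(b)
  expect_equal(mb$alpha, 1.5)
  expect_equal(mb$beta, 1.5)

  g <- param_spec("c", 1187, family = "gamma", mean = 1187, se = 137)
  mg <- moment_match(g)
  expect_equal(mg$shape, 1187^2 / 137^2)
  expect_equal(mg$scale, 137^2 / 1187)

  # round trip: analytic mean/variance of the fitted family equal (m, s^2)
  cases <- list(c("beta", 0.61, 0.03), c("beta", 0.59, 0.30),
                c("gamma", 1548, 411), c("lognormal", 7.8e-5, 7.8e-5))
  for (cs in cases) {
    fam <- cs[1]; m <- as.numeric(cs[2]); s <- as.numeric(cs[3])
    mm <- moment_match(param_spec("x", m, family = fam, mean = m, se = s))
    if (fam == "beta") {
      ab <- mm$alpha + mm$beta
      expect_equal(mm$alpha / ab, m, tolerance = 1e-12)
      expect_equal(mm$alpha * mm$beta / (ab^2 * (ab + 1)), s^2, tolerance = 1e-12)
    } else if (fam == "gamma") {
      expect_equal(mm$shape * mm$scale, m, tolerance = 1e-12)
      expect_equal(mm$shape * mm$scale^2, s^2, tolerance = 1e-12)
    } else {
      expect_equal(exp(mm$meanlog + mm$sdlog^2 / 2), m, tolerance = 1e-12)
      expect_equal((exp(mm$sdlog^2) - 1) * exp(2 * mm$meanlog + mm$sdlog^2),
                   s^2, tolerance = 1e-12)
    }
  }

  expect_error(param_spec("bad", 0.5, family = "beta", mean = 0.5, se = 0.6),
               "infeasible")
  expect_error(moment_match(param_spec("f", 1, family = "fixed")),
               "no standard error|no distribution")
})

test_that("sampled parameter means converge to their specification means", {
  p <- thal_params()
  specs <- default_param_specs(p)
  active <- Filter(function(s) s$family != "fixed", specs)
  set.seed(19)
  n <- 1e4
  for (s in active) {
    draws <- thalcea:::sample_spec(s, n)
    mc_se <- s$se / sqrt(n)
    expect_lt(abs(mean(draws) - s$mean), 4 * mc_se)
  }
})

test_that("one-way analysis brackets the base case and reports directions", {
  p <- thal_params()
  lt <- default_table()
  base_icer <- run_cua(p, lt)$cua$icer

  degenerate <- param_spec("ccr", base = p$ccr, low = p$ccr, high = p$ccr,
                           family = "fixed",
                           setter = function(params, v) { params$ccr <- v; params })
  ow0 <- one_way(p, degenerate, lt)
  expect_equal(ow0$icer_low, base_icer, tolerance = 1e-9)
  expect_equal(ow0$icer_high, base_icer, tolerance = 1e-9)

  specs <- default_param_specs(p)
  ow_u <- one_way(p, specs$utility_btict_no_cardiac, lt)
  expect_gt(ow_u$icer_high, ow_u$icer_low)   # better comparator QoL -> higher ICER
  ow_c <- one_way(p, specs$ccr, lt)
  expect_gt(ow_c$icer_high, ow_c$icer_low)   # pricier charges -> higher ICER
})

test_that("tornado ordering is by descending spread, stable under input order", {
  e <- function(name, lo, hi) list(name = name, icer_low = lo, icer_high = hi,
                                   range = abs(hi - lo))
  entries <- list(e("a", 100, 110), e("b", 0, 100), e("c", 50, 100))
  t1 <- tornado(entries)
  expect_equal(t1$parameter, c("b", "c", "a"))
  expect_equal(t1$range, c(100, 50, 10))
  t2 <- tornado(rev(entries))
  expect_equal(t2$parameter, t1$parameter)
  expect_equal(tornado(list(e("only", 1, 2)))$parameter, "only")
  # ties break alphabetically
  t3 <- tornado(list(e("z", 0, 5), e("a", 10, 15)))
  expect_equal(t3$parameter, c("a", "z"))
})

test_that("tornado on model-driven entries is ordered and utility-sensitive", {
  p <- thal_params()
  lt <- default_table()
  specs <- default_param_specs(p)
  keep <- c("utility_btict_no_cardiac", "utility_post_hsct", "discount_rate",
            "ccr", "q_fail_q1", "p_cardiac_annual",
            "cost_q1_direct_medical", "lambda_death_cohort")
  entries <- lapply(specs[keep], one_way, params = p, table = lt)
  tor <- tornado(entries)
  expect_true(all(diff(tor$range) <= 0))
  expect_equal(sort(tor$parameter), sort(keep))
  # the wide 0.3-0.9 comparator-utility range outranks every transition and
  # survival input (the cost-driven bars depend on the cost structure; see
  # the methods vignette on sensitivity ranking)
  rank_of <- function(nm) which(tor$parameter == nm)
  for (nm in c("q_fail_q1", "p_cardiac_annual", "lambda_death_cohort",
               "cost_q1_direct_medical")) {
    expect_lt(rank_of("utility_btict_no_cardiac"), rank_of(nm))
  }
})

test_that("PSA is seeded, reproducible and degenerate when all parameters are fixed", {
  p <- thal_params()
  lt <- default_table()
  fixed_only <- list(param_spec("ccr", p$ccr, family = "fixed",
                                setter = function(params, v) params))
  psa_f <- run_psa(p, lt, specs = fixed_only, n_draws = 5, seed = 2)
  base <- run_cua(p, lt)$cua
  expect_equal(psa_f$draws$delta_cost_usd, rep(base$delta_cost, 5), tolerance = 1e-12)
  expect_equal(psa_f$draws$delta_qaly, rep(base$delta_qalys, 5), tolerance = 1e-12)

  a <- run_psa(p, lt, n_draws = 25, seed = 7)
  b <- run_psa(p, lt, n_draws = 25, seed = 7)
  expect_identical(a$draws, b$draws)
  expect_equal(nrow(a$draws), 25)
  expect_true(all(is.finite(unlist(a$draws))))
})

test_that("acceptability curves summarise net-benefit fractions", {
  fake <- structure(list(draws = data.frame(
    draw = 1:4,
    delta_cost_usd = c(-10, 20, 30, 40),
    delta_qaly = c(1, 2, -1, 4)),
    n_draws = 4, seed = 1, resamples = 0L), class = "psa_result")
  # lambda = 0: fraction of cost-saving draws
  expect_equal(ceac(fake, 0)$prob_cost_effective, 0.25)
  # dominant cloud: all cheaper and more effective
  dom <- fake; dom$draws$delta_cost_usd <- -abs(dom$draws$delta_cost_usd)
  dom$draws$delta_qaly <- abs(dom$draws$delta_qaly)
  expect_equal(ceac(dom, c(0.001, 1, 1e6))$prob_cost_effective, rep(1, 3))
  # two draws with NMB +1 / -1 at a threshold
  two <- fake
  two$draws <- data.frame(draw = 1:2, delta_cost_usd = c(9, 11),
                          delta_qaly = c(1, 1))
  expect_equal(ceac(two, 10)$prob_cost_effective, 0.5)

  # monotone in WTP when no draw loses QALYs; limit is P(dQALY > 0)
  pos <- fake; pos$draws$delta_qaly <- abs(pos$draws$delta_qaly)
  grid <- c(0, 5, 10, 50, 1e8)
  curve <- ceac(pos, grid)$prob_cost_effective
  expect_true(all(diff(curve) >= 0))
  expect_equal(curve[length(curve)], mean(pos$draws$delta_qaly > 0))
})
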