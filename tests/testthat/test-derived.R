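test_that("clonal half-life follows ln2 over the net loss rate", {
  expect_equal(clonal_half_life(log(2) + 0.004, 0.004), 1.0)
  expect_equal(clonal_half_life(0.01, 0.01), Inf)   # sustained indefinitely
  expect_equal(clonal_half_life(0.005, 0.01), Inf)
  # slow-cell rates land inside the long clonal half-life regime
  expect_equal(clonal_half_life(0.011, 0.004), 99.02, tolerance = 1e-3)
  hl <- clonal_half_life(0.011, 0.004)
  expect_true(hl > 70 && hl < 140)
})

test_that("clonal half-life exceeds cell lifespan whenever cells self-renew", {
  set.seed(6)
  for (i in 1:50) {
    delta <- stats::runif(1, 0.01, 0.3)
    alpha <- stats::runif(1, 1e-4, delta * 0.99)
    expect_gt(clonal_half_life(delta, alpha), log(2) / delta)
    expect_gt(clonal_half_life(delta, alpha) / (1 / delta), log(2))
  }
})

test_that("size-weighted mean lifespan reduces correctly", {
  expect_equal(weighted_mean_lifespan(c(0.05, 0.05, 0.05), c(1, 5, 3)), 20)
  expect_equal(weighted_mean_lifespan(c(0.1, 0.01), c(1, 9)), 1 / 0.019,
               tolerance = 1e-12)
  expect_error(weighted_mean_lifespan(c(0.1, 0.2), c(0, 0)), "positive")
})

test_that("upslope estimator inverts production for slowly fed populations", {
  expect_equal(lifespan_from_upslope(0.1, 1), 20)
  expect_error(lifespan_from_upslope(0, 0.5), "positive")
  expect_error(lifespan_from_upslope(0.1, 1.5), "epsilon")
  # homogeneous truth: the instantaneous early slope is eps*(f + 2 alpha),
  # and with it the estimator recovers 1/delta with a small bias when
  # f << alpha; the finite-window least-squares slope sits slightly below
  # the instantaneous one because the curve flattens as labelling proceeds
  p <- homog_params(epsilon = 0.8, alpha = 0.045, f = 0.005)
  p0 <- 0.8 * (0.005 + 0.09)
  expect_equal(lifespan_from_upslope(p0, 0.8), 21.05, tolerance = 1e-3)
  expect_lt(abs(lifespan_from_upslope(p0, 0.8) - 1 / p$delta_fast) /
              (1 / p$delta_fast), 0.10)
  d <- experiment_design()
  out <- solve_labelling(p, d, c(0.5, 1, 1.5, 2))
  slope <- estimate_upslope(out$time, out$frac_brdu, t_max = 2)
  expect_equal(slope, p0, tolerance = 0.10)
  expect_lt(slope, p0)
})

test_that("Ki67 estimator matches its construction and asymptote", {
  k_forced <- 2 * (1 - exp(-0.5))   # makes log(1 - k/2) = -0.5
  expect_equal(lifespan_from_ki67(k_forced, 3.1), 6.2, tolerance = 1e-9)
  expect_equal(lifespan_from_ki67(0.001, 3.1), 2 * 3.1 / 0.001,
               tolerance = 1e-3)
  expect_error(lifespan_from_ki67(0, 3.1), "k must")
  expect_error(lifespan_from_ki67(0.5, -1), "positive")
})

test_that("Ki67 estimator is decreasing in k and linear in T", {
  ks <- seq(0.05, 0.95, by = 0.05)
  vals <- lifespan_from_ki67(ks, 3.1)
  expect_true(all(diff(vals) < 0))
  expect_equal(lifespan_from_ki67(0.3, 6.2), 2 * lifespan_from_ki67(0.3, 3.1))
})

test_that("both approximation estimators recover 1/delta on noise-free data", {
  # regime of validity: slowly turning-over memory (lifespans of weeks, as
  # for these subsets); the Ki67 relation additionally reads T as a fixed
  # expression duration, which the Erlang-staged model approximates
  d <- experiment_design()
  set.seed(12)
  for (i in 1:5) {
    alpha <- stats::runif(1, 0.01, 0.035)
    f <- stats::runif(1, 0.001, 0.2 * (alpha + 0.005))
    p <- homog_params(epsilon = 0.7, beta = 1 / 3.1, alpha = alpha, f = f)
    if (f / p$delta_fast > 0.2) next
    out <- solve_labelling(p, d, c(0.5, 1, 1.5, 2))
    slope <- estimate_upslope(out$time, out$frac_brdu, t_max = 2)
    est_up <- lifespan_from_upslope(slope, 0.7)
    p10 <- homog_params(epsilon = 0.7, beta = 1 / 3.1, alpha = alpha, f = f,
                        n_stages = 10L)
    k <- unname(attr(steady_state(p10), "summaries")["frac_ki67hi"])
    est_k <- lifespan_from_ki67(k, 3.1)
    true_ls <- 1 / p$delta_fast
    expect_lt(abs(est_up - true_ls) / true_ls, 0.15)
    expect_lt(abs(est_k - true_ls) / true_ls, 0.15)
  }
})

test_that("subset averaging weights by relative abundance", {
  expect_equal(weighted_subset_average(0.3, 0.5, 1), 0.4)
  expect_equal(weighted_subset_average(0.4, 0.2, 7.5), 0.2235, tolerance = 1e-3)
  expect_equal(weighted_subset_average(0.08, 0.04, 7.5), 0.04471,
               tolerance = 1e-3)
  expect_error(weighted_subset_average(1, 1, 0), "positive")
})

test_that("lifespan summaries propagate infinite half-lives gracefully", {
  draws <- data.frame(alpha_fast = c(0.1, 0.1, 0.1), alpha_slow = 0.01,
                      delta_fast = c(0.2, 0.09, 0.3), delta_slow = 0.012,
                      nu = 0.4)
  out <- lifespan_summary(draws)
  hl <- out[out$quantity == "half_life_fast", ]
  expect_equal(hl$frac_infinite, 1 / 3)
  expect_true(is.finite(out[out$quantity == "mean_lifespan", "median"]))
})
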