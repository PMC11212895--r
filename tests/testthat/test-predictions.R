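test_that("the source dilution curve fits constants and recovers parameters", {
  const <- dilution_observations(data.frame(
    mouse_id = paste0("m", 1:8), t_tam = seq(0, 126, length.out = 8),
    subset = "naive_CD4", labelled_fraction = 0.6))
  fit <- fit_source_dilution_curve(const)
  expect_equal(unname(stats::predict(fit, c(0, 50, 126))), rep(0.6, 3),
               tolerance = 1e-9)
  set.seed(9)
  tt <- seq(0, 126, length.out = 15)
  y <- pmin(pmax(0.3 + (0.9 - 0.3) * exp(-0.03 * tt) +
                   stats::rnorm(15, 0, 0.02), 0), 1)
  obs <- dilution_observations(data.frame(mouse_id = paste0("m", 1:15),
                                          t_tam = tt, subset = "naive_CD4",
                                          labelled_fraction = y))
  fit2 <- fit_source_dilution_curve(obs)
  expect_equal(fit2$pars$m0, 0.9, tolerance = 0.1)
  expect_equal(fit2$pars$m_inf, 0.3, tolerance = 0.1)
  expect_equal(fit2$pars$r, 0.03, tolerance = 0.1 * 0.03 / 0.03 * 0.3)
  # influx of unlabelled cells can only dilute: fitted curve non-increasing
  grid <- stats::predict(fit2, seq(0, 126, by = 1))
  expect_true(all(diff(grid) <= 1e-12))
  expect_error(fit_source_dilution_curve(obs[1:3, ]), "5 timepoints")
})

test_that("label dilution follows the closed form for a homogeneous pool", {
  p <- homog_params(epsilon = 0.6, beta = 1 / 3.1, alpha = 0.03, f = 0.01)
  tt <- c(0, 20, 50, 100)
  tr <- memdyn:::dilution_trajectory(p, function(t) 0.4, tt, 0.9)
  closed <- 0.4 + (0.9 - 0.4) * exp(-0.01 * tt)
  expect_equal(tr$aggregate, closed, tolerance = 1e-8)
})

test_that("a closed self-renewing population keeps its labelled fraction", {
  p0 <- close_parameters(kinetic_params("branched", epsilon = 0.6,
                                        beta = 1 / 3.1, alpha_fast = 0.03,
                                        f = 0, phi_fast_fraction = 1,
                                        N_fast = 1, N_slow = 0))
  tr <- memdyn:::dilution_trajectory(p0, function(t) 0.1, c(0, 60, 120), 0.8)
  expect_equal(tr$aggregate, rep(0.8, 3), tolerance = 1e-9)
})

test_that("dilution predictions are invariant to absolute population size", {
  base <- kinetic_params("branched", epsilon = 0.6, beta = 1 / 3.1,
                         alpha_fast = 0.15, alpha_slow = 0.007, f = 0.01,
                         phi_fast_fraction = 0.6, N_fast = 0.4, N_slow = 0.6)
  big <- kinetic_params("branched", epsilon = 0.6, beta = 1 / 3.1,
                        alpha_fast = 0.15, alpha_slow = 0.007, f = 0.01,
                        phi_fast_fraction = 0.6, N_fast = 4e6, N_slow = 6e6)
  src <- function(t) 0.8 * exp(-0.02 * t)
  t1 <- memdyn:::dilution_trajectory(close_parameters(base), src,
                                     c(10, 50, 100), 0.8)
  t2 <- memdyn:::dilution_trajectory(close_parameters(big), src,
                                     c(10, 50, 100), 0.8)
  expect_equal(t1$aggregate, t2$aggregate, tolerance = 1e-8)
})

test_that("posterior dilution bands cover chain-simulated observations", {
  truth <- paper_like_truth()
  p_tcm <- truth$params[["young.TCM.host"]]
  p_tem <- truth$params[["young.TEM.host"]]
  tt <- seq(0, 126, by = 14)
  # posterior stand-in: jittered draws around the generating parameters
  set.seed(15)
  n <- 300
  draws <- data.frame(
    f = p_tcm$f * exp(stats::rnorm(n, 0, 0.1)),
    epsilon = p_tcm$epsilon, beta = p_tcm$beta,
    alpha_slow = p_tcm$alpha_slow * exp(stats::rnorm(n, 0, 0.1)),
    dalpha = (p_tcm$alpha_fast - p_tcm$alpha_slow) * exp(stats::rnorm(n, 0, 0.1)),
    nu = p_tcm$N_fast, pf = p_tcm$phi_fast_fraction)
  src <- fit_source_dilution_curve(generate_dilution_dataset(
    p_tcm, p_tem, precision = Inf, seed = 1)[1:10, ])
  pred <- predict_label_dilution(draws, "branched", src, "naive_to_TCM",
                                 times = tt, n_draws = 200, seed = 2)
  expect_true(all(pred$lo <= pred$hi))
  expect_equal(pred$n_rejected, 0L)
  # coverage of noisy chain data at the 95% level across seeds
  n_cov <- 0L; n_tot <- 0L
  for (s in 1:5) {
    dil <- generate_dilution_dataset(p_tcm, p_tem, precision = 400,
                                     seed = 100 + s)
    y <- dil$labelled_fraction[dil$subset == "TCM"]
    t_d <- dil$t_tam[dil$subset == "TCM"]
    lo <- stats::approx(pred$times, pred$lo, t_d, rule = 2)$y
    hi <- stats::approx(pred$times, pred$hi, t_d, rule = 2)$y
    se <- sqrt(y * (1 - y) / 401)
    n_cov <- n_cov + sum(y >= lo - 2 * se & y <= hi + 2 * se)
    n_tot <- n_tot + length(y)
  }
  expect_gte(n_cov / n_tot, 0.9)
  # chaining: TEM prediction from the predicted TCM trajectory
  pred_tem <- predict_label_dilution(draws, "branched", pred, "TCM_to_TEM",
                                     times = tt, n_draws = 100, seed = 3)
  expect_true(all(is.finite(pred_tem$median)))
  expect_true(all(diff(pred_tem$median) <= 1e-6))
})

test_that("transferred cohorts show the observed Ki67 behaviour", {
  truth <- paper_like_truth()
  p <- truth$params[["young.TEM.host"]]
  # isolated transfer: Ki67 declines; bulk transfer with precursors: preserved
  alone <- predict_transfer_ki67(p, "bulk", influx_on = FALSE, horizon = 7,
                                 times = c(0, 7))
  bulk <- predict_transfer_ki67(p, "bulk", influx_on = TRUE, horizon = 7,
                                times = c(0, 7))
  expect_lt(alone$frac_ki67hi[2], alone$frac_ki67hi[1])
  expect_lt(abs(bulk$frac_ki67hi[2] - bulk$frac_ki67hi[1]) /
              bulk$frac_ki67hi[1], 0.2)
  # marked (recently divided) cohort starts Ki67-enriched
  yp <- predict_transfer_ki67(p, "yfp_pos", influx_on = FALSE, horizon = 7,
                              times = c(0, 7))
  yn <- predict_transfer_ki67(p, "yfp_neg", influx_on = FALSE, horizon = 7,
                              times = c(0, 7))
  expect_gt(yp$frac_ki67hi[1], alone$frac_ki67hi[1])
  # decline and convergence of the two cohorts
  expect_lt(yp$frac_ki67hi[2], yp$frac_ki67hi[1])
  expect_lt(abs(yp$frac_ki67hi[2] - yn$frac_ki67hi[2]),
            abs(yp$frac_ki67hi[1] - yn$frac_ki67hi[1]))
})

test_that("marked-cohort convergence holds across topologies and parameters", {
  set.seed(33)
  for (topo in c("branched", "linear", "burst")) {
    for (r in 1:3) {
      p <- random_params(topo)
      yp <- predict_transfer_ki67(p, "yfp_pos", influx_on = FALSE,
                                  horizon = 7, times = c(0, 7))
      yn <- predict_transfer_ki67(p, "yfp_neg", influx_on = FALSE,
                                  horizon = 7, times = c(0, 7))
      expect_lt(abs(yp$frac_ki67hi[2] - yn$frac_ki67hi[2]),
                abs(yp$frac_ki67hi[1] - yn$frac_ki67hi[1]))
    }
  }
})

test_that("a rarely dividing marked cohort loses Ki67 monotonically", {
  tr <- predict_transfer_ki67(homog_params(alpha = 0.02, f = 0.01,
                                           beta = 0.4),
                              "yfp_pos", influx_on = FALSE, horizon = 7)
  expect_true(all(diff(tr$frac_ki67hi) < 0))
  expect_error(predict_transfer_ki67(homog_params(), "bulk", horizon = 20),
               "14")
})
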