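# One shared fit reused across several assertions (fits are the expensive
# step; the checks are orthogonal).
shared <- local({
  truth <- paper_like_truth(strata = "young.TCM.host")
  p <- truth$params[[1]]
  d <- experiment_design()
  obs <- generate_labelling_dataset(truth, d, seed = 3)
  ip <- make_influx_prior(log(p$f), 0.15)
  fit <- fit_labelling_model(obs, "branched", influx_prior = ip, design = d,
                             seed = 11)
  list(truth = p, obs = obs, fit = fit, design = d, ip = ip)
})

test_that("the branched fit recovers its generating parameters", {
  fit <- shared$fit
  p <- shared$truth
  truth_vals <- c(f = p$f, epsilon = p$epsilon, beta = p$beta,
                  alpha_slow = p$alpha_slow, nu = p$N_fast,
                  pf = p$phi_fast_fraction)
  qs <- apply(fit$draws[names(truth_vals)], 2, stats::quantile,
              probs = c(0.025, 0.975), na.rm = TRUE)
  covered <- truth_vals >= qs[1, ] & truth_vals <= qs[2, ]
  expect_gte(sum(covered), 5L)   # at least 5 of 6 inside their 95% CrI
  # closed loss rates follow the draws, and net loss is their difference
  expect_equal(fit$draws$lambda_fast,
               fit$draws$delta_fast - fit$draws$alpha_fast, tolerance = 1e-9)
})

test_that("the BrdU uptake efficiency is tightly constrained by the data", {
  # the conditional BrdU-within-Ki67-high channel pins epsilon
  expect_lt(stats::sd(shared$fit$draws$epsilon), 0.1)
  expect_lt(stats::sd(shared$fit$draws$beta), 0.05)  # and the Ki67 lifetime
})

test_that("prior-only sampling reproduces the prior", {
  fit <- fit_labelling_model(shared$obs, "branched",
                             influx_prior = shared$ip,
                             design = shared$design, prior_only = TRUE,
                             n_chains = 3, n_warmup = 500, n_iter = 1000,
                             seed = 4)
  # f prior is lognormal(meanlog, 0.15): compare quantiles
  qs <- stats::quantile(fit$draws$f, c(0.25, 0.5, 0.75))
  qth <- stats::qlnorm(c(0.25, 0.5, 0.75), shared$ip$rate_meanlog, 0.15)
  expect_equal(unname(qs), qth, tolerance = 0.05)
  # epsilon prior is logit-normal(0, 1.5): median 0.5
  expect_equal(unname(stats::quantile(fit$draws$epsilon, 0.5)), 0.5,
               tolerance = 0.1)
})

test_that("the likelihood peaks at the generating parameters on noise-free data", {
  truth <- paper_like_truth(strata = "young.TCM.host")
  truth$events_per_sample <- Inf
  d <- experiment_design(mice_per_timepoint = 1L)
  obs <- generate_labelling_dataset(truth, d, seed = 1)
  p <- truth$params[[1]]
  base <- c(f = p$f, epsilon = p$epsilon, beta = p$beta,
            alpha_slow = p$alpha_slow, dalpha = p$alpha_fast - p$alpha_slow,
            nu = p$N_fast, pf = p$phi_fast_fraction,
            prec_brdu = 5e4, prec_hi = 5e4, prec_lo = 5e4, prec_k = 5e4)
  ll_of <- function(nat) {
    pv <- memdyn:::fast_par_vector(nat, "branched", 1L)
    pred <- memdyn:::.labelling_curves_cpp(pv, 0L, 1L, d$pulse_end,
                                           sort(unique(obs$t_label)))
    mu <- pred[match(obs$t_label, pred[, 1]), 2:5]
    mu <- pmin(pmax(mu, 1e-5), 1 - 1e-5)
    y <- cbind(memdyn:::shrink_fraction(obs$frac_brdu, 1e6),
               memdyn:::shrink_fraction(obs$frac_brdu_in_ki67hi, 1e6),
               memdyn:::shrink_fraction(obs$frac_brdu_in_ki67lo, 1e6),
               memdyn:::shrink_fraction(obs$frac_ki67hi, 1e6))
    prec <- rep(unname(base[8:11]), each = nrow(obs))
    sum(stats::dbeta(y, mu * prec, (1 - mu) * prec, log = TRUE))
  }
  ll_true <- ll_of(base)
  for (nm in c("f", "epsilon", "beta", "alpha_slow", "dalpha", "nu")) {
    pert <- base
    pert[nm] <- pert[nm] * 1.5
    if (nm %in% c("epsilon", "nu") && pert[nm] >= 1) pert[nm] <- 0.99
    expect_lt(ll_of(pert), ll_true)
  }
})

test_that("posterior predictive curves cover the held-in observations", {
  pred <- predict(shared$fit, times = sort(unique(shared$obs$t_label)),
                  n_draws = 150)
  channels <- c("frac_brdu", "frac_brdu_in_ki67hi", "frac_brdu_in_ki67lo",
                "frac_ki67hi")
  n_tot <- 0L; n_cov <- 0L
  for (ch in channels) {
    lo <- pred[[paste0(ch, "_lo")]][match(shared$obs$t_label, pred$time)]
    hi <- pred[[paste0(ch, "_hi")]][match(shared$obs$t_label, pred$time)]
    y <- shared$obs[[ch]]
    # widen by the counting noise the band does not model
    se <- sqrt(pmax(y * (1 - y), 1e-4) / shared$obs$n_events)
    n_cov <- n_cov + sum(y >= lo - 2 * se & y <= hi + 2 * se)
    n_tot <- n_tot + length(y)
  }
  expect_gte(n_cov / n_tot, 0.9)
})

test_that("fit objects print, summarise and predict coherently", {
  fit <- shared$fit
  expect_output(print(fit), "branched")
  s <- summary(fit)
  expect_true(all(c("q2.5", "q50", "q97.5") %in% names(s)))
  cf <- coef(fit)
  expect_true(all(c("f", "epsilon", "delta_fast") %in% names(cf)))
  expect_error(fit_labelling_model(shared$obs[shared$obs$t_label < 5, ],
                                   "branched"), "8 timepoints")
})

test_that("ELPD of a fit compared with itself is exactly zero", {
  cmp <- compare_models(list(a = shared$fit, b = shared$fit))
  expect_equal(cmp$pairs$delta_elpd, 0, tolerance = 1e-9)
  expect_true(cmp$pairs$indistinguishable)
})
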