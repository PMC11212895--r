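test_that("replacement curves are monotone and bounded by the source", {
  tt <- seq(0, 400, by = 10)
  hom <- replacement_curve(tt, 0.01, 0.8, t0 = 42)
  expect_true(all(diff(hom) >= 0))
  expect_true(all(hom <= 0.8 + 1e-12))
  expect_equal(hom[tt <= 42], rep(0, sum(tt <= 42)))
  two <- replacement_curve(tt, 0.02, 0.8, t0 = 42, model = "two_compartment",
                           rate2 = 0.002, w = 0.6)
  expect_true(all(diff(two) >= 0))
  expect_true(all(two <= 0.8 + 1e-12))
  # the slow compartment keeps the two-compartment curve below the
  # homogeneous curve with the fast rate (first-in, last-out shortfall)
  fast_only <- replacement_curve(tt, 0.02, 0.8, t0 = 42)
  expect_true(all(two <= fast_only + 1e-12))
})

test_that("a flat zero donor-fraction series pins the rate near zero", {
  # given that the source is known to be substantially chimeric (HSC donor
  # fractions of 70-90% in this system), a series stuck at zero can only
  # mean no replacement is occurring
  obs <- chimerism_observations(data.frame(
    mouse_id = paste0("m", 1:30), t_bmt = seq(49, 340, length.out = 30),
    subset = "TCM", donor_fraction = 0))
  fit <- fit_replacement(obs, seed = 2,
                         priors = list(source_chimerism = c(stats::qlogis(0.8),
                                                            0.5)))
  expect_lt(unname(stats::quantile(fit$draws$rate, 0.975)), 0.005)
})

test_that("replacement fit recovers simulated truth", {
  set.seed(21)
  tt <- seq(49, 345, length.out = 30)
  mu <- replacement_curve(tt, 0.01, 0.8, t0 = 42)
  y <- pmin(pmax(mu + stats::rnorm(30, 0, 0.03), 0.001), 0.999)
  obs <- chimerism_observations(data.frame(mouse_id = paste0("m", 1:30),
                                           t_bmt = tt, subset = "TCM",
                                           donor_fraction = y))
  fit <- fit_replacement(obs, seed = 22)
  expect_true(fit$converged)
  qs <- apply(fit$draws[c("rate", "source_chimerism")], 2,
              stats::quantile, c(0.025, 0.975))
  expect_true(qs[1, "rate"] <= 0.01 && 0.01 <= qs[2, "rate"])
  expect_true(qs[1, "source_chimerism"] <= 0.8 && 0.8 <= qs[2, "source_chimerism"])
})

test_that("influx priors summarise posteriors faithfully", {
  # lognormal-shaped draws reproduce their own quantiles within 5%
  set.seed(4)
  draws <- data.frame(rate = stats::rlnorm(4000, -4.6, 0.2),
                      source_chimerism = stats::rbeta(4000, 40, 15))
  pr <- influx_prior_from_replacement(draws)
  expect_true(pr$quantile_match)
  qf <- stats::qlnorm(c(0.025, 0.975), pr$rate_meanlog, pr$rate_sdlog)
  qe <- stats::quantile(draws$rate, c(0.025, 0.975))
  expect_true(all(abs(qf - qe) / qe < 0.05))
  # degenerate posterior collapses to a point mass with a warning
  dd <- data.frame(rate = rep(0.01, 1500), source_chimerism = rep(0.7, 1500))
  expect_warning(pp <- influx_prior_from_replacement(dd), "degenerate")
  expect_equal(exp(pp$rate_meanlog), 0.01, tolerance = 1e-9)
  expect_lt(pp$rate_sdlog, 1e-5)
})

test_that("the fitted influx prior is far closer to the posterior than the vague prior", {
  set.seed(5)
  draws <- data.frame(rate = stats::rlnorm(4000, -4.6, 0.15),
                      source_chimerism = stats::rbeta(4000, 40, 15))
  pr <- influx_prior_from_replacement(draws)
  # histogram KL divergence of posterior draws from each prior density
  brk <- stats::quantile(draws$rate, seq(0, 1, 0.05))
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  p_emp <- rep(0.05, 20)
  kl <- function(meanlog, sdlog) {
    q <- stats::plnorm(brk[-1], meanlog, sdlog) -
      stats::plnorm(brk[-length(brk)], meanlog, sdlog)
    sum(p_emp * log(p_emp / pmax(q, 1e-300)))
  }
  kl_fit <- kl(pr$rate_meanlog, pr$rate_sdlog)
  kl_vague <- kl(log(0.01), 2.0)
  expect_gt(kl_vague / kl_fit, 10)
})

test_that("chimerism normalisation and precursor matching behave as expected", {
  expect_equal(normalize_chimerism(0.5, 0.5), 1.0)
  expect_error(normalize_chimerism(0.5, 0), "positive")
  # influx chimerism of TCM matches naive CD4, not the much higher DP1
  rank <- match_precursors(0.78, c(DP1 = 0.95, naive_CD4 = 0.80, TCM = 0.55))
  expect_equal(rank$candidate[1], "naive_CD4")
  rank2 <- match_precursors(0.56, c(DP1 = 0.95, naive_CD4 = 0.80, TCM = 0.55))
  expect_equal(rank2$candidate[1], "TCM")
})

test_that("synthetic precursor structure is recovered by chimerism matching", {
  # naive -> TCM -> TEM ground truth: the influx chimerism of each subset at
  # a finite observation time matches its true precursor in >= 90% of seeds
  wins <- 0L
  for (s in 1:20) {
    set.seed(700 + s)
    t_obs <- 250
    naive <- 0.82
    chi_tcm <- replacement_curve(t_obs, 0.01, naive, 42)
    chi_tem <- replacement_curve(t_obs, 0.008, chi_tcm, 42)
    noisy <- function(x) stats::rbeta(1, x * 400, (1 - x) * 400)
    cands <- c(DP1 = noisy(0.95), naive_CD4 = noisy(naive),
               TCM = noisy(chi_tcm))
    influx_tem <- noisy(chi_tcm)  # TEM influx carries its source's chimerism
    if (match_precursors(influx_tem, cands)$candidate[1] == "TCM")
      wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})
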