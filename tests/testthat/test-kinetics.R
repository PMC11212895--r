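test_that("parameter closure solves the single-population balance", {
  p <- homog_params(alpha = 0.045, f = 0.005)
  expect_equal(p$delta_fast, 0.05, tolerance = 1e-12)  # f + alpha = delta
  p0 <- close_parameters(kinetic_params("branched", epsilon = 0.5, beta = 0.3,
                                        alpha_fast = 0, alpha_slow = 0, f = 0,
                                        phi_fast_fraction = 1, N_fast = 1,
                                        N_slow = 0))
  expect_equal(p0$delta_fast, 0)
  expect_equal(p0$delta_slow, 0)
})

test_that("closure yields zero net growth under direct numerical integration", {
  # independent check: integrate the closed system 100 days with deSolve and
  # confirm each pool's size is unchanged
  p <- close_parameters(kinetic_params("branched", epsilon = 0.5, beta = 0.32,
                                       alpha_fast = 0.2, alpha_slow = 0.005,
                                       f = 0.01, phi_fast_fraction = 0.8,
                                       N_fast = 0.2, N_slow = 0.8))
  gen <- memdyn:::build_generator(p, "chase")
  x0 <- as.numeric(steady_state(p))
  rhs <- function(t, x, parms) list(as.numeric(gen$A %*% x + gen$b))
  sol <- deSolve::ode(x0, c(0, 100), rhs, NULL, rtol = 1e-10, atol = 1e-12)
  expect_lt(abs(sum(sol[2, -1]) - sum(x0)) / sum(x0), 1e-6)
})

test_that("stationarity residual is zero iff the balance holds", {
  p <- homog_params(alpha = 0.045, f = 0.005)       # closed: residual 0
  expect_lt(max(abs(stationarity_residual(p))), 1e-12)
  # growth without loss: residual equals f + alpha in the single pool
  pg <- kinetic_params("branched", epsilon = 0.5, beta = 0.3,
                       alpha_fast = 0.045, delta_fast = 0, delta_slow = 0,
                       f = 0.005, phi_fast_fraction = 1, N_fast = 1, N_slow = 0)
  expect_equal(unname(stationarity_residual(pg)["fast"]), 0.05,
               tolerance = 1e-12)
  set.seed(11)
  for (topo in c("branched", "linear", "burst", "temporal")) {
    for (r in 1:5) {
      p <- random_params(topo)
      expect_lt(max(abs(stationarity_residual(p))), 1e-9)
    }
  }
})

test_that("steady-state Ki67 split matches the closed form and its limits", {
  # no influx, no division: nothing feeds Ki67-high
  p0 <- close_parameters(kinetic_params("branched", epsilon = 0.5, beta = 0.3,
                                        alpha_fast = 0, alpha_slow = 0, f = 0,
                                        phi_fast_fraction = 1, N_fast = 1,
                                        N_slow = 0))
  s0 <- attr(steady_state(p0), "summaries")
  expect_equal(unname(s0["frac_ki67hi"]), 0)
  # beta = 0 under stationarity: cells never leave Ki67-high
  p1 <- close_parameters(kinetic_params("branched", epsilon = 0.5, beta = 0,
                                        alpha_fast = 0.02, f = 0.01,
                                        phi_fast_fraction = 1, N_fast = 1,
                                        N_slow = 0))
  s1 <- attr(steady_state(p1), "summaries")
  expect_equal(unname(s1["frac_ki67hi"]), 1, tolerance = 1e-12)
  # closed form (f + 2a)/(a + b + d) against long-time integration
  expect_equal(ki67_equilibrium_fraction(0.01, 0.02, 0.3226, 0.03), 0.1342,
               tolerance = 1e-3)
  p2 <- close_parameters(kinetic_params("branched", epsilon = 0.5,
                                        beta = 0.3226, alpha_fast = 0.02,
                                        f = 0.01, phi_fast_fraction = 1,
                                        N_fast = 1, N_slow = 0))
  # independent long-time integration of hand-written label-free flows
  rhs <- function(t, x, parms) {
    phi <- 0.01  # constant influx f * N0
    dhi <- phi + 2 * 0.02 * sum(x) - (0.02 + p2$delta_fast + 0.3226) * x[1]
    dlo <- 0.3226 * x[1] - (0.02 + p2$delta_fast) * x[2]
    list(c(dhi, dlo))
  }
  sol <- deSolve::ode(c(0.5, 0.5), c(0, 500), rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  k_long <- unname(sol[2, 2] / sum(sol[2, -1]))
  expect_equal(unname(attr(steady_state(p2), "summaries")["frac_ki67hi"]),
               k_long, tolerance = 1e-6)
  expect_equal(ki67_equilibrium_fraction(0.01, 0.02, 0.3226, p2$delta_fast),
               k_long, tolerance = 1e-6)
  expect_equal(ki67_equilibrium_fraction(0, 0, 1, 1), 0)
  expect_error(ki67_equilibrium_fraction(0, 0, 0, 0), "positive")
})

test_that("labelling solution honours trivial limits", {
  d <- experiment_design()
  p <- homog_params(epsilon = 0)
  out <- solve_labelling(p, d, c(0, 7, 21, 30))
  expect_equal(out$frac_brdu, rep(0, 4))
  k0 <- unname(attr(steady_state(p), "summaries")["frac_ki67hi"])
  expect_equal(out$frac_ki67hi, rep(k0, 4), tolerance = 1e-10)
  p2 <- homog_params(epsilon = 0.8)
  out2 <- solve_labelling(p2, d, 0)
  expect_equal(out2$frac_brdu, 0)
})

test_that("labelling solution matches the closed form and the hand-written ODE oracle", {
  d <- experiment_design()
  p <- homog_params(epsilon = 0.8, beta = 0.3226, alpha = 0.045, f = 0.005)
  tt <- c(1, 3, 7, 14, 21)
  out <- solve_labelling(p, d, tt)
  expect_equal(out$frac_brdu, homog_pulse_closed_form(0.8, 0.045, 0.005, tt),
               tolerance = 1e-8)
  tt2 <- c(1, 7, 14, 21, 25, 30, 35)
  out2 <- solve_labelling(p, d, tt2)
  orc <- homog_ode_oracle(0.8, 0.3226, 0.045, 0.05, 0.005, tt2)
  expect_equal(out2$frac_brdu, orc$frac_brdu, tolerance = 1e-7)
  expect_equal(out2$frac_brdu_in_ki67hi, orc$frac_brdu_in_ki67hi,
               tolerance = 1e-7)
  expect_equal(out2$frac_brdu_in_ki67lo, orc$frac_brdu_in_ki67lo,
               tolerance = 1e-7)
})

test_that("compiled and pure-R solver paths agree on all topologies", {
  d <- experiment_design()
  tt <- c(0, 1, 3, 7, 14, 21, 25, 30, 35)
  set.seed(7)
  for (topo in c("branched", "linear", "burst", "temporal")) {
    for (ns in c(1L, 3L)) {
      p <- random_params(topo, n_stages = ns)
      a <- solve_labelling(p, d, tt)
      # re-derive through the R block solver
      so <- memdyn:::steady_occupancy(p)
      gp <- memdyn:::build_generator(p, "pulse")
      pos_idx <- so$neg_idx + memdyn:::state_dim(p) / 2L
      ystar <- c(so$hi, so$lo)
      blk <- function(gen, z0, tt2) {
        App <- gen$A[pos_idx, pos_idx, drop = FALSE]
        C <- gen$A[pos_idx, so$neg_idx, drop = FALSE]
        memdyn:::propagate_affine(App - C,
                                  as.numeric(C %*% ystar) + gen$b[pos_idx],
                                  z0, tt2)
      }
      inp <- tt <= d$pulse_end
      z <- matrix(NA_real_, length(ystar), length(tt))
      z[, inp] <- blk(gp, numeric(length(ystar)), tt[inp])
      zp <- as.numeric(blk(gp, numeric(length(ystar)), d$pulse_end))
      z[, !inp] <- blk(so$gen_chase, zp, tt[!inp] - d$pulse_end)
      expect_equal(a$frac_brdu, colSums(z) / sum(ystar), tolerance = 1e-9)
    }
  }
})

test_that("label accrues monotonically during the pulse and stays in [0,1]", {
  d <- experiment_design()
  tt <- seq(0, 21, by = 0.5)
  set.seed(3)
  for (topo in c("branched", "linear", "burst", "temporal")) {
    for (r in 1:3) {
      p <- random_params(topo)
      out <- solve_labelling(p, d, tt)
      expect_true(all(diff(out$frac_brdu) > -1e-10))
      full <- solve_labelling(p, d, seq(0, 35, by = 1))
      expect_true(all(full$frac_brdu >= -1e-12 & full$frac_brdu <= 1 + 1e-12))
      expect_true(all(full$frac_brdu_in_ki67hi <= 1 + 1e-12))
    }
  }
})

test_that("the labelled fraction within Ki67-high saturates below epsilon's bound", {
  # with eps < 1, BrdU+|Ki67-high approaches but never exceeds the fixed
  # point implied by eps (deviation from 100% labelling bounds eps)
  d <- experiment_design()
  for (eps in c(0.4, 0.7, 0.95)) {
    p <- homog_params(epsilon = eps)
    out <- solve_labelling(p, d, seq(0.5, 21, by = 0.5))
    expect_true(all(out$frac_brdu_in_ki67hi < 1 - 1e-6))
    expect_true(max(out$frac_brdu_in_ki67hi) < eps + (1 - eps) * 0.999)
  }
})

test_that("solution is continuous at the pulse-chase switch", {
  p <- branched_params()
  d <- experiment_design()
  out <- solve_labelling(p, d, c(21 - 1e-6, 21, 21 + 1e-6))
  expect_lt(diff(range(out$frac_brdu)), 1e-6)
})

test_that("staged Ki67 sharpens the delay before labelled Ki67-low cells appear", {
  # the Ki67 lifetime is the delay before BrdU+ Ki67-low cells first appear;
  # an Erlang chain makes the onset sharper than the exponential stage
  d <- experiment_design()
  tt <- seq(0.25, 6, by = 0.25)
  p1 <- homog_params(epsilon = 0.8, beta = 1 / 3.1, n_stages = 1L)
  p5 <- homog_params(epsilon = 0.8, beta = 1 / 3.1, n_stages = 5L)
  lo1 <- solve_labelling(p1, d, tt)$frac_brdu_in_ki67lo
  lo5 <- solve_labelling(p5, d, tt)$frac_brdu_in_ki67lo
  early <- tt <= 1.5  # well before the mean Ki67 lifetime of 3.1 d
  expect_true(all(lo5[early] < lo1[early]))
  t_on1 <- tt[min(which(lo1 > 0.01))]
  t_on5 <- tt[min(which(lo5 > 0.01))]
  expect_gt(t_on5, t_on1)   # staged onset lags by a delay approaching T
})

test_that("division-only dynamics grow exponentially (conservation law)", {
  # delta = 0, influx 0: total follows N0 * exp(alpha * t) exactly
  p <- kinetic_params("branched", epsilon = 0.5, beta = 0.3,
                      alpha_fast = 0.07, delta_fast = 0, delta_slow = 0,
                      f = 0, phi_fast_fraction = 1, N_fast = 1, N_slow = 0)
  gen <- memdyn:::build_generator(p, "pulse")
  x0 <- numeric(memdyn:::state_dim(p))
  x0[memdyn:::state_index(p, 1L, 1L, 0L)] <- 0.3
  x0[memdyn:::state_index(p, 1L, 0L, 0L)] <- 0.7
  out <- memdyn:::propagate_affine(gen$A, gen$b, x0, c(5, 10, 20))
  expect_equal(colSums(out), exp(0.07 * c(5, 10, 20)), tolerance = 1e-8)
})

test_that("non-stationary parameters are refused with guidance", {
  p <- kinetic_params("branched", epsilon = 0.5, beta = 0.3, alpha_fast = 0.1,
                      delta_fast = 0.5, delta_slow = 0.5, f = 0.01,
                      phi_fast_fraction = 1, N_fast = 1, N_slow = 0)
  expect_error(steady_state(p), "close_parameters")
  expect_error(solve_labelling(p, experiment_design(), 7), "close_parameters")
})

test_that("incompatible closures and invalid parameters are rejected", {
  expect_error(close_parameters(
    kinetic_params("linear", epsilon = 0.5, beta = 0.3, alpha_fast = 0.01,
                   alpha_slow = 0.005, gamma = 0.5, f = 0.001, N_fast = 0.5,
                   N_slow = 0.5)), "no non-negative")
  expect_error(kinetic_params("branched", epsilon = 1.2, beta = 0.3,
                              alpha_fast = 0.1, f = 0.01,
                              phi_fast_fraction = 1, N_fast = 1, N_slow = 0),
               "epsilon")
  expect_error(kinetic_params("temporal", epsilon = 0.5, beta = 0.3,
                              alpha_fast = 0.1, f = 0.01, N_fast = 1,
                              N_slow = 0.5), "single pool")
})
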