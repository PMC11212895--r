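# Shared fixtures and independent oracles for the test suite.

# single-pool population expressed through the branched container
homog_params <- function(epsilon = 0.8, beta = 0.3226, alpha = 0.045,
                         f = 0.005, n_stages = 1L) {
  close_parameters(kinetic_params("branched", epsilon = epsilon, beta = beta,
                                  alpha_fast = alpha, f = f,
                                  phi_fast_fraction = 1, N_fast = 1,
                                  N_slow = 0, n_stages = n_stages))
}

# the benchmark two-pool branched stratum used across tests
branched_params <- function() {
  close_parameters(kinetic_params("branched", epsilon = 0.6, beta = 1 / 3.1,
                                  alpha_fast = 0.15, alpha_slow = 0.007,
                                  f = 0.008, phi_fast_fraction = 0.6,
                                  N_fast = 0.45, N_slow = 0.55))
}

# random stationary parameter sets per topology (for property loops)
random_params <- function(topology, n_stages = 1L) {
  repeat {
    nu <- stats::runif(1, 0.15, 0.6)
    p <- try(switch(topology,
      branched = kinetic_params("branched", epsilon = stats::runif(1, 0.3, 0.9),
        beta = stats::runif(1, 0.2, 0.5), alpha_fast = stats::runif(1, 0.05, 0.3),
        alpha_slow = stats::runif(1, 0.002, 0.02), f = stats::runif(1, 0.003, 0.02),
        phi_fast_fraction = stats::runif(1), N_fast = nu, N_slow = 1 - nu,
        n_stages = n_stages),
      linear = kinetic_params("linear", epsilon = stats::runif(1, 0.3, 0.9),
        beta = stats::runif(1, 0.2, 0.5), alpha_fast = stats::runif(1, 0.05, 0.3),
        alpha_slow = stats::runif(1, 0.002, 0.02), gamma = stats::runif(1, 0.002, 0.05),
        f = stats::runif(1, 0.003, 0.02), N_fast = nu, N_slow = 1 - nu,
        n_stages = n_stages),
      burst = kinetic_params("burst", epsilon = stats::runif(1, 0.3, 0.9),
        beta = stats::runif(1, 0.2, 0.5), alpha_fast = stats::runif(1, 0.05, 0.3),
        activation = stats::runif(1, 0.005, 0.05), reversion = stats::runif(1, 0.01, 0.1),
        f = stats::runif(1, 0.003, 0.02), N_fast = nu, N_slow = 1 - nu,
        n_stages = n_stages),
      temporal = kinetic_params("temporal", epsilon = stats::runif(1, 0.3, 0.9),
        beta = stats::runif(1, 0.2, 0.5), alpha_fast = stats::runif(1, 0.02, 0.1),
        delta_fast = stats::runif(1, 0.1, 0.3), f = stats::runif(1, 0.003, 0.02),
        N_fast = 1, N_slow = 0, n_stages = n_stages)),
      silent = TRUE)
    if (!inherits(p, "try-error")) {
      pc <- try(close_parameters(p), silent = TRUE)
      if (!inherits(pc, "try-error")) return(pc)
    }
  }
}

# Independent numerical-integration oracle: integrates the labelling system
# with deSolve from a hand-written right-hand side for a single homogeneous
# population (flows written from first principles, no reuse of the package's
# generator machinery). States: (Khi-, Klo-, Khi+, Klo+).
homog_ode_oracle <- function(epsilon, beta, alpha, delta, f, times,
                             pulse_end = 21) {
  rhs <- function(t, x, parms) {
    eps <- if (t <= pulse_end) epsilon else 0
    hin <- x[1]; lon <- x[2]; hip <- x[3]; lop <- x[4]
    N <- hin + lon + hip + lop
    phi <- f * N
    # divisions: mother removed, two Ki67-high daughters; during the pulse
    # unlabelled mothers yield labelled daughters with probability eps
    dhin <- phi * (1 - eps) + 2 * alpha * (1 - eps) * (hin + lon) -
      (alpha + delta + beta) * hin
    dlon <- beta * hin - (alpha + delta) * lon
    dhip <- phi * eps + 2 * alpha * eps * (hin + lon) + 2 * alpha * (hip + lop) -
      (alpha + delta + beta) * hip
    dlop <- beta * hip - (alpha + delta) * lop
    list(c(dhin, dlon, dhip, dlop))
  }
  k0 <- (f + 2 * alpha) / (alpha + beta + delta)
  x0 <- c(k0, 1 - k0, 0, 0)
  ev <- sort(unique(c(0, pulse_end, times)))
  sol <- deSolve::ode(y = x0, times = ev, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  sol <- sol[match(times, sol[, 1]), -1, drop = FALSE]
  data.frame(time = times,
             frac_brdu = (sol[, 3] + sol[, 4]) / rowSums(sol),
             frac_ki67hi = (sol[, 1] + sol[, 3]) / rowSums(sol),
             frac_brdu_in_ki67hi = sol[, 3] / (sol[, 1] + sol[, 3]),
             frac_brdu_in_ki67lo = sol[, 4] / (sol[, 2] + sol[, 4]))
}

# closed-form pulse-phase labelled fraction for the homogeneous model:
# dL/dt has upslope eps*(f + 2*alpha) and relaxation rate 2*alpha*eps + f
homog_pulse_closed_form <- function(epsilon, alpha, f, times) {
  p0 <- epsilon * (f + 2 * alpha)
  r <- 2 * alpha * epsilon + f
  p0 / r * (1 - exp(-r * times))
}

make_influx_prior <- function(meanlog, sdlog) {
  structure(list(rate_meanlog = meanlog, rate_sdlog = sdlog,
                 chimerism_shape1 = 10, chimerism_shape2 = 5,
                 quantile_match = TRUE),
            class = "influx_prior")
}

quick_sampler <- list(n_chains = 3L, n_warmup = 1200L, n_iter = 1000L)
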