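#' Kinetic parameters for one stratified memory population
#'
#' Bundles all rates and subpopulation sizes describing the dynamics of one
#' memory CD4 T cell population (one cohort x subset x lineage stratum) under
#' a given topology of kinetic heterogeneity. Rates are per day; sizes are in
#' arbitrary cell units (only ratios matter for the observed fractions).
#'
#' Topologies:
#' \describe{
#'   \item{branched}{new cells bifurcate at entry into independent fast and
#'     slow subpopulations; a fraction \code{phi_fast_fraction} of the influx
#'     enters the fast pool.}
#'   \item{linear}{all influx enters the fast pool; cells mature fast to slow
#'     at rate \code{gamma}.}
#'   \item{burst}{a quiescent pool (slow) receives the influx; cells are
#'     triggered into a dynamic state (fast) at rate \code{activation} and
#'     revert at rate \code{reversion}. By default the quiescent pool does not
#'     divide (\code{alpha_slow = 0}).}
#'   \item{temporal}{a single kinetically homogeneous pool in which the loss
#'     rate depends on Ki67 expression: \code{delta_fast} is the loss rate of
#'     Ki67-high cells and \code{delta_slow} that of Ki67-low cells;
#'     \code{alpha_fast} is the common division rate. \code{N_slow} must be 0
#'     (\code{N_fast} is the total pool size).}
#' }
#'
#' Ki67 decay high to low is exponential with rate \code{beta = 1/T} where
#' \code{T} is the Ki67 lifetime in days; setting \code{n_stages > 1} replaces
#' the single stage by an Erlang chain of \code{n_stages} stages with the same
#' total mean \code{T}, which sharpens the delay before labelled Ki67-low
#' cells first appear.
#'
#' The per-capita influx rate \code{f} gives a total influx
#' \code{phi = f * (N_fast + N_slow)} of new cells per day; new cells enter as
#' Ki67-high, reflecting recent division in the precursor compartment.
#'
#' @param topology one of \code{"branched"}, \code{"linear"}, \code{"burst"},
#'   \code{"temporal"}.
#' @param epsilon probability that a division during the labelling period
#'   renders both daughters BrdU-positive, in \[0,1\].
#' @param beta Ki67-high to Ki67-low transit rate, /day (1 / Ki67 lifetime).
#' @param alpha_fast,alpha_slow division rates of the fast and slow pools, /day.
#' @param delta_fast,delta_slow loss rates, /day; either may be \code{NA} and
#'   solved by \code{\link{close_parameters}}.
#' @param gamma fast-to-slow maturation rate, /day (linear topology).
#' @param activation,reversion slow-to-fast triggering and fast-to-slow return
#'   rates, /day (burst topology).
#' @param f per-capita influx rate, /day.
#' @param phi_fast_fraction fraction of the influx entering the fast pool.
#'   Defaults: 1 (linear), 0 (burst), 1 (temporal); must be given for branched.
#' @param N_fast,N_slow subpopulation sizes (cells).
#' @param n_stages number of Erlang stages for Ki67-high transit (default 1,
#'   i.e. exponential).
#' @return an object of class \code{kinetic_params}.
#' @seealso \code{\link{close_parameters}}, \code{\link{solve_labelling}}
#' @export
kinetic_params <- function(topology = c("branched", "linear", "burst", "temporal"),
                           epsilon, beta, alpha_fast, alpha_slow = 0,
                           delta_fast = NA_real_, delta_slow = NA_real_,
                           gamma = 0, activation = 0, reversion = 0,
                           f, phi_fast_fraction = NULL,
                           N_fast, N_slow, n_stages = 1L) {
  topology <- match.arg(topology)
  if (is.null(phi_fast_fraction)) {
    phi_fast_fraction <- switch(topology,
      branched = stop("phi_fast_fraction must be supplied for the branched topology",
                      call. = FALSE),
      linear = 1, burst = 0, temporal = 1)
  }
  p <- list(topology = topology, epsilon = epsilon, beta = beta,
            alpha_fast = alpha_fast, alpha_slow = alpha_slow,
            delta_fast = delta_fast, delta_slow = delta_slow,
            gamma = gamma, activation = activation, reversion = reversion,
            f = f, phi_fast_fraction = phi_fast_fraction,
            N_fast = N_fast, N_slow = N_slow, n_stages = as.integer(n_stages))
  validate_kinetic_params(p)
  class(p) <- "kinetic_params"
  p
}

validate_kinetic_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.nan(x)
  for (nm in c("epsilon", "beta", "alpha_fast", "alpha_slow", "gamma",
               "activation", "reversion", "f", "phi_fast_fraction",
               "N_fast", "N_slow")) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a single number", call. = FALSE)
  }
  nonneg <- c("beta", "alpha_fast", "alpha_slow", "gamma", "activation",
              "reversion", "f", "N_fast", "N_slow")
  for (nm in nonneg) {
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be non-negative", call. = FALSE)
  }
  for (nm in c("epsilon", "phi_fast_fraction")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop("parameter '", nm, "' must lie in [0,1]", call. = FALSE)
  }
  for (nm in c("delta_fast", "delta_slow")) {
    if (!is.na(p[[nm]]) && p[[nm]] < 0) stop("parameter '", nm, "' must be non-negative", call. = FALSE)
  }
  if (p$topology == "temporal" && p$N_slow != 0)
    stop("temporal topology uses a single pool: set N_slow = 0 (N_fast is the total size)",
         call. = FALSE)
  if (p$n_stages < 1L) stop("n_stages must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (", x$topology, " topology)\n", sep = "")
  cat(sprintf("  epsilon = %.4g, beta = %.4g /d (Ki67 lifetime %.3g d, %d stage%s)\n",
              x$epsilon, x$beta, 1 / x$beta, x$n_stages, if (x$n_stages > 1) "s" else ""))
  cat(sprintf("  fast: alpha = %.4g, delta = %.4g /d, N = %.4g\n",
              x$alpha_fast, x$delta_fast, x$N_fast))
  cat(sprintf("  slow: alpha = %.4g, delta = %.4g /d, N = %.4g\n",
              x$alpha_slow, x$delta_slow, x$N_slow))
  cat(sprintf("  influx: f = %.4g /d (fast share %.3g)", x$f, x$phi_fast_fraction))
  extra <- switch(x$topology,
    linear = sprintf(", gamma = %.4g /d", x$gamma),
    burst = sprintf(", activation = %.4g, reversion = %.4g /d", x$activation, x$reversion),
    "")
  cat(extra, "\n", sep = "")
  invisible(x)
}

total_influx <- function(p) p$f * (p$N_fast + p$N_slow)

#' Solve loss rates so that subpopulation sizes are stationary
#'
#' Closes a partially specified parameter set under the quasi-equilibrium
#' assumption: both host and donor memory populations were approximately
#' constant in size over the 35-day labelling window, so the loss rate of each
#' subpopulation is determined by its division rate and the influx it
#' receives. By default the two loss rates (\code{delta_fast},
#' \code{delta_slow}) are solved; for the temporal topology
#' \code{delta_slow} (the Ki67-low loss rate) is solved given
#' \code{delta_fast}.
#'
#' @param p a \code{\link{kinetic_params}} object, with the rates to be solved
#'   set to \code{NA} (they are overwritten in any case).
#' @return a \code{kinetic_params} object satisfying
#'   \code{max(abs(stationarity_residual(p))) <= 1e-9}.
#' @export
close_parameters <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  phi <- total_influx(p)
  pf <- p$phi_fast_fraction
  bad <- function(nm, val) stop("close_parameters: no non-negative solution for ",
                                nm, " (", signif(val, 4),
                                "); parameter set incompatible with stationarity",
                                call. = FALSE)
  if (p$topology == "temporal") {
    N <- p$N_fast
    if (N <= 0) stop("temporal topology requires N_fast > 0", call. = FALSE)
    if (is.na(p$delta_fast)) stop("temporal closure solves delta_slow; supply delta_fast",
                                  call. = FALSE)
    Y <- sum(ki67hi_stage_occupancy_temporal(p))
    if (Y >= N) stop("close_parameters: Ki67-high occupancy exceeds pool size; ",
                     "reduce influx or division rate, or increase beta", call. = FALSE)
    dlo <- (phi + p$alpha_fast * N - p$delta_fast * Y) / (N - Y)
    if (dlo < 0) bad("delta_slow", dlo)
    p$delta_slow <- dlo
  } else {
    Nf <- p$N_fast; Ns <- p$N_slow
    inflow_f <- switch(p$topology,
      branched = phi * pf,
      linear = phi,
      burst = phi * pf + p$activation * Ns)
    inflow_s <- switch(p$topology,
      branched = phi * (1 - pf),
      linear = p$gamma * Nf,
      burst = phi * (1 - pf) + p$reversion * Nf)
    out_f <- switch(p$topology, branched = 0, linear = p$gamma, burst = p$reversion)
    out_s <- switch(p$topology, branched = 0, linear = 0, burst = p$activation)
    if (Nf > 0) {
      df <- p$alpha_fast - out_f + inflow_f / Nf
      if (df < 0) bad("delta_fast", df)
      p$delta_fast <- df
    } else {
      if (inflow_f > 0) stop("close_parameters: nonzero inflow into empty fast pool",
                             call. = FALSE)
      p$delta_fast <- if (is.na(p$delta_fast)) 0 else p$delta_fast
    }
    if (Ns > 0) {
      ds <- p$alpha_slow - out_s + inflow_s / Ns
      if (ds < 0) bad("delta_slow", ds)
      p$delta_slow <- ds
    } else {
      if (inflow_s > 0) stop("close_parameters: nonzero inflow into empty slow pool",
                             call. = FALSE)
      p$delta_slow <- if (is.na(p$delta_slow)) 0 else p$delta_slow
    }
  }
  p
}

# Steady Ki67-high stage occupancies of the temporal model's single pool,
# given the pool size; does not depend on the Ki67-low loss rate.
ki67hi_stage_occupancy_temporal <- function(p) {
  N <- p$N_fast
  n <- p$n_stages
  bn <- p$beta * n
  phi <- total_influx(p)
  y <- numeric(n)
  y[1] <- (phi + 2 * p$alpha_fast * N) / (p$alpha_fast + p$delta_fast + bn)
  if (n > 1) for (j in 2:n) y[j] <- bn * y[j - 1] / (p$alpha_fast + p$delta_fast + bn)
  y
}

#' Relative growth rate of each subpopulation at the label-free steady state
#'
#' Returns \code{dN_i/dt / N_i} per day for the fast and slow subpopulations
#' (for the temporal topology, the single pool's total relative growth rate is
#' reported in both entries). A zero vector certifies quasi-equilibrium. For a
#' subpopulation of size zero the residual is reported on the absolute scale
#' (cells/day) rather than dividing by zero.
#'
#' @param p a \code{\link{kinetic_params}} object with all rates specified.
#' @return named numeric vector \code{c(fast = , slow = )}, /day.
#' @export
stationarity_residual <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (is.na(p$delta_fast) || is.na(p$delta_slow))
    stop("loss rates unspecified; call close_parameters() first", call. = FALSE)
  phi <- total_influx(p)
  pf <- p$phi_fast_fraction
  rel <- function(flow, N) if (N > 0) flow / N else flow
  if (p$topology == "temporal") {
    N <- p$N_fast
    Y <- sum(ki67hi_stage_occupancy_temporal(p))
    flow <- phi + p$alpha_fast * N - p$delta_fast * Y - p$delta_slow * (N - Y)
    r <- rel(flow, N)
    return(c(fast = r, slow = r))
  }
  Nf <- p$N_fast; Ns <- p$N_slow
  flow_f <- switch(p$topology,
    branched = phi * pf + (p$alpha_fast - p$delta_fast) * Nf,
    linear = phi + (p$alpha_fast - p$delta_fast - p$gamma) * Nf,
    burst = phi * pf + p$activation * Ns +
      (p$alpha_fast - p$delta_fast - p$reversion) * Nf)
  flow_s <- switch(p$topology,
    branched = phi * (1 - pf) + (p$alpha_slow - p$delta_slow) * Ns,
    linear = p$gamma * Nf + (p$alpha_slow - p$delta_slow) * Ns,
    burst = phi * (1 - pf) + p$reversion * Nf +
      (p$alpha_slow - p$delta_slow - p$activation) * Ns)
  c(fast = rel(flow_f, Nf), slow = rel(flow_s, Ns))
}

# ---- state indexing -------------------------------------------------------
# Active pools: 2 for heterogeneous topologies, 1 for temporal.
# Within a pool: Ki67 stages 1..n (high) then stage 0 (low); BrdU- block
# first, then BrdU+. State count d = npool * (n+1) * 2.

n_pools <- function(p) if (p$topology == "temporal") 1L else 2L

state_dim <- function(p) n_pools(p) * (p$n_stages + 1L) * 2L

# index of (pool, stage, brdu): stage in 1..n = Ki67 high, 0 = low; brdu 0/1
state_index <- function(p, pool, stage, brdu) {
  n <- p$n_stages
  per_pool <- n + 1L
  npool <- n_pools(p)
  stage_slot <- ifelse(stage == 0L, per_pool, stage)
  (brdu * npool + (pool - 1L)) * per_pool + stage_slot
}

state_labels <- function(p) {
  n <- p$n_stages
  npool <- n_pools(p)
  pools <- if (npool == 1L) "pool" else c("fast", "slow")
  lab <- character(state_dim(p))
  for (b in 0:1) for (i in seq_len(npool)) for (s in c(seq_len(n), 0L)) {
    lab[state_index(p, i, s, b)] <- paste0(pools[i], ".",
      if (s == 0L) "ki67lo" else paste0("ki67hi", if (n > 1) s else ""),
      ".", if (b == 1L) "brdu_pos" else "brdu_neg")
  }
  lab
}

# loss and division rates per pool; for temporal, delta depends on Ki67 state
pool_rates <- function(p, pool, stage) {
  if (p$topology == "temporal") {
    list(alpha = p$alpha_fast,
         delta = if (stage == 0L) p$delta_slow else p$delta_fast)
  } else if (pool == 1L) {
    list(alpha = p$alpha_fast, delta = p$delta_fast)
  } else {
    list(alpha = p$alpha_slow, delta = p$delta_slow)
  }
}

# pool-to-pool transition rates (applied to every (stage, brdu) state)
pool_transitions <- function(p) {
  switch(p$topology,
    branched = matrix(0, 2, 2),
    linear = matrix(c(0, p$gamma, 0, 0), 2, 2, byrow = TRUE),  # [from, to]
    burst = matrix(c(0, p$reversion, p$activation, 0), 2, 2, byrow = TRUE),
    temporal = matrix(0, 1, 1))
}

# Generator of the labelling dynamics: dx/dt = A x + b.
# phase "pulse": divisions of BrdU- mothers label both daughters with
# probability epsilon, and incoming cells are BrdU+ with probability epsilon;
# phase "chase": daughters inherit the mother's BrdU status and influx is
# unlabelled. Daughters always enter Ki67-high stage 1.
build_generator <- function(p, phase = c("pulse", "chase")) {
  phase <- match.arg(phase)
  eps <- if (phase == "pulse") p$epsilon else 0
  n <- p$n_stages
  npool <- n_pools(p)
  per_pool <- n + 1L
  d <- npool * per_pool * 2L
  ix <- function(pool, stage, brdu) {
    # stage 0 (Ki67-low) occupies the last slot of each pool block
    (brdu * npool + (pool - 1L)) * per_pool + (if (stage == 0L) per_pool else stage)
  }
  A <- matrix(0, d, d)
  b <- numeric(d)
  bn <- p$beta * n
  trans <- pool_transitions(p)
  phi <- total_influx(p)
  phi_pool <- if (npool == 1L) phi else c(phi * p$phi_fast_fraction,
                                          phi * (1 - p$phi_fast_fraction))
  temporal <- p$topology == "temporal"
  for (i in seq_len(npool)) {
    alpha_i <- if (temporal || i == 1L) p$alpha_fast else p$alpha_slow
    t_out <- if (npool == 2L) trans[i, 3L - i] else 0
    for (br in 0:1) {
      hi1_pos <- ix(i, 1L, 1L)
      hi1_neg <- ix(i, 1L, 0L)
      for (s in c(seq_len(n), 0L)) {
        j <- ix(i, s, br)
        delta_is <- if (temporal) {
          if (s == 0L) p$delta_slow else p$delta_fast
        } else if (i == 1L) p$delta_fast else p$delta_slow
        # outflows: division removes mother; death; Ki67 transit; pool moves
        out <- alpha_i + delta_is + t_out
        if (s != 0L) out <- out + bn
        A[j, j] <- A[j, j] - out
        # Ki67 transit to next stage (or to low from stage n)
        if (s != 0L) {
          jn <- ix(i, if (s == n) 0L else s + 1L, br)
          A[jn, j] <- A[jn, j] + bn
        }
        # pool transitions preserve Ki67 stage and BrdU status
        if (t_out > 0) {
          jk <- ix(3L - i, s, br)
          A[jk, j] <- A[jk, j] + t_out
        }
        # division: two daughters into Ki67-high stage 1 of the same pool
        if (br == 1L) {
          A[hi1_pos, j] <- A[hi1_pos, j] + 2 * alpha_i
        } else {
          if (eps > 0) A[hi1_pos, j] <- A[hi1_pos, j] + 2 * alpha_i * eps
          A[hi1_neg, j] <- A[hi1_neg, j] + 2 * alpha_i * (1 - eps)
        }
      }
    }
    # influx enters Ki67-high stage 1
    b[ix(i, 1L, 1L)] <- b[ix(i, 1L, 1L)] + phi_pool[i] * eps
    b[ix(i, 1L, 0L)] <- b[ix(i, 1L, 0L)] + phi_pool[i] * (1 - eps)
  }
  list(A = A, b = b)
}

# ---- linear propagation ---------------------------------------------------

# exp(M) by scaling and squaring with a truncated Taylor series; M is small
expm_dense <- function(M) {
  nrm <- max(colSums(abs(M)))
  s <- max(0L, ceiling(log2(max(nrm, .Machine$double.eps))) + 4L)
  Ms <- M / 2^s
  d <- nrow(M)
  E <- diag(d) + Ms
  term <- Ms
  for (k in 2:16) {
    term <- term %*% Ms / k
    E <- E + term
  }
  if (s > 0) for (i in seq_len(s)) E <- E %*% E
  E
}

# Solve dx/dt = A x + b from x0, returning states at `times` (ascending, >= 0)
# columns = times. Uses the eigendecomposition of the augmented homogeneous
# system; falls back to stepping with scaling-and-squaring exponentials when
# the eigenvector basis is ill-conditioned.
propagate_affine <- function(A, b, x0, times) {
  d <- length(x0)
  At <- rbind(cbind(A, b), 0)
  z0 <- c(x0, 1)
  out <- matrix(NA_real_, d, length(times))
  eg <- tryCatch(eigen(At), error = function(e) NULL)
  w <- NULL
  if (!is.null(eg)) {
    w <- tryCatch(solve(eg$vectors, z0), error = function(e) NULL)
    if (!is.null(w)) {
      recon <- max(Mod(eg$vectors %*% w - z0))
      if (!is.finite(recon) || recon > 1e-8 * max(1, max(Mod(z0)))) w <- NULL
    }
  }
  if (!is.null(w)) {
    for (k in seq_along(times)) {
      z <- eg$vectors %*% (w * exp(eg$values * times[k]))
      out[, k] <- Re(z[seq_len(d)])
    }
  } else {
    ts <- c(0, times)
    z <- z0
    for (k in seq_along(times)) {
      dt <- ts[k + 1] - ts[k]
      if (dt > 0) z <- expm_dense(At * dt) %*% z
      out[, k] <- z[seq_len(d)]
    }
  }
  out
}

# BrdU-negative steady occupancies (vector over pools x stages, ordered
# high stages 1..n then low per pool), solving the Ki67 balance with pool
# sizes fixed. Shared by steady_state() and the labelling solver.
steady_occupancy <- function(p) {
  n <- p$n_stages
  npool <- n_pools(p)
  gen <- build_generator(p, "chase")
  Npool <- if (npool == 1L) p$N_fast else c(p$N_fast, p$N_slow)
  hi_idx <- integer(0)
  for (i in seq_len(npool)) hi_idx <- c(hi_idx, state_index(p, i, seq_len(n), 0L))
  lo_idx <- vapply(seq_len(npool), function(i) state_index(p, i, 0L, 0L), 1L)
  neg_idx <- c(hi_idx, lo_idx)
  # empty pools have zero occupancy and are excluded from the balance solve
  act <- which(Npool > 0)
  hi_act <- as.vector(outer(seq_len(n), (act - 1) * n, `+`))
  Ab <- gen$A[neg_idx, neg_idx, drop = FALSE]
  bb <- gen$b[neg_idx]
  nh <- length(hi_idx)
  Ahh <- Ab[hi_act, hi_act, drop = FALSE]
  Ahl <- Ab[hi_act, nh + act, drop = FALSE]
  S <- matrix(0, length(act), length(hi_act))
  for (i in seq_along(act)) S[i, ((i - 1) * n + 1):(i * n)] <- 1
  M <- Ahh - Ahl %*% S
  rhs <- -(Ahl %*% Npool[act] + bb[hi_act])
  ya <- tryCatch(as.numeric(solve(M, rhs)), error = function(e)
    stop("steady state: singular Ki67 balance system", call. = FALSE))
  y <- numeric(nh)
  y[hi_act] <- ya
  xlo <- Npool
  xlo[act] <- Npool[act] - as.numeric(S %*% ya)
  if (any(y < -1e-9 * max(Npool)) || any(xlo < -1e-9 * max(Npool)))
    stop("steady state: negative occupancy; parameters imply Ki67-high ",
         "fraction outside [0,1]", call. = FALSE)
  list(hi = pmax(y, 0), lo = pmax(xlo, 0),
       hi_idx = hi_idx, lo_idx = lo_idx, neg_idx = neg_idx, gen_chase = gen)
}

#' Label-free steady state of the compartment model
#'
#' Computes the distribution of cells over Ki67 stages within each
#' subpopulation at the BrdU-free steady state, given stationary parameters.
#' All BrdU-positive compartments are exactly zero; the Ki67-high/low split
#' balances influx (entering Ki67-high), division (returning cells to
#' Ki67-high), Ki67 decay, and loss.
#'
#' @param p a stationary \code{\link{kinetic_params}} object (see
#'   \code{\link{close_parameters}}); refused otherwise.
#' @param tol maximum permitted absolute stationarity residual, /day.
#' @return numeric vector of compartment sizes (named by compartment) of
#'   length \code{2 * npools * (n_stages + 1)}, with attribute
#'   \code{"summaries"} holding the derived fractions.
#' @export
steady_state <- function(p, tol = 1e-8) {
  stopifnot(inherits(p, "kinetic_params"))
  res <- stationarity_residual(p)
  if (max(abs(res)) > tol)
    stop("parameters are not stationary (residual ", signif(max(abs(res)), 3),
         "/day); use close_parameters() to solve the loss rates", call. = FALSE)
  so <- steady_occupancy(p)
  x <- numeric(state_dim(p))
  x[so$hi_idx] <- so$hi
  x[so$lo_idx] <- so$lo
  names(x) <- state_labels(p)
  attr(x, "summaries") <- state_summaries(p, x)
  x
}

# Derived observable fractions from a full state vector
state_summaries <- function(p, x) {
  n <- p$n_stages
  npool <- n_pools(p)
  hi <- pos <- hi_pos <- total <- 0
  for (i in seq_len(npool)) for (br in 0:1) {
    hs <- x[state_index(p, i, seq_len(n), br)]
    lo <- x[state_index(p, i, 0L, br)]
    total <- total + sum(hs) + lo
    hi <- hi + sum(hs)
    if (br == 1L) {
      pos <- pos + sum(hs) + lo
      hi_pos <- hi_pos + sum(hs)
    }
  }
  lo_tot <- total - hi
  lo_pos <- pos - hi_pos
  sdiv <- function(a, b) if (b > 0) a / b else 0
  stats::setNames(as.numeric(c(total, sdiv(hi, total), sdiv(pos, total),
                               sdiv(hi_pos, hi), sdiv(lo_pos, lo_tot))),
                  c("total", "frac_ki67hi", "frac_brdu",
                    "frac_brdu_in_ki67hi", "frac_brdu_in_ki67lo"))
}

#' Stationary Ki67-high fraction of a homogeneous population
#'
#' Closed form for a single kinetically homogeneous population with per-capita
#' influx \code{f} (new cells Ki67-high), division rate \code{alpha} (division
#' removes the mother and creates two Ki67-high daughters), Ki67 decay rate
#' \code{beta} and loss rate \code{delta}:
#' \deqn{k^* = (f + 2\alpha) / (\alpha + \beta + \delta).}
#'
#' @param f,alpha,beta,delta rates, /day; all non-negative with
#'   \code{alpha + beta + delta > 0}.
#' @return the stationary Ki67-high fraction.
#' @export
ki67_equilibrium_fraction <- function(f, alpha, beta, delta) {
  if (any(c(f, alpha, beta, delta) < 0))
    stop("rates must be non-negative", call. = FALSE)
  den <- alpha + beta + delta
  if (den <= 0) stop("alpha + beta + delta must be positive", call. = FALSE)
  (f + 2 * alpha) / den
}

#' Deterministic BrdU/Ki67 labelling timecourse
#'
#' Solves the compartmental labelling dynamics from the label-free steady
#' state through a BrdU pulse of \code{design$pulse_end} days followed by a
#' chase, and returns the four observed summary fractions at the requested
#' times. During the pulse each division labels both daughters BrdU-positive
#' with probability \code{epsilon} and incoming cells are labelled with the
#' same probability; during the chase no new label is created, labelled
#' mothers beget labelled daughters (label dilution below detection is
#' ignored over the short chase), and unlabelled influx dilutes the labelled
#' fraction. The system is linear with piecewise-constant coefficients and is
#' solved exactly by matrix exponentials, with continuity at the pulse end.
#'
#' @param p stationary \code{\link{kinetic_params}}.
#' @param design an \code{\link{experiment_design}} (only \code{pulse_end} is
#'   used here).
#' @param times days since BrdU start, within \[0, design$chase_end\].
#' @return data.frame with columns \code{time}, \code{frac_brdu},
#'   \code{frac_brdu_in_ki67hi}, \code{frac_brdu_in_ki67lo},
#'   \code{frac_ki67hi}, \code{total}.
#' @export
solve_labelling <- function(p, design = experiment_design(), times) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(times < 0) || any(times > design$chase_end + 1e-9))
    stop("times must lie in [0, chase_end]", call. = FALSE)
  res <- stationarity_residual(p)
  if (max(abs(res)) > 1e-8)
    stop("parameters are not stationary (residual ", signif(max(abs(res)), 3),
         "/day); use close_parameters() to solve the loss rates", call. = FALSE)
  # compiled fast path; falls back to the R implementation on failure
  topo_code <- match(p$topology, c("branched", "linear", "burst", "temporal")) - 1L
  par <- c(epsilon = p$epsilon, beta = p$beta, alpha_fast = p$alpha_fast,
           alpha_slow = p$alpha_slow, delta_fast = p$delta_fast,
           delta_slow = p$delta_slow, gamma = p$gamma,
           activation = p$activation, reversion = p$reversion, f = p$f,
           phi_fast_fraction = p$phi_fast_fraction, N_fast = p$N_fast,
           N_slow = p$N_slow)
  cpp <- .labelling_curves_cpp(par, topo_code, p$n_stages, design$pulse_end,
                               times)
  if (nrow(cpp) > 0 && all(is.finite(cpp))) {
    out <- data.frame(time = cpp[, 1], frac_brdu = cpp[, 2],
                      frac_brdu_in_ki67hi = cpp[, 3],
                      frac_brdu_in_ki67lo = cpp[, 4],
                      frac_ki67hi = cpp[, 5], total = cpp[, 6])
    out <- out[match(times, out$time), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  ts <- sort(unique(times))
  # Because BrdU status does not affect any rate, the (pool, Ki67-stage)
  # marginal stays at its steady state throughout: only the BrdU-positive
  # block needs integrating. With steady occupancies y*, the positive block
  # z obeys z' = (App - C) z + (C y* + b_pos), where App and C are the
  # positive-positive and positive-from-negative blocks of the generator.
  so <- steady_occupancy(p)
  n <- p$n_stages
  npool <- n_pools(p)
  pos_idx <- so$neg_idx + state_dim(p) / 2L  # same ordering, BrdU+ block
  ystar <- c(so$hi, so$lo)                   # ordered like neg_idx
  solve_block <- function(gen, z0, tt) {
    App <- gen$A[pos_idx, pos_idx, drop = FALSE]
    C <- gen$A[pos_idx, so$neg_idx, drop = FALSE]
    Ae <- App - C
    ce <- as.numeric(C %*% ystar) + gen$b[pos_idx]
    propagate_affine(Ae, ce, z0, tt)
  }
  pe <- design$pulse_end
  in_pulse <- ts <= pe + 1e-12
  d2 <- length(pos_idx)
  z <- matrix(NA_real_, d2, length(ts))
  gp <- build_generator(p, "pulse")
  z0 <- numeric(d2)
  if (any(in_pulse)) z[, in_pulse] <- solve_block(gp, z0, ts[in_pulse])
  if (any(!in_pulse)) {
    zp <- as.numeric(solve_block(gp, z0, pe))
    z[, !in_pulse] <- solve_block(so$gen_chase, zp, ts[!in_pulse] - pe)
  }
  N <- sum(ystar)
  if (min(z) < -1e-6 * N)
    stop("solve_labelling: negative state encountered (min ", signif(min(z), 3),
         "); solver failure for this parameter set", call. = FALSE)
  z <- pmin(pmax(z, 0), ystar)  # positive block bounded by the marginal
  nh <- npool * n
  hi_tot <- sum(so$hi)
  lo_tot <- sum(so$lo)
  hi_pos <- colSums(z[seq_len(nh), , drop = FALSE])
  lo_pos <- colSums(z[nh + seq_len(npool), , drop = FALSE])
  sdiv <- function(a, b) if (b > 0) a / b else rep(0, length(a))
  out <- data.frame(time = ts,
                    frac_brdu = (hi_pos + lo_pos) / N,
                    frac_brdu_in_ki67hi = sdiv(hi_pos, hi_tot),
                    frac_brdu_in_ki67lo = sdiv(lo_pos, lo_tot),
                    frac_ki67hi = hi_tot / N,
                    total = N)
  # restore the caller's time order (duplicate times map to identical rows)
  out <- out[match(times, out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}
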