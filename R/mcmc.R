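# Adaptive random-walk Metropolis machinery used by all model fits.
# Proposals are multivariate normal on the unconstrained (log / logit)
# parameter scale; during warmup the proposal covariance tracks the running
# empirical covariance (Haario-style) and the global step size is tuned
# toward an acceptance rate of ~0.3. Chains are initialised at the posterior
# mode (found by BFGS) with the inverse Hessian as the initial proposal
# covariance.

find_map <- function(logpost, init, n_restarts = 1L, jitter = 0.3,
                     maxit = 150L) {
  d <- length(init)
  best <- NULL
  starts <- list(init)
  if (n_restarts > 0)
    for (k in seq_len(n_restarts))
      starts[[k + 1L]] <- init + stats::rnorm(d, 0, jitter)
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, function(x) -logpost(x), method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-10), hessian = TRUE),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(list(par = init, cov = diag(0.05, d)))
  H <- best$hessian
  cv <- tryCatch({
    eg <- eigen(H, symmetric = TRUE)
    ev <- pmax(eg$values, 1e-6 * max(abs(eg$values), 1))
    eg$vectors %*% diag(1 / ev, d) %*% t(eg$vectors)
  }, error = function(e) diag(0.05, d))
  if (any(!is.finite(cv))) cv <- diag(0.05, d)
  list(par = best$par, cov = cv)
}

run_mcmc <- function(logpost, init, n_chains = 3L, n_warmup = 600L,
                     n_iter = 600L, prop_cov = NULL, seed = NULL,
                     indep_prob = 0.08) {
  d <- length(init)
  if (is.null(prop_cov)) prop_cov <- diag(0.05, d)
  draws <- array(NA_real_, c(n_iter, n_chains, d))
  lps <- matrix(NA_real_, n_iter, n_chains)
  accept <- numeric(n_chains)
  # occasional independence proposals from the Laplace approximation give
  # stuck chains a global escape route; the random walk does local work
  ind_cov <- prop_cov * 2 + diag(1e-10, d)
  ind_L <- safe_chol(ind_cov)
  ind_Li <- tryCatch(solve(ind_L), error = function(e) NULL)
  if (is.null(ind_Li)) indep_prob <- 0
  ind_logq <- function(x) {
    z <- ind_Li %*% (x - init)
    -0.5 * sum(z * z)
  }
  for (ch in seq_len(n_chains)) {
    if (!is.null(seed)) set.seed(seed + ch)
    x <- init + as.numeric(chol_sample(prop_cov)) * 0.5
    lp <- logpost(x)
    tries <- 0L
    while (!is.finite(lp) && tries < 50L) {
      x <- init + as.numeric(chol_sample(prop_cov)) * 0.5
      lp <- logpost(x)
      tries <- tries + 1L
    }
    if (!is.finite(lp)) { x <- init; lp <- logpost(x) }
    log_scale <- log(2.38 / sqrt(d))
    mu <- x
    cv <- prop_cov
    L <- safe_chol(cv)
    n_acc <- 0L
    total <- n_warmup + n_iter
    for (it in seq_len(total)) {
      if (indep_prob > 0 && stats::runif(1) < indep_prob) {
        prop <- init + as.numeric(ind_L %*% stats::rnorm(d))
        lp_prop <- logpost(prop)
        a <- lp_prop - lp + ind_logq(x) - ind_logq(prop)
        walk <- FALSE
      } else {
        prop <- x + exp(log_scale) * as.numeric(L %*% stats::rnorm(d))
        lp_prop <- logpost(prop)
        a <- lp_prop - lp
        walk <- TRUE
      }
      if (is.finite(lp_prop) && log(stats::runif(1)) < a) {
        x <- prop; lp <- lp_prop
        if (it > n_warmup) n_acc <- n_acc + 1L
        acc_now <- 1
      } else acc_now <- 0
      if (it <= n_warmup) {
        # Robbins-Monro step-size tuning and covariance adaptation
        eta <- 1 / (20 + it)
        if (walk) log_scale <- log_scale + 5 * eta * (acc_now - 0.3)
        dx <- x - mu
        mu <- mu + eta * dx
        cv <- cv + eta * (tcrossprod(dx) - cv)
        if (it %% 25L == 0L) L <- safe_chol(cv + diag(1e-9, d))
      } else {
        draws[it - n_warmup, ch, ] <- x
        lps[it - n_warmup, ch] <- lp
      }
    }
    accept[ch] <- n_acc / n_iter
  }
  list(draws = draws, logpost = lps, accept = accept)
}

chol_sample <- function(cv) {
  d <- nrow(cv)
  safe_chol(cv) %*% stats::rnorm(d)
}

safe_chol <- function(cv) {
  out <- tryCatch(t(chol(cv)), error = function(e) NULL)
  if (is.null(out)) {
    eg <- eigen(cv, symmetric = TRUE)
    ev <- pmax(eg$values, 1e-10)
    out <- eg$vectors %*% diag(sqrt(ev), nrow(cv))
  }
  out
}

# Split-Rhat (Gelman et al.): chains halved, between/within variance ratio
split_rhat <- function(x) {
  # x: iterations x chains matrix for one parameter
  n <- nrow(x)
  h <- floor(n / 2)
  sub <- cbind(x[seq_len(h), , drop = FALSE],
               x[(n - h + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- h * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((h - 1) / h * W + B / h) / W)
}

# Effective sample size from pooled autocorrelations (initial monotone
# positive sequence estimator)
ess_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  xc <- sweep(x, 2, colMeans(x))
  max_lag <- min(n - 1, 200L)
  rho <- rep(0, max_lag)
  denom <- sum(xc^2) / (n * m)
  if (denom <= 0) return(n * m)
  for (k in seq_len(max_lag)) {
    s <- 0
    for (ch in seq_len(m)) s <- s + sum(xc[1:(n - k), ch] * xc[(k + 1):n, ch])
    rho[k] <- (s / (n * m)) / denom
  }
  tau <- 1
  k <- 1
  while (k < max_lag - 1) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  max(1, n * m / tau)
}

mcmc_diagnostics <- function(draws, par_names) {
  d <- dim(draws)[3]
  rhat <- ess <- numeric(d)
  for (j in seq_len(d)) {
    xj <- draws[, , j, drop = TRUE]
    if (is.null(dim(xj))) xj <- matrix(xj, ncol = 1)
    rhat[j] <- split_rhat(xj)
    ess[j] <- ess_basic(xj)
  }
  data.frame(parameter = par_names, rhat = rhat, ess = round(ess))
}
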