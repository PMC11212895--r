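# Bayesian fitting of the labelling models to one stratified timecourse
# (cohort x subset x lineage). Parameters are sampled on an unconstrained
# scale (log for rates, logit for fractions) with normal priors; loss rates
# are not free parameters but are closed from the quasi-equilibrium
# assumption at every draw.

par_spec_labelling <- function(topology, influx_prior = NULL, priors = NULL) {
  row <- function(name, transform, mean, sd)
    data.frame(name = name, transform = transform, mean = mean, sd = sd,
               stringsAsFactors = FALSE)
  sp <- rbind(
    row("f", "log", log(0.01), 2.0),
    row("epsilon", "logit", 0, 1.5),
    row("beta", "log", log(1 / 3.1), 0.5))
  sp <- rbind(sp, switch(topology,
    branched = rbind(
      row("alpha_slow", "log", log(0.007), 1),
      row("dalpha", "log", log(0.15), 1),
      row("nu", "logit", stats::qlogis(0.3), 1),
      row("pf", "logit", 0, 1.5)),
    linear = rbind(
      row("alpha_slow", "log", log(0.007), 1),
      row("dalpha", "log", log(0.15), 1),
      row("gamma", "log", log(0.01), 1.5),
      row("nu", "logit", stats::qlogis(0.3), 1)),
    burst = rbind(
      row("alpha_fast", "log", log(0.15), 1),
      row("activation", "log", log(0.01), 1.5),
      row("reversion", "log", log(0.05), 1.5),
      row("nu", "logit", stats::qlogis(0.3), 1)),
    temporal = rbind(
      row("alpha", "log", log(0.05), 1),
      row("delta_fast", "log", log(0.2), 1))))
  sp <- rbind(sp,
    row("prec_brdu", "log", log(200), 1.5),
    row("prec_hi", "log", log(200), 1.5),
    row("prec_lo", "log", log(200), 1.5),
    row("prec_k", "log", log(200), 1.5))
  if (!is.null(influx_prior)) {
    stopifnot(inherits(influx_prior, "influx_prior"))
    sp$mean[sp$name == "f"] <- influx_prior$rate_meanlog
    sp$sd[sp$name == "f"] <- influx_prior$rate_sdlog
  }
  if (!is.null(priors)) {
    for (nm in names(priors)) {
      j <- match(nm, sp$name)
      if (is.na(j)) stop("unknown prior parameter: ", nm, call. = FALSE)
      sp$mean[j] <- priors[[nm]][1]
      sp$sd[j] <- priors[[nm]][2]
    }
  }
  sp
}

to_natural <- function(theta, spec) {
  out <- ifelse(spec$transform == "log", exp(theta), stats::plogis(theta))
  names(out) <- spec$name
  out
}

labelling_params_from_draw <- function(nat, topology, n_stages = 1L) {
  p <- switch(topology,
    branched = kinetic_params("branched", epsilon = nat[["epsilon"]],
      beta = nat[["beta"]], alpha_fast = nat[["alpha_slow"]] + nat[["dalpha"]],
      alpha_slow = nat[["alpha_slow"]], f = nat[["f"]],
      phi_fast_fraction = nat[["pf"]], N_fast = nat[["nu"]],
      N_slow = 1 - nat[["nu"]], n_stages = n_stages),
    linear = kinetic_params("linear", epsilon = nat[["epsilon"]],
      beta = nat[["beta"]], alpha_fast = nat[["alpha_slow"]] + nat[["dalpha"]],
      alpha_slow = nat[["alpha_slow"]], gamma = nat[["gamma"]],
      f = nat[["f"]], N_fast = nat[["nu"]], N_slow = 1 - nat[["nu"]],
      n_stages = n_stages),
    burst = kinetic_params("burst", epsilon = nat[["epsilon"]],
      beta = nat[["beta"]], alpha_fast = nat[["alpha_fast"]], alpha_slow = 0,
      activation = nat[["activation"]], reversion = nat[["reversion"]],
      f = nat[["f"]], N_fast = nat[["nu"]], N_slow = 1 - nat[["nu"]],
      n_stages = n_stages),
    temporal = kinetic_params("temporal", epsilon = nat[["epsilon"]],
      beta = nat[["beta"]], alpha_fast = nat[["alpha"]],
      delta_fast = nat[["delta_fast"]], f = nat[["f"]],
      N_fast = 1, N_slow = 0, n_stages = n_stages))
  close_parameters(p)
}

# clamp an observed count-based fraction away from {0,1} for the beta density
shrink_fraction <- function(y, n) {
  n <- ifelse(is.finite(n) & n > 0, n, 1e4)
  (y * n + 0.5) / (n + 1)
}

# Fast path used inside the samplers: closes the loss rates analytically and
# returns the parameter vector consumed by the compiled solver, or NULL when
# the draw admits no stationary solution. Mirrors close_parameters().
fast_par_vector <- function(nat, topology, n_stages) {
  f <- nat[["f"]]; eps <- nat[["epsilon"]]; beta <- nat[["beta"]]
  gam <- 0; act <- 0; rev <- 0; pf <- 1
  if (topology == "branched") {
    nu <- nat[["nu"]]; pf <- nat[["pf"]]
    af <- nat[["alpha_slow"]] + nat[["dalpha"]]; as_ <- nat[["alpha_slow"]]
    df <- af + f * pf / nu
    ds <- as_ + f * (1 - pf) / (1 - nu)
  } else if (topology == "linear") {
    nu <- nat[["nu"]]; gam <- nat[["gamma"]]
    af <- nat[["alpha_slow"]] + nat[["dalpha"]]; as_ <- nat[["alpha_slow"]]
    df <- af - gam + f / nu
    ds <- as_ + gam * nu / (1 - nu)
  } else if (topology == "burst") {
    nu <- nat[["nu"]]; act <- nat[["activation"]]; rev <- nat[["reversion"]]
    af <- nat[["alpha_fast"]]; as_ <- 0; pf <- 0
    df <- af - rev + act * (1 - nu) / nu
    ds <- -act + (f + rev * nu) / (1 - nu)
  } else {  # temporal
    af <- nat[["alpha"]]; as_ <- 0
    df <- nat[["delta_fast"]]
    bn <- beta * n_stages
    r1 <- (f + 2 * af) / (af + df + bn)
    Y <- r1 * sum((bn / (af + df + bn))^(seq_len(n_stages) - 1))
    if (Y >= 1) return(NULL)
    ds <- (f + af - df * Y) / (1 - Y)
    nu <- 1
  }
  if (df < 0 || ds < 0) return(NULL)
  nf <- if (topology == "temporal") 1 else nu
  ns <- if (topology == "temporal") 0 else 1 - nu
  c(epsilon = eps, beta = beta, alpha_fast = af, alpha_slow = as_,
    delta_fast = df, delta_slow = ds, gamma = gam, activation = act,
    reversion = rev, f = f, phi_fast_fraction = pf, N_fast = nf, N_slow = ns)
}

topology_code <- function(topology)
  match(topology, c("branched", "linear", "burst", "temporal")) - 1L

labelling_loglik_pointwise <- function(obs, pred_by_time, nat) {
  mu <- pred_by_time[match(obs$t_label, pred_by_time$time), ]
  cl <- function(x) pmin(pmax(x, 1e-5), 1 - 1e-5)
  ll <- stats::dbeta(shrink_fraction(obs$frac_brdu, obs$n_events),
                     cl(mu$frac_brdu) * nat[["prec_brdu"]],
                     (1 - cl(mu$frac_brdu)) * nat[["prec_brdu"]], log = TRUE) +
    stats::dbeta(shrink_fraction(obs$frac_brdu_in_ki67hi, obs$n_events),
                 cl(mu$frac_brdu_in_ki67hi) * nat[["prec_hi"]],
                 (1 - cl(mu$frac_brdu_in_ki67hi)) * nat[["prec_hi"]], log = TRUE) +
    stats::dbeta(shrink_fraction(obs$frac_brdu_in_ki67lo, obs$n_events),
                 cl(mu$frac_brdu_in_ki67lo) * nat[["prec_lo"]],
                 (1 - cl(mu$frac_brdu_in_ki67lo)) * nat[["prec_lo"]], log = TRUE) +
    stats::dbeta(shrink_fraction(obs$frac_ki67hi, obs$n_events),
                 cl(mu$frac_ki67hi) * nat[["prec_k"]],
                 (1 - cl(mu$frac_ki67hi)) * nat[["prec_k"]], log = TRUE)
  ll
}

#' Fit a labelling model to one stratified BrdU/Ki67 timecourse
#'
#' Bayesian fit of the compartmental labelling model of the chosen topology
#' to the four observed summary fractions of one stratum, by adaptive
#' Metropolis sampling initialised at the posterior mode. The three BrdU
#' fractions and the Ki67-high fraction are given independent beta
#' likelihoods parameterised by the model mean and one fitted precision per
#' channel. Loss rates are closed from quasi-equilibrium at every draw, so
#' the net loss rates are determined by the influx: supplying an informative
#' influx prior (from \code{\link{influx_prior_from_replacement}}) is what
#' makes influx and net loss separately identifiable.
#'
#' @param obs a \code{labelling_obs} table for a single stratum.
#' @param topology model topology (see \code{\link{kinetic_params}}).
#' @param influx_prior optional \code{influx_prior} object; replaces the
#'   vague lognormal prior on the per-capita influx rate \code{f}.
#' @param priors optional named list of \code{c(mean, sd)} overrides on the
#'   unconstrained scale.
#' @param design the \code{\link{experiment_design}}.
#' @param n_stages Erlang stages for Ki67 transit.
#' @param n_chains,n_warmup,n_iter sampler settings.
#' @param seed integer seed; recorded in the result.
#' @param prior_only if \code{TRUE} the likelihood is disabled and the
#'   sampler explores the prior (for prior predictive checks).
#' @param loglik_draws number of (thinned) posterior draws on which the
#'   pointwise log-likelihood matrix is evaluated for LOO.
#' @return object of class \code{labelling_fit} with posterior draws on the
#'   natural scale (including the closed loss rates and the net loss rates
#'   \code{lambda_fast}, \code{lambda_slow}), sampler diagnostics, the
#'   pointwise log-likelihood matrix and its PSIS-LOO ELPD.
#' @export
fit_labelling_model <- function(obs, topology = c("branched", "linear", "burst", "temporal"),
                                influx_prior = NULL, priors = NULL,
                                design = experiment_design(), n_stages = 1L,
                                n_chains = 4L, n_warmup = 2500L, n_iter = 2000L,
                                seed = 1L, prior_only = FALSE,
                                loglik_draws = 400L) {
  topology <- match.arg(topology)
  obs <- as.data.frame(obs)
  if (!prior_only && length(unique(obs$t_label)) < 8)
    stop("need observations at >= 8 timepoints", call. = FALSE)
  spec <- par_spec_labelling(topology, influx_prior, priors)
  d <- nrow(spec)
  times <- sort(unique(obs$t_label))
  tidx <- match(obs$t_label, times)
  ysh <- cbind(shrink_fraction(obs$frac_brdu, obs$n_events),
               shrink_fraction(obs$frac_brdu_in_ki67hi, obs$n_events),
               shrink_fraction(obs$frac_brdu_in_ki67lo, obs$n_events),
               shrink_fraction(obs$frac_ki67hi, obs$n_events))
  topo <- topology_code(topology)
  nobs <- nrow(obs)
  # pointwise log-likelihood (one value per observation row) for one draw on
  # the natural scale; NULL when the draw admits no stationary solution
  loglik_nat <- function(nat) {
    pv <- fast_par_vector(nat, topology, n_stages)
    if (is.null(pv)) return(NULL)
    cpp <- .labelling_curves_cpp(pv, topo, n_stages, design$pulse_end, times)
    if (nrow(cpp) == 0 || any(!is.finite(cpp))) {
      # rare ill-conditioned cases: fall back to the R solver
      p <- tryCatch(labelling_params_from_draw(nat, topology, n_stages),
                    error = function(e) NULL)
      pred <- if (is.null(p)) NULL else
        tryCatch(solve_labelling(p, design, times), error = function(e) NULL)
      if (is.null(pred) || any(!is.finite(as.matrix(pred[-1])))) return(NULL)
      cpp <- cbind(pred$time, pred$frac_brdu, pred$frac_brdu_in_ki67hi,
                   pred$frac_brdu_in_ki67lo, pred$frac_ki67hi, pred$total)
    }
    mu <- cpp[tidx, 2:5, drop = FALSE]
    mu[mu < 1e-5] <- 1e-5
    mu[mu > 1 - 1e-5] <- 1 - 1e-5
    prec <- rep(c(nat[["prec_brdu"]], nat[["prec_hi"]], nat[["prec_lo"]],
                  nat[["prec_k"]]), each = nobs)
    ll <- stats::dbeta(ysh, mu * prec, (1 - mu) * prec, log = TRUE)
    rowSums(matrix(ll, nobs, 4))
  }
  logpost <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 30)) return(-Inf)
    lp <- sum(stats::dnorm(theta, spec$mean, spec$sd, log = TRUE))
    if (prior_only) return(lp)
    ll <- loglik_nat(to_natural(theta, spec))
    if (is.null(ll) || any(!is.finite(ll))) return(-Inf)
    lp + sum(ll)
  }
  set.seed(seed)
  map <- find_map(logpost, spec$mean, n_restarts = 1L)
  mc <- run_mcmc(logpost, map$par, n_chains = n_chains, n_warmup = n_warmup,
                 n_iter = n_iter, prop_cov = map$cov, seed = seed)
  diag_tab <- mcmc_diagnostics(mc$draws, spec$name)
  flat <- do.call(rbind, lapply(seq_len(n_chains), function(ch) mc$draws[, ch, ]))
  colnames(flat) <- spec$name
  nat_draws <- as.data.frame(t(apply(flat, 1, function(th) to_natural(th, spec))))
  # closed rates and derived net loss per draw
  extra <- t(apply(as.matrix(nat_draws), 1, function(nat) {
    p <- tryCatch(labelling_params_from_draw(nat, topology, n_stages),
                  error = function(e) NULL)
    if (is.null(p)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    c(p$delta_fast, p$delta_slow,
      p$delta_fast - p$alpha_fast, p$delta_slow - p$alpha_slow)
  }))
  colnames(extra) <- c("delta_fast", "delta_slow", "lambda_fast", "lambda_slow")
  nat_draws <- cbind(nat_draws, as.data.frame(extra))
  if (topology %in% c("branched", "linear"))
    nat_draws$alpha_fast <- nat_draws$alpha_slow + nat_draws$dalpha
  # pointwise log-likelihood on a thinned subset of draws
  keep <- unique(round(seq(1, nrow(flat), length.out = min(loglik_draws, nrow(flat)))))
  ll_mat <- NULL
  if (!prior_only) {
    ll_mat <- matrix(NA_real_, length(keep), nrow(obs))
    for (r in seq_along(keep)) {
      ll <- loglik_nat(to_natural(flat[keep[r], ], spec))
      ll_mat[r, ] <- if (is.null(ll)) -Inf else ll
    }
    ll_mat <- ll_mat[is.finite(rowSums(ll_mat)), , drop = FALSE]
  }
  elpd <- if (!is.null(ll_mat) && nrow(ll_mat) > 10) psis_loo(ll_mat) else NULL
  converged <- all(diag_tab$rhat < 1.05, na.rm = TRUE)
  structure(list(topology = topology, spec = spec, draws = nat_draws,
                 draws_unconstrained = flat, diagnostics = diag_tab,
                 accept = mc$accept, loglik = ll_mat, elpd = elpd,
                 converged = converged, seed = seed, prior_only = prior_only,
                 data = obs, design = design, n_stages = n_stages,
                 map = map$par),
            class = "labelling_fit")
}

#' @export
print.labelling_fit <- function(x, ...) {
  cat("Labelling model fit (", x$topology, " topology), ",
      nrow(x$draws), " posterior draws\n", sep = "")
  if (x$prior_only) cat("  [prior-only mode: likelihood disabled]\n")
  cat("  max split-Rhat: ", round(max(x$diagnostics$rhat), 3),
      "; min ESS: ", min(x$diagnostics$ess),
      if (!x$converged) "  ** NOT CONVERGED **" else "", "\n", sep = "")
  if (!is.null(x$elpd))
    cat(sprintf("  PSIS-LOO elpd: %.1f (SE %.1f)\n", x$elpd$elpd, x$elpd$se))
  print(summary(x))
  invisible(x)
}

#' @export
summary.labelling_fit <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  qs <- t(apply(object$draws, 2, stats::quantile, probs = probs, na.rm = TRUE))
  out <- data.frame(parameter = rownames(qs), qs, row.names = NULL,
                    check.names = FALSE)
  names(out)[-1] <- paste0("q", probs * 100)
  out
}

#' @export
coef.labelling_fit <- function(object, ...) {
  apply(object$draws, 2, stats::median, na.rm = TRUE)
}

#' Posterior median (and credible band) labelling curves from a fit
#' @param object a \code{labelling_fit}.
#' @param times days since BrdU start (default: a fine grid).
#' @param n_draws posterior draws used for the band.
#' @param ... unused.
#' @return data.frame with median and 2.5/97.5 percentile curves per channel.
#' @export
predict.labelling_fit <- function(object, times = seq(0, 35, by = 1),
                                  n_draws = 200L, ...) {
  dr <- object$draws
  idx <- unique(round(seq(1, nrow(dr), length.out = min(n_draws, nrow(dr)))))
  channels <- c("frac_brdu", "frac_brdu_in_ki67hi", "frac_brdu_in_ki67lo",
                "frac_ki67hi")
  arr <- array(NA_real_, c(length(idx), length(times), 4))
  for (r in seq_along(idx)) {
    nat <- unlist(dr[idx[r], , drop = TRUE])
    p <- tryCatch(labelling_params_from_draw(nat, object$topology, object$n_stages),
                  error = function(e) NULL)
    if (is.null(p)) next
    pred <- tryCatch(solve_labelling(p, object$design, times),
                     error = function(e) NULL)
    if (is.null(pred)) next
    for (c4 in 1:4) arr[r, , c4] <- pred[[channels[c4]]]
  }
  out <- data.frame(time = times)
  for (c4 in 1:4) {
    qs <- apply(arr[, , c4, drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.5, 0.975), na.rm = TRUE)
    out[[paste0(channels[c4], "_lo")]] <- qs[1, ]
    out[[paste0(channels[c4], "_med")]] <- qs[2, ]
    out[[paste0(channels[c4], "_hi")]] <- qs[3, ]
  }
  out
}

#' Posterior-predictive plot of a labelling fit
#' @param x a \code{labelling_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.labelling_fit <- function(x, ...) {
  pred <- stats::predict(x)
  oldpar <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  channels <- c("frac_brdu", "frac_brdu_in_ki67hi", "frac_brdu_in_ki67lo",
                "frac_ki67hi")
  titles <- c("BrdU+ fraction", "BrdU+ | Ki67-high", "BrdU+ | Ki67-low",
              "Ki67-high fraction")
  for (c4 in 1:4) {
    ch <- channels[c4]
    graphics::plot(pred$time, pred[[paste0(ch, "_med")]], type = "l",
                   ylim = c(0, 1), xlab = "days since BrdU start", ylab = ch,
                   main = titles[c4], ...)
    graphics::lines(pred$time, pred[[paste0(ch, "_lo")]], lty = 2)
    graphics::lines(pred$time, pred[[paste0(ch, "_hi")]], lty = 2)
    graphics::points(x$data$t_label, x$data[[ch]], pch = 19, cex = 0.6)
  }
  invisible(x)
}
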