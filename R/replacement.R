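# Donor-chimerism replacement kinetics: fitting donor-fraction timecourses
# after busulfan conditioning and bone-marrow transplant to estimate the
# per-capita influx rate into a memory subset and the chimerism of its
# source, which together provide the influx priors for the labelling fits.

#' Donor-fraction replacement curve
#'
#' Homogeneous model: after an equilibration delay \code{t0} the donor
#' fraction obeys \code{dX/dt = rate * (source_chimerism - X)} with
#' \code{X(t0) = 0}, i.e. a saturating approach to the source chimerism.
#' Two-compartment model: the population comprises two subpools turning over
#' at \code{rate} and \code{rate2} with weight \code{w} on the first, so the
#' donor fraction approaches the source plateau more slowly than any single
#' exponential and remains below it at finite times (first-in, last-out).
#'
#' @param t days since bone-marrow transplant.
#' @param rate,source_chimerism,t0 replacement parameters.
#' @param model \code{"homogeneous"} or \code{"two_compartment"}.
#' @param rate2,w second-compartment rate and first-compartment weight.
#' @return donor fraction at \code{t}, in \[0,1\].
#' @export
replacement_curve <- function(t, rate, source_chimerism, t0 = 42,
                              model = c("homogeneous", "two_compartment"),
                              rate2 = rate, w = 1) {
  model <- match.arg(model)
  tau <- pmax(t - t0, 0)
  if (model == "homogeneous") {
    source_chimerism * (1 - exp(-rate * tau))
  } else {
    source_chimerism * (1 - w * exp(-rate * tau) - (1 - w) * exp(-rate2 * tau))
  }
}

par_spec_replacement <- function(model, priors = NULL) {
  row <- function(name, transform, mean, sd)
    data.frame(name = name, transform = transform, mean = mean, sd = sd,
               stringsAsFactors = FALSE)
  sp <- rbind(row("rate", "log", log(0.01), 1.5),
              row("source_chimerism", "logit", 0, 1.5))
  if (model == "two_compartment")
    sp <- rbind(sp, row("rate2", "log", log(0.002), 1.5),
                row("w", "logit", 0, 1.2))
  sp <- rbind(sp, row("precision", "log", log(100), 1.5))
  if (!is.null(priors)) {
    for (nm in names(priors)) {
      j <- match(nm, sp$name)
      if (is.na(j)) stop("unknown prior parameter: ", nm, call. = FALSE)
      sp$mean[j] <- priors[[nm]][1]; sp$sd[j] <- priors[[nm]][2]
    }
  }
  sp
}

#' Fit a replacement model to a donor-chimerism timecourse
#'
#' Bayesian fit (adaptive Metropolis, beta observation model on the donor
#' fractions) of the slow accumulation of donor cells within one subset of
#' busulfan chimeric mice. The posterior over the per-capita replacement
#' rate maps directly onto the influx rate \code{f} of the labelling models;
#' the fitted plateau is the chimerism of the subset's source.
#'
#' @param obs \code{chimerism_obs} table for one subset.
#' @param model \code{"homogeneous"} (default) or \code{"two_compartment"}.
#' @param t0 post-transplant equilibration delay in days (default 42: donor
#'   chimerism stabilises through thymic development within about six weeks).
#' @param priors optional named list of \code{c(mean, sd)} overrides on the
#'   unconstrained scale.
#' @param n_chains,n_warmup,n_iter sampler settings.
#' @param seed integer seed.
#' @return object of class \code{replacement_fit}: posterior draws on the
#'   natural scale, diagnostics, pointwise log-likelihood matrix.
#' @export
fit_replacement <- function(obs, model = c("homogeneous", "two_compartment"),
                            t0 = 42, priors = NULL, n_chains = 4L,
                            n_warmup = 1200L, n_iter = 1200L, seed = 1L) {
  model <- match.arg(model)
  obs <- as.data.frame(obs)
  if (nrow(obs) < 5 || diff(range(obs$t_bmt)) < 60)
    stop("need >= 5 observations spanning >= 60 days", call. = FALSE)
  spec <- par_spec_replacement(model, priors)
  y <- shrink_fraction(obs$donor_fraction, 500)
  pointwise <- function(nat) {
    mu <- replacement_curve(obs$t_bmt, nat[["rate"]], nat[["source_chimerism"]],
                            t0, model,
                            rate2 = if (model == "two_compartment") nat[["rate2"]] else nat[["rate"]],
                            w = if (model == "two_compartment") nat[["w"]] else 1)
    mu <- pmin(pmax(mu, 1e-5), 1 - 1e-5)
    stats::dbeta(y, mu * nat[["precision"]], (1 - mu) * nat[["precision"]],
                 log = TRUE)
  }
  logpost <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 30)) return(-Inf)
    lp <- sum(stats::dnorm(theta, spec$mean, spec$sd, log = TRUE))
    nat <- to_natural(theta, spec)
    ll <- pointwise(nat)
    if (any(!is.finite(ll))) return(-Inf)
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
  keep <- unique(round(seq(1, nrow(flat), length.out = min(400L, nrow(flat)))))
  ll_mat <- t(vapply(keep, function(r) pointwise(to_natural(flat[r, ], spec)),
                     numeric(nrow(obs))))
  converged <- all(diag_tab$rhat < 1.05, na.rm = TRUE)
  structure(list(model = model, t0 = t0, draws = nat_draws,
                 diagnostics = diag_tab, accept = mc$accept, loglik = ll_mat,
                 converged = converged, seed = seed, data = obs, spec = spec),
            class = "replacement_fit")
}

#' @export
print.replacement_fit <- function(x, ...) {
  cat("Replacement fit (", x$model, " model), ", nrow(x$draws),
      " posterior draws\n", sep = "")
  cat("  max split-Rhat: ", round(max(x$diagnostics$rhat), 3),
      if (!x$converged) "  ** NOT CONVERGED **" else "", "\n", sep = "")
  qs <- t(apply(x$draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  print(round(qs, 4))
  invisible(x)
}

#' @export
coef.replacement_fit <- function(object, ...) {
  apply(object$draws, 2, stats::median)
}

#' Summarise a replacement posterior into an influx prior
#'
#' Moment-matches a lognormal distribution to the posterior draws of the
#' replacement rate (for use as the prior on the per-capita influx \code{f})
#' and a beta distribution to the draws of the source chimerism. The fitted
#' prior's 2.5/50/97.5 percentiles are checked against the empirical
#' quantiles of the draws (5\% relative tolerance); a mismatch is reported in
#' the \code{quantile_match} field.
#'
#' @param fit a \code{replacement_fit}, or a data.frame of draws with columns
#'   \code{rate} and \code{source_chimerism}.
#' @return object of class \code{influx_prior} with fields
#'   \code{rate_meanlog}, \code{rate_sdlog}, \code{chimerism_shape1},
#'   \code{chimerism_shape2}, \code{quantile_match}.
#' @export
influx_prior_from_replacement <- function(fit) {
  draws <- if (inherits(fit, "replacement_fit")) fit$draws else as.data.frame(fit)
  if (nrow(draws) < 1000)
    stop("need >= 1000 posterior draws", call. = FALSE)
  r <- draws$rate
  ch <- draws$source_chimerism
  if (stats::sd(r) < 1e-12 * max(mean(r), 1e-12)) {
    warning("degenerate rate posterior: emitting a near point-mass prior")
    out <- list(rate_meanlog = log(mean(r)), rate_sdlog = 1e-6,
                chimerism_shape1 = mean(ch) * 1e6,
                chimerism_shape2 = (1 - mean(ch)) * 1e6,
                quantile_match = TRUE)
    class(out) <- "influx_prior"
    return(out)
  }
  meanlog <- mean(log(r)); sdlog <- stats::sd(log(r))
  m <- mean(ch); v <- stats::var(ch)
  v <- min(v, m * (1 - m) * 0.99)
  conc <- m * (1 - m) / v - 1
  shape1 <- m * conc; shape2 <- (1 - m) * conc
  qemp <- stats::quantile(r, c(0.025, 0.5, 0.975))
  qfit <- stats::qlnorm(c(0.025, 0.5, 0.975), meanlog, sdlog)
  match_ok <- all(abs(qfit - qemp) / pmax(qemp, 1e-12) < 0.05)
  structure(list(rate_meanlog = meanlog, rate_sdlog = sdlog,
                 chimerism_shape1 = shape1, chimerism_shape2 = shape2,
                 quantile_match = match_ok),
            class = "influx_prior")
}

#' @export
print.influx_prior <- function(x, ...) {
  cat(sprintf("Influx prior: rate ~ lognormal(%.3f, %.3f) (median %.4g/day); ",
              x$rate_meanlog, x$rate_sdlog, exp(x$rate_meanlog)))
  cat(sprintf("source chimerism ~ beta(%.2f, %.2f)\n",
              x$chimerism_shape1, x$chimerism_shape2))
  if (!x$quantile_match) cat("  [warning: prior quantiles do not match posterior]\n")
  invisible(x)
}

#' Normalise a subset's chimerism to a reference compartment
#'
#' @param subset_chimerism donor fraction of the subset (or its influx).
#' @param reference_chimerism donor fraction of the reference compartment
#'   (e.g. DP1 thymocytes); must be positive.
#' @return the ratio (may exceed 1).
#' @export
normalize_chimerism <- function(subset_chimerism, reference_chimerism) {
  if (any(reference_chimerism <= 0))
    stop("reference chimerism must be positive", call. = FALSE)
  subset_chimerism / reference_chimerism
}

#' Rank candidate precursor populations by chimerism match
#'
#' Compares the inferred chimerism of the influx into a subset with the
#' observed chimerism of candidate precursor compartments, ranking candidates
#' by absolute distance. The developmental logic: the donor/host composition
#' of the flow into a subset should mirror that of its true source.
#'
#' @param influx_chimerism scalar (or draws) of the influx chimerism.
#' @param candidates named numeric vector of candidate-compartment chimerism
#'   values (e.g. \code{c(DP1 = 0.9, naive_CD4 = 0.75, TCM = 0.55)}).
#' @return data.frame ranked by match, columns \code{candidate, chimerism,
#'   distance}.
#' @export
match_precursors <- function(influx_chimerism, candidates) {
  stopifnot(length(candidates) >= 1, !is.null(names(candidates)))
  x <- mean(influx_chimerism)
  d <- abs(candidates - x)
  out <- data.frame(candidate = names(candidates),
                    chimerism = as.numeric(candidates),
                    distance = as.numeric(d))
  out <- out[order(out$distance), ]
  rownames(out) <- NULL
  out
}
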