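# Forward predictions for the two validation systems: heritable
# reporter-label dilution along the naive -> TCM -> TEM pathway, and the
# Ki67 trajectories of adoptively transferred cohorts marked by their
# division status (YFP induced in Ki67-expressing cells).

#' Fit an empirical dilution curve to the source population
#'
#' Least-squares fit of a smooth monotone description of the labelled
#' (reporter-positive) fraction of the source population against time since
#' tamoxifen. Default family is exponential decay to a plateau,
#' \code{m(t) = m_inf + (m0 - m_inf) * exp(-r t)}; a logistic alternative is
#' available. The naive CD4 pool dilutes because unlabelled cells flow in
#' from the thymus, so the fitted curve is non-increasing whenever
#' \code{m0 >= m_inf}.
#'
#' @param obs a \code{dilution_obs} table for the source subset (or any
#'   data.frame with \code{t_tam} and \code{labelled_fraction}).
#' @param family \code{"exp_plateau"} (default) or \code{"logistic"}.
#' @return object of class \code{source_curve} with the fitted parameters,
#'   residual summary, and a \code{predict} method.
#' @export
fit_source_dilution_curve <- function(obs, family = c("exp_plateau", "logistic")) {
  family <- match.arg(family)
  obs <- as.data.frame(obs)
  if (nrow(obs) < 5) stop("need >= 5 timepoints", call. = FALSE)
  t <- obs$t_tam; y <- obs$labelled_fraction
  if (stats::sd(y) < 1e-10) {
    pars <- c(m0 = mean(y), m_inf = mean(y), r = 0)
    fitted <- rep(mean(y), length(y))
  } else if (family == "exp_plateau") {
    fit <- minpack.lm::nlsLM(
      y ~ m_inf + (m0 - m_inf) * exp(-r * t),
      start = list(m0 = max(y), m_inf = min(y),
                   r = 1 / max(stats::median(t), 1)),
      lower = c(0, 0, 0), upper = c(1, 1, 10),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    pars <- stats::coef(fit)
    fitted <- stats::fitted(fit)
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ m_inf + (m0 - m_inf) / (1 + exp(r * (t - tmid))),
      start = list(m0 = max(y), m_inf = min(y), r = 0.05,
                   tmid = stats::median(t)),
      lower = c(0, 0, 0, 0), upper = c(1, 1, 10, max(t) * 2),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    pars <- stats::coef(fit)
    fitted <- stats::fitted(fit)
  }
  structure(list(family = family, pars = as.list(pars),
                 residual_sd = stats::sd(y - fitted), n = length(y),
                 range = range(t)),
            class = "source_curve")
}

#' @export
predict.source_curve <- function(object, times, ...) {
  p <- object$pars
  out <- if (object$family == "exp_plateau") {
    p$m_inf + (p$m0 - p$m_inf) * exp(-p$r * times)
  } else {
    p$m_inf + (p$m0 - p$m_inf) / (1 + exp(p$r * (times - p$tmid)))
  }
  pmin(pmax(out, 0), 1)
}

#' @export
print.source_curve <- function(x, ...) {
  cat("Source dilution curve (", x$family, "): ", sep = "")
  cat(paste(names(x$pars), signif(unlist(x$pars), 4), sep = " = ",
            collapse = ", "))
  cat(sprintf("; residual sd %.4f (n = %d)\n", x$residual_sd, x$n))
  invisible(x)
}

# Pool-level labelled-fraction dynamics for one parameter draw. The labelled
# cells obey the same flow structure as the labelling ODE with label
# creation by division disabled (heritable label: division preserves the
# labelled fraction) while the influx carries the source's labelled fraction
# at time t. Solved with deSolve because the source term is time-varying.
dilution_trajectory <- function(p, source_fn, times, init_fraction) {
  if (p$topology == "temporal")
    stop("label-dilution prediction requires a fast/slow topology", call. = FALSE)
  Npool <- c(p$N_fast, p$N_slow)
  phi <- total_influx(p)
  phi_pool <- c(phi * p$phi_fast_fraction, phi * (1 - p$phi_fast_fraction))
  trans <- pool_transitions(p)  # [from, to]
  active <- which(Npool > 0)
  rhs <- function(t, mu, parms) {
    m_s <- source_fn(t)
    dmu <- numeric(2)
    for (i in active) {
      inflow <- phi_pool[i] * m_s
      for (j in active) if (j != i) inflow <- inflow + trans[j, i] * Npool[j] * mu[j]
      outflow <- (p$delta_fast * (i == 1) + p$delta_slow * (i == 2) +
                    sum(trans[i, -i])) * Npool[i] * mu[i]
      selfrenew <- (if (i == 1) p$alpha_fast else p$alpha_slow) * Npool[i] * mu[i]
      dmu[i] <- (inflow + selfrenew - outflow) / Npool[i]
    }
    list(dmu)
  }
  mu0 <- rep(init_fraction, 2)
  sol <- deSolve::ode(y = mu0, times = union(0, times), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  sol <- sol[match(times, sol[, 1]), , drop = FALSE]
  mu <- sol[, -1, drop = FALSE]
  agg <- as.numeric(mu %*% Npool) / sum(Npool)
  list(aggregate = agg, fast = mu[, 1], slow = mu[, 2])
}

#' Predict reporter-label dilution in a memory subset
#'
#' For each posterior parameter draw, propagates the labelled fraction of a
#' memory subset forward in time: the subset receives influx carrying the
#' source population's labelled fraction, while divisions preserve the
#' heritable label, so in a closed self-renewing population the labelled
#' fraction stays constant and any decline measures the influx of unlabelled
#' precursors. Supports chaining: the TEM prediction can take the predicted
#' TCM trajectory (total, or its fast subpopulation only) as its source.
#'
#' @param draws data.frame of posterior draws of the natural-scale kinetic
#'   parameters of the target subset (as in \code{labelling_fit$draws}).
#' @param topology topology under which the draws were fitted.
#' @param source a \code{source_curve}, a \code{dilution_prediction} (for
#'   chaining), or a function of time returning the source labelled fraction.
#' @param source_mapping one of \code{"naive_to_TCM"}, \code{"TCM_to_TEM"},
#'   \code{"TCM_fast_to_TEM"}; with a \code{dilution_prediction} source the
#'   latter two select the total or fast-pool trajectory.
#' @param times days since tamoxifen at which to predict.
#' @param n_draws number of posterior draws to propagate (default 1000, or
#'   all available if fewer).
#' @param seed integer seed for the draw subsample.
#' @param init_fraction labelled fraction of the target at time 0; default
#'   is the source's value at time 0 (tamoxifen labels all CD4 cells, so
#'   memory starts near the naive labelled fraction).
#' @param n_stages Erlang stages used when re-closing each draw.
#' @return object of class \code{dilution_prediction}: \code{times},
#'   \code{median}, \code{lo}, \code{hi} (2.5/97.5 percentiles), per-draw
#'   trajectory matrices for chaining, and the count of non-stationary draws
#'   rejected.
#' @export
predict_label_dilution <- function(draws, topology, source,
                                   source_mapping = c("naive_to_TCM", "TCM_to_TEM",
                                                      "TCM_fast_to_TEM"),
                                   times, n_draws = 1000L, seed = 1L,
                                   init_fraction = NULL, n_stages = 1L) {
  source_mapping <- match.arg(source_mapping)
  draws <- as.data.frame(draws)
  set.seed(seed)
  idx <- if (nrow(draws) > n_draws) sample.int(nrow(draws), n_draws) else seq_len(nrow(draws))
  src_fns <- make_source_fns(source, source_mapping, length(idx), times)
  if (is.null(init_fraction)) init_fraction <- src_fns$at0
  traj <- matrix(NA_real_, length(idx), length(times))
  traj_fast <- matrix(NA_real_, length(idx), length(times))
  rejected <- 0L
  for (r in seq_along(idx)) {
    nat <- unlist(draws[idx[r], , drop = TRUE])
    p <- tryCatch(labelling_params_from_draw(nat, topology, n_stages),
                  error = function(e) NULL)
    if (is.null(p) || max(abs(stationarity_residual(p))) > 1e-6) {
      rejected <- rejected + 1L
      next
    }
    tr <- dilution_trajectory(p, src_fns$fn(r), times, init_fraction)
    traj[r, ] <- tr$aggregate
    traj_fast[r, ] <- tr$fast
  }
  ok <- rowSums(is.na(traj)) == 0
  qs <- apply(traj[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.5, 0.975), na.rm = TRUE)
  structure(list(times = times, median = qs[2, ], lo = qs[1, ], hi = qs[3, ],
                 draws_total = traj[ok, , drop = FALSE],
                 draws_fast = traj_fast[ok, , drop = FALSE],
                 n_rejected = rejected, source_mapping = source_mapping),
            class = "dilution_prediction")
}

# Resolve the source argument into per-draw source functions of time.
make_source_fns <- function(source, mapping, n_draws, times) {
  if (inherits(source, "source_curve")) {
    f <- function(r) function(t) stats::predict(source, t)
    return(list(fn = f, at0 = stats::predict(source, 0)))
  }
  if (inherits(source, "dilution_prediction")) {
    mat <- if (mapping == "TCM_fast_to_TEM") source$draws_fast else source$draws_total
    at0 <- stats::approx(source$times, source$median, xout = 0, rule = 2)$y
    f <- function(r) {
      row <- if (nrow(mat) >= n_draws) ((r - 1) %% nrow(mat)) + 1 else
        sample.int(nrow(mat), 1)
      yr <- mat[row, ]
      function(t) stats::approx(source$times, yr, xout = t, rule = 2)$y
    }
    return(list(fn = f, at0 = at0))
  }
  if (is.function(source)) {
    return(list(fn = function(r) source, at0 = source(0)))
  }
  stop("source must be a source_curve, dilution_prediction, or function",
       call. = FALSE)
}

#' @export
print.dilution_prediction <- function(x, ...) {
  cat("Label-dilution prediction (", x$source_mapping, "), ",
      nrow(x$draws_total), " draws", sep = "")
  if (x$n_rejected > 0) cat(" (", x$n_rejected, " non-stationary draws rejected)", sep = "")
  cat("\n")
  print(data.frame(time = x$times, median = round(x$median, 4),
                   lo = round(x$lo, 4), hi = round(x$hi, 4)), row.names = FALSE)
  invisible(x)
}

#' Predicted Ki67 trajectory of a transferred cohort
#'
#' Models the adoptive-transfer validation: in the donor reporter mouse,
#' tamoxifen marks every Ki67-high cell (YFP, heritable) at
#' \code{mark_offset} days before transfer; the marked cohort and its
#' complement then evolve under the full dynamics (with influx, which is
#' unmarked) until transfer, after which the requested cohort is followed
#' with (\code{influx_on = TRUE}, bulk transfer with precursors present) or
#' without (\code{influx_on = FALSE}, isolated transfer) the influx term.
#' Because fast cells are over-represented among Ki67-high cells, the marked
#' cohort starts Ki67-enriched and its Ki67 expression declines and
#' converges toward the unmarked cohort's.
#'
#' @param p stationary \code{\link{kinetic_params}}.
#' @param cohort \code{"yfp_pos"}, \code{"yfp_neg"}, or \code{"bulk"}.
#' @param influx_on logical: does the transferred population keep receiving
#'   new cells from its precursor?
#' @param horizon days post-transfer to follow (max 14).
#' @param times days post-transfer at which to report (default 0..horizon).
#' @param mark_offset days between tamoxifen marking and transfer (default 3).
#' @return data.frame with columns \code{time}, \code{frac_ki67hi},
#'   \code{size} (cohort size relative to the steady-state total).
#' @export
predict_transfer_ki67 <- function(p, cohort = c("yfp_pos", "yfp_neg", "bulk"),
                                  influx_on = FALSE, horizon = 7,
                                  times = NULL, mark_offset = 3) {
  cohort <- match.arg(cohort)
  if (horizon > 14) stop("horizon must be <= 14 days", call. = FALSE)
  if (is.null(times)) times <- seq(0, horizon, by = 0.5)
  if (any(times < 0 | times > horizon))
    stop("times must lie in [0, horizon]", call. = FALSE)
  x0 <- as.numeric(steady_state(p))
  n <- p$n_stages
  npool <- n_pools(p)
  # work on the BrdU-negative block only (BrdU plays no role here)
  neg <- integer(0)
  for (i in seq_len(npool)) neg <- c(neg, state_index(p, i, c(seq_len(n), 0L), 0L))
  gen <- build_generator(p, "chase")
  A <- gen$A[neg, neg, drop = FALSE]
  b <- gen$b[neg]
  hi_mask <- rep(c(rep(TRUE, n), FALSE), npool)
  xs <- x0[neg]
  # marking: Ki67-high cells -> marked cohort; evolve both to transfer time.
  # The marked cohort is closed (YFP is heritable and the influx is unmarked).
  marked0 <- xs * hi_mask
  unmarked0 <- xs * !hi_mask
  if (mark_offset > 0) {
    marked_t <- propagate_affine(A, b * 0, marked0, mark_offset)[, 1]
    unmarked_t <- propagate_affine(A, b, unmarked0, mark_offset)[, 1]
  } else {
    marked_t <- marked0; unmarked_t <- unmarked0
  }
  init <- switch(cohort, yfp_pos = marked_t, yfp_neg = unmarked_t,
                 bulk = marked_t + unmarked_t)
  # post-transfer influx applies to the unmarked/bulk stream only when on;
  # for the marked cohort influx never adds cells (new cells are unmarked)
  b_post <- if (influx_on && cohort != "yfp_pos") b else b * 0
  states <- propagate_affine(A, b_post, init, pmax(times, 1e-9))
  frac_hi <- colSums(states[hi_mask, , drop = FALSE]) / colSums(states)
  data.frame(time = times, frac_ki67hi = frac_hi,
             size = colSums(states) / sum(xs))
}
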