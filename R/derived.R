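# Closed-form summaries of fitted or specified kinetics: net loss rates and
# clonal half-lives, size-weighted mean lifespans, and the two lifespan
# approximations (BrdU upslope, Ki67 occupancy) used for cross-study
# comparison.

#' Clonal half-life from loss and self-renewal rates
#'
#' The net loss rate \code{lambda = delta - alpha} sets the decay of a cohort
#' of cells (and of the TCR clones it carries) in bulk; the half-life of the
#' cohort is \code{ln(2)/lambda}. When loss is balanced or exceeded by
#' self-renewal (\code{delta <= alpha}) the cohort is self-sustaining and the
#' half-life is infinite (returned as \code{Inf}, a documented sentinel, so
#' that posterior summaries over draws containing \code{lambda <= 0} remain
#' computable).
#'
#' @param delta loss rate, /day.
#' @param alpha self-renewal (division) rate, /day.
#' @return half-life in days; \code{Inf} when \code{delta <= alpha}.
#' @export
clonal_half_life <- function(delta, alpha) {
  lambda <- delta - alpha
  ifelse(lambda > 0, log(2) / lambda, Inf)
}

#' Size-weighted mean lifespan across subpopulations
#'
#' The mean lifespan of the population as a whole is the inverse of the
#' size-weighted average loss rate of its subpopulations (e.g. fast and slow
#' cells among both donor and host):
#' \code{1 / (sum(N_i * delta_i) / sum(N_i))}.
#'
#' @param loss_rates per-group loss rates, /day (all positive).
#' @param sizes per-group population sizes (non-negative, at least one
#'   positive).
#' @return mean lifespan in days.
#' @export
weighted_mean_lifespan <- function(loss_rates, sizes) {
  if (length(loss_rates) != length(sizes))
    stop("loss_rates and sizes must have equal length", call. = FALSE)
  if (any(sizes < 0) || sum(sizes) <= 0)
    stop("sizes must be non-negative with a positive total", call. = FALSE)
  if (any(loss_rates <= 0)) stop("loss rates must be positive", call. = FALSE)
  1 / (sum(sizes * loss_rates) / sum(sizes))
}

#' Mean lifespan from the initial BrdU labelling upslope
#'
#' At steady state the total production rate (division plus influx) balances
#' the average loss rate, whose inverse is the mean lifespan. The early rate
#' of increase \code{p} of the BrdU-positive fraction measures production
#' scaled by the per-division uptake efficiency \code{epsilon}, giving the
#' approximation \code{lifespan ~ 2 * epsilon / p}.
#'
#' @param p early rate of increase of the BrdU-positive fraction, /day.
#' @param epsilon BrdU uptake efficiency per division, in (0, 1].
#' @return approximate mean lifespan in days.
#' @export
lifespan_from_upslope <- function(p, epsilon) {
  if (any(p <= 0)) stop("upslope p must be positive", call. = FALSE)
  if (any(epsilon <= 0 | epsilon > 1))
    stop("epsilon must lie in (0, 1]", call. = FALSE)
  2 * epsilon / p
}

#' Mean lifespan from the Ki67-high fraction
#'
#' If a fraction \code{k} of cells express Ki67, and Ki67 is expressed for
#' \code{T} days after division, the mean lifespan is approximately
#' \code{-T / log(1 - k/2)}. For small \code{k} this approaches \code{2T/k}.
#'
#' @param k Ki67-high fraction, in (0, 1].
#' @param T_ki67 Ki67 expression lifetime in days.
#' @return approximate mean lifespan in days.
#' @export
lifespan_from_ki67 <- function(k, T_ki67) {
  if (any(k <= 0 | k > 1)) stop("k must lie in (0, 1]", call. = FALSE)
  if (any(T_ki67 <= 0)) stop("T_ki67 must be positive", call. = FALSE)
  -T_ki67 / log(1 - k / 2)
}

#' Abundance-weighted average over the two memory subsets
#'
#' Combines a central-memory and an effector-memory value using their
#' relative abundance (effector:central ratio, about 7.5 in lymph nodes):
#' \code{(value_cm + ratio * value_em) / (1 + ratio)}.
#'
#' @param value_cm value for central memory (TCM).
#' @param value_em value for effector memory (TEM).
#' @param em_cm_ratio TEM:TCM abundance ratio (positive).
#' @return the weighted average.
#' @export
weighted_subset_average <- function(value_cm, value_em, em_cm_ratio) {
  if (any(em_cm_ratio <= 0)) stop("em_cm_ratio must be positive", call. = FALSE)
  (value_cm + em_cm_ratio * value_em) / (1 + em_cm_ratio)
}

#' Estimate the early BrdU upslope from a labelling timecourse
#'
#' Weighted least-squares slope of the BrdU-positive fraction against time
#' over the early window \code{[0, t_max]}, through the origin (the labelled
#' fraction is zero when labelling starts). Weights default to the event
#' counts when present.
#'
#' @param times days since BrdU start.
#' @param frac_brdu BrdU-positive fractions.
#' @param t_max end of the early window in days (default 4).
#' @param weights optional observation weights.
#' @return the upslope \code{p}, /day.
#' @export
estimate_upslope <- function(times, frac_brdu, t_max = 4, weights = NULL) {
  sel <- times >= 0 & times <= t_max
  if (sum(sel & times > 0) < 1)
    stop("no observations with 0 < t <= t_max", call. = FALSE)
  tt <- times[sel]; yy <- frac_brdu[sel]
  w <- if (is.null(weights)) rep(1, sum(sel)) else weights[sel]
  sum(w * tt * yy) / sum(w * tt^2)
}

#' Lifespan summary table from posterior draws
#'
#' Applies the closed-form summaries to a table of posterior draws (as held
#' in a \code{labelling_fit}): net loss rates, clonal half-lives, and the
#' size-weighted mean lifespan of the stratum, reported as medians with
#' 2.5/97.5 percentiles. Draws with non-positive net loss give infinite
#' half-lives; the reported mass-at-infinity is the fraction of such draws.
#'
#' @param draws data.frame of posterior draws with columns
#'   \code{alpha_fast, alpha_slow, delta_fast, delta_slow, nu} (nu = fast
#'   fraction; absent for the temporal topology, where sizes come from the
#'   Ki67 split).
#' @return data.frame, one row per quantity: median, lo, hi,
#'   \code{frac_infinite}.
#' @export
lifespan_summary <- function(draws) {
  need <- c("alpha_fast", "alpha_slow", "delta_fast", "delta_slow")
  if (!all(need %in% names(draws)))
    stop("draws must contain ", paste(need, collapse = ", "), call. = FALSE)
  nu <- if ("nu" %in% names(draws)) draws$nu else rep(0.5, nrow(draws))
  qty <- list(
    lambda_fast = draws$delta_fast - draws$alpha_fast,
    lambda_slow = draws$delta_slow - draws$alpha_slow,
    half_life_fast = clonal_half_life(draws$delta_fast, draws$alpha_fast),
    half_life_slow = clonal_half_life(draws$delta_slow, draws$alpha_slow),
    mean_lifespan = vapply(seq_len(nrow(draws)), function(i)
      weighted_mean_lifespan(c(draws$delta_fast[i], draws$delta_slow[i]),
                             c(nu[i], 1 - nu[i])), 0))
  out <- do.call(rbind, lapply(names(qty), function(nm) {
    x <- qty[[nm]]
    qs <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 1)
    data.frame(quantity = nm, median = qs[2], lo = qs[1], hi = qs[3],
               frac_infinite = mean(!is.finite(x)))
  }))
  rownames(out) <- NULL
  out
}
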