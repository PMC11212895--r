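# Synthetic-data generation for all three modalities (BrdU/Ki67 labelling,
# donor chimerism, reporter dilution) from known ground truth, with
# counting noise, so that every pipeline stage is testable without external
# data. Also hosts the R-side interface to the exact stochastic simulation
# oracle.

#' Ground truth for synthetic-data generation
#'
#' Bundles the generating topology, kinetic parameters per stratum,
#' replacement parameters per subset, reference chimerism values and noise
#' settings.
#'
#' @param topology generating topology for the labelling data.
#' @param params named list of stationary \code{\link{kinetic_params}}, one
#'   per stratum, names like \code{"young.TCM.host"}.
#' @param replacement named list (per subset) of lists with fields
#'   \code{rate}, \code{source_chimerism}, \code{t0}.
#' @param reference named numeric vector of constant reference chimerism
#'   series to emit (e.g. \code{c(DP1 = 0.92, naive_CD4 = 0.82)}).
#' @param events_per_sample flow-event depth for binomial counting noise of
#'   the labelling fractions (\code{Inf} disables noise).
#' @param chimerism_precision beta precision of donor-fraction noise
#'   (\code{Inf} disables noise).
#' @return object of class \code{ground_truth}.
#' @export
ground_truth <- function(topology, params, replacement = list(),
                         reference = c(DP1 = 0.92, naive_CD4 = 0.82),
                         events_per_sample = 2000L,
                         chimerism_precision = 400) {
  stopifnot(is.list(params), length(params) >= 1)
  for (p in params) {
    stopifnot(inherits(p, "kinetic_params"))
    if (max(abs(stationarity_residual(p))) > 1e-8)
      stop("ground-truth parameters must be stationary (use close_parameters)",
           call. = FALSE)
  }
  structure(list(topology = topology, params = params,
                 replacement = replacement, reference = reference,
                 events_per_sample = events_per_sample,
                 chimerism_precision = chimerism_precision),
            class = "ground_truth")
}

#' Realistic ground-truth preset
#'
#' A branched-topology parameter set with magnitudes in the ranges the
#' labelling analysis infers for these subsets: slow cells divide rarely
#' (interdivision times 100-200 days) and live 60-100 days, fast cells turn
#' over on timescales of days, Ki67 lifetime 3.1 days, BrdU uptake
#' efficiency 0.6, and a constitutive influx of a few percent of the pool
#' per day. Central memory carries a larger fast subpopulation than effector
#' memory (matching its higher Ki67 expression), and donor (younger) cells a
#' larger fast share than host.
#'
#' @param topology topology of the preset (parameters are mapped onto the
#'   requested topology; default branched).
#' @param strata character vector of strata to include (default all eight).
#' @return a \code{\link{ground_truth}} object.
#' @export
paper_like_truth <- function(topology = "branched",
                             strata = NULL) {
  grid <- expand.grid(cohort = c("young", "old"), subset = c("TCM", "TEM"),
                      lineage = c("host", "donor"), stringsAsFactors = FALSE)
  keys <- paste(grid$cohort, grid$subset, grid$lineage, sep = ".")
  if (is.null(strata)) strata <- keys
  params <- list()
  for (i in seq_len(nrow(grid))) {
    key <- keys[i]
    if (!(key %in% strata)) next
    # fast share: higher in TCM than TEM, higher in donor than host,
    # host/donor converging in the old cohort
    nu <- switch(grid$subset[i], TCM = 0.45, TEM = 0.22)
    if (grid$lineage[i] == "donor" && grid$cohort[i] == "young") nu <- nu + 0.15
    if (grid$lineage[i] == "donor" && grid$cohort[i] == "old") nu <- nu + 0.05
    alpha_slow <- 0.007                     # interdivision ~ 140 d
    alpha_fast <- 0.15                      # fast timescale of days
    f <- if (grid$lineage[i] == "donor") 0.012 else 0.008
    pf <- 0.6
    base <- switch(topology,
      branched = kinetic_params("branched", epsilon = 0.6, beta = 1 / 3.1,
        alpha_fast = alpha_fast, alpha_slow = alpha_slow, f = f,
        phi_fast_fraction = pf, N_fast = nu, N_slow = 1 - nu),
      linear = kinetic_params("linear", epsilon = 0.6, beta = 1 / 3.1,
        alpha_fast = alpha_fast, alpha_slow = alpha_slow, gamma = 0.01,
        f = f, N_fast = nu, N_slow = 1 - nu),
      burst = kinetic_params("burst", epsilon = 0.6, beta = 1 / 3.1,
        alpha_fast = alpha_fast, alpha_slow = 0, activation = 0.01,
        reversion = 0.05, f = f, N_fast = nu, N_slow = 1 - nu),
      temporal = kinetic_params("temporal", epsilon = 0.6, beta = 1 / 3.1,
        alpha_fast = 0.05, delta_fast = 0.12, f = f, N_fast = 1, N_slow = 0),
      stop("unknown topology: ", topology, call. = FALSE))
    params[[key]] <- close_parameters(base)
  }
  ground_truth(topology, params,
    replacement = list(
      TCM = list(rate = 0.01, source_chimerism = 0.75, t0 = 42),
      TEM = list(rate = 0.008, source_chimerism = 0.65, t0 = 42)))
}

parse_stratum <- function(keys) {
  parts <- strsplit(keys, ".", fixed = TRUE)
  data.frame(cohort = vapply(parts, `[`, "", 1),
             subset = vapply(parts, `[`, "", 2),
             lineage = vapply(parts, `[`, "", 3),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic BrdU/Ki67 labelling dataset
#'
#' For each stratum, timepoint and mouse, the four summary fractions are
#' computed from the deterministic labelling solution and perturbed by
#' binomial counting at the design's event depth: the number of Ki67-high
#' events is binomial in the Ki67-high fraction, and BrdU-positive events
#' within Ki67-high/low are binomial within those gates, so the reported
#' overall BrdU-positive fraction is exactly consistent with the conditional
#' fractions. With \code{events_per_sample = Inf} the emitted fractions
#' equal the model output exactly. Deterministic given the seed.
#'
#' @param truth a \code{\link{ground_truth}}.
#' @param design an \code{\link{experiment_design}}.
#' @param seed integer seed.
#' @return a validated \code{labelling_obs} table.
#' @export
generate_labelling_dataset <- function(truth, design = experiment_design(),
                                       seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(seed)
  n_ev <- truth$events_per_sample
  rows <- list()
  meta <- parse_stratum(names(truth$params))
  for (s in seq_along(truth$params)) {
    p <- truth$params[[s]]
    pred <- solve_labelling(p, design, design$sample_times)
    for (ti in seq_along(design$sample_times)) {
      for (m in seq_len(design$mice_per_timepoint)) {
        k <- pred$frac_ki67hi[ti]
        phi_ <- pred$frac_brdu_in_ki67hi[ti]
        plo <- pred$frac_brdu_in_ki67lo[ti]
        if (is.finite(n_ev)) {
          nhi <- stats::rbinom(1, n_ev, k)
          xhi <- stats::rbinom(1, nhi, phi_)
          xlo <- stats::rbinom(1, n_ev - nhi, plo)
          k_obs <- nhi / n_ev
          phi_obs <- if (nhi > 0) xhi / nhi else 0
          plo_obs <- if (nhi < n_ev) xlo / (n_ev - nhi) else 0
          fb_obs <- (xhi + xlo) / n_ev
          nev_out <- n_ev
        } else {
          k_obs <- k; phi_obs <- phi_; plo_obs <- plo
          fb_obs <- pred$frac_brdu[ti]
          nev_out <- 1e9
        }
        rows[[length(rows) + 1L]] <- data.frame(
          mouse_id = sprintf("m%s_t%02d_%d", names(truth$params)[s], ti, m),
          cohort = meta$cohort[s], subset = meta$subset[s],
          lineage = meta$lineage[s], t_label = design$sample_times[ti],
          frac_brdu = fb_obs, frac_brdu_in_ki67hi = phi_obs,
          frac_brdu_in_ki67lo = plo_obs, frac_ki67hi = k_obs,
          n_events = nev_out, stringsAsFactors = FALSE)
      }
    }
  }
  labelling_observations(do.call(rbind, rows))
}

#' Generate a synthetic donor-chimerism dataset
#'
#' Donor fractions follow the replacement curves in the ground truth with
#' beta counting noise; constant reference series (DP1 thymocytes, naive
#' CD4) are emitted at the configured chimerism. Deterministic given the
#' seed.
#'
#' @param truth a \code{\link{ground_truth}} with \code{replacement} entries.
#' @param times days since bone-marrow transplant to sample.
#' @param mice_per_time mice per timepoint.
#' @param seed integer seed.
#' @return a validated \code{chimerism_obs} table.
#' @export
generate_chimerism_dataset <- function(truth, times = seq(49, 350, by = 21),
                                       mice_per_time = 2L, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(seed)
  prec <- truth$chimerism_precision
  noisy <- function(mu) {
    mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
    if (!is.finite(prec)) return(mu)
    stats::rbeta(length(mu), mu * prec, (1 - mu) * prec)
  }
  rows <- list()
  add <- function(subset, t, mu) {
    rows[[length(rows) + 1L]] <<- data.frame(
      mouse_id = sprintf("c%s_%03d", subset, round(t)),
      t_bmt = t, subset = subset, donor_fraction = noisy(mu),
      stringsAsFactors = FALSE)
  }
  for (subset in names(truth$replacement)) {
    rp <- truth$replacement[[subset]]
    for (t in times) for (m in seq_len(mice_per_time))
      add(subset, t, replacement_curve(t, rp$rate, rp$source_chimerism,
                                       rp$t0 %||% 42))
  }
  for (subset in names(truth$reference)) {
    for (t in times) for (m in seq_len(mice_per_time))
      add(subset, t, truth$reference[[subset]])
  }
  chimerism_observations(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic reporter-dilution dataset
#'
#' Emits a naive-source series from an exponential-to-plateau dilution curve
#' and TCM/TEM series from the deterministic label-dilution dynamics of the
#' supplied kinetic parameters chained along naive -> TCM -> TEM, with beta
#' noise. Deterministic given the seed.
#'
#' @param p_tcm,p_tem stationary \code{\link{kinetic_params}} for the two
#'   memory subsets (fast/slow topologies).
#' @param source_pars list with \code{m0}, \code{m_inf}, \code{r} for the
#'   naive dilution curve.
#' @param times days since tamoxifen.
#' @param precision beta noise precision (\code{Inf} disables noise).
#' @param seed integer seed.
#' @return a validated \code{dilution_obs} table.
#' @export
generate_dilution_dataset <- function(p_tcm, p_tem,
                                      source_pars = list(m0 = 0.9, m_inf = 0.35,
                                                         r = 0.03),
                                      times = seq(0, 126, by = 14),
                                      precision = 400, seed = 1L) {
  set.seed(seed)
  src <- function(t) source_pars$m_inf +
    (source_pars$m0 - source_pars$m_inf) * exp(-source_pars$r * t)
  tcm <- dilution_trajectory(p_tcm, src, times, src(0))
  tcm_fn <- function(t) stats::approx(times, tcm$aggregate, xout = t, rule = 2)$y
  tem <- dilution_trajectory(p_tem, tcm_fn, times, src(0))
  noisy <- function(mu) {
    mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
    if (!is.finite(precision)) return(mu)
    stats::rbeta(length(mu), mu * precision, (1 - mu) * precision)
  }
  mk <- function(subset, vals) data.frame(
    mouse_id = sprintf("d%s_%03d", subset, round(times)),
    t_tam = times, subset = subset, labelled_fraction = noisy(vals),
    stringsAsFactors = FALSE)
  dilution_observations(rbind(mk("naive_CD4", src(times)),
                              mk("TCM", tcm$aggregate),
                              mk("TEM", tem$aggregate)))
}

#' Exact stochastic simulation of the labelling dynamics
#'
#' Event-driven (direct-method) stochastic simulation of per-cell division
#' with probabilistic BrdU uptake during the pulse, Ki67 staged decay,
#' death, pool transitions and constant influx, at a finite population size.
#' Serves as an independent oracle for the deterministic solver: means over
#' replicates converge on \code{\link{solve_labelling}} output.
#'
#' @param p stationary \code{\link{kinetic_params}}.
#' @param n_cells initial population size (>= 1e4 recommended for stable
#'   summaries).
#' @param design an \code{\link{experiment_design}}.
#' @param times days since BrdU start at which to record.
#' @param n_reps number of independent replicates.
#' @param seed integer seed.
#' @return data.frame per time: mean and Monte-Carlo standard error of the
#'   four summary fractions over replicates, plus the count of replicates
#'   that went extinct before the last recorded time.
#' @export
simulate_agentbased <- function(p, n_cells = 2e4, design = experiment_design(),
                                times = c(7, 14, 21, 28, 35), n_reps = 20L,
                                seed = 1L) {
  stopifnot(inherits(p, "kinetic_params"))
  set.seed(seed)
  times <- sort(times)
  x0 <- as.numeric(steady_state(p))
  scale <- n_cells / sum(x0)
  # one multinomial draw of the scaled steady state per replicate: a shared
  # initial draw would relax only on the slow-pool timescale and correlate
  # every replicate
  probs <- x0 / sum(x0)
  counts0 <- stats::rmultinom(n_reps, n_cells, probs)
  # reorder package state layout -> simulator layout [b][pool][stage(0=lo)]
  n <- p$n_stages
  npool <- n_pools(p)
  cpp_order <- integer(0)
  for (b in 0:1) for (i in seq_len(npool))
    cpp_order <- c(cpp_order, state_index(p, i, c(0L, seq_len(n)), b))
  counts_cpp <- counts0[cpp_order, , drop = FALSE]
  storage.mode(counts_cpp) <- "integer"
  alpha <- if (npool == 1L) p$alpha_fast else c(p$alpha_fast, p$alpha_slow)
  if (p$topology == "temporal") {
    delta_hi <- p$delta_fast; delta_lo <- p$delta_slow
  } else {
    delta_hi <- c(p$delta_fast, p$delta_slow)
    delta_lo <- delta_hi
  }
  trans <- pool_transitions(p)
  phi <- total_influx(p) * scale
  phi_pool <- if (npool == 1L) phi else
    c(phi * p$phi_fast_fraction, phi * (1 - p$phi_fast_fraction))
  raw <- .ssa_labelling_cpp(counts_cpp, npool, n, as.numeric(alpha),
                            as.numeric(delta_hi), as.numeric(delta_lo),
                            p$beta, p$epsilon, design$pulse_end, trans,
                            as.numeric(phi_pool), as.numeric(times),
                            as.integer(n_reps))
  # raw dims: 5 x n_times x n_reps (total, hi, pos, hi_pos, extinct).
  # Fractions are estimated as ratios of counts POOLED over replicates: the
  # count expectations obey the same linear dynamics at every population
  # size, so the pooled ratio is an unbiased estimate of the deterministic
  # fraction, whereas the mean of per-replicate ratios carries an O(1/N)
  # bias from population-size fluctuations. Standard errors are jackknife
  # (leave-one-replicate-out) errors of the pooled ratio.
  out <- data.frame(time = times)
  stats_names <- c("frac_brdu", "frac_brdu_in_ki67hi", "frac_brdu_in_ki67lo",
                   "frac_ki67hi")
  tot <- matrix(raw[1, , ], ncol = n_reps)
  hi <- matrix(raw[2, , ], ncol = n_reps)
  pos <- matrix(raw[3, , ], ncol = n_reps)
  hp <- matrix(raw[4, , ], ncol = n_reps)
  extinct <- apply(matrix(raw[5, , ], ncol = n_reps) > 0, 2, any)
  pooled <- function(num, den) {
    sdiv <- function(a, b) ifelse(b > 0, a / b, 0)
    est <- sdiv(rowSums(num), rowSums(den))
    jack <- vapply(seq_len(n_reps), function(r)
      sdiv(rowSums(num[, -r, drop = FALSE]), rowSums(den[, -r, drop = FALSE])),
      numeric(nrow(num)))
    se <- sqrt((n_reps - 1) / n_reps *
                 rowSums((jack - rowMeans(jack))^2))
    list(est = est, se = se)
  }
  chans <- list(pooled(pos, tot), pooled(hp, hi),
                pooled(pos - hp, tot - hi), pooled(hi, tot))
  for (c4 in 1:4) {
    out[[stats_names[c4]]] <- chans[[c4]]$est
    out[[paste0(stats_names[c4], "_se")]] <- chans[[c4]]$se
  }
  out$total_mean <- rowMeans(tot)
  attr(out, "n_extinct") <- sum(extinct)
  if (any(extinct))
    warning(sum(extinct), " replicate(s) went extinct", call. = FALSE)
  out
}
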