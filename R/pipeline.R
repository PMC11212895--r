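# End-to-end orchestration: replacement fits -> influx priors -> stratified
# labelling fits x topologies -> model comparison -> derived quantities ->
# validation predictions, as a single reproducible, resumable run.

#' Default pipeline configuration
#'
#' @param out_dir output directory for stage tables and the manifest.
#' @param seed master seed; each stage derives its own from it.
#' @param topologies topologies to fit per stratum.
#' @param strata strata to fit (default: all in the truth).
#' @param truth a \code{\link{ground_truth}} used to simulate input tables
#'   when no real tables are supplied.
#' @param labelling_csv,chimerism_csv optional paths to real input tables
#'   (read with the package readers); when \code{NULL} synthetic tables are
#'   generated from \code{truth}.
#' @param design an \code{\link{experiment_design}}.
#' @param sampler list of sampler settings (\code{n_chains},
#'   \code{n_warmup}, \code{n_iter}).
#' @return a named list, the pipeline configuration.
#' @export
pipeline_config <- function(out_dir = tempfile("memdyn_run_"), seed = 1L,
                            topologies = c("branched", "linear", "burst", "temporal"),
                            strata = NULL, truth = paper_like_truth(),
                            labelling_csv = NULL, chimerism_csv = NULL,
                            design = experiment_design(),
                            sampler = list(n_chains = 3L, n_warmup = 600L,
                                           n_iter = 400L)) {
  list(out_dir = out_dir, seed = as.integer(seed), topologies = topologies,
       strata = strata, truth = truth, labelling_csv = labelling_csv,
       chimerism_csv = chimerism_csv, design = design, sampler = sampler)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: (1) assemble input tables (read
#' or simulate); (2) fit replacement models per subset and derive influx
#' priors; (3) fit every requested topology to every stratum; (4) compare
#' topologies per stratum by LOO; (5) derived lifespan summaries; (6)
#' transfer-cohort Ki67 predictions. Each stage writes CSV outputs under
#' \code{config$out_dir}; a stage whose outputs already exist (same config
#' digest) is skipped on re-run, and a stage failure halts downstream
#' stages with the manifest recording partial completion.
#'
#' @param config a \code{\link{pipeline_config}} list.
#' @return object of class \code{run_manifest}: config digest, seeds,
#'   per-stage status, output-file inventory, and the in-memory stage
#'   results.
#' @export
run_full_analysis <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- config_digest(config)
  manifest <- list(digest = digest, seed = config$seed, stages = list(),
                   files = character())
  results <- list()
  status_path <- file.path(config$out_dir, "manifest.rds")
  prev <- if (file.exists(status_path)) readRDS(status_path) else NULL
  resumable <- !is.null(prev) && identical(prev$digest, digest)
  run_stage <- function(name, fun) {
    if (resumable && isTRUE(prev$stages[[name]]$ok) &&
        all(file.exists(prev$stages[[name]]$files))) {
      manifest$stages[[name]] <<- prev$stages[[name]]
      manifest$stages[[name]]$resumed <<- TRUE
      return(readRDS(file.path(config$out_dir, paste0(name, ".rds"))))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(ok = FALSE, error = conditionMessage(res),
                                       files = character())
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    saveRDS(res$value, file.path(config$out_dir, paste0(name, ".rds")))
    manifest$stages[[name]] <<- list(ok = TRUE, files = res$files,
                                     resumed = FALSE)
    manifest$files <<- c(manifest$files, res$files)
    saveRDS(manifest, status_path)
    res$value
  }
  on.exit(saveRDS(manifest, status_path))
  sampler <- config$sampler
  # stage 1: inputs
  inputs <- run_stage("inputs", function() {
    lab <- if (!is.null(config$labelling_csv))
      read_labelling_table(config$labelling_csv) else
      generate_labelling_dataset(config$truth, config$design,
                                 seed = config$seed)
    chi <- if (!is.null(config$chimerism_csv))
      read_chimerism_table(config$chimerism_csv) else
      generate_chimerism_dataset(config$truth, seed = config$seed + 1L)
    f1 <- file.path(config$out_dir, "labelling.csv")
    f2 <- file.path(config$out_dir, "chimerism.csv")
    write_obs_table(lab, f1)
    write_obs_table(chi, f2)
    list(value = list(labelling = lab, chimerism = chi), files = c(f1, f2))
  })
  # stage 2: replacement fits and influx priors
  priors <- run_stage("replacement", function() {
    out <- list()
    rows <- list()
    for (subset in intersect(c("TCM", "TEM"), unique(inputs$chimerism$subset))) {
      sub <- inputs$chimerism[inputs$chimerism$subset == subset, ]
      fit <- fit_replacement(sub, "homogeneous",
                             n_chains = sampler$n_chains,
                             n_warmup = sampler$n_warmup,
                             n_iter = max(sampler$n_iter, 400L),
                             seed = config$seed + 10L)
      out[[subset]] <- list(fit = fit,
                            prior = influx_prior_from_replacement(fit))
      cf <- coef(fit)
      rows[[subset]] <- data.frame(subset = subset, rate = cf[["rate"]],
                                   source_chimerism = cf[["source_chimerism"]])
    }
    f <- file.path(config$out_dir, "replacement_estimates.csv")
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
    list(value = out, files = f)
  })
  # stage 3: labelling fits per stratum x topology
  fits <- run_stage("labelling_fits", function() {
    lab <- inputs$labelling
    keys <- unique(paste(lab$cohort, lab$subset, lab$lineage, sep = "."))
    if (!is.null(config$strata)) keys <- intersect(keys, config$strata)
    out <- list()
    k <- 0L
    for (key in keys) {
      meta <- parse_stratum(key)
      sub <- lab[lab$cohort == meta$cohort & lab$subset == meta$subset &
                   lab$lineage == meta$lineage, ]
      ip <- priors[[meta$subset]]$prior
      for (topo in config$topologies) {
        k <- k + 1L
        out[[paste(key, topo, sep = "|")]] <- fit_labelling_model(
          sub, topo, influx_prior = ip, design = config$design,
          n_chains = sampler$n_chains, n_warmup = sampler$n_warmup,
          n_iter = sampler$n_iter, seed = config$seed + 100L + k)
      }
    }
    f <- file.path(config$out_dir, "fit_summaries.csv")
    summ <- do.call(rbind, lapply(names(out), function(nm) {
      s <- summary(out[[nm]])
      cbind(fit = nm, s)
    }))
    utils::write.csv(summ, f, row.names = FALSE)
    list(value = out, files = f)
  })
  # stage 4: model comparison per stratum
  comparisons <- run_stage("comparison", function() {
    keys <- unique(sub("\\|.*$", "", names(fits)))
    out <- list()
    rows <- list()
    for (key in keys) {
      these <- fits[grep(paste0("^", key, "\\|"), names(fits))]
      names(these) <- sub("^.*\\|", "", names(these))
      if (length(these) < 2) next
      cmp <- compare_models(these)
      out[[key]] <- cmp
      rows[[key]] <- cbind(stratum = key, cmp$pairs)
    }
    f <- file.path(config$out_dir, "model_comparison.csv")
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
    list(value = out, files = f)
  })
  # stage 5: derived quantities
  derived <- run_stage("derived", function() {
    rows <- list()
    for (nm in names(fits)) {
      fit <- fits[[nm]]
      if (!all(c("delta_fast", "delta_slow") %in% names(fit$draws))) next
      ls <- lifespan_summary(fit$draws[stats::complete.cases(fit$draws), ])
      rows[[nm]] <- cbind(fit = nm, ls)
    }
    f <- file.path(config$out_dir, "derived_quantities.csv")
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, f, row.names = FALSE)
    list(value = tab, files = f)
  })
  # stage 6: transfer predictions from the first available stratum's truth
  # or posterior median parameters
  predictions <- run_stage("predictions", function() {
    fit1 <- fits[[1]]
    nat <- coef(fit1)
    p <- labelling_params_from_draw(nat, fit1$topology)
    rows <- list()
    for (cohort in c("yfp_pos", "yfp_neg", "bulk")) {
      for (influx_on in c(TRUE, FALSE)) {
        tr <- predict_transfer_ki67(p, cohort, influx_on = influx_on,
                                    horizon = 7, times = c(0, 7))
        rows[[paste(cohort, influx_on)]] <- cbind(cohort = cohort,
                                                  influx_on = influx_on, tr)
      }
    }
    f <- file.path(config$out_dir, "transfer_predictions.csv")
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, f, row.names = FALSE)
    list(value = tab, files = f)
  })
  manifest$results <- list(inputs = inputs, priors = priors, fits = fits,
                           comparisons = comparisons, derived = derived,
                           predictions = predictions)
  class(manifest) <- "run_manifest"
  saveRDS(manifest, status_path)
  manifest
}

config_digest <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(cfg, digits.d = 12,
                                              list.len = 1e4)), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ", config ", substr(x$digest, 1, 8),
      ")\n", sep = "")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-16s %s%s\n", nm,
                if (isTRUE(st$ok)) "ok" else paste("FAILED:", st$error),
                if (isTRUE(st$resumed)) " (resumed)" else ""))
  }
  cat(length(x$files), "output file(s)\n")
  invisible(x)
}
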