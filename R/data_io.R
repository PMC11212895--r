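#' Sampling design of a BrdU pulse-chase experiment
#'
#' Defaults mirror the labelling assay design: BrdU administered for 21 days
#' (intraperitoneal injection then drinking water), with sampling during the
#' pulse and for up to 14 days of chase, about two mice per timepoint.
#'
#' @param pulse_end day BrdU administration stops (default 21).
#' @param chase_end last day of the assay (default 35).
#' @param sample_times days at which mice are sacrificed; default a grid of
#'   13 times over \[1, 35\].
#' @param mice_per_timepoint mice sampled per timepoint (default 2).
#' @param events_per_sample flow-cytometry events acquired per sample,
#'   setting the counting-noise depth (default 2000).
#' @return object of class \code{experiment_design}.
#' @export
experiment_design <- function(pulse_end = 21, chase_end = 35,
                              sample_times = c(1, 2, 4, 7, 10, 14, 17, 21,
                                               24, 27, 30, 33, 35),
                              mice_per_timepoint = 2L,
                              events_per_sample = 2000L) {
  if (!(pulse_end > 0 && chase_end > pulse_end))
    stop("need 0 < pulse_end < chase_end", call. = FALSE)
  if (any(sample_times < 0) || any(sample_times > chase_end))
    stop("sample_times must lie in [0, chase_end]", call. = FALSE)
  if (mice_per_timepoint < 1L) stop("mice_per_timepoint must be >= 1", call. = FALSE)
  if (events_per_sample < 1L && is.finite(events_per_sample))
    stop("events_per_sample must be >= 1", call. = FALSE)
  structure(list(pulse_end = pulse_end, chase_end = chase_end,
                 sample_times = sample_times,
                 mice_per_timepoint = as.integer(mice_per_timepoint),
                 events_per_sample = events_per_sample),
            class = "experiment_design")
}

# ---- observation tables ---------------------------------------------------
# Observations are plain data.frames with a class tag and validated columns;
# fractions are proportions in [0,1] (readers can convert from percent).

labelling_cols <- c("mouse_id", "cohort", "subset", "lineage", "t_label",
                    "frac_brdu", "frac_brdu_in_ki67hi", "frac_brdu_in_ki67lo",
                    "frac_ki67hi", "n_events")
chimerism_cols <- c("mouse_id", "t_bmt", "subset", "donor_fraction")
dilution_cols <- c("mouse_id", "t_tam", "subset", "labelled_fraction")

#' Assemble and validate a table of BrdU/Ki67 labelling observations
#'
#' One row per mouse x subset x lineage x timepoint. Fractions are
#' proportions. Rows violating the invariants (fractions in \[0,1\],
#' \code{t_label >= 0}, positive event counts, and the consistency identity
#' \code{frac_brdu == frac_ki67hi * frac_brdu_in_ki67hi +
#' (1 - frac_ki67hi) * frac_brdu_in_ki67lo} within \code{1e-6}) are dropped
#' with row-indexed warnings, or raise an error when
#' \code{on_invalid = "error"}.
#'
#' @param df data.frame with columns \code{mouse_id, cohort, subset, lineage,
#'   t_label, frac_brdu, frac_brdu_in_ki67hi, frac_brdu_in_ki67lo,
#'   frac_ki67hi, n_events}.
#' @param on_invalid \code{"drop"} (default) or \code{"error"}.
#' @return validated data.frame of class \code{labelling_obs}.
#' @export
labelling_observations <- function(df, on_invalid = c("drop", "error")) {
  on_invalid <- match.arg(on_invalid)
  check_cols(df, labelling_cols, "labelling")
  df$cohort <- check_enum(df$cohort, c("young", "old"), "cohort")
  df$subset <- check_enum(df$subset, c("TCM", "TEM"), "subset")
  df$lineage <- check_enum(df$lineage, c("host", "donor"), "lineage")
  fr <- c("frac_brdu", "frac_brdu_in_ki67hi", "frac_brdu_in_ki67lo", "frac_ki67hi")
  bad <- rep(FALSE, nrow(df))
  why <- character(nrow(df))
  for (cl in fr) {
    b <- !is.finite(df[[cl]]) | df[[cl]] < 0 | df[[cl]] > 1
    why[b & !bad] <- paste(cl, "outside [0,1]")
    bad <- bad | b
  }
  b <- !is.finite(df$t_label) | df$t_label < 0
  why[b & !bad] <- "t_label negative"
  bad <- bad | b
  b <- !is.finite(df$n_events) | df$n_events < 1
  why[b & !bad] <- "n_events not a positive count"
  bad <- bad | b
  cons <- df$frac_ki67hi * df$frac_brdu_in_ki67hi +
    (1 - df$frac_ki67hi) * df$frac_brdu_in_ki67lo
  b <- !bad & abs(cons - df$frac_brdu) > 1e-6
  why[b] <- "frac_brdu inconsistent with conditional fractions"
  bad <- bad | b
  df <- drop_invalid(df, bad, why, on_invalid, "labelling")
  class(df) <- c("labelling_obs", "data.frame")
  df
}

#' Assemble and validate a table of donor-chimerism observations
#'
#' One row per mouse x subset x time since bone-marrow transplant.
#'
#' @param df data.frame with columns \code{mouse_id, t_bmt, subset,
#'   donor_fraction}; \code{subset} one of DP1, naive_CD4, TCM, TEM.
#' @param on_invalid \code{"drop"} (default) or \code{"error"}.
#' @return validated data.frame of class \code{chimerism_obs}.
#' @export
chimerism_observations <- function(df, on_invalid = c("drop", "error")) {
  on_invalid <- match.arg(on_invalid)
  check_cols(df, chimerism_cols, "chimerism")
  df$subset <- check_enum(df$subset, c("DP1", "naive_CD4", "TCM", "TEM"), "subset")
  bad <- !is.finite(df$donor_fraction) | df$donor_fraction < 0 | df$donor_fraction > 1
  why <- ifelse(bad, "donor_fraction outside [0,1]", "")
  b <- !is.finite(df$t_bmt) | df$t_bmt < 0
  why[b & !bad] <- "t_bmt negative"
  bad <- bad | b
  df <- drop_invalid(df, bad, why, on_invalid, "chimerism")
  class(df) <- c("chimerism_obs", "data.frame")
  df
}

#' Assemble and validate a table of reporter-dilution observations
#'
#' One row per mouse x subset x time since tamoxifen; \code{labelled_fraction}
#' is the frequency of reporter-positive (mTom+ or YFP+) cells.
#'
#' @param df data.frame with columns \code{mouse_id, t_tam, subset,
#'   labelled_fraction}; \code{subset} one of naive_CD4, TCM, TEM.
#' @param on_invalid \code{"drop"} (default) or \code{"error"}.
#' @return validated data.frame of class \code{dilution_obs}.
#' @export
dilution_observations <- function(df, on_invalid = c("drop", "error")) {
  on_invalid <- match.arg(on_invalid)
  check_cols(df, dilution_cols, "dilution")
  df$subset <- check_enum(df$subset, c("naive_CD4", "TCM", "TEM"), "subset")
  bad <- !is.finite(df$labelled_fraction) | df$labelled_fraction < 0 |
    df$labelled_fraction > 1
  why <- ifelse(bad, "labelled_fraction outside [0,1]", "")
  b <- !is.finite(df$t_tam) | df$t_tam < 0
  why[b & !bad] <- "t_tam negative"
  bad <- bad | b
  df <- drop_invalid(df, bad, why, on_invalid, "dilution")
  class(df) <- c("dilution_obs", "data.frame")
  df
}

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing mandatory ", what, " column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(df)
}

check_enum <- function(x, levels, nm) {
  x <- as.character(x)
  bad <- !(x %in% levels)
  if (any(bad))
    stop("column '", nm, "' contains values outside {",
         paste(levels, collapse = ", "), "}: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  x
}

drop_invalid <- function(df, bad, why, on_invalid, what) {
  if (any(bad)) {
    msg <- paste0(what, " row ", which(bad), ": ", why[bad], collapse = "; ")
    if (on_invalid == "error") stop(msg, call. = FALSE)
    warning("dropping ", sum(bad), " invalid ", what, " row(s) -- ", msg,
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

# ---- CSV readers / writers ------------------------------------------------

read_obs_csv <- function(path, rename = NULL, percent = FALSE, frac_cols,
                         validate, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(rename)) {
    for (nm in names(rename)) {
      j <- match(rename[[nm]], names(df))
      if (!is.na(j)) names(df)[j] <- nm
    }
  }
  if (nrow(df) == 0) {
    warning("empty ", what, " table: ", path, call. = FALSE)
  }
  if (percent) for (cl in intersect(frac_cols, names(df))) df[[cl]] <- df[[cl]] / 100
  validate(df)
}

#' Read a BrdU/Ki67 labelling table from CSV
#'
#' @param path CSV file path.
#' @param rename optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   \code{c(frac_brdu = "pct.brdu")}.
#' @param percent if \code{TRUE}, fraction columns in the file are
#'   percentages and are divided by 100.
#' @param on_invalid passed to \code{\link{labelling_observations}}.
#' @return validated \code{labelling_obs} data.frame.
#' @export
read_labelling_table <- function(path, rename = NULL, percent = FALSE,
                                 on_invalid = "drop") {
  read_obs_csv(path, rename, percent,
               c("frac_brdu", "frac_brdu_in_ki67hi", "frac_brdu_in_ki67lo",
                 "frac_ki67hi"),
               function(df) labelling_observations(df, on_invalid), "labelling")
}

#' Read a donor-chimerism table from CSV
#' @inheritParams read_labelling_table
#' @return validated \code{chimerism_obs} data.frame.
#' @export
read_chimerism_table <- function(path, rename = NULL, percent = FALSE,
                                 on_invalid = "drop") {
  read_obs_csv(path, rename, percent, "donor_fraction",
               function(df) chimerism_observations(df, on_invalid), "chimerism")
}

#' Read a reporter-dilution table from CSV
#' @inheritParams read_labelling_table
#' @return validated \code{dilution_obs} data.frame.
#' @export
read_dilution_table <- function(path, rename = NULL, percent = FALSE,
                                on_invalid = "drop") {
  read_obs_csv(path, rename, percent, "labelled_fraction",
               function(df) dilution_observations(df, on_invalid), "dilution")
}

#' Write an observation table to CSV
#'
#' Round-trips with the corresponding reader: writing then reading is the
#' identity on validated tables.
#'
#' @param obs a validated observation data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_obs_table <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
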