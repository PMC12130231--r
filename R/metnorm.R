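# Internal-standard assignment, ratio normalization, and run (batch)
# correction for targeted MRM peak areas.

#' Construct a peak table
#'
#' Long-format table of raw MRM peak areas: one row per (run, sample,
#' analyte). Calibration rows carry the expected concentration (micromolar);
#' biological rows do not.
#'
#' @param df data frame with columns `run_id`, `sample_id`, `analysis_id`,
#'   `condition` (`induced`, `uninduced` or `calibration`), `clone_id`
#'   (may be `NA`), `replicate`, `analyte_id`, `analyte_role` (`target` or
#'   `internal_standard`), `area` (non-negative), `expected_conc` (`NA`
#'   except on calibration rows).
#' @return The validated data frame with class `peak_table`.
#' @export
peak_table <- function(df) {
  need <- c("run_id", "sample_id", "analysis_id", "condition", "clone_id",
            "replicate", "analyte_id", "analyte_role", "area", "expected_conc")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("peak table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$area < 0, na.rm = TRUE)) stop("peak areas must be non-negative")
  if (!all(df$condition %in% c("induced", "uninduced", "calibration"))) {
    stop("condition must be induced, uninduced or calibration")
  }
  if (!all(df$analyte_role %in% c("target", "internal_standard"))) {
    stop("analyte_role must be target or internal_standard")
  }
  is_cal <- df$condition == "calibration"
  if (any(!is.na(df$expected_conc) & !is_cal)) {
    stop("expected_conc only allowed on calibration rows")
  }
  if (any(is_cal & df$analyte_role == "target" & is.na(df$expected_conc))) {
    stop("calibration target rows need expected_conc")
  }
  key <- paste(df$run_id, df$sample_id, df$analyte_id)
  if (anyDuplicated(key)) stop("(run, sample, analyte) must be unique")
  class(df) <- c("peak_table", "data.frame")
  df
}

#' @export
print.peak_table <- function(x, ...) {
  cat("peak_table:", nrow(x), "rows,",
      length(unique(x$analyte_id[x$analyte_role == "target"])), "targets,",
      length(unique(x$analyte_id[x$analyte_role == "internal_standard"])),
      "internal standards,", length(unique(x$run_id)), "run(s)\n")
  invisible(x)
}

# adjusted R-squared of a simple weighted regression of y on x
.wls_adj_r2 <- function(x, y, w) {
  n <- length(x)
  if (n < 3L || stats::var(x) == 0) return(NA_real_)
  fit <- stats::lm.wfit(cbind(1, x), y, w)
  ybar <- sum(w * y) / sum(w)
  ss_tot <- sum(w * (y - ybar)^2)
  ss_res <- sum(w * fit$residuals^2)
  if (ss_tot <= 0) return(NA_real_)
  r2 <- 1 - ss_res / ss_tot
  1 - (1 - r2) * (n - 1) / (n - 2)
}

#' Assign reference internal standards
#'
#' Metabolites flagged as having a structure-matched internal standard get
#' that standard. For the rest, a weighted linear calibration regression of
#' expected concentration on the metabolite/IS peak-area ratio is fit per
#' (metabolite, internal standard, run); an internal standard qualifies in a
#' run when its adjusted R-squared reaches `r2_threshold`. The reference is
#' the standard qualifying in the largest fraction of runs, provided that
#' fraction reaches `run_fraction` (ties select all); otherwise the
#' highest-fraction standard is used as a fallback.
#'
#' @param pt a [peak_table()] containing calibration rows.
#' @param panel data frame describing the internal-standard panel, columns
#'   `analyte_id` and `structure_match_target` (the metabolite the standard
#'   shares a structure with, or `NA`).
#' @param r2_threshold minimum adjusted R-squared for a run to qualify.
#' @param run_fraction minimum fraction of eligible runs that must qualify.
#' @param weighting calibration regression weights: `"none"`, `"inv_x"`
#'   (1/concentration) or `"inv_x2"` (1/concentration squared, the default).
#' @return An object of class `is_assignment`: per metabolite the reference
#'   standard set, selection basis (`same_structure`, `regression_best` or
#'   `regression_fallback`), the per-(IS, run) adjusted R-squared table and
#'   the qualifying-run percentage.
#' @export
assign_internal_standards <- function(pt, panel, r2_threshold = 0.85,
                                      run_fraction = 0.75,
                                      weighting = c("inv_x2", "inv_x", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(pt, "peak_table"))
  mets <- sort(unique(pt$analyte_id[pt$analyte_role == "target"]))
  iss <- sort(unique(panel$analyte_id))
  cal <- pt[pt$condition == "calibration", , drop = FALSE]
  r2_rows <- list()
  assignments <- stats::setNames(vector("list", length(mets)), mets)
  failed <- character()
  for (m in mets) {
    sm <- panel$analyte_id[!is.na(panel$structure_match_target) &
                             panel$structure_match_target == m]
    if (length(sm)) {
      assignments[[m]] <- list(reference = sm[[1L]], basis = "same_structure",
                               pct = stats::setNames(numeric(0), character(0)))
      next
    }
    runs_m <- unique(pt$run_id[pt$analyte_id == m])
    pct <- stats::setNames(rep(NA_real_, length(iss)), iss)
    for (is_id in iss) {
      qualified <- 0L; eligible <- 0L
      for (r in runs_m) {
        cm <- cal[cal$run_id == r & cal$analyte_id == m, , drop = FALSE]
        ci <- cal[cal$run_id == r & cal$analyte_id == is_id, , drop = FALSE]
        if (nrow(ci) == 0L) next              # IS not detected in this run
        dd <- merge(cm[, c("sample_id", "area", "expected_conc")],
                    ci[, c("sample_id", "area")], by = "sample_id",
                    suffixes = c("_m", "_i"))
        dd <- dd[dd$area_m > 0 & dd$area_i > 0, , drop = FALSE]
        if (nrow(dd) < 3L) {
          message("run ", r, ": <3 calibration points for ", m, "/", is_id,
                  "; run excluded")
          next
        }
        eligible <- eligible + 1L
        ratio <- dd$area_m / dd$area_i
        w <- switch(weighting, none = rep(1, nrow(dd)),
                    inv_x = 1 / dd$expected_conc,
                    inv_x2 = 1 / dd$expected_conc^2)
        ar2 <- .wls_adj_r2(ratio, dd$expected_conc, w)
        r2_rows[[length(r2_rows) + 1L]] <-
          data.frame(metabolite = m, is_id = is_id, run_id = r, adj_r2 = ar2,
                     stringsAsFactors = FALSE)
        if (!is.na(ar2) && ar2 >= r2_threshold) qualified <- qualified + 1L
      }
      if (eligible > 0L) pct[[is_id]] <- qualified / eligible
    }
    if (all(is.na(pct))) { failed <- c(failed, m); next }
    best <- max(pct, na.rm = TRUE)
    top <- names(pct)[!is.na(pct) & pct == best]
    basis <- if (best >= run_fraction) "regression_best" else "regression_fallback"
    assignments[[m]] <- list(reference = sort(top), basis = basis, pct = pct)
  }
  if (length(failed)) {
    stop("no eligible calibration run for metabolite(s): ",
         paste(failed, collapse = ", "))
  }
  structure(list(assignments = assignments,
                 r2_table = do.call(rbind, r2_rows),
                 r2_threshold = r2_threshold, run_fraction = run_fraction,
                 weighting = weighting),
            class = "is_assignment")
}

#' @export
print.is_assignment <- function(x, ...) {
  basis <- vapply(x$assignments, `[[`, character(1), "basis")
  cat("is_assignment:", length(x$assignments), "metabolites\n")
  print(table(basis))
  invisible(x)
}

#' Normalize peak areas to internal-standard ratios
#'
#' Per biological sample, each metabolite value is the mean over its
#' reference internal standards of log2(metabolite area / IS area). Samples
#' in which some reference standards are undetected fall back to the reduced
#' reference set; when none are detected (or the metabolite area is zero or
#' missing) the cell is left missing, with a message.
#'
#' @param pt a [peak_table()].
#' @param assign an [assign_internal_standards()] result covering every
#'   metabolite in `pt`.
#' @return An object of class `normalized_matrix` (stage `"normalized"`):
#'   metabolite x sample matrix of log2 ratios plus the sample annotation
#'   table.
#' @export
normalize_peaks <- function(pt, assign) {
  stopifnot(inherits(pt, "peak_table"), inherits(assign, "is_assignment"))
  bio <- pt[pt$condition != "calibration", , drop = FALSE]
  mets <- sort(unique(bio$analyte_id[bio$analyte_role == "target"]))
  missing_assign <- setdiff(mets, names(assign$assignments))
  if (length(missing_assign)) {
    stop("assignment missing for metabolite(s): ",
         paste(missing_assign, collapse = ", "))
  }
  sample_ids <- unique(bio$sample_id)
  smp <- unique(bio[, c("sample_id", "run_id", "analysis_id", "condition",
                        "clone_id", "replicate")])
  smp <- smp[match(sample_ids, smp$sample_id), , drop = FALSE]
  rownames(smp) <- NULL
  analytes <- unique(bio$analyte_id)
  areas <- matrix(NA_real_, length(analytes), length(sample_ids),
                  dimnames = list(analytes, sample_ids))
  areas[cbind(match(bio$analyte_id, analytes),
              match(bio$sample_id, sample_ids))] <- bio$area
  areas[!is.na(areas) & areas <= 0] <- NA_real_   # zero area = undetected
  vals <- matrix(NA_real_, nrow = length(mets), ncol = length(sample_ids),
                 dimnames = list(mets, sample_ids))
  n_reduced <- 0L; n_missing <- 0L
  for (m in mets) {
    am <- areas[m, ]
    refs <- assign$assignments[[m]]$reference
    ais <- areas[refs, , drop = FALSE]
    log_ratios <- log2(sweep(1 / ais, 2, am, `*`))
    v <- colMeans(log_ratios, na.rm = TRUE)
    n_is_used <- colSums(!is.na(log_ratios))
    v[n_is_used == 0L | is.na(am)] <- NA_real_
    n_reduced <- n_reduced + sum(n_is_used > 0L & n_is_used < length(refs))
    n_missing <- n_missing + sum(is.na(v))
    vals[m, ] <- v
  }
  if (n_reduced > 0L) {
    message(n_reduced, " cell(s) normalized with a reduced IS set")
  }
  if (n_missing > 0L) {
    message(n_missing, " cell(s) left missing (undetected metabolite or IS)")
  }
  structure(list(values = vals, samples = smp, stage = "normalized"),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix (stage ", x$stage, "): ", nrow(x$values),
      " metabolites x ", ncol(x$values), " samples, ",
      sum(is.na(x$values)), " missing\n", sep = "")
  invisible(x)
}

#' Correct run-to-run (batch) effects
#'
#' For each metabolite, the values of every run are centered and scaled so
#' that each run's median and interquartile range match the metabolite's
#' overall (across-runs) median and IQR. The overall targets are the median
#' of the per-run medians and the median of the per-run IQRs, which makes
#' the correction exactly idempotent. Runs with zero IQR are centered only.
#'
#' @param nm a `normalized_matrix` at stage `"normalized"` (re-applying to a
#'   corrected matrix is a no-op by construction).
#' @return The matrix with stage `"batch_corrected"`.
#' @export
batch_correct <- function(nm) {
  stopifnot(inherits(nm, "normalized_matrix"))
  vals <- nm$values
  runs <- nm$samples$run_id[match(colnames(vals), nm$samples$sample_id)]
  for (m in rownames(vals)) {
    v <- vals[m, ]
    run_ids <- unique(runs[!is.na(v)])
    if (length(run_ids) <= 1L) next         # single run: identity transform
    med_r <- vapply(run_ids, function(r) stats::median(v[runs == r], na.rm = TRUE),
                    numeric(1))
    iqr_r <- vapply(run_ids, function(r) stats::IQR(v[runs == r], na.rm = TRUE),
                    numeric(1))
    med_all <- stats::median(med_r)
    iqr_all <- stats::median(iqr_r[iqr_r > 0])
    if (!is.finite(iqr_all)) iqr_all <- 0
    for (i in seq_along(run_ids)) {
      r <- run_ids[[i]]
      sel <- runs == r & !is.na(v)
      if (iqr_r[[i]] > 0 && iqr_all > 0) {
        vals[m, sel] <- (v[sel] - med_r[[i]]) / iqr_r[[i]] * iqr_all + med_all
      } else {
        vals[m, sel] <- v[sel] - med_r[[i]] + med_all
      }
    }
  }
  structure(list(values = vals, samples = nm$samples,
                 stage = "batch_corrected"),
            class = "normalized_matrix")
}
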