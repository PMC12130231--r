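# Differential metabolite abundance: induction contrast with optional clone
# modeling, Benjamini-Hochberg control per analysis.

#' Describe an induction experiment design
#'
#' @param analysis analysis id (one SLC cell line).
#' @param model `"one_way"` (wild-type overexpression: induction only) or
#'   `"two_way_clone"` (knockout-overexpression: induction plus a clone main
#'   effect).
#' @param samples data frame with columns `sample_id`, `condition`
#'   (`induced`/`uninduced`), `clone` (`NA` for one-way) and `replicate`.
#' @param target_replicates replicate count the design aims for per condition
#'   (and clone); deviations only raise a warning.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(analysis, model = c("one_way", "two_way_clone"),
                              samples, target_replicates = 4L) {
  model <- match.arg(model)
  need <- c("sample_id", "condition", "clone", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("design missing column(s): ", paste(miss, collapse = ", "))
  if (!all(samples$condition %in% c("induced", "uninduced"))) {
    stop("design conditions must be induced/uninduced")
  }
  if (model == "one_way") {
    if (any(!is.na(samples$clone))) stop("one_way design must not carry clone labels")
    cells <- table(samples$condition)
  } else {
    if (any(is.na(samples$clone))) stop("two_way_clone design needs clone labels")
    if (length(unique(samples$clone)) < 2L) stop("two_way_clone needs >=2 clones")
    cells <- table(samples$condition, samples$clone)
    if (any(cells == 0L)) stop("every clone needs both conditions")
  }
  if (any(cells != target_replicates)) {
    warning("design is not balanced at ", target_replicates,
            " replicates per condition", if (model == "two_way_clone") " per clone")
  }
  structure(list(analysis = analysis, model = model, samples = samples,
                 target_replicates = target_replicates),
            class = "experiment_design")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at 1).
#'
#' @param pvalues numeric vector of p values in \[0, 1\] (`NA` allowed and
#'   passed through).
#' @return Adjusted p values in input order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# induction F-test for one metabolite; returns c(lfc, p)
.induction_test <- function(y, cond, clone, model) {
  ind <- cond == "induced"
  if (!any(ind) || !any(!ind)) return(c(NA_real_, NA_real_))
  if (model == "two_way_clone") {
    cl <- unique(clone)
    per <- vapply(cl, function(k) {
      mean(y[ind & clone == k]) - mean(y[!ind & clone == k])
    }, numeric(1))
    lfc <- mean(per)
    fit <- stats::lm(y ~ factor(clone) + factor(cond))
  } else {
    lfc <- mean(y[ind]) - mean(y[!ind])
    fit <- stats::lm(y ~ factor(cond))
  }
  an <- stats::anova(fit)
  row <- grep("cond", rownames(an))
  ss_cond <- an[row, "Sum Sq"]
  p <- an[row, "Pr(>F)"]
  # degenerate variance: no induction signal means p = 1, pure signal means ~0
  if (is.nan(p) || is.na(p)) p <- if (ss_cond <= 1e-24) 1 else 0
  c(lfc, p)
}

#' Differential abundance between induced and uninduced samples
#'
#' Per metabolite, fits an ordinary linear model of the batch-corrected log2
#' values on induction (plus a clone main effect for two-way designs, no
#' interaction) and tests the induction term by F-test. The log2 fold change
#' is the difference of condition means (averaged over clones), not the model
#' coefficient; the two agree on balanced designs. P values are adjusted by
#' Benjamini-Hochberg across the metabolites of this analysis and calls made
#' at `fdr`.
#'
#' @param nm a batch-corrected `normalized_matrix`.
#' @param design an [experiment_design()]; its samples must appear in `nm`.
#' @param fdr false discovery rate for the significance call (default 0.05).
#' @return A data frame of class `diff_table` with columns `analysis`,
#'   `feature`, `lfc`, `p`, `padj`, `significant`. Metabolites missing
#'   entirely in one condition get `NA` statistics and are excluded from the
#'   BH family.
#' @export
test_differential <- function(nm, design, fdr = 0.05) {
  stopifnot(inherits(nm, "normalized_matrix"), inherits(design, "experiment_design"))
  if (nm$stage != "batch_corrected") {
    stop("test_differential needs a batch-corrected matrix")
  }
  smp <- design$samples
  missing_s <- setdiff(smp$sample_id, colnames(nm$values))
  if (length(missing_s)) stop("design sample(s) absent from matrix: ",
                              paste(missing_s, collapse = ", "))
  vals <- nm$values[, smp$sample_id, drop = FALSE]
  out <- data.frame(analysis = design$analysis, feature = rownames(vals),
                    lfc = NA_real_, p = NA_real_, padj = NA_real_,
                    significant = NA, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(vals))) {
    v <- vals[i, ]
    ok <- !is.na(v)
    cond <- smp$condition[ok]
    if (!all(c("induced", "uninduced") %in% cond)) {
      message("feature ", rownames(vals)[i],
              " missing in one condition; excluded from testing")
      next
    }
    res <- .induction_test(v[ok], cond, smp$clone[ok], design$model)
    out$lfc[i] <- res[[1L]]; out$p[i] <- res[[2L]]
  }
  tested <- !is.na(out$p)
  out$padj[tested] <- bh_adjust(out$p[tested])
  out$significant[tested] <- out$padj[tested] < fdr
  class(out) <- c("diff_table", "data.frame")
  out
}

#' @export
print.diff_table <- function(x, ...) {
  cat("diff_table:", length(unique(x$analysis)), "analysis(es),", nrow(x),
      "features,", sum(x$significant, na.rm = TRUE), "significant\n")
  print.data.frame(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Stack per-analysis differential tables into a cohort table
#'
#' @param ... `diff_table` objects (or one list of them).
#' @return A single `diff_table` with all rows.
#' @export
bind_diff_tables <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && !is.data.frame(args[[1L]])) {
    args <- args[[1L]]
  }
  out <- do.call(rbind, lapply(args, as.data.frame))
  class(out) <- c("diff_table", "data.frame")
  rownames(out) <- NULL
  out
}
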