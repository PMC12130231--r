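# Profile clustering: standardization, Ward clustering with
# silhouette-guided cluster count, property enrichment, uniqueness scores.

#' Build a standardized profile matrix from a cohort
#'
#' Restricts to features measured with a finite log2 fold change in every
#' analysis, then standard-normalizes each item's profile (mean 0, sample SD
#' 1). Items with constant profiles cannot be standardized and are dropped
#' with a warning.
#'
#' @param diff cohort `diff_table` with columns `analysis`, `feature`, `lfc`.
#' @return Item x feature numeric matrix of class `profile_matrix` with
#'   attribute `standardized = TRUE`.
#' @export
build_profile_matrix <- function(diff) {
  df <- as.data.frame(diff)
  if (nrow(df) == 0L) stop("empty cohort")
  items <- sort(unique(df$analysis))
  wide <- matrix(NA_real_, length(items), 0)
  tab <- df[is.finite(df$lfc), c("analysis", "feature", "lfc")]
  counts <- table(tab$feature)
  keep <- names(counts)[counts == length(items)]
  if (length(keep) == 0L) stop("no feature measured in all analyses")
  keep <- sort(keep)
  tab <- tab[tab$feature %in% keep, , drop = FALSE]
  wide <- matrix(NA_real_, length(items), length(keep),
                 dimnames = list(items, keep))
  wide[cbind(match(tab$analysis, items), match(tab$feature, keep))] <- tab$lfc
  sds <- apply(wide, 1, stats::sd)
  if (any(sds == 0)) {
    warning("excluding ", sum(sds == 0),
            " item(s) with constant profiles (cannot standardize): ",
            paste(items[sds == 0], collapse = ", "))
    wide <- wide[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  std <- (wide - rowMeans(wide)) / sds
  structure(std, standardized = TRUE, class = c("profile_matrix", "matrix",
                                                "array"))
}

#' Cluster standardized profiles with silhouette-guided cut selection
#'
#' Ward minimum-variance agglomeration (the squared-Euclidean-distance
#' convention, `hclust` method `ward.D2`) on Euclidean distances between
#' profiles. The dendrogram is cut at every candidate cluster count in the
#' band implied by an average cluster size of `size_lo`-`size_hi` items, and
#' the count maximizing the mean silhouette width is chosen (ties toward the
#' smallest count).
#'
#' @param pm a [build_profile_matrix()] result (>= 3 items).
#' @param size_lo,size_hi target average cluster size band (default 5-10).
#' @return List of class `slc_clustering`: `labels` (named integer vector),
#'   `tree` (the `hclust` object), `k`, `mean_silhouette`, and
#'   `silhouette_by_k` (named vector over the candidate counts).
#' @export
cluster_profiles <- function(pm, size_lo = 5L, size_hi = 10L) {
  stopifnot(inherits(pm, "profile_matrix"))
  x <- unclass(pm)
  x <- x[order(rownames(x)), , drop = FALSE]     # item-order invariance
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 items to cluster")
  d <- stats::dist(x)
  hc <- stats::hclust(d, method = "ward.D2")
  lo <- ceiling(n / size_hi); hi <- floor(n / size_lo)
  if (lo > hi || lo < 2L || hi > n - 1L) {
    lo <- max(2L, min(lo, n - 1L)); hi <- min(n - 1L, max(hi, 2L))
    if (lo > hi) { lo <- 2L; hi <- n - 1L }
    message("candidate cluster-count range clamped to [", lo, ", ", hi, "]")
  }
  ks <- seq.int(lo, hi)
  sil <- vapply(ks, function(k) {
    mean(cluster::silhouette(stats::cutree(hc, k = k), d)[, "sil_width"])
  }, numeric(1))
  names(sil) <- ks
  k <- ks[[which.max(sil)]]                      # which.max takes the first tie
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, tree = hc, k = k,
                 mean_silhouette = unname(sil[[as.character(k)]]),
                 silhouette_by_k = sil),
            class = "slc_clustering")
}

#' @export
print.slc_clustering <- function(x, ...) {
  cat("slc_clustering:", length(x$labels), "items in", x$k,
      "clusters (mean silhouette ", round(x$mean_silhouette, 3), ")\n")
  invisible(x)
}

#' Test clusters for enrichment of functional properties
#'
#' One-sided (greater) Fisher's exact test of each functional property in
#' each cluster, for properties carried by at least `min_annotations`
#' clustered items. P values are Benjamini-Hochberg-adjusted within each
#' property class separately, and enrichment called at `fdr` (default 20%).
#'
#' @param cl an `slc_clustering` (or named label vector).
#' @param ann long annotation data frame with columns `slc`, `class`,
#'   `property`.
#' @param min_annotations minimum cohort-wide carriers for a property to be
#'   tested.
#' @param fdr false discovery rate for the enrichment call.
#' @return Data frame of class `enrichment_result`: `cluster`, `class`,
#'   `property`, `in_cluster`, `cluster_size`, `in_cohort`, `cohort_size`,
#'   `odds_ratio`, `p`, `padj`, `enriched`.
#' @export
enrich_properties <- function(cl, ann, min_annotations = 3L, fdr = 0.20) {
  labels <- if (inherits(cl, "slc_clustering")) cl$labels else cl
  rows <- list()
  for (class_name in sort(unique(ann$class))) {
    sub <- ann[ann$class == class_name, , drop = FALSE]
    universe <- intersect(names(labels), unique(sub$slc))
    if (length(universe) == 0L) {
      warning("no clustered item annotated for class ", class_name,
              "; skipped")
      next
    }
    lab_u <- labels[universe]
    for (prop in sort(unique(sub$property))) {
      carriers <- intersect(sub$slc[sub$property == prop], universe)
      if (length(carriers) < min_annotations) next
      for (k in sort(unique(lab_u))) {
        members <- universe[lab_u == k]
        a <- length(intersect(members, carriers))
        tab <- matrix(c(a, length(members) - a,
                        length(carriers) - a,
                        length(universe) - length(members) -
                          length(carriers) + a), 2L, 2L)
        ft <- stats::fisher.test(tab, alternative = "greater")
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = k, class = class_name, property = prop,
          in_cluster = a, cluster_size = length(members),
          in_cohort = length(carriers), cohort_size = length(universe),
          odds_ratio = unname(ft$estimate), p = ft$p.value,
          padj = NA_real_, enriched = NA, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), class = character(), property = character(),
               in_cluster = integer(), cluster_size = integer(),
               in_cohort = integer(), cohort_size = integer(),
               odds_ratio = numeric(), p = numeric(), padj = numeric(),
               enriched = logical(), stringsAsFactors = FALSE)
  for (class_name in unique(out$class)) {
    sel <- out$class == class_name
    out$padj[sel] <- bh_adjust(out$p[sel])
  }
  out$enriched <- out$padj < fdr
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Uniqueness of differential gene expression
#'
#' For every (gene, analysis) pair, computes the z-score of the shrunken
#' log2 fold change within the analysis (across genes) and across analyses
#' (across the gene's other measurements). Hits must be significant
#' (adjusted p < `padj_max`) and pass the minimum-signal rule: at least
#' `min_count` reads in both replicates of at least one condition. Output is
#' ordered by min(|z_within|, |z_across|), descending.
#'
#' @param diff cohort gene `diff_table` with columns `analysis`, `feature`,
#'   `lfc`, `padj` and replicate counts `count_uninduced_1`,
#'   `count_uninduced_2`, `count_induced_1`, `count_induced_2`.
#' @param padj_max significance cutoff for hits.
#' @param min_count read-count floor applied to both replicates of one
#'   condition.
#' @return Data frame of class `uniqueness_scores`: `analysis`, `feature`,
#'   `lfc`, `z_within`, `z_across`, `padj`, `min_signal`, `is_hit`.
#' @export
uniqueness_scores <- function(diff, padj_max = 0.05, min_count = 50L) {
  df <- as.data.frame(diff)
  need <- c("analysis", "feature", "lfc", "padj", "count_uninduced_1",
            "count_uninduced_2", "count_induced_1", "count_induced_2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("uniqueness input missing column(s): ",
                         paste(miss, collapse = ", "))
  # zero spread means zero deviation for every member, hence z = 0
  zscore <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  df$z_within <- stats::ave(df$lfc, df$analysis, FUN = zscore)
  n_meas <- stats::ave(df$lfc, df$feature, FUN = length)
  df$z_across <- stats::ave(df$lfc, df$feature, FUN = function(v) {
    if (length(v) < 3L) rep(NA_real_, length(v)) else zscore(v)
  })
  few <- unique(df$feature[n_meas < 3L])
  if (length(few)) {
    message(length(few), " gene(s) measured in <3 analyses; z_across missing")
  }
  df$min_signal <- (pmin(df$count_uninduced_1, df$count_uninduced_2) >= min_count) |
    (pmin(df$count_induced_1, df$count_induced_2) >= min_count)
  df$is_hit <- !is.na(df$padj) & df$padj < padj_max & df$min_signal &
    !is.na(df$z_across) & !is.na(df$z_within)
  rank_stat <- pmin(abs(df$z_within), abs(df$z_across))
  out <- df[order(-rank_stat, df$feature, df$analysis),
            c("analysis", "feature", "lfc", "z_within", "z_across", "padj",
              "min_signal", "is_hit")]
  rownames(out) <- NULL
  class(out) <- c("uniqueness_scores", "data.frame")
  out
}
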