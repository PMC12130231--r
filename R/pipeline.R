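# End-to-end orchestration: configuration validation, staged execution,
# manifest with seeds and config hash.

.CONFIG_KEYS <- c("peaks", "panel", "ontology", "ontology_dialect", "pathways",
                  "annotations", "gene_diff", "out", "seed", "padj", "is_r2",
                  "run_fraction", "enrichment_fdr", "min_annotations",
                  "min_counts", "size_lo", "size_hi", "permutations", "stages")

.ALL_STAGES <- c("normalize", "diffabund", "pairs", "pathway_perm", "cluster",
                 "enrich", "coherence", "uniqueness", "pathway_lfc")

#' Validate a pipeline configuration
#'
#' @param config named list (or path to a YAML file) with input paths,
#'   thresholds and stage toggles. Unknown keys are rejected; thresholds are
#'   range-checked. Defaults: `padj` 0.05, `is_r2` 0.85, `run_fraction`
#'   0.75, `enrichment_fdr` 0.20, `min_annotations` 3, `min_counts` 50,
#'   cluster size band 5-10, `permutations` 1000, `seed` 1, all stages on.
#' @return The completed configuration list, classed `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  defaults <- list(ontology_dialect = "tsv_edges", seed = 1L, padj = 0.05,
                   is_r2 = 0.85, run_fraction = 0.75, enrichment_fdr = 0.20,
                   min_annotations = 3L, min_counts = 50L, size_lo = 5L,
                   size_hi = 10L, permutations = 1000L, stages = .ALL_STAGES)
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  in01 <- function(key) {
    v <- config[[key]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1) {
      stop("config key ", key, " must be a probability in (0, 1]")
    }
  }
  for (k in c("padj", "is_r2", "run_fraction", "enrichment_fdr")) in01(k)
  if (config$permutations < 1L) stop("permutations must be >= 1")
  if (config$size_lo < 1L || config$size_hi < config$size_lo) {
    stop("invalid cluster size band")
  }
  bad <- setdiff(config$stages, .ALL_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(config, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order: normalize -> diffabund
#' -> \{pairs, pathway_perm, cluster -> \{enrich, coherence\}, uniqueness,
#' pathway_lfc\}, writing per-stage CSV outputs and a manifest JSON
#' (config hash, package version, seeds) into the output directory. A stage
#' failure leaves partial outputs plus a `FAILED` marker file and raises an
#' error.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @return Invisibly, a named list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  out_dir <- cfg$out %||% stop("config key 'out' (output directory) required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  on_fail <- function(stage, e) {
    writeLines(paste0("stage ", stage, ": ", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  run_stage <- function(stage, expr) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    tryCatch(expr, error = function(e) on_fail(stage, e))
  }
  g <- if (!is.null(cfg[["ontology"]])) {
    load_ontology(cfg[["ontology"]], cfg$ontology_dialect)
  }
  net <- if (!is.null(cfg[["pathways"]])) read_pathway_network(cfg[["pathways"]])
  ann <- if (!is.null(cfg[["annotations"]])) read_annotations(cfg[["annotations"]])

  run_stage("normalize", {
    pt <- read_peak_table(cfg$peaks)
    panel <- utils::read.csv(cfg$panel, stringsAsFactors = FALSE)
    assign <- assign_internal_standards(pt, panel, r2_threshold = cfg$is_r2,
                                        run_fraction = cfg$run_fraction)
    nm <- batch_correct(normalize_peaks(pt, assign))
    utils::write.csv(nm$values, file.path(out_dir, "normalized_matrix.csv"))
    results$normalize <- list(peaks = pt, assign = assign, nm = nm)
  })
  run_stage("diffabund", {
    nm <- results$normalize$nm
    smp <- nm$samples
    tabs <- lapply(sort(unique(smp$analysis_id)), function(an) {
      s <- smp[smp$analysis_id == an, , drop = FALSE]
      model <- if (length(unique(stats::na.omit(s$clone_id))) >= 2L) {
        "two_way_clone"
      } else "one_way"
      dsg <- experiment_design(an, model,
                               data.frame(sample_id = s$sample_id,
                                          condition = s$condition,
                                          clone = s$clone_id,
                                          replicate = s$replicate,
                                          stringsAsFactors = FALSE))
      sub <- nm
      sub$values <- nm$values[, s$sample_id, drop = FALSE]
      test_differential(sub, dsg, fdr = cfg$padj)
    })
    diff <- bind_diff_tables(tabs)
    utils::write.csv(diff, file.path(out_dir, "diff_metabolites.csv"),
                     row.names = FALSE)
    results$diffabund <- diff
  })
  run_stage("pairs", {
    pr <- categorize_pairs(results$diffabund, ann, g, net, fdr = cfg$padj)
    utils::write.csv(pr, file.path(out_dir, "pairs.csv"), row.names = FALSE)
    results$pairs <- pr
  })
  run_stage("pathway_perm", {
    mets <- intersect(unique(results$diffabund$feature), g$terms)
    fmap <- feature_pathway_map(net, mets, "metabolite", g = g)
    pv <- permutation_pvalues(results$diffabund, fmap, B = cfg$permutations,
                              seed = cfg$seed)
    utils::write.csv(pv, file.path(out_dir, "pathway_permutation.csv"),
                     row.names = FALSE)
    results$pathway_perm <- pv
  })
  gene_diff <- if (!is.null(cfg[["gene_diff"]])) {
    gd <- utils::read.csv(cfg[["gene_diff"]], stringsAsFactors = FALSE)
    class(gd) <- c("diff_table", "data.frame")
    gd
  }
  run_stage("cluster", {
    src <- gene_diff %||% results$diffabund
    cl <- cluster_profiles(build_profile_matrix(src),
                           size_lo = cfg$size_lo, size_hi = cfg$size_hi)
    utils::write.csv(data.frame(item = names(cl$labels), label = cl$labels),
                     file.path(out_dir, "cluster_labels.csv"),
                     row.names = FALSE)
    results$cluster <- cl
  })
  run_stage("enrich", {
    long <- annotation_long(ann)
    enr <- enrich_properties(results$cluster, long,
                             min_annotations = cfg$min_annotations,
                             fdr = cfg$enrichment_fdr)
    utils::write.csv(enr, file.path(out_dir, "enrichment.csv"),
                     row.names = FALSE)
    results$enrich <- enr
  })
  run_stage("coherence", {
    long <- annotation_long(ann)
    groupings <- list(clusters = results$cluster$labels)
    for (cls in unique(long$class)) {
      sub <- long[long$class == cls, , drop = FALSE]
      sub <- sub[!duplicated(sub$slc), , drop = FALSE]
      groupings[[cls]] <- stats::setNames(sub$property, sub$slc)
    }
    nvi <- pairwise_nvi_matrix(groupings)
    utils::write.csv(nvi, file.path(out_dir, "nvi_matrix.csv"))
    results$coherence <- nvi
  })
  run_stage("uniqueness", {
    if (!is.null(gene_diff) && "count_uninduced_1" %in% names(gene_diff)) {
      un <- uniqueness_scores(gene_diff, padj_max = cfg$padj,
                              min_count = cfg$min_counts)
      utils::write.csv(un, file.path(out_dir, "uniqueness.csv"),
                       row.names = FALSE)
      results$uniqueness <- un
    }
  })
  run_stage("pathway_lfc", {
    if (!is.null(gene_diff)) {
      src <- gene_diff
      feats <- unique(src$feature)
      kind <- "gene"
    } else {
      src <- results$diffabund
      feats <- intersect(unique(src$feature), g$terms)
      kind <- "metabolite"
    }
    if (kind == "metabolite") {
      fmap <- feature_pathway_map(net, feats, "metabolite", g = g)
      top <- top_level_pathways(net, fmap, k = 9L)
      mlfc <- vapply(top, function(p) {
        suppressWarnings(mean_pathway_lfc(src, fmap, p))
      }, numeric(1))
      utils::write.csv(data.frame(pathway = top, mean_lfc = mlfc),
                       file.path(out_dir, "pathway_lfc.csv"),
                       row.names = FALSE)
      results$pathway_lfc <- mlfc
    }
  })
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_file)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_file)),
                   package_version = as.character(utils::packageVersion("slcfunmap")),
                   seed = cfg$seed,
                   stages = intersect(.ALL_STAGES, cfg$stages))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(results)
}
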