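test_that("profile matrix restricts to shared features and standardizes", {
  diff <- data.frame(
    analysis = rep(c("a1", "a2"), each = 3),
    feature = c("f1", "f2", "f3", "f1", "f2", "f4"),
    lfc = c(1, 2, 3, 4, 5, 6), stringsAsFactors = FALSE)
  pm <- build_profile_matrix(diff)
  # f3 and f4 are not shared and must be dropped from all analyses
  expect_setequal(colnames(pm), c("f1", "f2"))
  expect_true(attr(pm, "standardized"))
  expect_equal(unname(rowMeans(pm)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(pm, 1, sd)), c(1, 1), tolerance = 1e-12)

  # the (1, 2, 3) row standardizes to (-1, 0, 1) with the sample SD
  diff3 <- data.frame(analysis = "a1", feature = c("f1", "f2", "f3"),
                      lfc = c(1, 2, 3), stringsAsFactors = FALSE)
  pm3 <- build_profile_matrix(diff3)
  expect_equal(unname(pm3["a1", c("f1", "f2", "f3")]), c(-1, 0, 1))

  # standardization is idempotent
  again <- build_profile_matrix(data.frame(
    analysis = rep(rownames(pm3), each = ncol(pm3)),
    feature = rep(colnames(pm3), times = nrow(pm3)),
    lfc = as.vector(t(pm3)), stringsAsFactors = FALSE))
  expect_equal(unclass(again), unclass(pm3), tolerance = 1e-9)

  # constant rows are excluded with a warning
  diffc <- rbind(diff3, data.frame(analysis = "a2",
                                   feature = c("f1", "f2", "f3"),
                                   lfc = c(7, 7, 7)))
  expect_warning(pmc <- build_profile_matrix(diffc), "constant")
  expect_equal(rownames(pmc), "a1")
})

test_that("silhouette-guided clustering recovers planted groups", {
  co <- gen_lfc_cohort(40, n_items = 40, n_features = 60, k_true = 6,
                       separation = 10, noise_sd = 0.3)
  pm <- build_profile_matrix(co$diff)
  cl <- cluster_profiles(pm, size_lo = 5, size_hi = 10)
  expect_equal(cl$k, 6L)
  expect_gt(adjusted_rand_index(cl$labels, co$truth$true_labels), 0.9)
  # chosen cut maximizes mean silhouette among the candidates, recomputed
  # from the definition via cluster::silhouette on the stored tree
  d <- dist(unclass(pm)[order(rownames(pm)), ])
  for (k in as.integer(names(cl$silhouette_by_k))) {
    sw <- mean(cluster::silhouette(cutree(cl$tree, k = k), d)[, "sil_width"])
    expect_lte(sw, cl$mean_silhouette + 1e-12)
  }
  # cutting the stored tree at k reproduces the labels
  expect_equal(cutree(cl$tree, k = cl$k), cl$labels)
})

test_that("clustering is invariant to item order and keeps twins together", {
  co <- gen_lfc_cohort(8, n_items = 20, n_features = 30, k_true = 4,
                       separation = 8, noise_sd = 0.3)
  pm <- build_profile_matrix(co$diff)
  cl1 <- cluster_profiles(pm)
  pm2 <- pm[rev(seq_len(nrow(pm))), ]
  class(pm2) <- class(pm); attr(pm2, "standardized") <- TRUE
  cl2 <- cluster_profiles(pm2)
  expect_equal(cl1$labels, cl2$labels[names(cl1$labels)])
  # duplicated item always shares its twin's cluster
  x <- unclass(pm)
  x <- rbind(x, twin = x[1, ])
  rownames(x)[nrow(x)] <- "twin"
  pm3 <- structure(x, standardized = TRUE,
                   class = c("profile_matrix", "matrix", "array"))
  cl3 <- cluster_profiles(pm3)
  expect_equal(unname(cl3$labels["twin"]),
               unname(cl3$labels[rownames(pm)[1]]))
})

test_that("Fisher enrichment matches the exact hypergeometric tail", {
  # cohort of 50 with 6 carriers; cluster of 5 holding 4 of them:
  # one-sided p = 666 / 2,118,760
  labels <- setNames(c(rep(1, 5), rep(2, 45)), sprintf("s%02d", 1:50))
  carriers <- c(sprintf("s%02d", 1:4), "s06", "s07")
  ann <- rbind(
    data.frame(slc = carriers, class = "family", property = "F1",
               stringsAsFactors = FALSE),
    data.frame(slc = setdiff(names(labels), carriers), class = "family",
               property = "F2", stringsAsFactors = FALSE))
  enr <- enrich_properties(labels, ann, min_annotations = 3)
  row <- enr[enr$cluster == 1 & enr$property == "F1", ]
  expect_equal(row$p, 666 / 2118760, tolerance = 1e-12)
  expect_equal(row$p, sum(dhyper(4:5, 6, 44, 5)), tolerance = 1e-12)
  expect_equal(row$in_cluster, 4L)
  # a property carried by everyone cannot be enriched
  ann_all <- data.frame(slc = names(labels), class = "fold", property = "X",
                        stringsAsFactors = FALSE)
  enr2 <- enrich_properties(labels, ann_all)
  expect_true(all(enr2$p[enr2$class == "fold"] == 1))
  # properties under the annotation floor are not tested
  ann_few <- rbind(ann, data.frame(slc = c("s01", "s02"), class = "family",
                                   property = "RARE"))
  enr3 <- enrich_properties(labels, ann_few, min_annotations = 3)
  expect_false("RARE" %in% enr3$property)
})

test_that("perfect property fidelity flags every true cluster at FDR 20%", {
  co <- gen_lfc_cohort(12, n_items = 30, n_features = 40, k_true = 5,
                       separation = 12, noise_sd = 0.2,
                       property_fidelity = 1)
  cl <- cluster_profiles(build_profile_matrix(co$diff), size_lo = 5,
                         size_hi = 10)
  enr <- enrich_properties(cl, co$annotations)
  expect_gt(adjusted_rand_index(cl$labels, co$truth$true_labels), 0.99)
  # map each true cluster to its recovered label and check its family hit
  for (k in sort(unique(co$truth$true_labels))) {
    members <- names(co$truth$true_labels)[co$truth$true_labels == k]
    lab <- unique(cl$labels[members])
    expect_length(lab, 1L)
    hit <- enr[enr$cluster == lab & enr$class == "family" &
                 enr$property == paste0("family_", k), ]
    expect_equal(nrow(hit), 1L)
    expect_true(hit$enriched)
  }
})

test_that("uniqueness z-scores and filters follow their definitions", {
  # 100 analyses; gene gSpike has LFC 10 in a1 and 0 elsewhere:
  # mean 0.1, sample SD exactly 1, so z_across = 9.9
  analyses <- sprintf("a%d", 1:100)
  diff <- do.call(rbind, lapply(analyses, function(a) {
    data.frame(analysis = a, feature = c("gSpike", "gFlat", "gLow"),
               lfc = c(ifelse(a == "a1", 10, 0), 1, 0.5),
               padj = 0.01,
               count_uninduced_1 = 100, count_uninduced_2 = 100,
               count_induced_1 = 100, count_induced_2 = 100,
               stringsAsFactors = FALSE)
  }))
  diff$count_induced_1[diff$feature == "gLow"] <- 60
  diff$count_induced_2[diff$feature == "gLow"] <- 40
  diff$count_uninduced_1[diff$feature == "gLow"] <- 45
  diff$count_uninduced_2[diff$feature == "gLow"] <- 45
  un <- uniqueness_scores(diff)
  spike <- un[un$feature == "gSpike" & un$analysis == "a1", ]
  expect_equal(spike$z_across, 9.9, tolerance = 1e-12)
  expect_true(spike$is_hit)
  expect_equal(un$feature[1], "gSpike")   # top-ranked hit
  expect_equal(un$analysis[1], "a1")
  # identical LFC across analyses gives z_across = 0
  expect_true(all(un$z_across[un$feature == "gFlat"] == 0))
  # counts (60, 40) and (45, 45): no condition has both replicates >= 50
  expect_true(all(!un$min_signal[un$feature == "gLow"]))
  expect_true(all(!un$is_hit[un$feature == "gLow"]))
})

test_that("genes seen in under three analyses lose their across z-score", {
  diff <- data.frame(analysis = c("a1", "a2", "a1", "a2", "a3"),
                     feature = c("gTwo", "gTwo", "gThree", "gThree", "gThree"),
                     lfc = c(1, 2, 1, 2, 3), padj = 0.01,
                     count_uninduced_1 = 100, count_uninduced_2 = 100,
                     count_induced_1 = 100, count_induced_2 = 100,
                     stringsAsFactors = FALSE)
  expect_message(un <- uniqueness_scores(diff), "<3 analyses")
  expect_true(all(is.na(un$z_across[un$feature == "gTwo"])))
  expect_true(all(!un$is_hit[un$feature == "gTwo"]))
  expect_false(anyNA(un$z_across[un$feature == "gThree"]))
})
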