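test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(-0.1), "\\[0, 1\\]")
})

test_that("experiment_design validates model structure", {
  smp <- data.frame(sample_id = sprintf("s%d", 1:8),
                    condition = rep(c("induced", "uninduced"), each = 4),
                    clone = NA_character_, replicate = rep(1:4, 2),
                    stringsAsFactors = FALSE)
  expect_s3_class(experiment_design("A", "one_way", smp), "experiment_design")
  expect_warning(experiment_design("A", "one_way", smp[1:7, ]),
                 "not balanced")
  expect_error(experiment_design("A", "two_way_clone", smp), "clone labels")
  smp2 <- transform(smp, clone = "c1")
  expect_error(experiment_design("A", "two_way_clone", smp2), ">=2 clones")
})

mk_one_way <- function(values_uninduced, values_induced, analysis = "A") {
  n1 <- length(values_uninduced); n2 <- length(values_induced)
  samples <- data.frame(
    sample_id = sprintf("s%d", seq_len(n1 + n2)),
    run_id = "r1", analysis_id = analysis,
    condition = rep(c("uninduced", "induced"), c(n1, n2)),
    clone_id = NA_character_, replicate = c(seq_len(n1), seq_len(n2)),
    stringsAsFactors = FALSE)
  vals <- matrix(c(values_uninduced, values_induced), 1,
                 dimnames = list("M1", samples$sample_id))
  dsg <- experiment_design(analysis, "one_way",
                           data.frame(sample_id = samples$sample_id,
                                      condition = samples$condition,
                                      clone = NA_character_,
                                      replicate = samples$replicate,
                                      stringsAsFactors = FALSE))
  list(nm = make_nm(vals, samples), design = dsg)
}

test_that("identical conditions give a null result", {
  x <- mk_one_way(c(1, 2, 3, 4), c(1, 2, 3, 4))
  dt <- test_differential(x$nm, x$design)
  expect_equal(dt$lfc, 0)
  expect_equal(dt$p, 1)
})

test_that("one-way ANOVA equals the two-sample t-test (F = t^2)", {
  set.seed(42)
  for (i in 1:5) {
    u <- rnorm(4); v <- rnorm(4, mean = 1)
    x <- mk_one_way(u, v)
    dt <- test_differential(x$nm, x$design)
    tt <- t.test(v, u, var.equal = TRUE)
    expect_equal(dt$p, tt$p.value, tolerance = 1e-12)
    expect_equal(dt$lfc, mean(v) - mean(u), tolerance = 1e-12)
  }
  # near-noise-free strong effect
  set.seed(1)
  x <- mk_one_way(1 + rnorm(4, 0, 1e-6), 3 + rnorm(4, 0, 1e-6))
  dt <- suppressWarnings(test_differential(x$nm, x$design))
  expect_equal(dt$lfc, 2, tolerance = 1e-4)
  expect_lt(dt$p, 1e-10)
})

test_that("two-way clone model absorbs clone offsets", {
  samples <- data.frame(
    sample_id = sprintf("s%d", 1:16), run_id = "r1", analysis_id = "A",
    condition = rep(rep(c("uninduced", "induced"), each = 4), 2),
    clone_id = rep(c("c1", "c2"), each = 8), replicate = rep(1:4, 4),
    stringsAsFactors = FALSE)
  set.seed(7)
  eps <- rnorm(16, 0, 0.05)
  mu <- ifelse(samples$clone_id == "c1", 5, -5) +
    ifelse(samples$condition == "induced", 1, 0)
  vals <- matrix(mu + eps, 1, dimnames = list("M1", samples$sample_id))
  dsg2 <- experiment_design("A", "two_way_clone",
                            data.frame(sample_id = samples$sample_id,
                                       condition = samples$condition,
                                       clone = samples$clone_id,
                                       replicate = samples$replicate,
                                       stringsAsFactors = FALSE))
  dt2 <- test_differential(make_nm(vals, samples), dsg2)
  expect_equal(dt2$lfc, 1, tolerance = 0.1)
  expect_lt(dt2$p, 1e-6)
  # explicit normal-equations oracle for the additive model
  X <- cbind(1, samples$clone_id == "c2", samples$condition == "induced")
  beta <- solve(t(X) %*% X, t(X) %*% (mu + eps))
  expect_equal(dt2$lfc, beta[3], tolerance = 1e-10)
  # a one-way misfit on the same data has far larger residual variance
  dsg1 <- suppressWarnings(experiment_design("A", "one_way",
                            data.frame(sample_id = samples$sample_id,
                                       condition = samples$condition,
                                       clone = NA_character_,
                                       replicate = samples$replicate,
                                       stringsAsFactors = FALSE)))
  dt1 <- test_differential(make_nm(vals, samples), dsg1)
  expect_gt(dt1$p, dt2$p)
})

test_that("features absent from one condition are excluded from BH", {
  samples <- data.frame(
    sample_id = sprintf("s%d", 1:8), run_id = "r1", analysis_id = "A",
    condition = rep(c("uninduced", "induced"), each = 4),
    clone_id = NA_character_, replicate = rep(1:4, 2),
    stringsAsFactors = FALSE)
  set.seed(3)
  vals <- matrix(rnorm(16), 2, dimnames = list(c("M1", "M2"),
                                               samples$sample_id))
  vals["M2", samples$condition == "induced"] <- NA
  dsg <- experiment_design("A", "one_way",
                           data.frame(sample_id = samples$sample_id,
                                      condition = samples$condition,
                                      clone = NA_character_,
                                      replicate = samples$replicate,
                                      stringsAsFactors = FALSE))
  expect_message(dt <- test_differential(make_nm(vals, samples), dsg),
                 "missing in one condition")
  expect_true(is.na(dt$p[dt$feature == "M2"]))
  expect_true(is.na(dt$significant[dt$feature == "M2"]))
  # BH family has a single member: padj equals p
  expect_equal(dt$padj[dt$feature == "M1"], dt$p[dt$feature == "M1"])
})

test_that("planted effects are recovered within three standard errors", {
  effects <- c(0.5, 1, 1.5, 2)
  planted <- data.frame(analysis = "A", metabolite = sprintf("M%02d", 1:4),
                        effect = effects, stringsAsFactors = FALSE)
  ex <- gen_metabolomics_experiment(13, analyses = "A",
                                    metabolites = sprintf("M%02d", 1:8),
                                    planted = planted, noise_sd = 0.1)
  asg <- assign_internal_standards(ex$peaks, ex$panel)
  nm <- batch_correct(normalize_peaks(ex$peaks, asg))
  dt <- test_differential(nm, ex$designs$A)
  est <- dt$lfc[match(planted$metabolite, dt$feature)]
  # per-observation log2 noise ~ sqrt(noise_sd^2 + (noise_sd/2)^2); LFC SE
  se <- sqrt(0.1^2 + 0.05^2) * sqrt(2 / 4)
  expect_true(all(abs(est - effects) < 3 * se))
  expect_true(all(dt$significant[match(planted$metabolite, dt$feature)]))
})
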