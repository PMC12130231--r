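test_that("peak_table validates schema and uniqueness", {
  df <- data.frame(run_id = "r1", sample_id = "s1", analysis_id = "A",
                   condition = "induced", clone_id = NA, replicate = 1,
                   analyte_id = "M1", analyte_role = "target", area = 100,
                   expected_conc = NA_real_, stringsAsFactors = FALSE)
  expect_s3_class(peak_table(df), "peak_table")
  expect_error(peak_table(transform(df, area = -1)), "non-negative")
  expect_error(peak_table(rbind(df, df)), "unique")
  expect_error(peak_table(transform(df, expected_conc = 5)),
               "calibration rows")
})

test_that("structure-matched standards are assigned directly", {
  ex <- gen_metabolomics_experiment(2, analyses = "A", noise_sd = 0.05,
                                    structure_matched = "M01")
  asg <- assign_internal_standards(ex$peaks, ex$panel)
  a <- asg$assignments[["M01"]]
  expect_equal(a$basis, "same_structure")
  expect_equal(a$reference, unname(ex$truth$true_is_map[["M01"]]))
  expect_length(a$reference, 1L)
})

test_that("calibration regression recovers the true standard", {
  ex <- gen_metabolomics_experiment(4, analyses = sprintf("A%d", 1:4),
                                    metabolites = sprintf("M%02d", 1:12),
                                    n_is = 4, n_runs = 2, noise_sd = 0.1)
  asg <- assign_internal_standards(ex$peaks, ex$panel)
  hits <- vapply(names(asg$assignments), function(m) {
    identical(asg$assignments[[m]]$reference,
              unname(ex$truth$true_is_map[[m]]))
  }, logical(1))
  expect_true(all(hits))
  expect_true(all(vapply(asg$assignments, `[[`, character(1), "basis") ==
                    "regression_best"))
  # adjusted R2 table is populated and bounded above by 1
  expect_true(all(asg$r2_table$adj_r2 <= 1 + 1e-12, na.rm = TRUE))
})

test_that("qualification ties select all standards, fallback picks the best", {
  # hand-built calibration: two standards proportional to the metabolite in
  # every run (both qualify at 100%), one pure-noise decoy
  concs <- c(1, 2, 4, 8, 16, 32)
  mk_cal <- function(run, noise) {
    f <- 2^noise
    rows <- list()
    for (k in seq_along(concs)) {
      sid <- paste(run, k, sep = "_")
      add <- function(analyte, role, area, ec = NA_real_) {
        rows[[length(rows) + 1L]] <<- data.frame(
          run_id = run, sample_id = sid, analysis_id = "cal",
          condition = "calibration", clone_id = NA_character_, replicate = k,
          analyte_id = analyte, analyte_role = role, area = area,
          expected_conc = ec, stringsAsFactors = FALSE)
      }
      add("M", "target", concs[k] * 3 * f[k], concs[k])
      add("IS_a", "internal_standard", 10)
      add("IS_b", "internal_standard", 20)
      add("IS_c", "internal_standard", 10 * 2^(5 * sin(7 * k)))
    }
    do.call(rbind, rows)
  }
  bio <- data.frame(run_id = "r1", sample_id = "b1", analysis_id = "A",
                    condition = "induced", clone_id = NA_character_,
                    replicate = 1, analyte_id = "M", analyte_role = "target",
                    area = 100, expected_conc = NA_real_,
                    stringsAsFactors = FALSE)
  pt <- peak_table(rbind(mk_cal("r1", rep(0, 6)), mk_cal("r2", rep(0, 6)), bio))
  panel <- data.frame(analyte_id = c("IS_a", "IS_b", "IS_c"),
                      structure_match_target = NA_character_,
                      stringsAsFactors = FALSE)
  asg <- assign_internal_standards(pt, panel)
  a <- asg$assignments[["M"]]
  expect_equal(a$basis, "regression_best")
  expect_equal(a$reference, c("IS_a", "IS_b"))   # tie at 100% selects both

  # degrade run r2 for every IS: best qualifies in only 50% < 75% of runs
  noisy <- 2 * sin(11 * seq_along(concs))
  pt2 <- peak_table(rbind(mk_cal("r1", rep(0, 6)), mk_cal("r2", noisy), bio))
  asg2 <- assign_internal_standards(pt2, panel)
  a2 <- asg2$assignments[["M"]]
  expect_equal(a2$basis, "regression_fallback")
  expect_equal(a2$reference, c("IS_a", "IS_b"))
  expect_equal(max(a2$pct, na.rm = TRUE), 0.5)
})

test_that("normalization computes log2 ratios and averages reference sets", {
  mk <- function(analyte, role, area) {
    data.frame(run_id = "r1", sample_id = "s1", analysis_id = "A",
               condition = "induced", clone_id = NA_character_, replicate = 1,
               analyte_id = analyte, analyte_role = role, area = area,
               expected_conc = NA_real_, stringsAsFactors = FALSE)
  }
  pt <- peak_table(rbind(mk("M1", "target", 100), mk("M2", "target", 400),
                         mk("M3", "target", 200),
                         mk("IS1", "internal_standard", 100),
                         mk("IS2", "internal_standard", 400)))
  asg <- structure(list(assignments = list(
    M1 = list(reference = "IS1", basis = "same_structure"),
    M2 = list(reference = "IS1", basis = "same_structure"),
    M3 = list(reference = c("IS1", "IS2"), basis = "regression_best"))),
    class = "is_assignment")
  nm <- normalize_peaks(pt, asg)
  expect_equal(nm$stage, "normalized")
  expect_equal(nm$values["M1", "s1"], 0)
  expect_equal(nm$values["M2", "s1"], 2)
  # mean(log2(200/100), log2(200/400)) = mean(1, -1) = 0
  expect_equal(nm$values["M3", "s1"], 0)
})

test_that("missing standards fall back to the reduced reference set", {
  mk <- function(sample, analyte, role, area) {
    data.frame(run_id = "r1", sample_id = sample, analysis_id = "A",
               condition = "induced", clone_id = NA_character_, replicate = 1,
               analyte_id = analyte, analyte_role = role, area = area,
               expected_conc = NA_real_, stringsAsFactors = FALSE)
  }
  pt <- peak_table(rbind(mk("s1", "M1", "target", 200),
                         mk("s1", "IS1", "internal_standard", 100),
                         mk("s2", "M1", "target", 200),
                         mk("s2", "IS1", "internal_standard", 0),
                         mk("s2", "IS2", "internal_standard", 50),
                         mk("s3", "M1", "target", 200),
                         mk("s3", "IS1", "internal_standard", 0)))
  asg <- structure(list(assignments = list(
    M1 = list(reference = c("IS1", "IS2"), basis = "regression_best"))),
    class = "is_assignment")
  msgs <- capture_messages(nm <- normalize_peaks(pt, asg))
  expect_match(paste(msgs, collapse = " "), "reduced IS set")
  expect_equal(nm$values["M1", "s2"], 2)   # falls back to IS2 alone
  expect_true(is.na(nm$values["M1", "s3"]))   # no reference detected
})

test_that("shared run effects cancel in the ratio normalization", {
  ex <- gen_metabolomics_experiment(9, analyses = c("A1", "A2"),
                                    noise_sd = 0, decoy_noise_sd = 0,
                                    n_runs = 2,
                                    batch_effects = c(run1 = 1, run2 = 10))
  pt <- ex$peaks
  # raw areas carry the 10x run multiplier
  m01 <- pt[pt$analyte_id == "M01" & pt$condition != "calibration", ]
  r1 <- m01$area[m01$run_id == "run1"]; r2 <- m01$area[m01$run_id == "run2"]
  expect_equal(mean(r2) / mean(r1), 10, tolerance = 1e-9)
  asg <- assign_internal_standards(pt, ex$panel)
  nm <- normalize_peaks(pt, asg)
  v <- nm$values["M01", ]
  runs <- nm$samples$run_id
  expect_equal(mean(v[runs == "run1"]), mean(v[runs == "run2"]),
               tolerance = 1e-9)
})

test_that("batch correction aligns run medians and is idempotent", {
  samples <- data.frame(sample_id = sprintf("s%d", 1:12),
                        run_id = rep(c("r1", "r2"), each = 6),
                        analysis_id = "A",
                        condition = rep(c("induced", "uninduced"), 6),
                        clone_id = NA_character_, replicate = rep(1:6, 2),
                        stringsAsFactors = FALSE)
  set.seed(1)
  base <- rnorm(6)
  vals <- matrix(c(base, base + 5), 1, 12,
                 dimnames = list("M1", samples$sample_id))
  nm <- make_nm(vals, samples, stage = "normalized")
  bc <- batch_correct(nm)
  expect_equal(bc$stage, "batch_corrected")
  v <- bc$values["M1", ]
  runs <- samples$run_id
  # constant shift removed: both run medians equal the across-run median
  expect_equal(median(v[runs == "r1"]), median(v[runs == "r2"]))
  expect_equal(median(v[runs == "r1"]),
               median(c(median(base), median(base + 5))))
  # idempotence
  bc2 <- batch_correct(make_nm(bc$values, samples, stage = "normalized"))
  expect_equal(bc2$values, bc$values, tolerance = 1e-9)

  # single-run matrix: identity
  one <- make_nm(vals[, 1:6, drop = FALSE], samples[1:6, ],
                 stage = "normalized")
  expect_equal(batch_correct(one)$values, one$values)

  # zero-IQR run is centered only
  vals2 <- matrix(c(rep(2, 6), base), 1, 12,
                  dimnames = list("M1", samples$sample_id))
  bc3 <- batch_correct(make_nm(vals2, samples, stage = "normalized"))
  v3 <- bc3$values["M1", ]
  expect_equal(diff(range(v3[runs == "r1"])), 0)
  expect_equal(unname(median(v3[runs == "r1"])),
               median(c(2, median(base))))
})
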