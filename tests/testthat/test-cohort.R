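test_that("a noiseless plate is called perfectly with cluster centers 0 and -1", {
  cfg <- sim_config(4, 4, noise_sd = 0, sample_offset_sd = 0, seed = 1)
  sim <- simulate_cohort(cfg)
  res <- genotype_cohort(sim$measurements)
  sc <- score_calls(res, sim$truth)
  expect_equal(sc$n_correct, 8)
  male_dd <- res$samples$ddcq[res$samples$sample_id %in% res$male_ids]
  female_dd <- res$samples$ddcq[res$samples$sample_id %in% res$female_ids]
  expect_equal(median(male_dd), 0)
  expect_equal(median(female_dd), -1)
})

test_that("a realistic 81-animal cohort is recovered from its seed", {
  cfg <- sim_config(40, 41, replicates = 4, noise_sd = 0.12,
                    sample_offset_sd = 0.5, seed = 1)
  sim <- simulate_cohort(cfg)
  res <- genotype_cohort(sim$measurements)
  sc <- score_calls(res, sim$truth)
  expect_equal(sc$n, 81)
  expect_equal(sc$n_correct, 81)
})

test_that("per-sample input-amount offsets cancel in delta-Cq", {
  cfg0 <- sim_config(3, 3, noise_sd = 0, sample_offset_sd = 0, seed = 9)
  cfg1 <- sim_config(3, 3, noise_sd = 0, sample_offset_sd = 2.0, seed = 9)
  r0 <- genotype_cohort(simulate_cohort(cfg0)$measurements)
  r1 <- genotype_cohort(simulate_cohort(cfg1)$measurements)
  expect_equal(r1$samples$delta_cq, r0$samples$delta_cq, tolerance = 1e-9)
  expect_equal(r1$samples$ddcq, r0$samples$ddcq, tolerance = 1e-9)
})

test_that("samples missing a target role are excluded and reported", {
  sim <- simulate_cohort(sim_config(3, 3, noise_sd = 0, sample_offset_sd = 0))
  meas <- sim$measurements
  meas <- meas[!(meas$sample_id == "M001" & meas$target_role == "sex"), ]
  res <- genotype_cohort(meas)
  expect_equal(res$excluded, "M001")
  expect_false("M001" %in% res$samples$sample_id)
  expect_equal(nrow(res$samples), 5)
})

test_that("low-replicate samples still get values but are flagged repeat", {
  sim <- simulate_cohort(sim_config(3, 3, noise_sd = 0, sample_offset_sd = 0))
  meas <- sim$measurements
  # leave one usable autosome replicate for M001: others undetermined
  idx <- which(meas$sample_id == "M001" & meas$target_role == "autosome")
  meas$cq[idx[-1]] <- NA
  res <- genotype_cohort(meas)
  row <- res$samples[res$samples$sample_id == "M001", ]
  expect_equal(row$n_kept_auto, 1)
  expect_true(row$low_replicate)
  expect_equal(row$call, "repeat")
  expect_false(is.na(row$ddcq))
})

test_that("an all-female batch is callable against a male standard", {
  cfg <- sim_config(0, 8, noise_sd = 0, sample_offset_sd = 0, seed = 2,
                    autosome = assay_model("autosome", 1.0, 24),
                    sex = assay_model("sex", 1.0, 25))
  sim <- simulate_cohort(cfg)
  # male standard delta-Cq for these models: cq_ref difference (both 2 copies)
  male_delta <- (24 - 1) - (25 - 1)
  res <- genotype_cohort(sim$measurements,
                         cohort_config(male_standard = male_delta))
  expect_equal(res$reference_used, "male_standard")
  expect_true(all(res$samples$call == "female"))
  expect_equal(unique(res$samples$ddcq), -1)
})

test_that("an outlier-ridden replicate group does not derail the call", {
  sim <- simulate_cohort(sim_config(4, 4, noise_sd = 0.05, sample_offset_sd = 0.3,
                                    seed = 3))
  meas <- sim$measurements
  idx <- which(meas$sample_id == "F002" & meas$target_role == "sex")
  meas$cq[idx[1:2]] <- meas$cq[idx[1:2]] + c(4, -4)   # two gross outliers
  res <- genotype_cohort(meas)
  row <- res$samples[res$samples$sample_id == "F002", ]
  expect_equal(row$n_kept_sex, 2)
  expect_equal(row$n_discarded, 2)
  expect_equal(row$call, "female")
})

test_that("unimodal batches raise a warning suggesting the male standard", {
  set.seed(21)
  meas <- plate_from_means(auto_means = 24 + rnorm(6, 0, 0.02),
                           sex_means = rep(25, 6))
  w <- capture_warnings(genotype_cohort(meas))
  expect_true(any(grepl("male standard", w)))
})
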