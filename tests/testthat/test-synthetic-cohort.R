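# The synthetic cohort generator: stated defaults, determinism, control
# behaviour, fraction-scaled methylation and planted proportional hazards.

test_that("default configuration states the study cohort", {
  cfg <- default_config()
  expect_equal(cfg$n_localized, 19L)
  expect_equal(cfg$n_mhspc, 28L)
  expect_equal(cfg$n_mcrpc, 49L)
  expect_equal(cfg$mean_depth, 96)
  expect_equal(cfg$n_target_regions, 366L)
  expect_equal(cfg$n_pos_control, 29L)
  expect_equal(cfg$n_neg_control, 42L)
  expect_equal(cfg$mcrpc_low_mass, 17 / 49)
  expect_error(cohort_config(n_dmr_regions = 500L), "n_dmr_regions")
  expect_error(cohort_config(n_localized = 0L, n_mhspc = 0L,
                             n_mcrpc = 0L), "degenerate")
  expect_error(cohort_config(nonsense = 1), "unknown config")
})

test_that("the same seed reproduces byte-identical files; a different
           seed does not", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  dir3 <- withr::local_tempdir()
  cfg <- cohort_config(n_target_regions = 5L, n_dmr_regions = 2L,
                       n_pos_control = 1L, n_neg_control = 1L,
                       mean_depth = 20, seed = 11L)
  generate_cohort(cfg, out_dir = dir1)
  generate_cohort(cfg, out_dir = dir2)
  cfg2 <- cohort_config(n_target_regions = 5L, n_dmr_regions = 2L,
                        n_pos_control = 1L, n_neg_control = 1L,
                        mean_depth = 20, seed = 12L)
  generate_cohort(cfg2, out_dir = dir3)
  files <- list.files(dir1, recursive = TRUE)
  h <- function(d) unname(tools::md5sum(file.path(d, files)))
  expect_identical(h(dir1), h(dir2))
  expect_false(identical(h(dir1), h(dir3)))
})

test_that("control regions methylate as selected: positives > 95%,
           negatives < 0.5% per CpG", {
  sim <- generate_cohort(test_cohort_config(seed = 3L))
  pool <- pool_haplotypes(sim$cohort)
  cls <- sim$regions$class[match(pool$region, sim$regions$name)]
  pos <- pool[cls == "positive_control", ]
  neg <- pool[cls == "negative_control", ]
  expect_gt(mean_methylation(pos$pattern, pos$count), 0.95)
  expect_lt(mean_methylation(neg$pattern, neg$count), 0.005)
})

test_that("mean MHL in planted regions is non-decreasing across disease
           states, and absent without tumor signal", {
  sim <- generate_cohort(test_cohort_config(seed = 4L))
  blocks <- regions_as_blocks(
    sim$regions[sim$regions$class == "target", , drop = FALSE])
  m <- build_mhl_matrix(sim$cohort, blocks)
  dmr_cols <- blocks$region_name %in%
    sim$truth_regions$name[sim$truth_regions$is_dmr]
  st <- sim$clinical$state
  mu <- vapply(c("localized", "mHSPC", "mCRPC"), function(s) {
    mean(m$values[st == s, dmr_cols], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mu) > 0))
  # null construction: tumor reads indistinguishable from background
  null <- generate_cohort(test_cohort_config(
    seed = 4L, tumor_meth_prob = 0.03))
  mn <- build_mhl_matrix(null$cohort, blocks)
  tr <- null$truth_regions[match(blocks$region_name,
                                 null$truth_regions$name), ]
  dn <- tr$is_dmr
  base <- !tr$is_dmr & !tr$is_high_background
  expect_lt(abs(mean(mn$values[, dn], na.rm = TRUE) -
                  mean(mn$values[, base], na.rm = TRUE)), 0.01)
  # no-tumor limit: fraction identically zero
  zero <- generate_cohort(test_cohort_config(
    seed = 5L, frac_localized_max = 0, frac_mhspc_max = 0,
    mcrpc_low_mass = 1, frac_mcrpc_low_max = 0))
  expect_true(all(zero$truth_patients$true_fraction == 0))
  mz <- build_mhl_matrix(zero$cohort, blocks)
  tz <- zero$truth_regions[match(blocks$region_name,
                                 zero$truth_regions$name), ]
  bz <- !tz$is_dmr & !tz$is_high_background
  expect_lt(abs(mean(mz$values[, tz$is_dmr], na.rm = TRUE) -
                  mean(mz$values[, bz], na.rm = TRUE)), 0.01)
})

test_that("realized methylation in planted regions tracks the assigned
           ctDNA fraction at high depth", {
  sim <- generate_cohort(cohort_config(
    n_localized = 2L, n_mhspc = 2L, n_mcrpc = 8L,
    n_target_regions = 12L, n_dmr_regions = 12L,
    n_pos_control = 0L, n_neg_control = 0L,
    mean_depth = 400, seed = 6L))
  pool <- pool_haplotypes(sim$cohort)
  cfg <- sim$config
  for (i in seq_len(nrow(sim$clinical))) {
    s <- sim$cohort[[i]]
    f <- sim$truth_patients$true_fraction[i]
    expected <- f * cfg$tumor_meth_prob + (1 - f) * cfg$background_meth_prob
    got <- mean_methylation(s$records$pattern, s$records$count)
    expect_lt(abs(got - expected), 0.02)
  }
})

test_that("survival times satisfy the planted proportional hazards", {
  # Cox on the true risk should estimate a coefficient near 1
  coefs <- vapply(1:5, function(sd) {
    sim <- generate_cohort(cohort_config(
      n_target_regions = 1L, n_dmr_regions = 1L, n_pos_control = 0L,
      n_neg_control = 0L, mean_depth = 5, seed = 100L + sd))
    cl <- sim$clinical
    tr <- sim$truth_patients
    unname(coef(survival::coxph(
      survival::Surv(cl$os_months, cl$os_event) ~ tr$true_risk)))
  }, numeric(1))
  expect_lt(abs(mean(coefs) - 1), 0.25)
})

test_that("about 17/49 mCRPC patients fall below 1% predicted fraction
           under defaults", {
  lows <- vapply(1:10, function(sd) {
    set.seed(sd)
    cfg <- default_config()
    # patient draw only (cheap): replicate the mixture expectation
    sim <- generate_cohort(cohort_config(
      n_target_regions = 1L, n_dmr_regions = 0L, n_pos_control = 0L,
      n_neg_control = 0L, mean_depth = 2, seed = sd))
    sum(sim$truth_patients$true_fraction[
      sim$truth_patients$state == "mCRPC"] <= 0.01)
  }, numeric(1))
  expect_lt(abs(mean(lows) - 17), 4)
})
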