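test_that("cohort generation is reproducible and honours group structure", {
  spec <- cohort_spec(n_per_group = 6, n_timepoints = 40, seed = 4)
  coh1 <- generate_cohort(spec)
  coh2 <- generate_cohort(spec)
  expect_identical(lapply(coh1, `[[`, "timeseries"),
                   lapply(coh2, `[[`, "timeseries"))
  expect_length(coh1, 12)
  expect_setequal(unique(vapply(coh1, `[[`, "", "label")),
                  c("control", "case"))
  expect_true(all(vapply(coh1, `[[`, 0, "mean_fd") >= 0))
  expect_true(all(vapply(coh1, function(s) !anyNA(s$timeseries), TRUE)))
})

test_that("planted correlation shift is recovered at the generating value", {
  pp <- data.frame(roi_i = 10L, roi_j = 3L, delta_r = 0.4)
  spec <- cohort_spec(n_per_group = 50, n_rois = 16, n_timepoints = 200,
                      planted_pairs = pp, base_correlation = 0.2,
                      n_blocks = 4, noise_sd = 0, motion_fraction = 0,
                      seed = 8)
  coh <- generate_cohort(spec)
  r_at <- vapply(coh, function(s) compute_fcm(s$timeseries)[10, 3], 0)
  lab <- vapply(coh, `[[`, "", "label")
  diff <- mean(r_at[lab == "case"]) - mean(r_at[lab == "control"])
  se <- sqrt(var(r_at[lab == "case"]) / 50 + var(r_at[lab == "control"]) / 50)
  expect_lt(abs(diff - 0.4), 3 * se + 0.02)
})

test_that("no planted effect means no group difference at any default pair", {
  pp <- default_planted_pairs()
  pp$delta_r <- 0
  spec <- cohort_spec(n_per_group = 30, n_timepoints = 100,
                      planted_pairs = pp, motion_fraction = 0, seed = 5)
  coh <- generate_cohort(spec)
  lab <- vapply(coh, `[[`, "", "label")
  fcms <- lapply(coh, function(s) compute_fcm(s$timeseries))
  for (k in c(1, 10, 40)) {  # spot-check hub and background pairs
    v <- vapply(fcms, function(m) m[pp$roi_i[k], pp$roi_j[k]], 0)
    diff <- mean(v[lab == "case"]) - mean(v[lab == "control"])
    se <- sqrt(var(v[lab == "case"]) / 30 + var(v[lab == "control"]) / 30)
    expect_lt(abs(diff), 3 * se)
  }
})

test_that("non-positive-definite planted structure fails loudly, no repair", {
  pp <- data.frame(roi_i = c(5L, 5L, 5L, 5L), roi_j = c(1L, 2L, 3L, 4L),
                   delta_r = rep(0.65, 4))
  spec <- cohort_spec(n_per_group = 2, n_rois = 8, n_blocks = 2,
                      planted_pairs = pp, base_correlation = 0.4, seed = 1)
  expect_error(generate_cohort(spec), "not positive definite")
})

test_that("spec invariants are enforced", {
  expect_error(cohort_spec(base_correlation = 1.2), "base_correlation")
  expect_error(cohort_spec(motion_fraction = 1.5), "motion_fraction")
  expect_error(cohort_spec(
    planted_pairs = data.frame(roi_i = 3L, roi_j = 3L, delta_r = 0.1)),
    "distinct")
  expect_error(cohort_spec(
    planted_pairs = data.frame(roi_i = 200L, roi_j = 1L, delta_r = 0.1)),
    "1..n_rois")
  expect_error(cohort_spec(
    planted_pairs = data.frame(roi_i = c(5L, 2L), roi_j = c(2L, 5L),
                               delta_r = c(0.1, 0.1))),
    "at most once")
})

test_that("empirical control correlations converge to the target matrix", {
  spec <- cohort_spec(n_per_group = 10, n_rois = 20, n_timepoints = 5000,
                      planted_pairs = data.frame(roi_i = integer(0),
                                                 roi_j = integer(0),
                                                 delta_r = numeric(0)),
                      n_blocks = 4, noise_sd = 0, motion_fraction = 0,
                      seed = 3)
  coh <- generate_cohort(spec)
  ctrl <- coh[vapply(coh, `[[`, "", "label") == "control"]
  emp <- Reduce(`+`, lapply(ctrl, function(s)
    compute_fcm(s$timeseries))) / length(ctrl)
  blk <- sort(rep_len(1:4, 20))
  target <- outer(blk, blk, "==") * 0.3
  diag(target) <- 1
  expect_lt(max(abs(emp - target)), 0.02)
})

test_that("motion-corrupted subjects have higher variance and higher FD", {
  spec <- cohort_spec(n_per_group = 10, n_timepoints = 60,
                      motion_fraction = 0.3, motion_noise_sd = 2, seed = 6)
  coh <- generate_cohort(spec)
  mot <- vapply(coh, `[[`, TRUE, "motion")
  v <- vapply(coh, function(s) mean(apply(s$timeseries, 2, var)), 0)
  fd <- vapply(coh, `[[`, 0, "mean_fd")
  expect_gt(min(v[mot]), max(v[!mot]))
  expect_gt(min(fd[mot]), 0.2)
  expect_lt(max(fd[!mot]), 0.2)
})

test_that("write_cohort / read_cohort round-trips", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_per_group = 2, n_rois = 6, n_timepoints = 15,
                      n_blocks = 2,
                      planted_pairs = data.frame(roi_i = 5L, roi_j = 2L,
                                                 delta_r = 0.2),
                      seed = 9)
  coh <- generate_cohort(spec)
  write_cohort(coh, dir)
  expect_length(list.files(dir, pattern = "_rois.txt$"), 4)
  pheno <- read.csv(file.path(dir, "phenotype.csv"))
  expect_equal(nrow(pheno), 4)
  expect_true(is.numeric(pheno$mean_fd) && all(pheno$mean_fd >= 0))
  back <- read_cohort(dir)
  for (i in seq_along(coh)) {
    expect_equal(back[[i]]$timeseries, coh[[i]]$timeseries,
                 tolerance = 1e-6)
    expect_identical(back[[i]]$label, coh[[i]]$label)
  }
})
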