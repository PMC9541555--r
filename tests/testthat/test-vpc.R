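test_that("VPC of self-simulated data shows no systematic deviation", {
  d <- simulate_cohort(default_cohort(seed = 67))
  fit <- truth_pd_fit(d, "act")
  v <- run_vpc(d, fit, channel = "act", n_sim = 500, seed = 68)
  expect_s3_class(v, "vpc")
  expect_length(v$bins, 9)
  # percentile ordering within every bin
  expect_true(all(v$observed[, "p10"] <= v$observed[, "p50"] &
                    v$observed[, "p50"] <= v$observed[, "p90"]))
  expect_true(all(v$pred_median[, "p10"] <= v$pred_median[, "p50"] &
                    v$pred_median[, "p50"] <= v$pred_median[, "p90"]))
  # the observed median lies inside the simulated median's 95% band in
  # at least 7 of the 9 bins
  inside <- v$observed[, "p50"] >= v$band_lower[, "p50"] &
    v$observed[, "p50"] <= v$band_upper[, "p50"]
  expect_gte(sum(inside), 7)
})

test_that("a grossly mis-specified delay is flagged by the VPC", {
  d <- simulate_cohort(default_cohort(seed = 71))
  wrong <- truth_pd_fit(d, "act", t_half = 14)  # ten-fold delay error
  v <- run_vpc(d, wrong, channel = "act", n_sim = 300, seed = 72)
  early <- v$bins %in% c(5, 15, 30)
  outside <- v$observed[early, "p50"] < v$band_lower[early, "p50"] |
    v$observed[early, "p50"] > v$band_upper[early, "p50"]
  expect_true(any(outside))
})

test_that("prediction correction is the identity for a flat PRED", {
  co <- default_cohort(design = study_design(n_subjects = 6,
                                             weight_range = c(4.2, 4.2)),
                       seed = 73)
  d <- simulate_cohort(co, channels = "conc")
  fit <- truth_pk_fit(d)
  v <- run_vpc(d, fit, channel = "conc", n_sim = 100, seed = 74)
  obs <- d[d$EVID == 0 & d$DVID == 1, ]
  expect_equal(v$points$value, obs$DV, tolerance = 1e-12)
})

test_that("VPC results are reproducible and render to file", {
  d <- simulate_cohort(default_cohort(seed = 79), channels = "conc")
  fit <- truth_pk_fit(d)
  v1 <- run_vpc(d, fit, channel = "conc", n_sim = 100, seed = 80)
  v2 <- run_vpc(d, fit, channel = "conc", n_sim = 100, seed = 80)
  expect_identical(v1$pred_median, v2$pred_median)
  expect_identical(v1$observed, v2$observed)
  path <- withr::local_tempfile(fileext = ".pdf")
  plot(v1, file = path)
  expect_true(file.exists(path) && file.size(path) > 0)
  tab <- vpc_table(v1)
  expect_identical(nrow(tab), length(v1$bins) * 3L)
  # guard rails
  expect_error(run_vpc(d, fit, channel = "act"), "absent")
  expect_error(run_vpc(d, fit, channel = "conc", n_sim = 50), "100")
})
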