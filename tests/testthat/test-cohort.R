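test_that("default design reproduces the study layout", {
  co <- default_cohort(seed = 3)
  expect_s3_class(co, "study_cohort")
  expect_identical(nrow(co$subjects), 10L)
  expect_true(all(co$subjects$weight >= 4 & co$subjects$weight <= 4.5))
  expect_identical(sum(co$design$times > 0), 8L)
  expect_identical(co$design$times[1], 0)
  expect_equal(co$subjects$dose, 15 * co$subjects$weight)
  # truths default to the effect-compartment reference values
  expect_equal(co$truths$pk$cl, 0.135)
  expect_equal(co$truths$pd$act$c50, 20.1)
  expect_equal(co$truths$pd$rtime$t_half_delay, 2.04)
})

test_that("individual parameters are positive log-normal deviates", {
  co <- default_cohort(seed = 5)
  pars <- draw_individual_parameters(co)
  for (pk in pars$pk) expect_true(all(unlist(pk) > 0))
  # zero CV: parameters collapse to the allometrically scaled truths
  co0 <- co
  co0$truths$bsv <- lapply(co0$truths$bsv, function(b) b * 0)
  p0 <- draw_individual_parameters(co0)
  for (i in seq_len(10)) {
    expect_equal(unlist(p0$pk[[i]]),
                 unlist(individualize(co$truths$pk,
                                      co$subjects$weight[i])))
    expect_equal(p0$pd$act[[i]]$c50, 20.1)
  }
})

test_that("sampled clearance reproduces the generating CV", {
  co <- default_cohort(seed = 7)
  co$subjects <- data.frame(id = 1, weight = 70, dose = 1050)
  draws <- vapply(1:10000, function(k) {
    draw_individual_parameters(co, seed = k)$pk[[1]]$cl
  }, 0)
  cv <- 100 * sd(draws) / mean(draws)
  expect_lt(abs(cv - 24.7) / 24.7, 0.10)
})

test_that("simulated datasets are reproducible and well formed", {
  co <- default_cohort(seed = 11)
  d1 <- simulate_cohort(co)
  d2 <- simulate_cohort(co)
  expect_identical(d1, d2)
  d3 <- simulate_cohort(co, seed = 12)
  expect_false(identical(d1, d3))
  # layout: 10 dose rows; 2 baseline PD + 8 x 3 channels per subject
  expect_identical(sum(d1$EVID == 1), 10L)
  expect_identical(sum(d1$EVID == 0), 260L)
  expect_identical(sum(d1$EVID == 0 & d1$TIME == 0), 20L)
  expect_true(all(d1$DV[d1$EVID == 0] > 0))
})

test_that("noise-free simulation equals the structural predictions", {
  co <- default_cohort(seed = 13)
  co$truths$bsv <- lapply(co$truths$bsv, function(b) b * 0)
  co$truths$ruv <- lapply(co$truths$ruv, function(r) c(add = 0, prop = 0))
  d <- simulate_cohort(co)
  for (i in 1:3) {
    w <- co$subjects$weight[i]
    pk <- individualize(co$truths$pk, w)
    sel <- d$ID == i & d$EVID == 0 & d$DVID == 1
    expect_equal(d$DV[sel],
                 predict_cp(pk, co$subjects$dose[i], d$TIME[sel]))
    sel <- d$ID == i & d$EVID == 0 & d$DVID == 2
    expect_equal(d$DV[sel],
                 predict_effect(pk, co$truths$pd$act,
                                co$subjects$dose[i], d$TIME[sel])$effect)
  }
})

test_that("simulated baselines sit at the reference intercepts", {
  co <- default_cohort(seed = 17)
  d <- simulate_cohort(co)
  act0 <- d$DV[d$EVID == 0 & d$TIME == 0 & d$DVID == 2]
  r0 <- d$DV[d$EVID == 0 & d$TIME == 0 & d$DVID == 3]
  expect_equal(mean(act0), 100, tolerance = 0.25)
  expect_equal(mean(r0), 0.4, tolerance = 0.5)
  expect_true(all(r0 > 0))  # redraw/floor keeps the channel positive
})
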