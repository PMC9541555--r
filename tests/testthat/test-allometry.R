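test_that("allometric scaling reproduces reference arithmetic", {
  # at the standard weight the scaling is the identity, for any exponent
  for (e in c(0, 0.25, 0.75, 1, 2))
    expect_equal(scale_allometric(0.135, 70, e), 0.135)
  # volumes scale linearly with weight
  expect_equal(scale_allometric(12.3, 4, 1), 0.7028571428571428,
               tolerance = 1e-10)
  # clearances scale with the 3/4 power
  expect_equal(scale_allometric(0.135, 4, 0.75), 0.01577811917276375,
               tolerance = 1e-10)
})

test_that("allometric scaling is multiplicative and rejects bad input", {
  set.seed(11)
  for (i in 1:20) {
    p <- runif(1, 0.01, 50)
    a <- runif(1, 0.5, 3)
    w <- runif(1, 0.5, 200)
    e <- runif(1, -1, 2)
    expect_equal(scale_allometric(a * p, w, e),
                 a * scale_allometric(p, w, e))
  }
  expect_error(scale_allometric(-1, 4, 0.75), "p_std")
  expect_error(scale_allometric(1, 0, 0.75), "weight")
  expect_error(scale_allometric(1, 4, Inf), "exponent")
})

test_that("weight-based dosing arithmetic is exact", {
  expect_identical(dose_total(4, 15), 60)
  expect_identical(dose_total(4, 0), 0)
  expect_identical(dose_total(4.5, 15), 67.5)
  expect_error(dose_total(0, 15), "weight")
  expect_error(dose_total(4, -1), "dose_per_kg")
})

test_that("formulation volumes follow the per-mg recipe linearly", {
  v <- formulation_volumes(60)
  expect_equal(unname(v), c(3.6, 12, 15.6))
  v1 <- formulation_volumes(1)
  expect_equal(unname(v1), c(0.06, 0.2, 0.26))
  expect_equal(unname(formulation_volumes(0)), c(0, 0, 0))
  expect_error(formulation_volumes(-1), "dose_mg")
})
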