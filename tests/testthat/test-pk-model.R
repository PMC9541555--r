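ref_pk <- function() individualize(default_truths()$pk, 4.25)

test_that("bolus solution satisfies initial condition and AUC identity", {
  pk <- ref_pk()
  dose <- 63.75
  expect_equal(predict_cp(pk, dose, 1e-9), dose / pk$v1,
               tolerance = 1e-6)
  auc <- integrate(function(t) predict_cp(pk, dose, t), 0, Inf,
                   rel.tol = 1e-10)$value
  expect_equal(auc, dose / pk$cl, tolerance = 1e-3)
})

test_that("closed-form concentrations match the ODE oracle to 1e-6", {
  times <- c(0.5, 1, 2, 5, 15, 30, 60, 120, 180, 300, 420)
  for (p in random_pk_sets(8, seed = 21)) {
    pk <- pk_pars(p$cl, p$q, p$v1, p$v2)
    cp <- predict_cp(pk, p$dose, times)
    ora <- ode_oracle(p$cl, p$q, p$v1, p$v2, p$dose, times)
    expect_equal(cp, ora$cp, tolerance = 1e-6)
  }
})

test_that("zero-order infusion superposition matches the ODE oracle", {
  p <- random_pk_sets(1, seed = 5)[[1]]
  pk <- pk_pars(p$cl, p$q, p$v1, p$v2)
  times <- c(1, 5, 10, 14.9, 15, 16, 30, 60, 240)
  cp <- predict_cp(pk, p$dose, times, infusion_duration = 15)
  ora <- ode_oracle(p$cl, p$q, p$v1, p$v2, p$dose, times,
                    infusion_duration = 15)
  expect_equal(cp, ora$cp, tolerance = 1e-6)
})

test_that("mass balance holds at every output time", {
  times <- c(0, 1, 5, 30, 60, 180, 420)
  for (p in random_pk_sets(6, seed = 31)) {
    am <- pk_amounts(pk_pars(p$cl, p$q, p$v1, p$v2), p$dose, times)
    expect_equal(am$central + am$peripheral + am$eliminated,
                 rep(p$dose, length(times)), tolerance = 1e-6)
    ora <- ode_oracle(p$cl, p$q, p$v1, p$v2, p$dose, times)
    expect_equal(am$peripheral, ora$peripheral, tolerance = 1e-6)
    expect_equal(am$eliminated, ora$eliminated, tolerance = 1e-6)
  }
})

test_that("bolus concentration declines monotonically", {
  pk <- ref_pk()
  tt <- seq(0.1, 420, by = 0.5)
  cp <- predict_cp(pk, 60, tt)
  expect_true(all(diff(cp) < 0))
})

test_that("near-degenerate eigenvalues fall back to the numerical path", {
  # q chosen so the two hybrid rate constants coincide to ~1e-9
  cl <- 0.016
  v1 <- 0.75
  q <- 1e-20
  v2 <- q / (cl / v1)
  pk <- pk_pars(cl, q, v1, v2)
  times <- c(5, 60, 420)
  cp <- predict_cp(pk, 60, times)
  ora <- ode_oracle(cl, q, v1, v2, 60, times)
  expect_equal(cp, ora$cp, tolerance = 1e-6)
})

test_that("invalid prediction inputs are rejected", {
  pk <- ref_pk()
  expect_error(predict_cp(pk, 60, c(-1, 5)), "times")
  expect_error(pk_pars(-1, 0.1, 1, 1))
  expect_error(pk_pars(1, 0.1, 1, -2), "v2")
})
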