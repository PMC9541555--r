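test_that("delayed concentration has the defining half-time behaviour", {
  # constant plasma concentration: the delayed compartment reaches half of
  # it after exactly one delay half-time, and approaches it asymptotically
  const_cp <- list(C = 8, lambda = 0)
  expect_equal(predict_delayed(const_cp, 3, 3), 4, tolerance = 1e-12)
  expect_equal(predict_delayed(const_cp, 3, 300), 8, tolerance = 1e-10)
  # vanishing delay: delayed concentration tracks plasma
  pk <- individualize(default_truths()$pk, 4.2)
  mac <- dabicoag:::cp_macro(pk)
  coefs <- list(C = 60 * mac$C, lambda = mac$lambda)
  tt <- c(1, 5, 30, 120)
  x <- predict_delayed(coefs, 1e-4, tt)
  expect_equal(x, predict_cp(pk, 60, tt), tolerance = 1e-3)
  expect_error(predict_delayed(const_cp, 0, 1), "t_half")
})

test_that("analytic delayed solution matches numerical integration", {
  p <- random_pk_sets(3, seed = 41)
  for (s in p) {
    pk <- pk_pars(s$cl, s$q, s$v1, s$v2)
    mac <- dabicoag:::cp_macro(pk)
    coefs <- list(C = s$dose * mac$C, lambda = mac$lambda)
    tt <- c(0.5, 2, 5, 15, 60, 180, 420)
    for (th in c(0.7, 2, 10)) {
      analytic <- predict_delayed(coefs, th, tt)
      ora <- ode_oracle(s$cl, s$q, s$v1, s$v2, s$dose, tt,
                        t_half_delay = th)
      expect_equal(analytic, ora$ce, tolerance = 1e-6)
      # function-input route integrates the same equation
      fn <- predict_delayed(function(t) predict_cp(pk, s$dose, t), th, tt)
      expect_equal(fn, analytic, tolerance = 1e-6)
    }
  }
})

test_that("sigmoid response hits its anchor points and is monotone", {
  pd <- default_truths()$pd$act
  expect_equal(sigmoid_emax(0, pd), 100)
  expect_equal(sigmoid_emax(pd$c50, pd), 100 + 899 / 2)
  expect_equal(sigmoid_emax(1e9, pd), 100 + 899, tolerance = 1e-3)
  set.seed(13)
  for (i in 1:10) {
    pdr <- pd_pars(runif(1, 0, 100), runif(1, 1, 900), runif(1, 1, 80),
                   runif(1, 0.2, 4), runif(1, 0.5, 5))
    cc <- sort(runif(50, 0, 200))
    expect_true(all(diff(sigmoid_emax(cc, pdr)) > 0))
    expect_true(all(sigmoid_emax(cc, pdr) <= pdr$e0 + pdr$emax))
  }
  expect_error(sigmoid_emax(-1, pd), "conc")
})

test_that("effect trajectory composes the three model layers", {
  tr <- default_truths()
  pk <- individualize(tr$pk, 4.25)
  times <- c(0, 5, 15, 30, 60, 120, 180, 300, 420)
  traj <- predict_effect(pk, tr$pd$act, 63.75, times)
  expect_equal(traj$effect[1], 100)              # baseline at t = 0
  expect_true(all(traj$effect >= 100 - 1e-9))
  # flat response when the drug has no effect
  flat <- predict_effect(pk, pd_pars(100, 0, 20, 1, 1.4), 63.75, times)
  expect_equal(flat$effect, rep(100, length(times)))
  # full coupled system against the ODE oracle
  ora <- ode_oracle(pk$cl, pk$q, pk$v1, pk$v2, 63.75, times[-1],
                    t_half_delay = tr$pd$act$t_half_delay)
  expect_equal(traj$cp[-1], ora$cp, tolerance = 1e-5)
  eff_ora <- sigmoid_emax(pmax(ora$ce, 0), tr$pd$act)
  expect_equal(traj$effect[-1], eff_ora, tolerance = 1e-5)
})

test_that("effect-compartment and turnover mechanisms share dynamics", {
  tr <- default_truths()
  pk <- individualize(tr$pk, 4.1)
  times <- c(0, 5, 15, 30, 60, 120, 300)
  ec <- tr$pd$act
  to <- pd_pars(ec$e0, ec$emax, ec$c50, ec$hill, ec$t_half_delay,
                "turnover")
  t1 <- predict_effect(pk, ec, 61.5, times)
  t2 <- predict_effect(pk, to, 61.5, times)
  # identical delay rate and midpoint: trajectories are bit-comparable
  expect_true(max(abs(t1$effect - t2$effect) /
                    pmax(abs(t1$effect), 1)) <= 1e-9)
  expect_identical(t1$cp, t2$cp)
})
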