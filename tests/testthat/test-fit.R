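# Small noise-free cohorts: the marginal fit must collapse to exact
# nonlinear regression and recover the generating values.
test_that("noise-free data identify the structural PK parameters", {
  co <- default_cohort(design = study_design(n_subjects = 3),
                       truths = noisefree_truths(), seed = 29)
  d <- simulate_cohort(co)
  f <- fit_pk(d, bsv = character(0), error = "add",
              control = list(se = FALSE, max_restarts = 2))
  truth <- c(CL = 0.135, Q = 0.33, V1 = 12.3, V2 = 30.1)
  expect_lt(max(abs(f$estimates - truth) / truth), 1e-3)
})

test_that("noise-free single-subject data identify the PD parameters", {
  co <- default_cohort(design = study_design(n_subjects = 1),
                       truths = noisefree_truths(), seed = 31)
  d <- simulate_cohort(co)
  fpk <- fit_pk(d, bsv = character(0), error = "add",
                control = list(se = FALSE, max_restarts = 2))
  fpd <- fit_pd(d, fpk, readout = "act", bsv = character(0),
                control = list(se = FALSE, max_restarts = 2))
  expect_lt(abs(fpd$estimates[["Ce50"]] - 20.1) / 20.1, 1e-3)
  expect_lt(abs(fpd$estimates[["N"]] - 0.66) / 0.66, 1e-3)
  expect_lt(abs(fpd$estimates[["T1/2keo"]] - 1.4) / 1.4, 1e-3)
})

test_that("Laplace objective matches adaptive Gauss-Hermite quadrature", {
  # one-random-effect toy problem evaluated through the engine directly
  set.seed(37)
  subjects <- lapply(1:3, function(i) {
    times <- c(0.5, 1, 2, 4, 8)
    eta <- rnorm(1, 0, 0.4)
    f <- 100 / 10 * exp(-1 * exp(eta) / 10 * times)
    list(id = i, times = times, y = f + rnorm(5, 0, 0.4))
  })
  predfun <- function(nat, subj, eta)
    100 / nat$v * exp(-nat$cl * exp(eta[1]) / nat$v * subj$times)
  sdfun <- function(nat, subj, f) rep(nat$sd, length(f))
  unpack <- function(theta)
    list(cl = exp(theta[1]), v = exp(theta[2]), omega = exp(theta[3]),
         sd = exp(theta[4]))
  obj <- dabicoag:::nlme_objective(subjects, 1L, unpack, predfun, sdfun)
  for (theta in list(log(c(1, 10, 0.4, 0.4)),
                     log(c(1.3, 8, 0.25, 0.6)))) {
    nat <- unpack(theta)
    ora <- agh_neg2ll(subjects,
                      function(subj, eta) predfun(nat, subj, eta),
                      function(subj, f) sdfun(nat, subj, f),
                      om = nat$omega, nodes = 15)
    expect_lt(abs(obj$fn(theta) - ora), 0.5)
  }
})

test_that("estimates are invariant to subject order and time units", {
  d <- toy_dataset(n_subjects = 5, seed = 41)
  # tighter outer convergence so the 1e-3 agreement is about the model,
  # not the optimizer stopping rule
  ctl <- list(se = FALSE, max_restarts = 4, rel_change_tol = 1e-4)
  f1 <- fit_pk(d, bsv = "cl", error = "add", n_compartments = 1,
               control = ctl)
  # reversed subject order
  d2 <- d[order(-d$ID, d$TIME, -d$EVID), ]
  f2 <- fit_pk(d2, bsv = "cl", error = "add", n_compartments = 1,
               control = ctl)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-3)
  # hours instead of minutes: clearance rescales by 60, volume unchanged
  d3 <- d
  d3$TIME <- d3$TIME / 60
  f3 <- fit_pk(d3, bsv = "cl", error = "add", n_compartments = 1,
               control = ctl)
  expect_equal(f3$estimates[["CL"]] / 60, f1$estimates[["CL"]],
               tolerance = 1e-3)
  expect_equal(f3$estimates[["V1"]], f1$estimates[["V1"]],
               tolerance = 1e-3)
  # restarting the optimization at the optimum can only improve (or hold)
  # the objective: accepted steps never increase it
  st <- as.list(exp(f1$theta))
  names(st) <- names(f1$theta)
  f1b <- fit_pk(d, start = st, bsv = "cl", error = "add",
                n_compartments = 1, control = ctl)
  expect_lte(f1b$objective, f1$objective + 1e-6)
})

test_that("the generating model dominates a mis-specified reduction", {
  co <- default_cohort(design = study_design(n_subjects = 6), seed = 43)
  d <- simulate_cohort(co, channels = "conc")
  ctl <- list(se = FALSE, max_restarts = 2)
  f2 <- fit_pk(d, control = ctl)
  f1 <- fit_pk(d, n_compartments = 1, bsv = c("cl", "v1"), control = ctl)
  expect_lt(f2$objective, f1$objective)
  cmp <- compare_models(f1, f2)
  expect_identical(cmp$preferred, "b")
})

test_that("objective-change model selection follows the 3.84 rule", {
  stub <- function(obj, npar, d) structure(
    list(objective = obj, n_par = npar, data = d), class = "pkpd_fit")
  d <- data.frame(DV = 1:3, TIME = 1:3)
  # identical objectives: the simpler model is kept
  cmp <- compare_models(stub(100, 5, d), stub(100, 6, d))
  expect_identical(cmp$preferred, "a")
  expect_identical(cmp$delta_objective, 0)
  # a drop of exactly 3.84 does not justify the extra parameter
  expect_identical(compare_models(stub(100, 5, d),
                                  stub(96.16, 6, d))$preferred, "a")
  # a drop beyond the criterion does
  expect_identical(compare_models(stub(100, 5, d),
                                  stub(96.15, 6, d))$preferred, "b")
  # and the comparison refuses different datasets
  d2 <- data.frame(DV = 4:6, TIME = 1:3)
  expect_error(compare_models(stub(1, 1, d), stub(1, 1, d2)),
               "same dataset")
})

test_that("standard errors behave like asymptotic uncertainty", {
  ds <- toy_dataset(n_subjects = 4, seed = 47)
  db <- toy_dataset(n_subjects = 16, seed = 47)
  ctl <- list(se = FALSE, max_restarts = 2)
  fs <- fit_pk(ds, bsv = "cl", error = "add", n_compartments = 1,
               control = ctl)
  fb <- fit_pk(db, bsv = "cl", error = "add", n_compartments = 1,
               control = ctl)
  ses <- standard_errors(fs, n_boot = 15)
  seb <- standard_errors(fb, n_boot = 15)
  # the confidence interval always brackets the point estimate
  expect_true(all(ses$ci_lower <= ses$estimate &
                    ses$estimate <= ses$ci_upper))
  # quadrupling the cohort shrinks the clearance SE
  expect_lt(seb$se_pct[seb$parameter == "cl"],
            ses$se_pct[ses$parameter == "cl"])
})

test_that("delay mechanisms are exchangeable in estimation", {
  co <- default_cohort(design = study_design(n_subjects = 4), seed = 53)
  d <- simulate_cohort(co, channels = c("conc", "act"))
  ctl <- list(se = FALSE, max_restarts = 2)
  fpk <- fit_pk(d, bsv = c("cl", "v1"), control = ctl)
  fec <- fit_pd(d, fpk, readout = "act", mechanism = "effect_compartment",
                bsv = "t_half", control = ctl)
  fto <- fit_pd(d, fpk, readout = "act", mechanism = "turnover",
                bsv = "t_half", control = ctl)
  # same dynamics, same data: the objectives coincide and the objective
  # criterion cannot separate the mechanisms
  expect_lt(abs(fec$objective - fto$objective), 1e-6)
  expect_identical(names(fec$estimates)[1], "Ce50")
  expect_identical(names(fto$estimates)[1], "Cp50")
  cmp <- compare_models(fec, fto)
  expect_lt(abs(cmp$delta_objective), 3.84)
})

test_that("fit objects expose the standard modelling interface", {
  d <- toy_dataset(n_subjects = 4, seed = 59)
  f <- fit_pk(d, bsv = "cl", error = "add", n_compartments = 1,
              control = list(se = FALSE, max_restarts = 2))
  expect_s3_class(f, "pkpd_fit")
  expect_named(coef(f), c("CL", "V1"))
  expect_true(all(coef(f) > 0))
  expect_identical(dim(f$ebes), c(4L, 1L))
  ll <- logLik(f)
  expect_equal(as.numeric(ll), -f$objective / 2)
  pr <- predict(f, type = "population")
  expect_identical(nrow(pr), 20L)
  rs <- residuals(f)
  expect_identical(names(rs),
                   c("id", "time", "channel", "observed", "pred",
                     "residual"))
  # individual predictions track the data more closely than population ones
  ri <- residuals(f, level = "individual")
  rp <- residuals(f, level = "population")
  expect_lte(sum(ri$residual^2), sum(rp$residual^2))
  sims <- simulate(f, nsim = 2, seed = 61)
  expect_length(sims, 2)
  expect_identical(nrow(sims[[1]]), nrow(d))
})
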