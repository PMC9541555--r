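# Independent numerical oracles used to validate the closed-form model
# solutions and the Laplace approximation. These deliberately re-derive the
# dynamics from the compartmental mass-balance equations rather than reuse
# any package internals.

# High-accuracy ODE solution of the two-compartment + first-order-delay
# system. Returns cp, delayed concentration, compartment amounts and the
# cumulative eliminated amount.
ode_oracle <- function(cl, q, v1, v2, dose, times, t_half_delay = NULL,
                       infusion_duration = 0) {
  k10 <- cl / v1
  k12 <- if (v2 > 0) q / v1 else 0
  k21 <- if (v2 > 0) q / v2 else 0
  kdel <- if (is.null(t_half_delay)) 0 else log(2) / t_half_delay
  rhs <- function(t, y, p) {
    inp <- if (infusion_duration > 0 && t < infusion_duration)
      dose / infusion_duration else 0
    dA1 <- inp - k10 * y[1] - k12 * y[1] + k21 * y[2]
    dA2 <- k12 * y[1] - k21 * y[2]
    dX <- kdel * (y[1] / v1 - y[3])
    dAe <- k10 * y[1]
    list(c(dA1, dA2, dX, dAe))
  }
  y0 <- c(if (infusion_duration > 0) 0 else dose, 0, 0, 0)
  tt <- sort(unique(c(0, times)))
  out <- deSolve::ode(y0, tt, rhs, NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-13)
  i <- match(times, tt)
  data.frame(time = times, cp = out[i, 2] / v1, ce = out[i, 4],
             central = out[i, 2], peripheral = out[i, 3],
             eliminated = out[i, 5])
}

# Random strictly positive two-compartment parameter sets, seeded.
random_pk_sets <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(cl = exp(rnorm(1, log(0.02), 0.6)),
         q = exp(rnorm(1, log(0.05), 0.6)),
         v1 = exp(rnorm(1, log(0.8), 0.4)),
         v2 = exp(rnorm(1, log(2), 0.4)),
         dose = exp(rnorm(1, log(60), 0.3)))
  })
}

# Adaptive Gauss-Hermite marginal -2 log-likelihood for a model with one
# random effect per subject: y_ij ~ N(f(eta_i), sd_ij^2), eta ~ N(0, om^2).
# `predfun(subj, eta)` and `sdfun(subj, f)` are supplied by the caller.
agh_neg2ll <- function(subjects, predfun, sdfun, om, nodes = 15) {
  gh <- pracma::gaussHermite(nodes)
  total <- 0
  for (subj in subjects) {
    log_joint <- function(eta) {
      f <- predfun(subj, eta)
      sd <- sdfun(subj, f)
      sum(dnorm(subj$y, f, sd, log = TRUE)) + dnorm(eta, 0, om, log = TRUE)
    }
    # centre and scale the quadrature at the conditional mode
    opt <- optimize(function(e) -log_joint(e), c(-10, 10))
    mode <- opt$minimum
    h <- 1e-4
    d2 <- -(log_joint(mode + h) - 2 * log_joint(mode) +
              log_joint(mode - h)) / h^2
    s <- 1 / sqrt(max(d2, 1e-8))
    eta_j <- mode + sqrt(2) * s * gh$x
    lt <- vapply(eta_j, log_joint, 0) + gh$x^2 +
      log(gh$w) + log(sqrt(2) * s)
    m <- max(lt)
    total <- total - 2 * (m + log(sum(exp(lt - m))))
  }
  total
}

# Small one-compartment simulation used for optimizer-level checks:
# subjects of reference weight (allometric factors = 1), a single bolus,
# log-normal variability on clearance and additive error.
toy_dataset <- function(n_subjects = 4, times = c(0.5, 1, 2, 4, 8),
                        cl = 1, v1 = 10, om_cl = 0.3, om_v1 = 0,
                        sd_add = 0.3, dose = 100, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_subjects), function(i) {
    cli <- cl * exp(rnorm(1, 0, om_cl))
    v1i <- v1 * exp(if (om_v1 > 0) rnorm(1, 0, om_v1) else 0)
    f <- dose / v1i * exp(-cli / v1i * times)
    y <- f + rnorm(length(times), 0, sd_add)
    y <- pmax(y, 1e-3)
    rbind(data.frame(ID = i, TIME = 0, EVID = 1L, AMT = dose, RATE = 0,
                     DV = NA_real_, DVID = 0L, MDV = 1L, WT = 70),
          data.frame(ID = i, TIME = times, EVID = 0L, AMT = NA_real_,
                     RATE = 0, DV = y, DVID = 1L, MDV = 0L, WT = 70))
  })
  do.call(rbind, rows)
}

# Generating truths with variability switched off and a vanishing residual
# error, for exact-identifiability checks.
noisefree_truths <- function(jitter = 1e-6) {
  tr <- default_truths()
  tr$bsv <- lapply(tr$bsv, function(b) b * 0)
  tr$ruv <- lapply(tr$ruv, function(r) c(add = jitter, prop = 0))
  tr
}
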