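#' Two-compartment disposition parameters
#'
#' Container for the structural parameters of a linear two-compartment
#' intravenous disposition model, parameterized by clearances and volumes:
#' elimination clearance `cl` (L/min), intercompartmental clearance `q`
#' (L/min), central volume `v1` (L) and peripheral volume `v2` (L). A
#' one-compartment model is represented by `q = 0`, `v2 = NA`.
#'
#' Values may be population values standardized to 70 kg or individual
#' values; prediction functions expect individual values (see
#' [individualize()]).
#'
#' @param cl elimination clearance, L/min (> 0).
#' @param q intercompartmental clearance, L/min (>= 0; 0 collapses to a
#'   one-compartment model).
#' @param v1 central volume, L (> 0).
#' @param v2 peripheral volume, L (> 0, or NA when `q = 0`).
#' @return object of class `"pk_pars"`.
#' @export
pk_pars <- function(cl, q, v1, v2) {
  one_cmt <- (is.na(q) || q == 0)
  if (one_cmt) {
    q <- 0
    v2 <- NA_real_
  }
  stopifnot(is.finite(cl), cl > 0, is.finite(v1), v1 > 0, q >= 0)
  if (!one_cmt && (!is.finite(v2) || v2 <= 0))
    stop("'v2' must be strictly positive for a two-compartment model",
         call. = FALSE)
  structure(list(cl = cl, q = q, v1 = v1, v2 = v2),
            class = "pk_pars")
}

#' @export
print.pk_pars <- function(x, ...) {
  cat("Two-compartment disposition parameters (L, L/min):\n")
  print(unlist(x))
  invisible(x)
}

#' Individualize standardized parameters by allometry
#'
#' Applies theory-based allometric scaling (exponent 0.75 on clearances, 1 on
#' volumes) and optional log-normal subject deviations to a standardized
#' parameter set.
#'
#' @param pk `"pk_pars"` with values standardized to `std_weight` kg.
#' @param weight individual weight in kg.
#' @param eta named numeric vector of log-scale subject deviations (names
#'   among `cl`, `q`, `v1`, `v2`); missing names mean no deviation.
#' @param std_weight reference weight (kg), default 70.
#' @return `"pk_pars"` with individual values.
#' @export
individualize <- function(pk, weight, eta = numeric(0), std_weight = 70) {
  stopifnot(inherits(pk, "pk_pars"))
  e <- function(nm) if (nm %in% names(eta)) exp(eta[[nm]]) else 1
  cl <- scale_allometric(pk$cl, weight, 0.75, std_weight) * e("cl")
  v1 <- scale_allometric(pk$v1, weight, 1, std_weight) * e("v1")
  if (pk$q > 0) {
    q <- scale_allometric(pk$q, weight, 0.75, std_weight) * e("q")
    v2 <- scale_allometric(pk$v2, weight, 1, std_weight) * e("v2")
  } else {
    q <- 0
    v2 <- NA_real_
  }
  pk_pars(cl, q, v1, v2)
}

# Macro (exponential) representation of the unit-dose bolus solution:
# cp(t) = sum_m C[m] * exp(-lambda[m] * t) for a 1 mg bolus.
# Returns list(C, lambda, k10, k12, k21, degenerate).
cp_macro <- function(pk) {
  k10 <- pk$cl / pk$v1
  if (pk$q <= 0) {
    return(list(C = 1 / pk$v1, lambda = k10,
                k10 = k10, k12 = 0, k21 = 0, degenerate = FALSE))
  }
  k12 <- pk$q / pk$v1
  k21 <- pk$q / pk$v2
  s <- k10 + k12 + k21
  disc <- s^2 - 4 * k10 * k21
  disc <- max(disc, 0)
  alpha <- (s + sqrt(disc)) / 2
  beta <- (s - sqrt(disc)) / 2
  degen <- abs(alpha - beta) / alpha < 1e-8
  C1 <- (alpha - k21) / (pk$v1 * (alpha - beta))
  C2 <- (k21 - beta) / (pk$v1 * (alpha - beta))
  list(C = c(C1, C2), lambda = c(alpha, beta),
       k10 = k10, k12 = k12, k21 = k21, degenerate = degen)
}

# Right-hand side of the coupled PK(-delay) ODE system, amounts in mg.
# state: A1, A2, X (delayed concentration, mg/L), Ae (eliminated amount).
pkpd_rhs <- function(t, state, p) {
  cp <- state[1] / p$v1
  inp <- if (p$dur > 0 && t < p$dur) p$dose / p$dur else 0
  dA1 <- inp - (p$k10 + p$k12) * state[1] + p$k21 * state[2]
  dA2 <- p$k12 * state[1] - p$k21 * state[2]
  dX <- p$kdel * (cp - state[3])
  dAe <- p$k10 * state[1]
  list(c(dA1, dA2, dX, dAe))
}

# Numerical solution used for infusion input, degenerate eigenvalues and as
# an internal fallback; kdel = 0 disables the delay compartment.
ode_solution <- function(pk, dose, times, infusion_duration = 0, kdel = 0) {
  mac <- cp_macro(pk)
  p <- list(v1 = pk$v1, k10 = mac$k10, k12 = mac$k12, k21 = mac$k21,
            dose = dose, dur = infusion_duration, kdel = kdel)
  tt <- sort(unique(c(0, infusion_duration, times)))
  y0 <- c(A1 = if (infusion_duration > 0) 0 else dose, A2 = 0, X = 0, Ae = 0)
  out <- deSolve::lsoda(y0, tt, pkpd_rhs, p, rtol = 1e-10, atol = 1e-12)
  out[match(times, tt), , drop = FALSE]
}

#' Predict plasma concentration after a single intravenous dose
#'
#' Closed-form bi-exponential solution of the two-compartment model for a
#' bolus dose; for a zero-order infusion the solution is obtained by
#' superposition of the unit impulse response. When the two hybrid rate
#' constants nearly coincide the closed form is ill-conditioned and the
#' prediction falls back to a high-accuracy numerical integration.
#'
#' @param pk individual `"pk_pars"` (already weight-scaled).
#' @param dose total dose in mg.
#' @param times vector of times in minutes (>= 0).
#' @param infusion_duration infusion length in minutes; 0 means bolus.
#' @return numeric vector of plasma concentrations (mg/L).
#' @export
predict_cp <- function(pk, dose, times, infusion_duration = 0) {
  stopifnot(inherits(pk, "pk_pars"), is.finite(dose), dose >= 0)
  if (any(!is.finite(times)) || any(times < 0))
    stop("'times' must be non-negative", call. = FALSE)
  mac <- cp_macro(pk)
  if (mac$degenerate || infusion_duration > 0) {
    if (mac$degenerate)
      return(ode_solution(pk, dose, times, infusion_duration)[, "A1"] / pk$v1)
    # infusion: superposition of the unit-dose exponentials
    rate <- dose / infusion_duration
    cp <- numeric(length(times))
    for (m in seq_along(mac$C)) {
      lam <- mac$lambda[m]
      tin <- pmin(times, infusion_duration)
      tpost <- pmax(times - infusion_duration, 0)
      cp <- cp + rate * mac$C[m] / lam * (1 - exp(-lam * tin)) * exp(-lam * tpost)
    }
    return(cp)
  }
  drop(exp(-outer(times, mac$lambda)) %*% (dose * mac$C))
}

#' Compartment amounts and mass balance after a bolus dose
#'
#' Closed-form amounts (mg) in the central and peripheral compartments and
#' the cumulative eliminated amount, for checking the conservation identity
#' central + peripheral + eliminated = dose.
#'
#' @inheritParams predict_cp
#' @return data.frame with columns `time`, `central`, `peripheral`,
#'   `eliminated`.
#' @export
pk_amounts <- function(pk, dose, times) {
  stopifnot(inherits(pk, "pk_pars"), dose >= 0)
  mac <- cp_macro(pk)
  if (mac$degenerate) {
    out <- ode_solution(pk, dose, times)
    return(data.frame(time = times, central = out[, "A1"],
                      peripheral = out[, "A2"], eliminated = out[, "Ae"]))
  }
  E <- exp(-outer(times, mac$lambda))
  a1 <- drop(E %*% (dose * mac$C)) * pk$v1
  if (pk$q > 0) {
    al <- mac$lambda[1]; be <- mac$lambda[2]
    a2 <- dose * mac$k12 / (al - be) * (exp(-be * times) - exp(-al * times))
  } else a2 <- numeric(length(times))
  elim <- mac$k10 * pk$v1 *
    drop((1 - E) %*% (dose * mac$C / mac$lambda))
  data.frame(time = times, central = a1, peripheral = a2, eliminated = elim)
}
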