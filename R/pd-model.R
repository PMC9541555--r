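#' Delayed sigmoid-Emax pharmacodynamic parameters
#'
#' Parameters of a sigmoid Emax concentration-response driven by a delayed
#' concentration. Two delay mechanisms are supported and share identical
#' first-order dynamics: the *effect compartment* (hypothetical biophase
#' concentration `Ce` equilibrating with plasma at rate `keo`) and the
#' *turnover* model (a mediator `Cofact` produced at a first-order rate
#' `kin`). In either case the delayed concentration `X` follows
#' \eqn{dX/dt = k (C_p - X)}, \eqn{X(0) = 0}, with
#' \eqn{k = \ln 2 / t_{1/2}}, so the two mechanisms differ only in
#' interpretation (half-time reported as the equilibration half-time
#' T1/2keo or the turnover half-time TNOVER; the midpoint concentration as
#' Ce50 or Cp50).
#'
#' @param e0 baseline response (s for activated clotting time, min for
#'   thromboelastometric reaction time).
#' @param emax maximum drug effect, same units as `e0` (>= 0; 0 gives a
#'   flat response at baseline).
#' @param c50 delayed concentration giving half-maximal effect, mg/L (> 0).
#' @param hill Hill coefficient (> 0), steepness of the response.
#' @param t_half_delay delay half-time in minutes (> 0).
#' @param mechanism `"effect_compartment"` or `"turnover"`.
#' @return object of class `"pd_pars"`.
#' @export
pd_pars <- function(e0, emax, c50, hill, t_half_delay,
                    mechanism = c("effect_compartment", "turnover")) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.finite(e0), is.finite(emax), emax >= 0,
            is.finite(c50), c50 > 0, is.finite(hill), hill > 0,
            is.finite(t_half_delay), t_half_delay > 0)
  structure(list(e0 = e0, emax = emax, c50 = c50, hill = hill,
                 t_half_delay = t_half_delay, mechanism = mechanism),
            class = "pd_pars")
}

#' @export
print.pd_pars <- function(x, ...) {
  lab <- if (x$mechanism == "effect_compartment") "T1/2keo" else "TNOVER"
  c50lab <- if (x$mechanism == "effect_compartment") "Ce50" else "Cp50"
  cat(sprintf("Sigmoid Emax with %s delay:\n", gsub("_", " ", x$mechanism)))
  v <- c(E0 = x$e0, Emax = x$emax, x$c50, N = x$hill, x$t_half_delay)
  names(v)[c(3, 5)] <- c(paste0(c50lab, " (mg/L)"), paste0(lab, " (min)"))
  print(v)
  invisible(x)
}

#' Delayed concentration driven by a plasma profile
#'
#' Solves \eqn{dX/dt = k (C_p(t) - X)}, \eqn{X(0)=0},
#' \eqn{k = \ln 2 / t_{1/2}}. When `cp` is a list with components `C` and
#' `lambda` describing a sum of exponentials
#' \eqn{C_p(t) = \sum_m C_m e^{-\lambda_m t}} the solution is analytic; when
#' `cp` is a function of time the equation is integrated numerically.
#'
#' @param cp either a function `cp(t)` returning plasma concentration, or a
#'   list `list(C=, lambda=)` of exponential coefficients (a constant
#'   concentration corresponds to `lambda = 0`).
#' @param t_half_delay delay half-time in minutes (> 0).
#' @param times evaluation times in minutes.
#' @param mechanism mechanism label (dynamics identical; see [pd_pars()]).
#' @return numeric vector of delayed concentrations (mg/L).
#' @export
predict_delayed <- function(cp, t_half_delay, times,
                            mechanism = c("effect_compartment", "turnover")) {
  match.arg(mechanism)
  if (!is.finite(t_half_delay) || t_half_delay <= 0)
    stop("'t_half_delay' must be strictly positive", call. = FALSE)
  k <- log(2) / t_half_delay
  if (is.function(cp)) {
    rhs <- function(t, x, p) list(k * (cp(t) - x))
    tt <- sort(unique(c(0, times)))
    out <- deSolve::lsoda(c(X = 0), tt, rhs, NULL, rtol = 1e-10, atol = 1e-12)
    return(out[match(times, tt), "X"])
  }
  delayed_exponentials(cp$C, cp$lambda, k, times)
}

# Analytic solution of dX/dt = k(sum C_m exp(-lambda_m t) - X), X(0) = 0:
#   X(t) = k * sum_m C_m (exp(-lambda_m t) - exp(-k t)) / (k - lambda_m),
# with the confluent limit k -> lambda_m handled by C_m k t exp(-k t).
delayed_exponentials <- function(C, lambda, k, times) {
  x <- numeric(length(times))
  for (m in seq_along(C)) {
    lam <- lambda[m]
    if (abs(k - lam) <= 1e-8 * k) {
      x <- x + C[m] * k * times * exp(-k * times)
    } else {
      x <- x + C[m] * k * (exp(-lam * times) - exp(-k * times)) / (k - lam)
    }
  }
  x
}

#' Sigmoid Emax concentration-response
#'
#' \eqn{E(C) = E_0 + E_{max} C^N / (C_{50}^N + C^N)}: strictly increasing in
#' the concentration, equal to `e0` at zero and saturating at `e0 + emax`.
#'
#' @param conc delayed (effect-site or mediator) concentration, mg/L (>= 0).
#' @param pd `"pd_pars"` object.
#' @return response in the readout's units.
#' @export
sigmoid_emax <- function(conc, pd) {
  stopifnot(inherits(pd, "pd_pars"))
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("'conc' must be non-negative", call. = FALSE)
  cn <- conc^pd$hill
  pd$e0 + pd$emax * cn / (pd$c50^pd$hill + cn)
}

#' Predict the full concentration-effect trajectory
#'
#' Composes the two-compartment plasma prediction, the first-order delay and
#' the sigmoid Emax response for one subject and dose.
#'
#' @param pk individual `"pk_pars"`.
#' @param pd `"pd_pars"`.
#' @param dose total dose in mg.
#' @param times evaluation times in minutes.
#' @param infusion_duration infusion length in minutes (0 = bolus).
#' @return data.frame of class `"pkpd_trajectory"` with columns `time`,
#'   `cp`, `ce` (delayed concentration) and `effect`.
#' @export
predict_effect <- function(pk, pd, dose, times, infusion_duration = 0) {
  stopifnot(inherits(pk, "pk_pars"), inherits(pd, "pd_pars"))
  cp <- predict_cp(pk, dose, times, infusion_duration)
  mac <- cp_macro(pk)
  if (mac$degenerate || infusion_duration > 0) {
    k <- log(2) / pd$t_half_delay
    out <- ode_solution(pk, dose, times, infusion_duration, kdel = k)
    ce <- out[, "X"]
  } else {
    ce <- delayed_exponentials(dose * mac$C, mac$lambda,
                               log(2) / pd$t_half_delay, times)
  }
  ce <- pmax(ce, 0)
  structure(data.frame(time = times, cp = cp, ce = ce,
                       effect = sigmoid_emax(ce, pd)),
            class = c("pkpd_trajectory", "data.frame"))
}
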