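# Nonlinear mixed-effects engine: marginal -2 log-likelihood by the Laplace
# approximation with a Gauss-Newton (FOCE-style) curvature term, diagonal
# log-normal random effects and per-observation residual SDs that may depend
# on the prediction (combined error, evaluated at the subject's conditional
# mode, i.e. with eta-epsilon interaction).
#
# A "problem" couples per-subject data with two model callbacks:
#   predict_subject(nat, subj, eta) -> prediction vector aligned with subj$y
#   sigma_subject(nat, subj, f)     -> residual SD vector (same length)
# and an unpack(theta) -> nat translating the estimation-scale parameter
# vector into natural-scale quantities, including nat$omega (length-q vector
# of random-effect SDs; q = 0 means a fixed-effects-only model).

LARGE_OBJ <- 1e12

# paste0 treats zero-length arguments as "", which breaks empty
# random-effect sets; this keeps prefixing length-stable.
prefix_names <- function(prefix, x) {
  if (length(x)) paste0(prefix, x) else character(0)
}

# One subject's Laplace contribution: minimize the joint deviance
#   g(eta) = sum_j [ log(2 pi v_j) + (y_j - f_j)^2 / v_j ]
#          + q log(2 pi) + log|Omega| + eta' Omega^-1 eta
# over eta, then -2 log L_i = g(eta_hat) - q log(2 pi) + log det(H/2) with
# H/2 approximated by J' V^-1 J + Omega^-1 (Gauss-Newton).
laplace_subject <- function(nat, subj, eta_start, predict_subject,
                            sigma_subject, inner_control) {
  omega <- nat$omega
  q <- length(omega)
  if (q == 0L) {
    f <- predict_subject(nat, subj, numeric(0))
    if (any(!is.finite(f))) return(list(obj = LARGE_OBJ, eta = numeric(0)))
    sd <- pmax(sigma_subject(nat, subj, f), 1e-8)
    r <- subj$y - f
    obj <- sum(log(2 * pi * sd^2) + (r / sd)^2)
    return(list(obj = if (is.finite(obj)) obj else LARGE_OBJ,
                eta = numeric(0)))
  }
  oinv <- 1 / omega^2
  const <- q * log(2 * pi) + 2 * sum(log(omega))
  g <- function(eta) {
    f <- predict_subject(nat, subj, eta)
    if (any(!is.finite(f))) return(LARGE_OBJ)
    sd <- pmax(sigma_subject(nat, subj, f), 1e-8)
    r <- subj$y - f
    v <- sum(log(2 * pi * sd^2) + (r / sd)^2) + sum(eta^2 * oinv) + const
    if (is.finite(v)) v else LARGE_OBJ
  }
  opt <- tryCatch(
    stats::nlminb(eta_start, g, control = inner_control),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective))
    return(list(obj = LARGE_OBJ, eta = eta_start))
  # retry from the prior mode if the warm start went badly
  if (opt$objective >= LARGE_OBJ && any(eta_start != 0)) {
    opt2 <- tryCatch(stats::nlminb(numeric(q), g, control = inner_control),
                     error = function(e) NULL)
    if (!is.null(opt2) && opt2$objective < opt$objective) opt <- opt2
  }
  eta <- opt$par
  f0 <- predict_subject(nat, subj, eta)
  if (any(!is.finite(f0))) return(list(obj = LARGE_OBJ, eta = eta))
  sd0 <- pmax(sigma_subject(nat, subj, f0), 1e-8)
  h <- 1e-4
  J <- vapply(seq_len(q), function(k) {
    ek <- eta
    ek[k] <- ek[k] + h
    (predict_subject(nat, subj, ek) - f0) / h
  }, numeric(length(f0)))
  Hhalf <- crossprod(J / sd0) + diag(oinv, q)
  ld <- determinant(Hhalf, logarithm = TRUE)
  if (ld$sign <= 0)  # singular inner curvature: keep prior mode for eta
    return(list(obj = LARGE_OBJ, eta = numeric(q), singular = TRUE))
  obj <- opt$objective - q * log(2 * pi) + as.numeric(ld$modulus)
  list(obj = if (is.finite(obj)) obj else LARGE_OBJ, eta = eta)
}

# Build the outer objective (total -2 log marginal likelihood) over the
# free estimation-scale parameters. Conditional modes are warm-started
# across evaluations in `state`.
nlme_objective <- function(subjects, q, unpack, predict_subject,
                           sigma_subject,
                           inner_control = list(rel.tol = 1e-10,
                                                iter.max = 300,
                                                eval.max = 600)) {
  state <- new.env(parent = emptyenv())
  state$eta <- matrix(0, nrow = length(subjects), ncol = q)
  state$n_eval <- 0L
  fn <- function(theta) {
    nat <- unpack(theta)
    state$n_eval <- state$n_eval + 1L
    tot <- 0
    for (i in seq_along(subjects)) {
      res <- laplace_subject(nat, subjects[[i]], state$eta[i, ],
                             predict_subject, sigma_subject, inner_control)
      if (q > 0L) state$eta[i, ] <- res$eta
      tot <- tot + res$obj
      if (tot >= LARGE_OBJ) return(LARGE_OBJ)
    }
    tot
  }
  list(fn = fn, state = state)
}

# Outer maximization with restart-based convergence: rerun from the current
# optimum until the relative parameter change drops below rel_change_tol
# (mirroring a "three significant digits" convergence rule).
nlme_outer_fit <- function(obj, theta0, lower, upper, control = list()) {
  ctl <- utils::modifyList(list(iter.max = 400, eval.max = 1200,
                                rel.tol = 1e-9, rel_change_tol = 1e-3,
                                max_restarts = 8L), control)
  nlminb_ctl <- ctl[intersect(names(ctl),
                              c("iter.max", "eval.max", "rel.tol",
                                "step.min", "x.tol"))]
  theta <- theta0
  converged <- FALSE
  msg <- ""
  opt <- NULL
  for (r in seq_len(1L + ctl$max_restarts)) {
    opt <- stats::nlminb(theta, obj$fn, lower = lower, upper = upper,
                         control = nlminb_ctl)
    # parameters live on the log scale, so an absolute change in theta is a
    # relative change of the natural-scale estimate
    rel_change <- max(abs(opt$par - theta))
    msg <- opt$message
    theta <- opt$par
    # convergence = successive optimizations agree to the relative
    # parameter-change tolerance (three-significant-digit rule), with a
    # finite objective; the nlminb status line is recorded but a "false
    # convergence" report on an already-stationary point is not treated
    # as failure.
    if (r > 1L && is.finite(opt$objective) && opt$objective < LARGE_OBJ &&
        rel_change < ctl$rel_change_tol) {
      converged <- TRUE
      break
    }
  }
  list(theta = theta, objective = opt$objective, converged = converged,
       message = msg, n_evaluations = obj$state$n_eval)
}
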