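# Fast scalar-parameter two-compartment prediction used inside the
# estimation loops (no S3 dispatch); falls back to the ODE path only for
# the degenerate equal-eigenvalue case.
cp_fast <- function(cl, q, v1, v2, dose, times, dur = 0) {
  k10 <- cl / v1
  if (q <= 0) {
    C <- dose / v1
    lam <- k10
    if (dur > 0) {
      tin <- pmin(times, dur)
      return(C / (lam * dur) * (1 - exp(-lam * tin)) *
               exp(-lam * pmax(times - dur, 0)))
    }
    return(C * exp(-lam * times))
  }
  k12 <- q / v1
  k21 <- q / v2
  s <- k10 + k12 + k21
  disc <- s * s - 4 * k10 * k21
  if (disc < 0) disc <- 0
  rt <- sqrt(disc)
  alpha <- (s + rt) / 2
  beta <- (s - rt) / 2
  if (alpha - beta < 1e-8 * alpha)
    return(predict_cp(pk_pars(cl, q, v1, v2), dose, times, dur))
  C1 <- dose * (alpha - k21) / (v1 * (alpha - beta))
  C2 <- dose * (k21 - beta) / (v1 * (alpha - beta))
  if (dur > 0) {
    tin <- pmin(times, dur)
    tpost <- pmax(times - dur, 0)
    return(C1 / (alpha * dur) * (1 - exp(-alpha * tin)) * exp(-alpha * tpost) +
             C2 / (beta * dur) * (1 - exp(-beta * tin)) * exp(-beta * tpost))
  }
  C1 * exp(-alpha * times) + C2 * exp(-beta * times)
}

# Crude noncompartmental starting values from pooled data, standardized to
# 70 kg, optionally refined by a naive-pooled nonlinear least-squares fit on
# the log scale.
pk_auto_start <- function(subs, n_compartments, std_weight) {
  cl_i <- v1_i <- numeric(0)
  for (s in subs) {
    if (length(s$times) < 2) next
    cmax <- max(s$y)
    auc <- sum(diff(s$times) * (utils::head(s$y, -1) + utils::tail(s$y, -1)) / 2)
    ntail <- min(3L, length(s$times))
    tl <- utils::tail(s$times, ntail)
    yl <- utils::tail(s$y, ntail)
    sl <- tryCatch(-stats::coef(stats::lm(log(pmax(yl, 1e-9)) ~ tl))[[2]],
                   error = function(e) NA_real_)
    if (is.finite(sl) && sl > 0) auc <- auc + utils::tail(yl, 1) / sl
    fw <- s$weight / std_weight
    v1_i <- c(v1_i, (s$dose / cmax) / fw)
    cl_i <- c(cl_i, (s$dose / auc) / fw^0.75)
  }
  cl0 <- exp(mean(log(cl_i)))
  v10 <- exp(mean(log(v1_i)))
  start <- list(cl = cl0, q = if (n_compartments == 2) cl0 else 0,
                v1 = 0.7 * v10, v2 = if (n_compartments == 2) 2 * v10 else NA)
  # naive-pooled refinement (log-scale residuals)
  tt <- unlist(lapply(subs, `[[`, "times"))
  yy <- unlist(lapply(subs, `[[`, "y"))
  dose <- rep(vapply(subs, `[[`, 0, "dose"), vapply(subs, function(s) length(s$times), 0L))
  fw <- rep(vapply(subs, `[[`, 0, "weight"), vapply(subs, function(s) length(s$times), 0L)) / std_weight
  dur <- rep(vapply(subs, `[[`, 0, "infusion_duration"),
             vapply(subs, function(s) length(s$times), 0L))
  pool_pred <- function(lcl, lq, lv1, lv2) {
    out <- numeric(length(tt))
    for (i in seq_along(tt))
      out[i] <- cp_fast(exp(lcl) * fw[i]^0.75,
                        if (n_compartments == 2) exp(lq) * fw[i]^0.75 else 0,
                        exp(lv1) * fw[i],
                        if (n_compartments == 2) exp(lv2) * fw[i] else 1,
                        dose[i], tt[i], dur[i])
    log(pmax(out, 1e-12))
  }
  ref <- tryCatch({
    if (n_compartments == 2) {
      f <- minpack.lm::nlsLM(
        log(yy) ~ pool_pred(lcl, lq, lv1, lv2),
        start = list(lcl = log(start$cl), lq = log(start$q),
                     lv1 = log(start$v1), lv2 = log(start$v2)),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      f <- minpack.lm::nlsLM(
        log(yy) ~ pool_pred(lcl, 0, lv1, 0),
        start = list(lcl = log(start$cl), lv1 = log(start$v1)),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
    as.list(exp(stats::coef(f)))
  }, error = function(e) NULL)
  if (!is.null(ref)) {
    start$cl <- ref$lcl
    start$v1 <- ref$lv1
    if (n_compartments == 2) {
      start$q <- ref$lq
      start$v2 <- ref$lv2
    }
  }
  start
}

#' Fit the population pharmacokinetic model
#'
#' Estimates standardized two-compartment (or one-compartment) disposition
#' parameters from the plasma-concentration channel of an analysis dataset
#' by approximate marginal maximum likelihood. Between-subject variability
#' is log-normal (diagonal), residual error combines additive and
#' proportional components, and the marginal likelihood is approximated by
#' the Laplace method with a Gauss-Newton curvature term (see the package
#' vignette). All positive parameters are estimated on the log scale;
#' allometric exponents (0.75 clearances, 1 volumes) are fixed constants.
#'
#' @param data analysis dataset (data.frame as from [simulate_cohort()] or
#'   [read_pkpd_data()]); only the concentration channel (`DVID == 1`) is
#'   used.
#' @param start optional named list of starting values on the natural scale
#'   (`cl`, `q`, `v1`, `v2`, `om_cl`, ..., `sd_add`, `sd_prop`); anything
#'   missing is filled by a naive-pooled two-stage procedure.
#' @param fixed character vector of parameter names (same naming) held at
#'   their starting values.
#' @param bsv names of structural parameters carrying a random effect
#'   (default all).
#' @param error residual components to estimate: subset of
#'   `c("add", "prop")`.
#' @param n_compartments 1 or 2.
#' @param std_weight allometric reference weight, kg.
#' @param control list: outer optimizer settings (`iter.max`, `eval.max`,
#'   `rel_change_tol` relative-change convergence tolerance, default 1e-3,
#'   `max_restarts`) and `se` (logical; compute standard errors, default
#'   TRUE).
#' @return object of class `c("pk_fit", "pkpd_fit")`; see
#'   [summary.pkpd_fit()], [coef.pkpd_fit()], [predict.pkpd_fit()].
#' @export
fit_pk <- function(data, start = NULL, fixed = character(),
                   bsv = c("cl", "q", "v1", "v2"),
                   error = c("add", "prop"),
                   n_compartments = 2, std_weight = 70,
                   control = list()) {
  stopifnot(n_compartments %in% c(1, 2))
  subs_all <- split_subjects(data)
  subs <- lapply(subs_all, function(s) {
    keep <- s$dvid == 1
    s$times <- s$times[keep]
    s$y <- s$y[keep]
    s$dvid <- NULL
    s$fw_cl <- (s$weight / std_weight)^0.75
    s$fw_v <- s$weight / std_weight
    s
  })
  subs <- subs[vapply(subs, function(s) length(s$y) > 0, TRUE)]
  if (!length(subs))
    stop("no concentration observations (DVID == 1) in 'data'",
         call. = FALSE)
  structural <- if (n_compartments == 2) c("cl", "q", "v1", "v2") else
    c("cl", "v1")
  bsv <- intersect(bsv, structural)
  error <- match.arg(error, several.ok = TRUE)

  auto <- pk_auto_start(subs, n_compartments, std_weight)
  defaults <- c(auto,
                stats::setNames(as.list(rep(0.2, length(bsv))),
                                prefix_names("om_", bsv)),
                list(sd_add = max(1e-3, 0.1 * stats::median(
                  unlist(lapply(subs, `[[`, "y")))),
                  sd_prop = 0.15))
  if (!is.null(start)) defaults <- utils::modifyList(defaults, as.list(start))
  st <- defaults

  par_names <- c(structural, prefix_names("om_", bsv),
                 c("sd_add", "sd_prop")[c("add", "prop") %in% error])
  theta_full <- log(unlist(st[par_names]))
  names(theta_full) <- par_names
  free <- setdiff(par_names, fixed)
  lower <- ifelse(grepl("^om_", free), log(1e-4),
                  ifelse(grepl("^sd_", free), log(1e-6), -20))
  upper <- ifelse(grepl("^om_", free), log(4), 20)

  eta_idx <- stats::setNames(seq_along(bsv), bsv)
  unpack <- local({
    force(theta_full); force(free); force(structural); force(bsv)
    function(theta) {
      tf <- theta_full
      tf[free] <- theta
      nat <- as.list(exp(tf[structural]))
      nat$q <- if (n_compartments == 2) nat$q else 0
      nat$v2 <- if (n_compartments == 2) nat$v2 else 1
      nat$omega <- unname(exp(tf[prefix_names("om_", bsv)]))
      nat$sd_add <- if ("sd_add" %in% par_names) exp(tf[["sd_add"]]) else 0
      nat$sd_prop <- if ("sd_prop" %in% par_names) exp(tf[["sd_prop"]]) else 0
      nat
    }
  })
  predict_subject <- function(nat, subj, eta) {
    e <- function(nm) if (!is.na(eta_idx[nm])) exp(eta[eta_idx[[nm]]]) else 1
    cp_fast(nat$cl * subj$fw_cl * e("cl"),
            if (n_compartments == 2) nat$q * subj$fw_cl * e("q") else 0,
            nat$v1 * subj$fw_v * e("v1"),
            if (n_compartments == 2) nat$v2 * subj$fw_v * e("v2") else 1,
            subj$dose, subj$times, subj$infusion_duration)
  }
  sigma_subject <- function(nat, subj, f) {
    sqrt(nat$sd_add^2 + (nat$sd_prop * f)^2)
  }

  obj <- nlme_objective(subs, length(bsv), unpack, predict_subject,
                        sigma_subject)
  fitctl <- control[setdiff(names(control), "se")]
  res <- nlme_outer_fit(obj, theta_full[free], lower, upper, fitctl)
  theta_hat <- theta_full
  theta_hat[free] <- res$theta

  nat <- unpack(res$theta)
  # conditional modes at the optimum
  obj$fn(res$theta)
  ebes <- obj$state$eta
  if (length(bsv)) {
    dimnames(ebes) <- list(vapply(subs, `[[`, 0, "id"), bsv)
  }
  estimates <- c(CL = nat$cl, Q = if (n_compartments == 2) nat$q else NA,
                 V1 = nat$v1, V2 = if (n_compartments == 2) nat$v2 else NA)
  fit <- structure(list(
    estimates = estimates[!is.na(estimates)],
    bsv = stats::setNames(100 * nat$omega, bsv),
    ruv = list(conc = c(add = nat$sd_add, prop = nat$sd_prop)),
    objective = res$objective,
    converged = res$converged,
    message = res$message,
    n_evaluations = res$n_evaluations,
    ebes = ebes,
    theta = theta_hat,
    free = free,
    fixed = fixed,
    n_par = length(free),
    objective_fun = obj$fn,
    unpack = unpack,
    nat = nat,
    predict_subject = predict_subject,
    sigma_subject = sigma_subject,
    subjects = subs,
    data = data,
    bsv_names = bsv,
    error = error,
    n_compartments = n_compartments,
    std_weight = std_weight,
    start = st,
    se = NULL,
    call = match.call()),
    class = c("pk_fit", "pkpd_fit"))
  fit$refit <- function(data2, start2 = as.list(stats::setNames(
    exp(theta_hat), par_names))) {
    fit_pk(data2, start = start2, fixed = fixed, bsv = bsv, error = error,
           n_compartments = n_compartments, std_weight = std_weight,
           control = utils::modifyList(control, list(se = FALSE)))
  }
  if (isTRUE(control$se %||% TRUE))
    fit$se <- tryCatch(standard_errors(fit), error = function(e) NULL)
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a
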