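# Macro constants for the fast paths; degenerate (equal eigenvalue) sets
# are handed back to the robust S3 prediction functions.
macro_fast <- function(cl, q, v1, v2, dose) {
  k10 <- cl / v1
  if (q <= 0)
    return(list(C = dose / v1, lambda = k10, degenerate = FALSE))
  k12 <- q / v1
  k21 <- q / v2
  s <- k10 + k12 + k21
  disc <- max(s * s - 4 * k10 * k21, 0)
  rt <- sqrt(disc)
  alpha <- (s + rt) / 2
  beta <- (s - rt) / 2
  if (alpha - beta < 1e-8 * alpha)
    return(list(C = NA, lambda = NA, degenerate = TRUE,
                pk = pk_pars(cl, q, v1, v2)))
  list(C = dose * c(alpha - k21, k21 - beta) / (v1 * (alpha - beta)),
       lambda = c(alpha, beta), degenerate = FALSE)
}

pd_auto_start <- function(subs, pk_nat, e0, emax, std_weight) {
  # population-PK-driven pooled response fit over a delay half-time grid
  best <- NULL
  for (th in c(0.5, 1, 2, 4, 8)) {
    k <- log(2) / th
    ce <- numeric(0)
    yy <- numeric(0)
    for (s in subs) {
      sel <- !s$is_conc
      if (!any(sel)) next
      mac <- macro_fast(pk_nat$cl * s$fw_cl, pk_nat$q * s$fw_cl,
                        pk_nat$v1 * s$fw_v, pk_nat$v2 * s$fw_v, s$dose)
      if (mac$degenerate) next
      ce <- c(ce, pmax(delayed_exponentials(mac$C, mac$lambda, k,
                                            s$times[sel]), 0))
      yy <- c(yy, s$y[sel])
    }
    fit <- tryCatch({
      f <- minpack.lm::nlsLM(
        yy ~ e0 + emax * ifelse(ce > 0, ce^exp(ln), 0) /
          (exp(lc50)^exp(ln) + ifelse(ce > 0, ce^exp(ln), 1)),
        start = list(lc50 = log(stats::median(ce[ce > 0])), ln = 0),
        control = minpack.lm::nls.lm.control(maxiter = 150))
      list(sse = sum(stats::resid(f)^2), coef = exp(stats::coef(f)),
           t_half = th)
    }, error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$sse < best$sse)) best <- fit
  }
  if (is.null(best))
    return(list(c50 = 20, hill = 1, t_half = 2))
  list(c50 = min(max(unname(best$coef[["lc50"]]), 1e-3), 1e4),
       hill = min(max(unname(best$coef[["ln"]]), 0.1), 10),
       t_half = best$t_half)
}

#' Fit the pharmacodynamic model sequentially after the PK fit
#'
#' Sequential population PK/PD estimation: the population PK parameters
#' (structural, between-subject variability and concentration residual
#' error) are fixed at the values of a converged [fit_pk()] result, while
#' the concentration observations are retained so that the subject-level PK
#' random effects are re-estimated jointly with the pharmacodynamic
#' parameters (the "PPP&D" flavour of sequential fitting). The response is
#' a sigmoid Emax function of a delayed concentration; the delay is either
#' an effect-compartment equilibration (`keo`) or a mediator turnover
#' (`kin`), two mechanisms that share the same first-order dynamics here
#' and are distinguished by interpretation and reporting.
#'
#' By default the baseline `e0` and maximum effect `emax` are fixed at
#' their starting values (readout-specific defaults: 100 s and 899 s for
#' the activated clotting time, 0.4 min and 34 min for the reaction time)
#' and `c50`, the Hill coefficient and the delay half-time are estimated
#' together with their between-subject variabilities and the readout's
#' combined residual error.
#'
#' @param data analysis dataset containing concentration (`DVID == 1`) and
#'   readout observations.
#' @param pk_fit converged `"pk_fit"` object.
#' @param readout `"act"` (`DVID == 2`, seconds) or `"rtime"` (`DVID ==
#'   3`, minutes).
#' @param mechanism delay mechanism label.
#' @param start optional named list on the natural scale (`e0`, `emax`,
#'   `c50`, `hill`, `t_half`, `om_c50`, `om_t_half`, `sd_add`, `sd_prop`).
#' @param fixed parameter names held at starting values (default `e0`,
#'   `emax`).
#' @param bsv PD parameters carrying a random effect (subset of
#'   `c("c50", "t_half")`).
#' @param control as in [fit_pk()].
#' @return object of class `c("pd_fit", "pkpd_fit")`.
#' @export
fit_pd <- function(data, pk_fit, readout = c("act", "rtime"),
                   mechanism = c("effect_compartment", "turnover"),
                   start = NULL, fixed = c("e0", "emax"),
                   bsv = c("c50", "t_half"), control = list()) {
  readout <- match.arg(readout)
  mechanism <- match.arg(mechanism)
  stopifnot(inherits(pk_fit, "pk_fit"))
  if (!isTRUE(pk_fit$converged))
    warning("PK fit is not flagged as converged; PD estimates may be unreliable")
  dvid_pd <- channel_codes[[readout]]
  std_weight <- pk_fit$std_weight
  subs <- lapply(split_subjects(data), function(s) {
    keep <- s$dvid %in% c(1L, dvid_pd)
    s$times <- s$times[keep]
    s$y <- s$y[keep]
    s$is_conc <- s$dvid[keep] == 1L
    s$dvid <- NULL
    s$fw_cl <- (s$weight / std_weight)^0.75
    s$fw_v <- s$weight / std_weight
    s
  })
  subs <- subs[vapply(subs, function(s) any(!s$is_conc), TRUE)]
  if (!length(subs))
    stop(sprintf("no observations for readout '%s' (DVID == %d) in 'data'",
                 readout, dvid_pd), call. = FALSE)

  pk_nat <- list(cl = pk_fit$estimates[["CL"]],
                 q = if (pk_fit$n_compartments == 2)
                   pk_fit$estimates[["Q"]] else 0,
                 v1 = pk_fit$estimates[["V1"]],
                 v2 = if (pk_fit$n_compartments == 2)
                   pk_fit$estimates[["V2"]] else 1)
  omega_pk <- unname(pk_fit$bsv / 100)
  pk_bsv <- pk_fit$bsv_names
  sd_conc <- pk_fit$ruv$conc

  bsv <- intersect(bsv, c("c50", "t_half"))
  e0_default <- if (readout == "act") 100 else 0.4
  emax_default <- if (readout == "act") 899 else 34
  auto <- pd_auto_start(subs, pk_nat, e0_default, emax_default, std_weight)
  defaults <- c(list(e0 = e0_default, emax = emax_default), auto,
                stats::setNames(as.list(rep(0.15, length(bsv))),
                                prefix_names("om_", bsv)),
                list(sd_add = max(1e-3, 0.05 * stats::median(
                  unlist(lapply(subs, function(s) s$y[!s$is_conc])))),
                  sd_prop = 0.1))
  if (!is.null(start)) defaults <- utils::modifyList(defaults, as.list(start))
  st <- defaults

  par_names <- c("e0", "emax", "c50", "hill", "t_half",
                 prefix_names("om_", bsv), "sd_add", "sd_prop")
  theta_full <- log(unlist(st[par_names]))
  names(theta_full) <- par_names
  free <- setdiff(par_names, fixed)
  lower <- ifelse(grepl("^om_", free), log(1e-4),
                  ifelse(grepl("^sd_", free), log(1e-6), -20))
  upper <- ifelse(grepl("^om_", free), log(4), 20)

  q_pk <- length(pk_bsv)
  eta_pk_idx <- stats::setNames(seq_len(q_pk), pk_bsv)
  eta_pd_idx <- stats::setNames(q_pk + seq_along(bsv), bsv)
  n_cmt <- pk_fit$n_compartments

  unpack <- function(theta) {
    tf <- theta_full
    tf[free] <- theta
    nat <- as.list(exp(tf[c("e0", "emax", "c50", "hill", "t_half")]))
    nat$omega <- c(omega_pk, unname(exp(tf[prefix_names("om_", bsv)])))
    nat$sd_add <- exp(tf[["sd_add"]])
    nat$sd_prop <- exp(tf[["sd_prop"]])
    nat
  }
  predict_subject <- function(nat, subj, eta) {
    epk <- function(nm) if (!is.na(eta_pk_idx[nm]))
      exp(eta[eta_pk_idx[[nm]]]) else 1
    cl <- pk_nat$cl * subj$fw_cl * epk("cl")
    q <- if (n_cmt == 2) pk_nat$q * subj$fw_cl * epk("q") else 0
    v1 <- pk_nat$v1 * subj$fw_v * epk("v1")
    v2 <- if (n_cmt == 2) pk_nat$v2 * subj$fw_v * epk("v2") else 1
    mac <- macro_fast(cl, q, v1, v2, subj$dose)
    f <- numeric(length(subj$times))
    ic <- subj$is_conc
    if (mac$degenerate) {
      if (any(ic))
        f[ic] <- predict_cp(mac$pk, subj$dose, subj$times[ic],
                            subj$infusion_duration)
      ce <- predict_effect(mac$pk,
                           pd_pars(nat$e0, nat$emax, nat$c50, nat$hill,
                                   nat$t_half, mechanism),
                           subj$dose, subj$times[!ic],
                           subj$infusion_duration)$ce
    } else {
      if (any(ic))
        f[ic] <- drop(exp(-outer(subj$times[ic], mac$lambda)) %*% mac$C)
      kdel <- log(2) / nat$t_half
      epd <- function(nm) if (!is.na(eta_pd_idx[nm]))
        exp(eta[eta_pd_idx[[nm]]]) else 1
      kdel <- kdel / epd("t_half")   # eta on the half-time
      ce <- pmax(delayed_exponentials(mac$C, mac$lambda, kdel,
                                      subj$times[!ic]), 0)
      c50 <- nat$c50 * epd("c50")
      cn <- ce^nat$hill
      f[!ic] <- nat$e0 + nat$emax * cn / (c50^nat$hill + cn)
      return(f)
    }
    # degenerate path: sigmoid on the ODE-based delayed concentration
    epd <- function(nm) if (!is.na(eta_pd_idx[nm]))
      exp(eta[eta_pd_idx[[nm]]]) else 1
    c50 <- nat$c50 * epd("c50")
    cn <- pmax(ce, 0)^nat$hill
    f[!ic] <- nat$e0 + nat$emax * cn / (c50^nat$hill + cn)
    f
  }
  sigma_subject <- function(nat, subj, f) {
    sd <- numeric(length(f))
    ic <- subj$is_conc
    sd[ic] <- sqrt(sd_conc[["add"]]^2 + (sd_conc[["prop"]] * f[ic])^2)
    sd[!ic] <- sqrt(nat$sd_add^2 + (nat$sd_prop * f[!ic])^2)
    sd
  }

  obj <- nlme_objective(subs, q_pk + length(bsv), unpack, predict_subject,
                        sigma_subject)
  fitctl <- control[setdiff(names(control), "se")]
  res <- nlme_outer_fit(obj, theta_full[free], lower, upper, fitctl)
  theta_hat <- theta_full
  theta_hat[free] <- res$theta
  nat <- unpack(res$theta)
  obj$fn(res$theta)
  ebes <- obj$state$eta
  dimnames(ebes) <- list(vapply(subs, `[[`, 0, "id"),
                         c(prefix_names("pk.", pk_bsv),
                           if (length(bsv)) paste0("pd.", bsv)))

  c50_lab <- if (mechanism == "effect_compartment") "Ce50" else "Cp50"
  th_lab <- if (mechanism == "effect_compartment") "T1/2keo" else "TNOVER"
  estimates <- c(nat$c50, N = nat$hill, nat$t_half,
                 keo = log(2) / nat$t_half)
  names(estimates)[c(1, 3)] <- c(c50_lab, th_lab)
  names(estimates)[4] <- if (mechanism == "effect_compartment") "keo" else "kin"

  fit <- structure(list(
    estimates = estimates,
    e0 = nat$e0, emax = nat$emax,
    bsv = stats::setNames(100 * nat$omega[q_pk + seq_along(bsv)], bsv),
    ruv = stats::setNames(list(c(add = nat$sd_add, prop = nat$sd_prop)),
                          readout),
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
    readout = readout,
    mechanism = mechanism,
    pk_fit = pk_fit,
    std_weight = std_weight,
    start = st,
    se = NULL,
    call = match.call()),
    class = c("pd_fit", "pkpd_fit"))
  fit$refit <- function(data2, start2 = as.list(stats::setNames(
    exp(theta_hat), par_names))) {
    fit_pd(data2, pk_fit, readout = readout, mechanism = mechanism,
           start = start2, fixed = fixed, bsv = bsv,
           control = utils::modifyList(control, list(se = FALSE)))
  }
  if (isTRUE(control$se %||% TRUE))
    fit$se <- tryCatch(standard_errors(fit), error = function(e) NULL)
  fit
}
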