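#' @export
print.pkpd_fit <- function(x, digits = 4, ...) {
  kind <- if (inherits(x, "pk_fit")) "Population PK fit" else
    sprintf("Sequential PD fit (%s, %s)", x$readout,
            gsub("_", " ", x$mechanism))
  cat(kind, "\n")
  cat("Estimates (standardized scale):\n")
  print(signif(x$estimates, digits))
  if (length(x$bsv)) {
    cat("Between-subject variability (CV%):\n")
    print(signif(x$bsv, digits))
  }
  for (ch in names(x$ruv)) {
    cat(sprintf("Residual error (%s): additive %.4g, proportional %.4g\n",
                ch, x$ruv[[ch]][["add"]], x$ruv[[ch]][["prop"]]))
  }
  cat(sprintf("Objective (-2LL): %.3f  converged: %s  evaluations: %d\n",
              x$objective, x$converged, x$n_evaluations))
  invisible(x)
}

#' Summarize a fitted model
#'
#' @param object a `"pkpd_fit"`.
#' @param ... unused.
#' @return list of class `"summary.pkpd_fit"` with the estimate table
#'   (including SE\% and 95\% confidence limits when available),
#'   variability estimates and fit metadata.
#' @export
summary.pkpd_fit <- function(object, ...) {
  se <- object$se
  if (is.null(se))
    se <- tryCatch(standard_errors(object), error = function(e) NULL)
  structure(list(fit = object, se_table = se), class = "summary.pkpd_fit")
}

#' @export
print.summary.pkpd_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$se_table)) {
    cat("\nUncertainty (", attr(x$se_table, "method"), "):\n", sep = "")
    tab <- x$se_table
    tab[-1] <- lapply(tab[-1], signif, 4)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.pkpd_fit <- function(object, ...) object$estimates

#' @export
logLik.pkpd_fit <- function(object, ...) {
  structure(-object$objective / 2, df = object$n_par,
            nobs = sum(vapply(object$subjects,
                              function(s) length(s$y), 0L)),
            class = "logLik")
}

#' @export
vcov.pkpd_fit <- function(object, ...) {
  H <- pracma::hessian(object$objective_fun, object$theta[object$free])
  H <- (H + t(H)) / 2
  V <- 2 * solve(H)
  dimnames(V) <- list(object$free, object$free)
  V
}

#' @export
confint.pkpd_fit <- function(object, parm, level = 0.95, ...) {
  se <- object$se %||% standard_errors(object)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- se$estimate * exp(-z * se$se_pct / 100)
  hi <- se$estimate * exp(z * se$se_pct / 100)
  out <- cbind(lo, hi)
  dimnames(out) <- list(se$parameter,
                        sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                   1 - (1 - level) / 2)))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

# Internal: per-subject predictions at EBE ("individual") or eta = 0
# ("population"), optionally at new times.
fit_predictions <- function(object, type = "individual", times = NULL) {
  q <- ncol(object$ebes)
  out <- lapply(seq_along(object$subjects), function(i) {
    subj <- object$subjects[[i]]
    if (!is.null(times)) {
      subj$times <- times
      subj$y <- rep(NA_real_, length(times))
      if (!is.null(subj$is_conc))
        subj$is_conc <- rep(FALSE, length(times))
    }
    eta <- if (type == "individual" && q > 0) object$ebes[i, ] else
      numeric(q)
    f <- object$predict_subject(object$nat, subj, eta)
    data.frame(id = subj$id, time = subj$times,
               channel = if (is.null(subj$is_conc)) "conc" else
                 ifelse(subj$is_conc, "conc", object$readout),
               pred = f)
  })
  do.call(rbind, out)
}

#' Model predictions
#'
#' @param object a `"pkpd_fit"`.
#' @param type `"individual"` (empirical Bayes estimates) or
#'   `"population"` (random effects at zero).
#' @param times optional numeric vector of prediction times (minutes); the
#'   default predicts at the fitted observation times. For a PD fit, new
#'   times are predicted on the readout channel.
#' @param ... unused.
#' @return data.frame with `id`, `time`, `channel`, `pred`.
#' @export
predict.pkpd_fit <- function(object, type = c("individual", "population"),
                             times = NULL, ...) {
  type <- match.arg(type)
  fit_predictions(object, type, times)
}

#' Residuals of a fitted model
#'
#' @param object a `"pkpd_fit"`.
#' @param type `"weighted"` (residual divided by its modeled SD) or
#'   `"raw"`.
#' @param level `"individual"` (at empirical Bayes estimates) or
#'   `"population"`.
#' @param ... unused.
#' @return data.frame with `id`, `time`, `channel`, `observed`, `pred`,
#'   `residual`.
#' @export
residuals.pkpd_fit <- function(object, type = c("weighted", "raw"),
                               level = c("individual", "population"), ...) {
  type <- match.arg(type)
  level <- match.arg(level)
  pr <- fit_predictions(object, level)
  obs <- unlist(lapply(object$subjects, `[[`, "y"))
  r <- obs - pr$pred
  if (type == "weighted") {
    sd <- unlist(lapply(seq_along(object$subjects), function(i) {
      subj <- object$subjects[[i]]
      idx <- pr$id == subj$id
      object$sigma_subject(object$nat, subj, pr$pred[idx])
    }))
    r <- r / sd
  }
  cbind(pr[c("id", "time", "channel")],
        data.frame(observed = obs, pred = pr$pred, residual = r))
}

# Rebuild a generative cohort ("truth" = the fitted values) on the fit's
# own design; used by simulate() and the visual predictive check.
fit_cohort <- function(object) {
  d <- object$data
  dose_rows <- d[d$EVID == 1, ]
  subjects <- data.frame(id = dose_rows$ID, weight = dose_rows$WT,
                         dose = dose_rows$AMT)
  times <- sort(unique(d$TIME[d$EVID == 0]))
  if (!0 %in% times) times <- c(0, times)
  dur <- if (any(dose_rows$RATE > 0, na.rm = TRUE))
    dose_rows$AMT[1] / dose_rows$RATE[1] else 0
  if (inherits(object, "pk_fit")) {
    pkf <- object
    pd <- list()
    bsv <- list(pk = pkf$bsv)
    ruv <- pkf$ruv
  } else {
    pkf <- object$pk_fit
    pdp <- pd_pars(object$e0, object$emax,
                   object$estimates[[1]], object$estimates[["N"]],
                   object$estimates[[3]], object$mechanism)
    pd <- stats::setNames(list(pdp), object$readout)
    bsv <- list(pk = pkf$bsv)
    bsv[[object$readout]] <- object$bsv
    ruv <- c(pkf$ruv, object$ruv)
  }
  pk <- pk_pars(pkf$estimates[["CL"]],
                if (pkf$n_compartments == 2) pkf$estimates[["Q"]] else 0,
                pkf$estimates[["V1"]],
                if (pkf$n_compartments == 2) pkf$estimates[["V2"]] else NA)
  design <- study_design(n_subjects = nrow(subjects),
                         weight_range = range(subjects$weight),
                         dose_per_kg = mean(subjects$dose / subjects$weight),
                         times = times, infusion_duration = dur)
  structure(list(subjects = subjects, design = design,
                 truths = list(pk = pk, pd = pd, bsv = bsv, ruv = ruv),
                 seed = NULL),
            class = "study_cohort")
}

#' Simulate datasets from a fitted model
#'
#' Simulates complete replicate datasets at the fit's own design (same
#' subjects, weights, doses and nominal times), drawing new subject-level
#' random effects and residual errors from the fitted variability model.
#' For a PD fit both the concentration channel (from the underlying PK
#' fit) and the readout channel are simulated.
#'
#' @param object a `"pkpd_fit"`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `nsim` datasets in the analysis layout.
#' @export
simulate.pkpd_fit <- function(object, nsim = 1, seed = 1L, ...) {
  cohort <- fit_cohort(object)
  channels <- if (inherits(object, "pk_fit")) "conc" else
    c("conc", object$readout)
  lapply(seq_len(nsim), function(k) {
    simulate_cohort(cohort, channels = channels,
                    seed = derive_seed(seed, 7919 * k))
  })
}

#' Diagnostic plot for a fitted model
#'
#' Two panels: observations against individual predictions (unity line),
#' and weighted residuals against time.
#'
#' @param x a `"pkpd_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pkpd_fit <- function(x, ...) {
  r <- residuals.pkpd_fit(x, type = "weighted", level = "individual")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(r$pred, r$observed, xlab = "Individual prediction",
                 ylab = "Observation", main = "Observed vs predicted", ...)
  graphics::abline(0, 1, col = "grey50")
  graphics::plot(r$time, r$residual, xlab = "Time (min)",
                 ylab = "Weighted residual", main = "Residuals vs time", ...)
  graphics::abline(h = 0, col = "grey50")
  invisible(x)
}
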