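channel_units <- c(conc = "mg/L", act = "s", rtime = "min")

# Population (eta = 0) prediction for given subjects/times on one channel,
# from the generative model implied by a fit.
population_prediction <- function(cohort, ids, times, channel) {
  tr <- cohort$truths
  sub <- cohort$subjects
  out <- numeric(length(ids))
  for (i in seq_len(nrow(sub))) {
    sel <- ids == sub$id[i]
    if (!any(sel)) next
    pk_i <- individualize(tr$pk, sub$weight[i])
    if (channel == "conc") {
      out[sel] <- predict_cp(pk_i, sub$dose[i], times[sel],
                             cohort$design$infusion_duration)
    } else {
      out[sel] <- predict_effect(pk_i, tr$pd[[channel]], sub$dose[i],
                                 times[sel],
                                 cohort$design$infusion_duration)$effect
    }
  }
  out
}

#' Prediction-corrected visual predictive check
#'
#' Simulates replicate datasets from the fitted model at the original
#' design and compares observed percentiles (10th, 50th, 90th by default)
#' with the simulation-based distribution of the same percentiles.
#' Prediction correction rescales each observed and simulated value by
#' `median(PRED in bin) / PRED_ij`, where `PRED` is the population
#' prediction, removing between-subject differences in dose and weight
#' before binning. Bins are the nominal sampling times (the design is
#' balanced). The confidence band on each simulated percentile is the
#' 2.5th-97.5th percentile range across replicates.
#'
#' @param data the observed analysis dataset.
#' @param fit a converged `"pkpd_fit"`; for `channel = "conc"` a PK fit,
#'   for a readout channel a PD fit of that readout.
#' @param channel `"conc"`, `"act"` or `"rtime"`.
#' @param n_sim number of replicate simulations (>= 100).
#' @param seed integer seed for the simulations.
#' @param probs percentiles to track.
#' @param prediction_corrected apply prediction correction (default TRUE).
#' @return object of class `"vpc"`: list with `bins`, `observed` (matrix
#'   bins x percentiles), `pred_median`, `band_lower`, `band_upper`
#'   (same shape), the prediction-corrected observation points, and
#'   metadata.
#' @export
run_vpc <- function(data, fit, channel = c("conc", "act", "rtime"),
                    n_sim = 500, seed = 1L, probs = c(0.1, 0.5, 0.9),
                    prediction_corrected = TRUE) {
  channel <- match.arg(channel)
  stopifnot(inherits(fit, "pkpd_fit"))
  if (n_sim < 100) stop("'n_sim' must be at least 100", call. = FALSE)
  code <- channel_codes[[channel]]
  obs <- data[data$EVID == 0 & data$DVID == code, ]
  if (!nrow(obs))
    stop(sprintf("channel '%s' (DVID == %d) absent from 'data'",
                 channel, code), call. = FALSE)
  if (inherits(fit, "pd_fit") && channel != "conc" &&
      channel != fit$readout)
    stop("PD fit readout does not match requested channel", call. = FALSE)
  cohort <- fit_cohort(fit)
  bins <- sort(unique(obs$TIME))
  pred <- population_prediction(cohort, obs$ID, obs$TIME, channel)
  med_pred <- tapply(pred, match(obs$TIME, bins), stats::median)
  pc_fac <- if (prediction_corrected)
    as.numeric(med_pred[match(obs$TIME, bins)]) / pred else 1
  pc_obs <- obs$DV * pc_fac
  pctl <- function(v, tm) t(vapply(bins, function(b)
    stats::quantile(v[tm == b], probs, names = FALSE, type = 7),
    numeric(length(probs))))
  observed <- pctl(pc_obs, obs$TIME)

  sims <- simulate(fit, nsim = n_sim, seed = seed)
  sim_pct <- array(NA_real_, c(n_sim, length(bins), length(probs)))
  for (k in seq_len(n_sim)) {
    sd_k <- sims[[k]]
    sk <- sd_k[sd_k$EVID == 0 & sd_k$DVID == code, ]
    predk <- population_prediction(cohort, sk$ID, sk$TIME, channel)
    med_k <- tapply(predk, match(sk$TIME, bins), stats::median)
    fac <- if (prediction_corrected)
      as.numeric(med_k[match(sk$TIME, bins)]) / predk else 1
    sim_pct[k, , ] <- pctl(sk$DV * fac, sk$TIME)
  }
  pred_median <- apply(sim_pct, c(2, 3), stats::median)
  band_lower <- apply(sim_pct, c(2, 3), stats::quantile, probs = 0.025)
  band_upper <- apply(sim_pct, c(2, 3), stats::quantile, probs = 0.975)
  cn <- paste0("p", 100 * probs)
  dimnames(observed) <- dimnames(pred_median) <-
    dimnames(band_lower) <- dimnames(band_upper) <- list(bins, cn)
  structure(list(channel = channel, bins = bins, probs = probs,
                 observed = observed, pred_median = pred_median,
                 band_lower = band_lower, band_upper = band_upper,
                 points = data.frame(time = obs$TIME, value = pc_obs),
                 n_sim = n_sim, seed = seed,
                 prediction_corrected = prediction_corrected),
            class = "vpc")
}

#' @export
print.vpc <- function(x, ...) {
  cat(sprintf("%s check, channel %s (%s): %d bins, %d simulations\n",
              if (x$prediction_corrected) "Prediction-corrected VPC"
              else "VPC",
              x$channel, channel_units[[x$channel]], length(x$bins),
              x$n_sim))
  print(vpc_table(x), row.names = FALSE)
  invisible(x)
}

#' Export a VPC as a table
#'
#' @param x a `"vpc"` object.
#' @return data.frame with one row per bin x percentile: observed value,
#'   simulated median and 95\% confidence limits.
#' @export
vpc_table <- function(x) {
  stopifnot(inherits(x, "vpc"))
  cn <- colnames(x$observed)
  do.call(rbind, lapply(seq_along(cn), function(j) {
    data.frame(time = x$bins, percentile = cn[j],
               observed = x$observed[, j],
               sim_median = x$pred_median[, j],
               sim_lower = x$band_lower[, j],
               sim_upper = x$band_upper[, j],
               row.names = NULL)
  }))
}

#' Plot a visual predictive check
#'
#' Two panels: left, the (prediction-corrected) observations with their
#' percentile lines; right, observed percentiles (lines with symbols)
#' against the simulated percentile medians (lines) and their 95\%
#' confidence bands (shaded). Band shading requires at least 100
#' simulations.
#'
#' @param x a `"vpc"` object.
#' @param file optional output path; `.pdf` or `.png` decides the device.
#'   NULL plots on the current device.
#' @param ... unused.
#' @export
plot.vpc <- function(x, file = NULL, ...) {
  if (!length(x$bins)) stop("empty VPC result", call. = FALSE)
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           pdf = grDevices::pdf(file, width = 9, height = 4.5),
           png = grDevices::png(file, width = 1350, height = 675,
                                res = 150),
           stop("unsupported figure format: ", ext, call. = FALSE))
    on.exit(grDevices::dev.off())
  }
  ylab <- sprintf("%s (%s)%s", x$channel, channel_units[[x$channel]],
                  if (x$prediction_corrected) ", prediction-corrected"
                  else "")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  # restore par() before any file device is closed, or the restore itself
  # would open a stray default device
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  ylim <- range(x$points$value, x$band_lower, x$band_upper, na.rm = TRUE)
  graphics::plot(x$points$time, x$points$value, pch = 1, col = "grey40",
                 xlab = "Time (min)", ylab = ylab, ylim = ylim,
                 main = "Observations")
  for (j in seq_along(x$probs))
    graphics::lines(x$bins, x$observed[, j],
                    lty = if (x$probs[j] == 0.5) 1 else 2, lwd = 2)
  graphics::plot(NA, xlim = range(x$bins), ylim = ylim,
                 xlab = "Time (min)", ylab = ylab,
                 main = "Percentiles and prediction bands")
  if (x$n_sim >= 100) {
    for (j in seq_along(x$probs))
      graphics::polygon(c(x$bins, rev(x$bins)),
                        c(x$band_lower[, j], rev(x$band_upper[, j])),
                        col = grDevices::adjustcolor("steelblue", 0.3),
                        border = NA)
  }
  for (j in seq_along(x$probs)) {
    lty <- if (x$probs[j] == 0.5) 1 else 2
    graphics::lines(x$bins, x$pred_median[, j], col = "steelblue",
                    lty = lty, lwd = 2)
    graphics::lines(x$bins, x$observed[, j], lty = lty)
    graphics::points(x$bins, x$observed[, j], pch = 16)
  }
  invisible(x)
}
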