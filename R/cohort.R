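# Distinct sub-stream seeds derived from one user seed, kept inside the
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards; seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Study design for a single-dose cohort
#'
#' The default reproduces the single-dose anticoagulation study layout: 10
#' animals of 4-4.5 kg, one 15 mg/kg intravenous bolus, sampling at baseline
#' and 5, 15, 30, 60, 120, 180, 300 and 420 min, with three observation
#' channels (plasma concentration, activated clotting time, reaction time).
#'
#' @param n_subjects number of subjects.
#' @param weight_range kg, weights drawn uniformly on this interval.
#' @param dose_per_kg mg/kg.
#' @param times sampling times in minutes, baseline 0 first.
#' @param infusion_duration minutes; 0 models the brief manual injection as
#'   a bolus.
#' @return list of class `"study_design"`.
#' @export
study_design <- function(n_subjects = 10, weight_range = c(4, 4.5),
                         dose_per_kg = 15,
                         times = c(0, 5, 15, 30, 60, 120, 180, 300, 420),
                         infusion_duration = 0) {
  stopifnot(n_subjects >= 1, length(weight_range) == 2,
            all(weight_range > 0), dose_per_kg >= 0,
            all(times >= 0), !is.unsorted(times, strictly = TRUE))
  structure(list(n_subjects = n_subjects, weight_range = weight_range,
                 dose_per_kg = dose_per_kg, times = times,
                 infusion_duration = infusion_duration),
            class = "study_design")
}

#' Synthetic study cohort
#'
#' Couples a sampling design, generating ("truth") parameter values and a
#' seed into a reproducible cohort: subject weights are drawn uniformly on
#' the design's weight range and per-kg doses converted to absolute amounts.
#'
#' @param design `"study_design"`; default [study_design()].
#' @param truths generating values as returned by [default_truths()].
#' @param seed integer seed governing weights and, by default, simulation.
#' @return list of class `"study_cohort"` with elements `subjects`
#'   (data.frame `id`, `weight`, `dose`), `design`, `truths`, `seed`.
#' @export
default_cohort <- function(design = study_design(),
                           truths = default_truths(),
                           seed = 1L) {
  wts <- with_seed(seed, stats::runif(design$n_subjects,
                                      design$weight_range[1],
                                      design$weight_range[2]))
  subjects <- data.frame(id = seq_len(design$n_subjects),
                         weight = wts,
                         dose = dose_total(wts, design$dose_per_kg))
  structure(list(subjects = subjects, design = design, truths = truths,
                 seed = seed),
            class = "study_cohort")
}

#' @export
print.study_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %.3g-%.3g kg, %g mg/kg IV, %d sampling times (seed %d)\n",
              nrow(x$subjects), min(x$subjects$weight), max(x$subjects$weight),
              x$design$dose_per_kg, length(x$design$times), x$seed))
  invisible(x)
}

#' Draw individual parameters for a cohort
#'
#' Applies allometric scaling to the standardized truths and multiplies by
#' log-normal subject effects \eqn{\exp(\eta)}, \eqn{\eta \sim N(0,
#' \omega^2)} with \eqn{\omega = CV\%/100} on the log scale. Parameters
#' without a listed CV get \eqn{\eta = 0}. The exponential transform keeps
#' every sampled parameter strictly positive.
#'
#' @param cohort `"study_cohort"`.
#' @param seed integer seed (default the cohort's).
#' @return list with `eta` (named matrix, one row per subject), `pk` (list
#'   of individual `"pk_pars"`), `pd` (list per readout of lists of
#'   individual `"pd_pars"`).
#' @export
draw_individual_parameters <- function(cohort, seed = cohort$seed) {
  stopifnot(inherits(cohort, "study_cohort"))
  tr <- cohort$truths
  n <- nrow(cohort$subjects)
  readouts <- names(tr$pd)
  nm <- c(prefix_names("pk.", names(tr$bsv$pk)),
          unlist(lapply(readouts, function(rd)
            prefix_names(paste0(rd, "."), names(tr$bsv[[rd]])))))
  om <- c(tr$bsv$pk, unlist(unname(tr$bsv[readouts]))) / 100
  eta <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, 271828), {
    matrix(stats::rnorm(n * length(om), 0, rep(om, each = n)),
           nrow = n, dimnames = list(NULL, nm))
  })
  pk <- lapply(seq_len(n), function(i) {
    e <- eta[i, prefix_names("pk.", names(tr$bsv$pk))]
    names(e) <- names(tr$bsv$pk)
    individualize(tr$pk, cohort$subjects$weight[i], e)
  })
  pd <- lapply(readouts, function(rd) {
    lapply(seq_len(n), function(i) {
      p <- tr$pd[[rd]]
      e <- eta[i, prefix_names(paste0(rd, "."), names(tr$bsv[[rd]]))]
      names(e) <- names(tr$bsv[[rd]])
      mult <- function(nmp) if (nmp %in% names(e)) exp(e[[nmp]]) else 1
      pd_pars(p$e0, p$emax, p$c50 * mult("c50"), p$hill,
              p$t_half_delay * mult("t_half"), p$mechanism)
    })
  })
  names(pd) <- readouts
  list(eta = eta, pk = pk, pd = pd)
}

channel_codes <- c(conc = 1L, act = 2L, rtime = 3L)

#' Simulate an observed dataset from a cohort
#'
#' Generates noise-free trajectories from the structural model at the
#' cohort's design, then adds combined residual error
#' \eqn{y = f (1 + \epsilon_{prop}) + \epsilon_{add}} with independent
#' normal errors per observation and channel. Concentration is observed at
#' the post-dose times only (the pre-dose concentration is zero and not
#' emitted); both coagulation readouts include a baseline observation at
#' time 0. Non-positive draws are redrawn up to `max_redraw` times and then
#' clipped to `floor`.
#'
#' @param cohort `"study_cohort"`.
#' @param channels subset of `c("conc", "act", "rtime")` to simulate.
#' @param seed integer seed (default the cohort's seed); the same seed
#'   reproduces the dataset exactly.
#' @param max_redraw redraw attempts for non-positive values.
#' @param floor positive clipping floor after exhausted redraws.
#' @return data.frame in the analysis dataset layout (see
#'   [read_pkpd_data()]): columns `ID`, `TIME`, `EVID`, `AMT`, `RATE`,
#'   `DV`, `DVID`, `MDV`, `WT`.
#' @export
simulate_cohort <- function(cohort, channels = c("conc", "act", "rtime"),
                            seed = cohort$seed, max_redraw = 100,
                            floor = 1e-3) {
  stopifnot(inherits(cohort, "study_cohort"))
  channels <- match.arg(channels, several.ok = TRUE)
  pars <- draw_individual_parameters(cohort, seed = seed)
  des <- cohort$design
  tobs <- des$times[des$times > 0]
  rows <- list()
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, 3141593), {
    for (i in seq_len(nrow(cohort$subjects))) {
      sub <- cohort$subjects[i, ]
      rows[[length(rows) + 1L]] <- data.frame(
        ID = sub$id, TIME = 0, EVID = 1L, AMT = sub$dose,
        RATE = if (des$infusion_duration > 0)
          sub$dose / des$infusion_duration else 0,
        DV = NA_real_, DVID = 0L, MDV = 1L, WT = sub$weight)
      for (ch in channels) {
        if (ch == "conc") {
          tt <- tobs
          f <- predict_cp(pars$pk[[i]], sub$dose, tt, des$infusion_duration)
        } else {
          tt <- des$times
          f <- predict_effect(pars$pk[[i]], pars$pd[[ch]][[i]], sub$dose,
                              tt, des$infusion_duration)$effect
        }
        if (any(!is.finite(f)))
          stop(sprintf("non-finite prediction for subject %d, channel %s",
                       sub$id, ch), call. = FALSE)
        ruv <- cohort$truths$ruv[[ch]]
        y <- vapply(f, function(fj) {
          for (a in seq_len(max_redraw + 1L)) {
            yj <- fj * (1 + stats::rnorm(1, 0, ruv[["prop"]])) +
              stats::rnorm(1, 0, ruv[["add"]])
            if (yj > 0) return(yj)
          }
          floor
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          ID = sub$id, TIME = tt, EVID = 0L, AMT = NA_real_, RATE = 0,
          DV = y, DVID = channel_codes[[ch]], MDV = 0L, WT = sub$weight)
      }
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$ID, out$TIME, -out$EVID, out$DVID), ]
  rownames(out) <- NULL
  out
}
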