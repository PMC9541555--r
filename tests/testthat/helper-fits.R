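# Synthetic stand-in fit objects carrying the generating (truth) values,
# used to exercise simulation-based diagnostics without the cost of a full
# estimation run. They mimic the structure of fit_pk()/fit_pd() results.
truth_pk_fit <- function(data, tr = default_truths()) {
  structure(list(
    estimates = c(CL = tr$pk$cl, Q = tr$pk$q, V1 = tr$pk$v1,
                  V2 = tr$pk$v2),
    bsv = tr$bsv$pk,
    ruv = list(conc = tr$ruv$conc),
    n_compartments = 2,
    n_par = 10L,
    data = data,
    converged = TRUE),
    class = c("pk_fit", "pkpd_fit"))
}

truth_pd_fit <- function(data, readout = "act", tr = default_truths(),
                         t_half = NULL) {
  p <- tr$pd[[readout]]
  th <- if (is.null(t_half)) p$t_half_delay else t_half
  est <- c(p$c50, N = p$hill, th, log(2) / th)
  names(est)[c(1, 3, 4)] <- c("Ce50", "T1/2keo", "keo")
  structure(list(
    estimates = est,
    e0 = p$e0, emax = p$emax,
    bsv = tr$bsv[[readout]],
    ruv = stats::setNames(list(tr$ruv[[readout]]), readout),
    mechanism = p$mechanism,
    readout = readout,
    pk_fit = truth_pk_fit(data, tr),
    n_par = 7L,
    data = data,
    converged = TRUE),
    class = c("pd_fit", "pkpd_fit"))
}
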