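#' Simulation-based validation of the mutation-rate estimators
#'
#' Repeats the full two-step fluctuation experiment in silico at known
#' ground-truth rates and applies [estimate_rates_from_outcomes()] to
#' every replicate, yielding the sampling distribution of the estimated
#' spontaneous and persister mutation rates.  The estimators are deemed
#' validated when the input rates fall inside the interquartile range of
#' these distributions.
#'
#' @param n_sims number of simulated experiments.
#' @param design an [experiment_design()] (per-experiment well count =
#'   `n_plates * wells_per_plate`).
#' @param params an [mcld_parameters()] carrying the ground-truth
#'   `mu_s`, `mu_p`.
#' @param master_seed integer seed; per-replicate seeds are derived from
#'   it.
#' @return List of class `"estimator_validation"`: `estimates` (data
#'   frame `sim`, `mu_s_hat`, `mu_p_hat`, `fold_hat`, `early`, `late`),
#'   `truth`, `summary` (quartiles per rate), `covered` (logical: truth
#'   inside IQR for both rates).
#' @export
validate_estimators <- function(n_sims, design, params, master_seed = 1L) {
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max, n_sims)
  n_wells <- design$n_plates * design$wells_per_plate
  rows <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    set.seed(seeds[i])
    sim <- sim_wells(n_wells, design, params)
    fit <- estimate_rates_from_outcomes(sim$outcomes, design, params)
    rows[[i]] <- data.frame(
      sim = i,
      mu_s_hat = fit$mu_s$estimate,
      mu_p_hat = fit$mu_p$estimate,
      fold_hat = fit$fold,
      early = fit$counts$early_positives,
      late = fit$counts$late_positives)
  }
  est <- do.call(rbind, rows)
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
  summ <- rbind(mu_s_hat = qs(est$mu_s_hat), mu_p_hat = qs(est$mu_p_hat))
  covered <- params$mu_s >= summ["mu_s_hat", 1] &&
    params$mu_s <= summ["mu_s_hat", 3] &&
    params$mu_p >= summ["mu_p_hat", 1] &&
    params$mu_p <= summ["mu_p_hat", 3]
  structure(list(estimates = est,
                 truth = c(mu_s = params$mu_s, mu_p = params$mu_p),
                 summary = summ, covered = covered),
            class = "estimator_validation")
}

#' @export
print.estimator_validation <- function(x, ...) {
  cat(sprintf("Estimator validation over %d simulated experiments\n",
              nrow(x$estimates)))
  cat(sprintf("  mu_s: truth %.3g, IQR [%.3g, %.3g], median %.3g\n",
              x$truth["mu_s"], x$summary["mu_s_hat", 1],
              x$summary["mu_s_hat", 3], x$summary["mu_s_hat", 2]))
  cat(sprintf("  mu_p: truth %.3g, IQR [%.3g, %.3g], median %.3g\n",
              x$truth["mu_p"], x$summary["mu_p_hat", 1],
              x$summary["mu_p_hat", 3], x$summary["mu_p_hat", 2]))
  cat(sprintf("  truth inside both IQRs: %s\n", x$covered))
  invisible(x)
}
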