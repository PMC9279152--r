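#' Measurement-noise model for viability assays
#'
#' Multiplicative lognormal noise: each reading is the model value times
#' `exp(rnorm(1, 0, sigma_log))`, matching the single log-scale noise
#' term of the fitting likelihood.
#'
#' @param sigma_log standard deviation of log-scale noise (>= 0).
#' @return List of class `"noise_model"`.
#' @export
noise_model <- function(sigma_log = 0.1) {
  if (sigma_log < 0) stop("'sigma_log' must be >= 0", call. = FALSE)
  structure(list(sigma_log = sigma_log), class = "noise_model")
}

#' Synthetic dose-response growth-curve plate
#'
#' Generates raw viability readings for several constant doses over a
#' grid of timepoints with replicate wells: the closed-form TP solution
#' times lognormal measurement noise, including the day-0 reference
#' reading.  A pure function of (parameters, seed).
#'
#' @param tp a [tp_parameters()] ground truth.
#' @param doses drug concentrations (the day-0 reference is included per
#'   dose).
#' @param times timepoints in days (must include 0).
#' @param replicates biological replicates per condition.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param assay label stored in the `assay` column.
#' @return Raw viability data frame (columns `assay`, `time_d`, `conc`,
#'   `replicate`, `viability`) ready for [normalize_growth_curves()].
#' @export
gen_dose_response <- function(tp, doses = c(1, 3, 8, 20, 40),
                              times = c(0, 1, 2, 3, 5, 7, 10, 12),
                              replicates = 3, noise = noise_model(0.1),
                              seed = 1L, assay = "dose_response") {
  stopifnot(inherits(tp, "tp_parameters"), inherits(noise, "noise_model"))
  if (any(doses < 0) || replicates < 1)
    stop("doses must be >= 0 and replicates >= 1", call. = FALSE)
  if (!0 %in% times) times <- c(0, times)
  set.seed(as.integer(seed))
  grid <- expand.grid(time_d = sort(times), conc = doses,
                      replicate = seq_len(replicates))
  pred <- numeric(nrow(grid))
  for (conc in doses) {
    sel <- grid$conc == conc
    tr <- solve_tp(tp, schedule_constant(conc), N_init = 1,
                   t_grid = sort(unique(grid$time_d[sel])))
    pred[sel] <- tr$N[match(grid$time_d[sel], tr$time_d)]
  }
  eps <- stats::rnorm(nrow(grid), 0, noise$sigma_log)
  ## the day-0 reference reading is exact so that fold-changes carry
  ## independent multiplicative noise, matching the fitting likelihood
  eps[grid$time_d == 0] <- 0
  data.frame(assay = assay, time_d = grid$time_d, conc = grid$conc,
             replicate = grid$replicate, viability = pred * exp(eps))
}

#' Synthetic single-dose long-horizon kill curve
#'
#' One constant dose followed over a horizon long enough (>= 22 days)
#' for the biphasic decay -- fast killing of sensitive cells, slow decay
#' of persisters -- to be visible in the tail.
#'
#' @inheritParams gen_dose_response
#' @param dose the single treatment concentration.
#' @return Raw viability data frame as in [gen_dose_response()].
#' @export
gen_single_dose <- function(tp, dose = 5,
                            times = c(0, 2, 4, 7, 10, 14, 18, 22, 26, 30),
                            replicates = 2, noise = noise_model(0.1),
                            seed = 1L) {
  gen_dose_response(tp, doses = dose, times = times,
                    replicates = replicates, noise = noise, seed = seed,
                    assay = "single_dose")
}

#' Synthetic fluctuation-assay outcome table
#'
#' Wraps [simulate_experiment()]: simulates the two-step assay from
#' ground-truth parameters and returns the per-well outcome table.
#'
#' @param design an [experiment_design()].
#' @param params an [mcld_parameters()].
#' @param master_seed integer seed.
#' @return The outcome data frame (see [simulate_experiment()]).
#' @export
gen_fluctuation_outcomes <- function(design, params, master_seed = 1L) {
  simulate_experiment(design, params, master_seed)$outcomes
}

#' Synthetic pre-treatment count series and dead fractions
#'
#' Emulates the two assays used to decompose untreated growth into birth
#' and death rates: viable-cell counts N0 e^{gt} with lognormal counting
#' noise, and dead fractions from the accumulation model of
#' [estimate_death_birth_ratio()] with additive noise truncated to
#' `[0, 0.99]`.
#'
#' @param b,d ground-truth birth and death rates (per day).
#' @param N0 initial viable count.
#' @param times measurement days.
#' @param sigma_count log-scale noise on counts.
#' @param sigma_frac additive noise on dead fractions.
#' @param seed integer seed.
#' @return List with data frames `counts` (`time_d`, `count`) and
#'   `dead_fractions` (`time_d`, `fraction`).
#' @export
gen_pretreatment_counts <- function(b, d, N0 = 3.5e5, times = 0:6,
                                    sigma_count = 0.05,
                                    sigma_frac = 0.01, seed = 1L) {
  if (b <= d || d < 0) stop("need b > d >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  g <- b - d
  counts <- N0 * exp(g * times) *
    exp(stats::rnorm(length(times), 0, sigma_count))
  rho <- (d / g) * (1 - exp(-g * times))
  phi <- rho / (1 + rho)
  frac <- pmin(0.99, pmax(0, phi + stats::rnorm(length(times), 0,
                                                sigma_frac)))
  list(counts = data.frame(time_d = times, count = counts),
       dead_fractions = data.frame(time_d = times, fraction = frac))
}

#' Ground-truth parameter presets
#'
#' Plausible parameter sets for two colorectal-cancer cell-line
#' archetypes, used as defaults throughout examples and tests.  Each
#' preset carries two parameter sets serving different assays:
#'
#' * `$fit`: a [tp_parameters()] ground truth for growth-curve
#'   generation and TP-model fitting, with a drug-effect delay, a
#'   pre-delay growth phase, and a persister plateau large enough to be
#'   resolved over a 30-day single-dose assay.
#' * `$assay`: an [mcld_parameters()] set for the fluctuation
#'   experiment, with no drug-effect delay (treatment-time origin at the
#'   drug effect), a persister plateau of ~1.5% of the treated
#'   population, slow persister decay, and mutation rates
#'   `mu_s = 2e-6`, `mu_p = 2e-5` per cell per day (10-fold increase).
#' * `$dose`: the treatment concentration of the assay.
#'
#' Magnitudes (net growth ~0.35-0.5/day, persister death ~0.01-0.03/day)
#' are documentation-level choices, not measured values.
#'
#' @param name `"widr"` or `"difi"`.
#' @return List with components `fit`, `assay`, `dose`.
#' @examples
#' p <- preset_parameters("widr")
#' p$fit
#' @export
preset_parameters <- function(name = c("widr", "difi")) {
  name <- match.arg(name)
  if (name == "widr") {
    fit <- tp_parameters(B = 0.5, D0 = 0, k0 = 0.91, a = 0.5, t0 = 1.5,
                         S0 = 0.3, lambda_variant = "linear", k = 0.003,
                         Dp = 0.03, f0 = 0)
    tp_assay <- tp_parameters(B = 0.65, D0 = 0.15, k0 = 2.3, a = 0.2,
                              t0 = 0, S0 = 0, lambda_variant = "linear",
                              k = 0.002, Dp = 0.01, f0 = 0)
    assay <- mcld_parameters(b = 0.65, d = 0.15, mu_s = 2e-6, mu_p = 2e-5,
                             tp = tp_assay, dose = 5, dt = 0.05)
  } else {
    fit <- tp_parameters(B = 0.35, D0 = 0, k0 = 0.63, a = 0.6, t0 = 2,
                         S0 = 0.2, lambda_variant = "linear", k = 0.0024,
                         Dp = 0.02, f0 = 0)
    tp_assay <- tp_parameters(B = 0.5, D0 = 0.15, k0 = 2.0, a = 0.25,
                              t0 = 0, S0 = 0, lambda_variant = "linear",
                              k = 0.0025, Dp = 0.012, f0 = 0)
    assay <- mcld_parameters(b = 0.5, d = 0.15, mu_s = 2e-6, mu_p = 2e-5,
                             tp = tp_assay, dose = 5, dt = 0.05)
  }
  list(fit = fit, assay = assay, dose = assay$dose)
}
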