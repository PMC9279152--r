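#' Birth-death establishment model
#'
#' Resistant (and untreated) cells divide at rate `b` and die at rate `d`
#' with `b > d`: a supercritical birth-death process.  A newly arisen
#' mutant founds a lineage that may still be lost to demographic drift;
#' lineages that survive are called *established*.
#'
#' @param b division rate (per day).
#' @param d death rate (per day), `0 <= d < b`.
#' @return An object of class `"establishment_model"`.
#' @export
establishment_model <- function(b, d) {
  if (!is.numeric(b) || !is.numeric(d) || length(b) != 1L || length(d) != 1L)
    stop("'b' and 'd' must be numeric scalars", call. = FALSE)
  if (d < 0) stop("'d' must be nonnegative", call. = FALSE)
  if (b <= d)
    stop("supercritical assumption violated: need b > d", call. = FALSE)
  structure(list(b = b, d = d), class = "establishment_model")
}

#' Probability that a single-cell lineage survives drift
#'
#' Finite-horizon non-extinction probability of a birth-death lineage
#' founded by one cell:
#' \deqn{\psi(\Delta t) = \frac{b - d}{b - d e^{-(b-d)\Delta t}}.}
#' `psi(0) = 1`, psi decreases with the time window, and
#' `psi(Inf) = 1 - d/b`, the classical eventual-survival probability.
#'
#' @param m an [establishment_model()].
#' @param delta_t nonnegative time window(s) (days); `Inf` is allowed.
#' @return Survival probability in `(0, 1]`, vectorised over `delta_t`.
#' @examples
#' m <- establishment_model(b = 0.65, d = 0.15)
#' establishment_probability(m, c(0, 3, Inf))
#' @export
establishment_probability <- function(m, delta_t) {
  stopifnot(inherits(m, "establishment_model"))
  if (any(delta_t < 0)) stop("'delta_t' must be nonnegative", call. = FALSE)
  g <- m$b - m$d
  g / (m$b - m$d * exp(-g * delta_t))
}

#' Expected number of established mutants in a time window
#'
#' Integrates the mutant-supply intensity over a population trajectory:
#' a population of size `pop(t)` produces mutants at rate `mu * pop(t)`,
#' and a mutant arising at time t is established (survives drift) by the
#' end of the window with probability psi(horizon - t).  The expectation
#' \deqn{\mathcal{M} = \mu \int_0^T pop(t)\, \psi(T - t)\, dt}
#' is evaluated by composite trapezoidal quadrature on the supplied grid.
#' The number of established mutants per well is Poisson with this mean.
#'
#' @param mu mutation rate (per cell per day, >= 0).
#' @param times increasing time grid (days) covering the window.
#' @param pop population size at each grid time (>= 0): the sensitive
#'   population X(t) during drug-free expansion, or the persister
#'   population Z(t) under treatment.
#' @param m an [establishment_model()] for the resistant lineage.
#' @param horizon end of the establishment window (days); defaults to
#'   `max(times)`.  A later horizon means mutants must survive drift for
#'   longer to be counted.
#' @param source label, `"sensitive"` or `"persister"`.
#' @return An object of class `"expected_mutants"`: list with `value`,
#'   `window`, `horizon`, `source`.
#' @examples
#' m <- establishment_model(0.65, 0.15)
#' tt <- seq(0, 7.4, by = 0.01)
#' expected_mutants(2e-6, tt, 500 * exp(0.5 * tt), m)$value
#' @export
expected_mutants <- function(mu, times, pop, m, horizon = max(times),
                             source = c("sensitive", "persister")) {
  stopifnot(inherits(m, "establishment_model"))
  source <- match.arg(source)
  if (mu < 0) stop("'mu' must be nonnegative", call. = FALSE)
  if (length(times) != length(pop) || length(times) < 2L)
    stop("'times' and 'pop' must be equal-length vectors (>= 2)",
         call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (any(pop < 0)) stop("'pop' must be nonnegative", call. = FALSE)
  if (horizon < max(times))
    stop("'horizon' must not precede the end of the grid", call. = FALSE)
  integrand <- pop * establishment_probability(m, horizon - times)
  val <- mu * trapz(times, integrand)
  structure(list(value = val, window = range(times), horizon = horizon,
                 source = source),
            class = "expected_mutants")
}

#' @rdname expected_mutants
#' @param X sensitive-population sizes on the expansion grid.
#' @export
expected_mutants_sensitive <- function(mu, times, X, m,
                                       horizon = max(times)) {
  expected_mutants(mu, times, X, m, horizon = horizon, source = "sensitive")
}

#' @rdname expected_mutants
#' @param Z persister-population sizes on the treatment grid.
#' @export
expected_mutants_persisters <- function(mu, times, Z, m,
                                        horizon = max(times)) {
  expected_mutants(mu, times, Z, m, horizon = horizon, source = "persister")
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)

#' Probability that a well contains at least one established mutant
#'
#' Established mutants per well are Poisson with mean M, so
#' `P = 1 - exp(-M)`.
#'
#' @param mutants an [expected_mutants()] object, or a nonnegative number
#'   (or sum of several expectations).
#' @return Probability in `[0, 1)`.
#' @export
p_resistant <- function(mutants) {
  val <- if (inherits(mutants, "expected_mutants")) mutants$value else mutants
  if (any(val < 0)) stop("expected mutant count must be >= 0", call. = FALSE)
  1 - exp(-val)
}

#' Time for an established resistant lineage to become a visible colony
#'
#' An established lineage grows in expectation as
#' `exp((b - d) t) / (1 - d/b)` (conditioning on survival inflates the
#' mean by `1/psi(Inf)`), so its size crosses the visibility threshold
#' after about `log(threshold * (1 - d/b)) / (b - d)` days.  A quick
#' summary of the crossing-time scale; the estimators use the full
#' crossing-time distribution via [colony_visibility()].
#'
#' @param m an [establishment_model()].
#' @param threshold colony-visibility size (cells).
#' @return Lag in days.
#' @export
colony_detection_lag <- function(m, threshold = 50) {
  stopifnot(inherits(m, "establishment_model"))
  max(0, log(threshold * (1 - m$d / m$b)) / (m$b - m$d))
}

#' Probability that a mutant lineage is a visible colony after s days
#'
#' Exact transient solution of the linear birth-death process started
#' from one cell: the size after `s` days is zero with probability
#' alpha(s) and otherwise geometric with parameter beta(s), where
#' \deqn{\alpha(s) = \frac{d(e^{gs} - 1)}{b e^{gs} - d}, \quad
#'       \beta(s) = \frac{b(e^{gs} - 1)}{b e^{gs} - d}, \quad g = b - d,}
#' so the lineage has reached the visibility threshold with probability
#' \deqn{V(s) = (1 - \alpha(s)) \, \beta(s)^{\mathrm{thr} - 1}.}
#' V rises from 0 to the eventual-establishment probability `1 - d/b`
#' over a few multiples of `1/g`: it is the detection kernel that maps
#' mutant founding times to colony-appearance windows.  (Colonies do not
#' regress once visible, so "size >= threshold at s" and "first visible
#' by s" coincide up to the negligible probability `(d/b)^threshold` of
#' a visible colony collapsing.)
#'
#' @param m an [establishment_model()].
#' @param s time since founding (days); nonpositive values give 0.
#' @param threshold visibility size (cells).
#' @return Probability vector, same length as `s`.
#' @export
colony_visibility <- function(m, s, threshold = 50) {
  stopifnot(inherits(m, "establishment_model"))
  b <- m$b; d <- m$d; g <- b - d
  out <- numeric(length(s))
  pos <- which(s > 0)
  if (!length(pos)) return(out)
  gs <- g * s[pos]
  big <- gs > 30  # asymptotic regime, avoids exp overflow
  egs <- exp(pmin(gs, 30))
  alpha <- ifelse(big, d / b, d * (egs - 1) / (b * egs - d))
  beta <- ifelse(big, 1 - (b - d) / (b * exp(pmin(gs, 700))),
                 b * (egs - 1) / (b * egs - d))
  out[pos] <- (1 - alpha) * beta^(threshold - 1)
  out
}

#' Invert the positive-well fraction into a mutation rate
#'
#' Standard fluctuation-test inversion: with established mutants Poisson
#' per well, the fraction of positive wells is `p = 1 - exp(-mu * I)`
#' where `I` is the establishment-weighted population integral, so
#' `mu = -log(1 - p) / I`.  A Wilson 95% interval on p is propagated
#' through the same inversion.
#'
#' @param positives number of positive wells (or, if `n_wells` is `NULL`,
#'   the positive fraction directly, in which case no CI is computed).
#' @param n_wells total number of wells.
#' @param I establishment-weighted integral
#'   `int pop(t) psi(horizon - t) dt` (cell-days, > 0); see
#'   [expected_mutants()].
#' @param conf confidence level for the Wilson interval.
#' @return An object of class `"mutation_rate_estimate"`: list with
#'   `estimate`, `lower`, `upper` (per cell per day), `p_hat`, `n_wells`,
#'   `I`.  With all wells positive the point estimate is undefined and
#'   only the lower bound is reported.
#' @examples
#' estimate_mutation_rate(12, 480, I = 3e4)
#' @export
estimate_mutation_rate <- function(positives, n_wells = NULL, I,
                                   conf = 0.95) {
  if (I <= 0) stop("'I' must be positive", call. = FALSE)
  if (is.null(n_wells)) {
    p_hat <- positives
    if (p_hat < 0 || p_hat >= 1)
      stop("positive fraction must lie in [0, 1)", call. = FALSE)
    ci <- c(NA_real_, NA_real_)
  } else {
    if (positives < 0 || positives > n_wells)
      stop("'positives' must lie in [0, n_wells]", call. = FALSE)
    p_hat <- positives / n_wells
    ci <- wilson_ci(positives, n_wells, conf)
  }
  to_mu <- function(p) ifelse(p >= 1, Inf, -log(1 - p) / I)
  est <- if (p_hat >= 1) NA_real_ else to_mu(p_hat)
  if (p_hat >= 1)
    warning("all wells positive: point estimate undefined, ",
            "reporting lower bound only", call. = FALSE)
  structure(list(estimate = est, lower = to_mu(ci[1]), upper = to_mu(ci[2]),
                 p_hat = p_hat, n_wells = n_wells, I = I, conf = conf),
            class = "mutation_rate_estimate")
}

#' @export
print.mutation_rate_estimate <- function(x, ...) {
  cat(sprintf("mutation rate: %.3g per cell per day (%.0f%% CI %.3g-%.3g)\n",
              x$estimate, 100 * x$conf, x$lower, x$upper))
  cat(sprintf("  positive fraction %.4f, integral %.4g cell-days\n",
              x$p_hat, x$I))
  invisible(x)
}

wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

## -------------------------------------------------------------------------
## Two-window pipeline: from assay outcomes to (mu_s, mu_p)

## Deterministic populations implied by a design + parameter set:
## expansion X(t) = seed * exp((b-d) t) up to the target, treatment Z(tau)
## from the TP solution started at the expansion target.
assay_populations <- function(design, params, dt = 0.05) {
  g <- params$b - params$d
  t_hit <- min(log(design$expansion_target_cells /
                     design$seed_cells_per_well) / g, design$T_treat)
  t_exp <- seq(0, t_hit, by = dt)
  if (t_exp[length(t_exp)] < t_hit) t_exp <- c(t_exp, t_hit)
  X_exp <- design$seed_cells_per_well * exp(g * t_exp)
  tau <- seq(0, design$T_obs, by = dt)
  if (tau[length(tau)] < design$T_obs) tau <- c(tau, design$T_obs)
  tr <- solve_tp(params$tp, schedule_constant(params$dose),
                 N_init = design$expansion_target_cells, t_grid = tau)
  list(t_exp = t_exp, X_exp = X_exp, tau = tau, Z = tr$Z, X_treat = tr$X,
       t_hit = t_hit)
}

## Detection-weighted integrals for the early/late colony windows.  A
## mutant founded at time t is a visible colony by observation time s
## with probability V(s - t) from colony_visibility(), so the expected
## number of colonies first visible inside a window [s1, s2] is the
## founding intensity integrated against V(s2 - t) - V(s1 - t).
## Sensitive-derived mutants arise during expansion (X growing to the
## target; visibility clock keeps running through treatment) and from
## the declining sensitive population under treatment; persister-derived
## mutants arise from Z(t) under treatment.
assay_integrals <- function(design, params, dt = 0.05, m = NULL) {
  if (is.null(m)) m <- establishment_model(params$b, params$d)
  pops <- assay_populations(design, params, dt)
  thr <- design$colony_detection_threshold
  c_e <- design$early_cutoff_days
  c_l <- design$late_cutoff_days
  Tobs <- design$T_obs
  vis <- function(s) colony_visibility(m, s, thr)
  ## sensitive-derived, visible by the early cutoff: growth time is the
  ## remaining expansion plus c_e days of treatment (expansion channel),
  ## or c_e - tau (treatment channel)
  I_s <- trapz(pops$t_exp,
               pops$X_exp * vis(pops$t_hit - pops$t_exp + c_e)) +
    trapz(pops$tau, pops$X_treat * vis(c_e - pops$tau))
  ## persister-derived, first visible by the early cutoff / within the
  ## late window
  I_p_early <- trapz(pops$tau, pops$Z * vis(c_e - pops$tau))
  I_p_late <- trapz(pops$tau,
                    pops$Z * (vis(Tobs - pops$tau) - vis(c_l - pops$tau)))
  ## visible-by-late-cutoff integrals: a well whose first colony appears
  ## before c_l cannot score "late", so the late observable is censored
  ## by the no-earlier-colony probability exp(-Lambda(c_l))
  I_s_vis_cl <- trapz(pops$t_exp,
                      pops$X_exp * vis(pops$t_hit - pops$t_exp + c_l)) +
    trapz(pops$tau, pops$X_treat * vis(c_l - pops$tau))
  I_p_vis_cl <- trapz(pops$tau, pops$Z * vis(c_l - pops$tau))
  list(I_s = I_s, I_p_early = I_p_early, I_p_late = I_p_late,
       I_s_vis_cl = I_s_vis_cl, I_p_vis_cl = I_p_vis_cl,
       lag = colony_detection_lag(m, thr), pops = pops)
}

#' Estimate spontaneous and persister mutation rates from assay outcomes
#'
#' Two-window fluctuation analysis.  Early-window colonies (first visible
#' by `early_cutoff_days`) arise from spontaneous mutants of the sensitive
#' population (during expansion and during its decline under drug) plus
#' persister-derived mutants founded early in treatment; late-window
#' colonies (first visible at or after `late_cutoff_days`) are attributed
#' to persister-derived mutants.  Founding intensities are mapped to
#' observation windows with the exact colony-visibility kernel of
#' [colony_visibility()].  The
#' persister rate is inverted from the late fraction, then the spontaneous
#' rate from the early fraction after subtracting the expected early
#' persister-derived contribution.  Late colonies seeded by slow
#' pre-existing mutants are not corrected for (their expected number is
#' negligible in the operating regime; see the methods vignette).
#'
#' @param outcomes a well-outcome data frame from [simulate_experiment()]
#'   (or [read_outcomes()]), or a list with elements `wells`,
#'   `early_positives`, `late_positives` for hand-entered counts.
#' @param design the [experiment_design()] used.
#' @param params the [mcld_parameters()] describing the population
#'   dynamics (used for the deterministic X and Z trajectories and the
#'   establishment probabilities; `mu_s`/`mu_p` therein are ignored).
#' @param dt quadrature step (days).
#' @param establishment optional [establishment_model()] overriding the
#'   resistant birth-death rates used for drift survival and colony
#'   growth (defaults to `params$b`, `params$d`); exposed so the
#'   sensitivity of the estimates to the resistant division rate can be
#'   probed directly.
#' @return An object of class `"mutation_rate_fit"`: list with
#'   `mu_s`, `mu_p` ([estimate_mutation_rate()]-style entries), `fold`
#'   (`mu_p$estimate / mu_s$estimate`), the window integrals, and the
#'   counts used.
#' @export
estimate_rates_from_outcomes <- function(outcomes, design, params,
                                         dt = 0.05,
                                         establishment = NULL) {
  if (is.data.frame(outcomes)) {
    counts <- list(
      wells = nrow(outcomes),
      early_positives = sum(outcomes$colony_class == "early"),
      late_positives = sum(outcomes$colony_class == "late"))
  } else counts <- outcomes
  if (counts$early_positives > counts$wells ||
      counts$late_positives > counts$wells)
    stop("positive counts exceed the number of wells", call. = FALSE)
  ints <- assay_integrals(design, params, dt, m = establishment)
  n <- counts$wells
  p_e <- counts$early_positives / n
  p_l <- counts$late_positives / n
  M_e <- -log(1 - p_e)
  ## joint fixed-point solve: the early fraction mixes both rates, and
  ## the late fraction is censored by wells whose first colony appeared
  ## before the late cutoff (rate Lambda_cl)
  mu_p_pt <- 0
  mu_s_pt <- max(0, M_e / ints$I_s)
  for (it in seq_len(50)) {
    lam_cl <- mu_s_pt * ints$I_s_vis_cl + mu_p_pt * ints$I_p_vis_cl
    adj <- min(p_l * exp(lam_cl), 1 - 1e-12)
    mu_p_new <- if (ints$I_p_late > 0) -log(1 - adj) / ints$I_p_late else 0
    mu_s_new <- max(0, (M_e - mu_p_new * ints$I_p_early) / ints$I_s)
    if (abs(mu_p_new - mu_p_pt) < 1e-12 * (1 + mu_p_pt) &&
        abs(mu_s_new - mu_s_pt) < 1e-12 * (1 + mu_s_pt)) break
    mu_p_pt <- mu_p_new
    mu_s_pt <- mu_s_new
  }
  lam_cl <- mu_s_pt * ints$I_s_vis_cl + mu_p_pt * ints$I_p_vis_cl
  ## CIs: propagate each window's Wilson interval through its inversion,
  ## holding the other rate at its point estimate
  ci_l <- wilson_ci(counts$late_positives, n)
  adj_ci <- pmin(ci_l * exp(lam_cl), 1 - 1e-12)
  mu_p_ci <- if (ints$I_p_late > 0) -log(1 - adj_ci) / ints$I_p_late
             else c(0, 0)
  mu_p <- structure(list(estimate = mu_p_pt, lower = mu_p_ci[1],
                         upper = mu_p_ci[2], p_hat = p_l, n_wells = n,
                         I = ints$I_p_late, conf = 0.95),
                    class = "mutation_rate_estimate")
  ci_e <- wilson_ci(counts$early_positives, n)
  mu_s_ci <- pmax(0, (-log(1 - ci_e) - mu_p_pt * ints$I_p_early) / ints$I_s)
  mu_s <- structure(list(estimate = mu_s_pt, lower = mu_s_ci[1],
                         upper = mu_s_ci[2],
                         p_hat = p_e, n_wells = n,
                         I = ints$I_s, conf = 0.95),
                    class = "mutation_rate_estimate")
  fold <- if (mu_s_pt > 0) mu_p_pt / mu_s_pt else NA_real_
  structure(list(mu_s = mu_s, mu_p = mu_p, fold = fold,
                 integrals = ints[c("I_s", "I_p_early", "I_p_late", "lag")],
                 counts = counts),
            class = "mutation_rate_fit")
}

#' @export
print.mutation_rate_fit <- function(x, ...) {
  cat("Two-window fluctuation-assay estimates\n")
  cat(sprintf("  mu_s = %.3g /cell/day (early %d/%d wells)\n",
              x$mu_s$estimate, x$counts$early_positives, x$counts$wells))
  cat(sprintf("  mu_p = %.3g /cell/day (late %d/%d wells)\n",
              x$mu_p$estimate, x$counts$late_positives, x$counts$wells))
  cat(sprintf("  fold increase mu_p/mu_s = %.3g\n", x$fold))
  invisible(x)
}

#' Joint posterior of the pre-existing persister fraction and the fold
#' increase of the persister mutation rate
#'
#' Grid posterior over (f0, fold = mu_p/mu_s).  For each f0 the persister
#' trajectory Z(t) is recomputed from the TP model (a pre-existing
#' fraction adds persisters at treatment start), the establishment
#' integrals are rebuilt, the spontaneous rate is profiled out of the
#' early-count equation, and the binomial likelihood of the observed
#' early/late positive-well counts is accumulated in log space and
#' normalised over the grid.  A flat prior on the grid is assumed.
#'
#' @param counts list with `wells`, `early_positives`, `late_positives`.
#' @param design an [experiment_design()].
#' @param params an [mcld_parameters()]; its `tp` component is re-solved
#'   for every f0 in the grid.
#' @param f0_grid values of the initial persister fraction, in `[0, 1)`.
#' @param fold_grid values of mu_p/mu_s (default log-spaced on
#'   `[0.1, 1000]`).
#' @param dt quadrature step (days).
#' @return An object of class `"joint_posterior"`: list with `f0`,
#'   `fold`, `mass` (matrix `length(f0) x length(fold)` summing to 1),
#'   and marginals `marginal_f0`, `marginal_fold`.
#' @export
joint_posterior_fold <- function(counts, design, params,
                                 f0_grid = c(0, 0.001, 0.002, 0.005, 0.01),
                                 fold_grid = 10^seq(-1, 3, length.out = 81),
                                 dt = 0.05) {
  if (any(f0_grid < 0 | f0_grid >= 1))
    stop("'f0_grid' must lie in [0, 1)", call. = FALSE)
  if (counts$early_positives > counts$wells ||
      counts$late_positives > counts$wells)
    stop("positive counts exceed the number of wells", call. = FALSE)
  n <- counts$wells
  ll <- matrix(-Inf, nrow = length(f0_grid), ncol = length(fold_grid))
  for (i in seq_along(f0_grid)) {
    pars_i <- params
    pars_i$tp$f0 <- f0_grid[i]
    ints <- assay_integrals(design, pars_i, dt)
    M_e <- -log(1 - counts$early_positives / n)
    for (j in seq_along(fold_grid)) {
      fold <- fold_grid[j]
      ## profile mu_s: E[M_early] = mu_s I_s + fold mu_s I_p_early
      mu_s <- M_e / (ints$I_s + fold * ints$I_p_early)
      p_e <- 1 - exp(-mu_s * (ints$I_s + fold * ints$I_p_early))
      lam_cl <- mu_s * (ints$I_s_vis_cl + fold * ints$I_p_vis_cl)
      p_l <- exp(-lam_cl) * (1 - exp(-fold * mu_s * ints$I_p_late))
      ll[i, j] <- stats::dbinom(counts$early_positives, n, p_e, log = TRUE) +
        stats::dbinom(counts$late_positives, n, p_l, log = TRUE)
    }
  }
  ## log-space normalisation guards against underflow
  mx <- max(ll)
  if (!is.finite(mx))
    stop("zero likelihood everywhere on the grid", call. = FALSE)
  mass <- exp(ll - mx)
  mass <- mass / sum(mass)
  structure(list(f0 = f0_grid, fold = fold_grid, mass = mass,
                 marginal_f0 = rowSums(mass),
                 marginal_fold = colSums(mass)),
            class = "joint_posterior")
}

#' @export
print.joint_posterior <- function(x, ...) {
  map <- which(x$mass == max(x$mass), arr.ind = TRUE)[1, ]
  cat("Joint grid posterior over (f0, mu_p/mu_s)\n")
  cat(sprintf("  MAP: f0 = %.4g, fold = %.3g\n",
              x$f0[map[1]], x$fold[map[2]]))
  cat(sprintf("  P(fold > 1) = %.3f\n",
              sum(x$marginal_fold[x$fold > 1])))
  invisible(x)
}
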