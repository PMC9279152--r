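#' Net growth rate from a cell-count time series
#'
#' Least-squares slope of log counts versus time: the net growth rate
#' g = b - d of an exponentially growing culture, with the regression
#' standard error.
#'
#' @param time_d timepoints (days), at least three.
#' @param counts positive viable-cell counts.
#' @return List of class `"net_rate_estimate"`: `g`, `se`, `intercept`,
#'   `n`.
#' @examples
#' tt <- 0:5
#' estimate_net_rate(tt, 1e5 * exp(0.5 * tt))$g
#' @export
estimate_net_rate <- function(time_d, counts) {
  if (length(time_d) < 3L || length(counts) != length(time_d))
    stop("need >= 3 matched timepoints", call. = FALSE)
  if (any(counts <= 0)) stop("counts must be positive", call. = FALSE)
  fit <- stats::lm(log(counts) ~ time_d)
  cf <- summary(fit)$coefficients
  structure(list(g = unname(cf["time_d", "Estimate"]),
                 se = unname(cf["time_d", "Std. Error"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 n = length(time_d)),
            class = "net_rate_estimate")
}

#' Death-to-birth ratio from dead-fraction measurements
#'
#' Under the accumulation model -- dead cells are produced at rate
#' d N(t) from an exponentially growing live population N(t) = N0 e^{gt}
#' and counted alongside live cells -- the dead fraction is
#' \deqn{\phi(t) = \rho(t) / (1 + \rho(t)), \quad
#'       \rho(t) = (d/g)(1 - e^{-gt}),}
#' with asymptote `phi = d/b` (since b = g + d, the asymptotic odds are
#' `phi/(1-phi) = d/(b-d)`).  Given the net rate g, the transform
#' `rho = phi/(1-phi)` is linear in `(1 - e^{-gt})/g` with slope d, so
#' d is estimated by least squares through the origin and converted to
#' `r = d/b = d/(g + d)`.
#'
#' @param time_d measurement times (days).
#' @param dead_fraction observed dead fractions, each in `[0, 1)`.
#' @param g net growth rate b - d (per day), e.g. from
#'   [estimate_net_rate()].
#' @return List of class `"death_birth_estimate"`: `r` (= d/b), `se_r`,
#'   `d`, `se_d`, `g`.
#' @export
estimate_death_birth_ratio <- function(time_d, dead_fraction, g) {
  if (any(dead_fraction < 0 | dead_fraction >= 1))
    stop("dead fractions must lie in [0, 1)", call. = FALSE)
  if (length(time_d) != length(dead_fraction) || length(time_d) < 2L)
    stop("need >= 2 matched measurements", call. = FALSE)
  rho <- dead_fraction / (1 - dead_fraction)
  x <- (1 - exp(-g * time_d)) / g
  if (all(rho == 0)) {
    d_hat <- 0
    se_d <- 0
  } else {
    fit <- stats::lm(rho ~ x - 1)
    cf <- summary(fit)$coefficients
    d_hat <- max(0, unname(cf["x", "Estimate"]))
    se_d <- unname(cf["x", "Std. Error"])
  }
  r <- d_hat / (g + d_hat)
  ## delta method: dr/dd = g / (g + d)^2
  se_r <- se_d * g / (g + d_hat)^2
  structure(list(r = r, se_r = se_r, d = d_hat, se_d = se_d, g = g),
            class = "death_birth_estimate")
}

#' Combine net-rate and death-ratio estimates into birth and death rates
#'
#' Algebraic closure of the two measurable quantities: with g = b - d
#' and r = d/b, the rates are `b = g/(1 - r)` and `d = g r/(1 - r)`.
#' Standard errors are propagated to first order assuming independent
#' estimates.
#'
#' @param net a [estimate_net_rate()] result (or list with `g`, `se`).
#' @param ratio a [estimate_death_birth_ratio()] result (or list with
#'   `r`, `se_r`).
#' @return List of class `"growth_rate_estimate"`: `b`, `d`, `se_b`,
#'   `se_d`, plus the inputs `g` and `r`.
#' @export
combine_growth_rates <- function(net, ratio) {
  g <- net$g; r <- ratio$r
  if (r < 0 || r >= 1) stop("need 0 <= r < 1", call. = FALSE)
  b <- g / (1 - r)
  d <- g * r / (1 - r)
  se_g <- if (!is.null(net$se)) net$se else 0
  se_r <- if (!is.null(ratio$se_r)) ratio$se_r else 0
  se_b <- sqrt((se_g / (1 - r))^2 + (g * se_r / (1 - r)^2)^2)
  se_d <- sqrt((r * se_g / (1 - r))^2 + (g * se_r / (1 - r)^2)^2)
  structure(list(b = b, d = d, se_b = se_b, se_d = se_d, g = g, r = r),
            class = "growth_rate_estimate")
}

#' Poisson-dispersion test of per-well persister counts
#'
#' Discriminates the drug-induced from the pre-existing persister
#' scenario by the variance-to-mean ratio of persister abundance across
#' independent wells.  Persisters generated only after treatment are
#' Poisson across wells (index of dispersion near 1); persisters whose
#' fate was set during the drug-free expansion inherit the clone-size
#' fluctuations of a Luria-Delbruck process (variance much greater than
#' the mean).  The chi-square dispersion statistic
#' `(n - 1) * variance / mean` is referred to its chi-square
#' distribution with n - 1 degrees of freedom, two-sided.
#'
#' Viability readings can be supplied instead of counts through the
#' `calibration` factor (signal units per cell, default 1); the test
#' then operates on the rescaled signal, which is approximate for
#' non-integer data.
#'
#' @param counts nonnegative per-well persister counts (or viability
#'   signal), at least 20 wells.
#' @param alpha significance level for the verdict.
#' @param calibration viability-to-count factor: counts used are
#'   `counts / calibration`.
#' @return List of class `"dispersion_result"`: `n`, `mean`, `variance`,
#'   `index` (variance/mean), `statistic`, `p_value`, `verdict` (one of
#'   `"poisson-consistent"`, `"overdispersed"`, `"underdispersed"`).
#' @examples
#' dispersion_test(rpois(100, 5))$verdict
#' @export
dispersion_test <- function(counts, alpha = 0.05, calibration = 1) {
  counts <- counts / calibration
  n <- length(counts)
  if (n < 20L) stop("need at least 20 wells", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  m <- mean(counts)
  v <- stats::var(counts)
  if (m == 0) {
    warning("mean count is zero: dispersion index undefined", call. = FALSE)
    return(structure(list(n = n, mean = m, variance = v, index = NA_real_,
                          statistic = NA_real_, p_value = NA_real_,
                          verdict = "undefined"),
                     class = "dispersion_result"))
  }
  idx <- v / m
  stat <- (n - 1) * idx
  p_up <- stats::pchisq(stat, df = n - 1, lower.tail = FALSE)
  p_lo <- stats::pchisq(stat, df = n - 1, lower.tail = TRUE)
  p <- min(1, 2 * min(p_up, p_lo))
  verdict <- if (p >= alpha) "poisson-consistent"
             else if (idx > 1) "overdispersed" else "underdispersed"
  structure(list(n = n, mean = m, variance = v, index = idx,
                 statistic = stat, p_value = p, verdict = verdict),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf(paste0("Dispersion test on %d wells: mean %.2f, variance",
                     " %.2f, index %.3f\n"), x$n, x$mean, x$variance,
              x$index))
  cat(sprintf("  p = %.3g -> %s\n", x$p_value, x$verdict))
  invisible(x)
}
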