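#' Transition-to-persister (TP) model parameters
#'
#' Constructs and validates the full parameter vector of the deterministic
#' transition-to-persister model.  Under drug treatment, sensitive cells
#' X(t) divide at rate `B`, die at the drug-dependent rate D(M), and switch
#' to the persister state at rate lambda(M); persister cells Z(t) die at
#' rate `Dp`:
#'
#' \deqn{dX/dt = (B - D(M) - \lambda(M)) X, \quad
#'       dZ/dt = -D_p Z + \lambda(M) X.}
#'
#' Any back-switching of persisters to the sensitive state under drug is
#' folded into `Dp` (a persister that attempts to divide before acquiring
#' resistance dies), so no explicit reverse transition is modelled.
#'
#' Before the drug takes effect (`t < t0`) the total population grows
#' exponentially at the observed rate `S0` with the persister fraction held
#' at `f0`.
#'
#' @param B birth rate of sensitive cells (per day).
#' @param D0 unperturbed death rate (per day).
#' @param k0 maximal drug-induced additional death rate (per day); the
#'   death rate saturates at `D0 + k0` for high drug concentration.
#' @param a inverse characteristic drug concentration (per concentration
#'   unit); at `M = 1/a` the drug effect is half-maximal.
#' @param t0 delay between drug administration and drug effect (days).
#' @param S0 net growth rate observed before the drug effect, `t < t0`
#'   (per day).
#' @param lambda_variant functional form of the switching rate
#'   lambda(M); one of `"zero"`, `"constant"`, `"linear"`, `"saturating"`.
#' @param lambda0 constant switching rate (per day); used by the
#'   `"constant"` variant and as the plateau of `"saturating"`.
#' @param k proportionality coefficient of lambda to concentration (per
#'   day per concentration unit); used by `"linear"`.
#' @param Dp persister death rate under treatment (per day, > 0).
#' @param f0 initial persister fraction Z(t0)/N(t0), in `[0, 1]`.
#'
#' @return An object of class `"tp_parameters"` (named list).
#' @examples
#' p <- tp_parameters(B = 0.65, D0 = 0.15, k0 = 1.6, a = 0.2,
#'                    lambda_variant = "linear", k = 0.01, Dp = 0.03)
#' death_rate(p, 5)
#' @export
tp_parameters <- function(B, D0, k0, a, t0 = 0, S0 = 0,
                          lambda_variant = c("zero", "constant", "linear",
                                             "saturating"),
                          lambda0 = 0, k = 0, Dp = 0.03, f0 = 0) {
  lambda_variant <- match.arg(lambda_variant)
  p <- list(B = B, D0 = D0, k0 = k0, a = a, t0 = t0, S0 = S0,
            lambda_variant = lambda_variant, lambda0 = lambda0, k = k,
            Dp = Dp, f0 = f0)
  num <- p[setdiff(names(p), "lambda_variant")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1L))))
    stop("all TP parameters must be finite numeric scalars", call. = FALSE)
  if (B < 0 || D0 < 0 || k0 < 0)
    stop("rates B, D0, k0 must be nonnegative", call. = FALSE)
  if (a <= 0) stop("'a' must be positive", call. = FALSE)
  if (Dp <= 0) stop("persister death rate 'Dp' must be > 0", call. = FALSE)
  if (f0 < 0 || f0 > 1) stop("'f0' must lie in [0, 1]", call. = FALSE)
  if (t0 < 0) stop("'t0' must be nonnegative", call. = FALSE)
  if (lambda0 < 0 || k < 0)
    stop("switching-rate parameters must be nonnegative", call. = FALSE)
  structure(p, class = "tp_parameters")
}

#' @export
print.tp_parameters <- function(x, ...) {
  cat("TP model parameters (lambda variant:", x$lambda_variant, ")\n")
  num <- unlist(x[setdiff(names(x), "lambda_variant")])
  print(round(num, 6))
  invisible(x)
}

#' Drug-dependent death rate of sensitive cells
#'
#' Saturating dose response `D(M) = D0 + k0 * aM / (1 + aM)`: the
#' unperturbed death rate `D0` at zero drug, rising monotonically to the
#' maximal value `D0 + k0` at saturating concentration, with
#' half-saturation at `M = 1/a`.
#'
#' @param p a [tp_parameters()] object.
#' @param M drug concentration(s), nonnegative, in units of `1/a`.
#' @return Death rate(s) per day, in `[D0, D0 + k0]`.
#' @export
death_rate <- function(p, M) {
  stopifnot(inherits(p, "tp_parameters"))
  if (any(!is.finite(M) & !is.infinite(M)) || any(M < 0))
    stop("drug concentration 'M' must be nonnegative", call. = FALSE)
  sat <- ifelse(is.infinite(M), 1, p$a * M / (1 + p$a * M))
  p$D0 + p$k0 * sat
}

#' Drug-dependent sensitive-to-persister switching rate
#'
#' The four supported functional forms of lambda(M):
#' `zero` (no switching), `constant` (`lambda0`), `linear` (`k * M`), and
#' `saturating` (`lambda0 * aM / (1 + aM)`).  All are nonnegative and
#' nondecreasing in M.
#'
#' @inheritParams death_rate
#' @return Switching rate(s) per day.
#' @export
transition_rate <- function(p, M) {
  stopifnot(inherits(p, "tp_parameters"))
  if (any(M < 0))
    stop("drug concentration 'M' must be nonnegative", call. = FALSE)
  switch(p$lambda_variant,
    zero = rep(0, length(M)),
    constant = rep(p$lambda0, length(M)),
    linear = p$k * M,
    saturating = p$lambda0 * ifelse(is.infinite(M), 1,
                                    p$a * M / (1 + p$a * M)),
    stop("unknown lambda variant '", p$lambda_variant, "'", call. = FALSE)
  )
}

#' Piecewise-constant dose schedule
#'
#' A drug-concentration time course \[M\](t), held constant between grid
#' points: `concentrations[i]` applies on `[times[i], times[i + 1])` and
#' the last concentration extends to infinity.  A single-row schedule is a
#' constant dose; ramps are approximated by fine piecewise-constant grids.
#'
#' @param times strictly increasing timepoints (days), starting at the
#'   moment of drug administration.
#' @param concentrations nonnegative concentration at each timepoint.
#' @return An object of class `"dose_schedule"`.
#' @seealso [schedule_constant()], [schedule_ramp()]
#' @export
dose_schedule <- function(times, concentrations) {
  if (length(times) != length(concentrations) || length(times) < 1L)
    stop("'times' and 'concentrations' must have equal positive length",
         call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (any(concentrations < 0))
    stop("'concentrations' must be nonnegative", call. = FALSE)
  structure(list(times = as.numeric(times),
                 concentrations = as.numeric(concentrations)),
            class = "dose_schedule")
}

#' @rdname dose_schedule
#' @param M constant concentration.
#' @export
schedule_constant <- function(M) dose_schedule(0, M)

#' @rdname dose_schedule
#' @param M_from,M_to ramp endpoints.
#' @param horizon ramp duration (days).
#' @param step grid step for the piecewise-constant approximation (days).
#' @export
schedule_ramp <- function(M_from, M_to, horizon, step = 0.1) {
  tt <- seq(0, horizon, by = step)
  dose_schedule(tt, M_from + (M_to - M_from) * tt / horizon)
}

## concentration in force at each time t (piecewise-constant, right-open)
schedule_at <- function(schedule, t) {
  idx <- findInterval(t, schedule$times)
  idx[idx < 1L] <- 1L
  schedule$concentrations[idx]
}

## closed-form advance of (X, Z) over a constant-dose interval of length tau
## g = B - D(M) - lambda(M); resonance g + Dp -> 0 handled by its limit
advance_xz <- function(X0, Z0, g, lam, Dp, tau) {
  X0 <- as.numeric(X0); Z0 <- as.numeric(Z0)
  X <- X0 * exp(g * tau)
  denom <- g + Dp
  if (abs(denom) < 1e-10) {
    Z <- Z0 * exp(-Dp * tau) + lam * X0 * tau * exp(-Dp * tau)
  } else {
    Z <- Z0 * exp(-Dp * tau) + lam * X0 * (exp(g * tau) - exp(-Dp * tau)) / denom
  }
  c(X = X, Z = Z)
}

#' Solve the TP model on a time grid
#'
#' Deterministic solution of the transition-to-persister dynamics under a
#' piecewise-constant dose schedule.  For `t < t0` the total population
#' grows exponentially at `S0` with persister fraction frozen at `f0`;
#' from `t0` on, the two-compartment linear system is advanced with its
#' exact closed form on each constant-dose interval (X exponential, Z the
#' linear-ODE solution with exponential forcing).  `method = "ode"` uses
#' an adaptive numerical integrator instead and exists as a cross-check;
#' the two agree to integrator tolerance.
#'
#' @param p a [tp_parameters()] object.
#' @param schedule a [dose_schedule()]; times are measured from drug
#'   administration (t = 0).
#' @param N_init total population size at t = 0 (> 0).
#' @param t_grid increasing vector of output times (days).
#' @param method `"closed_form"` (default) or `"ode"` (deSolve::lsoda).
#' @return A data frame of class `"tp_trajectory"` with columns
#'   `time_d`, `X`, `Z`, `N`.
#' @examples
#' p <- tp_parameters(B = 0.65, D0 = 0.15, k0 = 1.6, a = 0.2, t0 = 1.5,
#'                    S0 = 0.3, lambda_variant = "linear", k = 0.01,
#'                    Dp = 0.03)
#' tr <- solve_tp(p, schedule_constant(5), N_init = 1, t_grid = 0:30)
#' head(tr)
#' @export
solve_tp <- function(p, schedule, N_init = 1, t_grid,
                     method = c("closed_form", "ode")) {
  stopifnot(inherits(p, "tp_parameters"), inherits(schedule, "dose_schedule"))
  method <- match.arg(method)
  if (!is.numeric(N_init) || N_init <= 0 || !is.finite(N_init))
    stop("'N_init' must be a positive finite number", call. = FALSE)
  if (any(diff(t_grid) < 0)) stop("'t_grid' must be increasing", call. = FALSE)

  if (method == "ode") return(solve_tp_ode(p, schedule, N_init, t_grid))

  t_grid <- as.numeric(t_grid)
  out <- matrix(NA_real_, nrow = length(t_grid), ncol = 2,
                dimnames = list(NULL, c("X", "Z")))

  pre <- t_grid < p$t0
  if (any(pre)) {
    N_pre <- N_init * exp(p$S0 * t_grid[pre])
    out[pre, "X"] <- (1 - p$f0) * N_pre
    out[pre, "Z"] <- p$f0 * N_pre
  }
  if (any(!pre)) {
    N_t0 <- N_init * exp(p$S0 * p$t0)
    ## constant-dose fast path: fully vectorised closed form
    if (length(schedule$times) == 1L ||
        all(schedule$times[-1L] <= p$t0)) {
      M <- schedule_at(schedule, max(p$t0, max(t_grid)))
      g <- p$B - death_rate(p, M) - transition_rate(p, M)
      lam <- transition_rate(p, M)
      tau <- t_grid[!pre] - p$t0
      X0 <- (1 - p$f0) * N_t0
      Z0 <- p$f0 * N_t0
      X <- X0 * exp(g * tau)
      denom <- g + p$Dp
      Z <- if (abs(denom) < 1e-10)
        Z0 * exp(-p$Dp * tau) + lam * X0 * tau * exp(-p$Dp * tau)
      else
        Z0 * exp(-p$Dp * tau) +
          lam * X0 * (exp(g * tau) - exp(-p$Dp * tau)) / denom
      out[!pre, "X"] <- X
      out[!pre, "Z"] <- Z
      traj <- data.frame(time_d = t_grid, X = out[, "X"], Z = out[, "Z"],
                         N = out[, "X"] + out[, "Z"])
      class(traj) <- c("tp_trajectory", "data.frame")
      return(traj)
    }
    state <- c(X = (1 - p$f0) * N_t0, Z = p$f0 * N_t0)
    ## segment breakpoints: t0, schedule changes after t0, requested times
    brk <- sort(unique(c(p$t0, schedule$times[schedule$times > p$t0])))
    targets <- t_grid[!pre]
    res <- matrix(NA_real_, nrow = length(targets), ncol = 2)
    cur_t <- p$t0
    for (i in seq_along(targets)) {
      tt <- targets[i]
      while (TRUE) {
        nxt <- brk[brk > cur_t + 1e-12]
        seg_end <- if (length(nxt) && nxt[1] < tt) nxt[1] else tt
        if (seg_end > cur_t + 1e-15) {
          M <- schedule_at(schedule, cur_t)
          g <- p$B - death_rate(p, M) - transition_rate(p, M)
          state <- advance_xz(state["X"], state["Z"], g,
                              transition_rate(p, M), p$Dp, seg_end - cur_t)
          cur_t <- seg_end
        }
        if (cur_t >= tt - 1e-12) break
      }
      res[i, ] <- state
    }
    out[!pre, ] <- res
  }
  traj <- data.frame(time_d = t_grid, X = out[, "X"], Z = out[, "Z"],
                     N = out[, "X"] + out[, "Z"])
  class(traj) <- c("tp_trajectory", "data.frame")
  traj
}

solve_tp_ode <- function(p, schedule, N_init, t_grid) {
  t_grid <- as.numeric(t_grid)
  post <- t_grid[t_grid >= p$t0]
  pre <- t_grid[t_grid < p$t0]
  rows <- NULL
  if (length(pre)) {
    N_pre <- N_init * exp(p$S0 * pre)
    rows <- data.frame(time_d = pre, X = (1 - p$f0) * N_pre,
                       Z = p$f0 * N_pre)
  }
  if (length(post) || any(t_grid >= p$t0)) {
    N_t0 <- N_init * exp(p$S0 * p$t0)
    y0 <- c(X = (1 - p$f0) * N_t0, Z = p$f0 * N_t0)
    times <- sort(unique(c(p$t0, post)))
    deriv <- function(t, y, parms) {
      M <- schedule_at(schedule, t)
      g <- p$B - death_rate(p, M) - transition_rate(p, M)
      list(c(g * y[1], -p$Dp * y[2] + transition_rate(p, M) * y[1]))
    }
    ## force integrator to stop at dose breakpoints so lsoda never smooths
    ## across a discontinuity
    evt <- schedule$times[schedule$times > p$t0]
    sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                          rtol = 1e-10, atol = 1e-12,
                          events = if (length(evt))
                            list(func = function(t, y, parms) y,
                                 time = evt) else NULL)
    sol <- as.data.frame(sol)
    keep <- sol$time %in% post
    rows <- rbind(rows, data.frame(time_d = sol$time[keep],
                                   X = sol$X[keep], Z = sol$Z[keep]))
  }
  rows <- rows[order(rows$time_d), , drop = FALSE]
  ## restore duplicates in t_grid if any
  idx <- match(t_grid, rows$time_d)
  traj <- data.frame(time_d = t_grid, X = rows$X[idx], Z = rows$Z[idx],
                     N = rows$X[idx] + rows$Z[idx])
  class(traj) <- c("tp_trajectory", "data.frame")
  traj
}

#' Final persister burden under alternative dose schedules
#'
#' Solves the TP model under each schedule and returns the persister
#' population Z at the common horizon.  Used to compare, e.g., a constant
#' dose against a gradual ramp to the same maximal concentration.
#'
#' @param p a [tp_parameters()] object.
#' @param schedules a list of [dose_schedule()] objects sharing the same
#'   total horizon.
#' @param horizon final time (days).
#' @param N_init total population at t = 0.
#' @return A data frame with one row per schedule: `schedule`,
#'   `Z_final`, `N_final`.
#' @export
predict_persisters_under_schedule <- function(p, schedules, horizon,
                                              N_init = 1) {
  if (!length(schedules)) stop("empty schedule list", call. = FALSE)
  if (!all(vapply(schedules, inherits, logical(1), "dose_schedule")))
    stop("'schedules' must be a list of dose_schedule objects", call. = FALSE)
  nm <- names(schedules)
  if (is.null(nm)) nm <- paste0("schedule_", seq_along(schedules))
  res <- lapply(schedules, function(s) {
    tr <- solve_tp(p, s, N_init = N_init, t_grid = horizon)
    c(Z = tr$Z, N = tr$N)
  })
  data.frame(schedule = nm,
             Z_final = vapply(res, `[[`, numeric(1), "Z"),
             N_final = vapply(res, `[[`, numeric(1), "N"),
             row.names = NULL)
}
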