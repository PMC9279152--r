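#' Normalise raw viability readings into growth-curve fold changes
#'
#' Converts a raw viability table into the fold-change dataset the TP
#' likelihood consumes.  With `reference = "day0"` every
#' (concentration, replicate) series is divided by its reading at the
#' earliest timepoint (the pre-treatment reference); with
#' `reference = "peak"` each series is divided by its maximum and shifted
#' in time so the maximum sits at time zero, which aligns assays run at
#' different seeding densities on the moment the drug takes effect.
#'
#' @param raw data frame with columns `assay`, `time_d`, `conc`,
#'   `replicate`, `viability` (positive).
#' @param reference `"day0"` or `"peak"`.
#' @return The normalised data frame (column `viability` now holds fold
#'   changes) with attributes `reference` and `t0_scaling_applied`;
#'   class `"growth_curve_dataset"`.
#' @export
normalize_growth_curves <- function(raw, reference = c("day0", "peak")) {
  reference <- match.arg(reference)
  need <- c("assay", "time_d", "conc", "replicate", "viability")
  if (!all(need %in% names(raw)))
    stop("raw table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(raw$viability <= 0))
    stop("viability readings must be positive", call. = FALSE)
  key <- interaction(raw$assay, raw$conc, raw$replicate, drop = TRUE)
  out <- do.call(rbind, lapply(split(raw, key), function(s) {
    s <- s[order(s$time_d), , drop = FALSE]
    if (reference == "day0") {
      if (min(s$time_d) > 0)
        stop("missing day-0 reference reading for conc ", s$conc[1],
             " replicate ", s$replicate[1], call. = FALSE)
      s$viability <- s$viability / s$viability[1]
    } else {
      imax <- which.max(s$viability)
      s$time_d <- s$time_d - s$time_d[imax]
      s$viability <- s$viability / s$viability[imax]
      s <- s[s$time_d >= 0, , drop = FALSE]
    }
    s
  }))
  rownames(out) <- NULL
  structure(out, reference = reference,
            t0_scaling_applied = reference == "peak",
            class = c("growth_curve_dataset", "data.frame"))
}

#' Gaussian log-likelihood of growth-curve data under the TP model
#'
#' Measurement noise is i.i.d. Gaussian on the log fold-change with a
#' single scale per assay, matching the multiplicative error of
#' luminescence viability readings.  Model predictions are
#' `log N(t)/N(0)` (day-0 reference) or `log N(t0 + t)/N(t0)`
#' (peak reference) from the closed-form TP solution at the dataset's
#' concentrations.
#'
#' @param p a [tp_parameters()] object.
#' @param data a [normalize_growth_curves()] dataset.
#' @param sigma noise scale on log fold-change (> 0).
#' @return Scalar log-likelihood; `-Inf` (with attribute `"flagged"`)
#'   when the model predicts a nonpositive population.
#' @export
tp_log_likelihood <- function(p, data, sigma) {
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  peak <- isTRUE(attr(data, "t0_scaling_applied"))
  ll <- 0
  for (conc in unique(data$conc)) {
    sub <- data[data$conc == conc, ]
    tt <- sort(unique(sub$time_d))
    pred <- predict_fold(p, conc, tt, peak)
    if (any(!is.finite(pred)) || any(pred <= 0)) {
      out <- -Inf
      attr(out, "flagged") <- TRUE
      return(out)
    }
    lp <- log(pred)[match(sub$time_d, tt)]
    ll <- ll + sum(stats::dnorm(log(sub$viability), lp, sigma, log = TRUE))
  }
  ll
}

## model fold-change at one constant dose
predict_fold <- function(p, conc, times, peak) {
  if (peak) {
    p2 <- p
    p2$t0 <- 0
    p2$S0 <- 0
    solve_tp(p2, schedule_constant(conc), N_init = 1, t_grid = times)$N
  } else {
    solve_tp(p, schedule_constant(conc), N_init = 1, t_grid = times)$N
  }
}

## -------------------------------------------------------------------------
## Parameterisation of the fit

## Only the net pre-drug growth rate G0 = B - D0 is identifiable from
## fold-change data, so fits sample G0 and build tp_parameters with
## B = G0, D0 = 0.
tp_from_theta <- function(theta, variant, f0_value) {
  tp_parameters(
    B = theta[["G0"]], D0 = 0, k0 = theta[["k0"]], a = theta[["a"]],
    t0 = if ("t0" %in% names(theta)) theta[["t0"]] else 0,
    S0 = if ("S0" %in% names(theta)) theta[["S0"]] else 0,
    lambda_variant = variant,
    lambda0 = if ("lambda0" %in% names(theta)) theta[["lambda0"]] else 0,
    k = if ("k" %in% names(theta)) theta[["k"]] else 0,
    Dp = if ("Dp" %in% names(theta)) theta[["Dp"]] else 1e-3,
    f0 = if ("f0" %in% names(theta)) theta[["f0"]]
         else if (is.numeric(f0_value)) f0_value else 0)
}

active_parameters <- function(variant, f0_mode, datasets) {
  peak_only <- all(vapply(datasets, function(d)
    isTRUE(attr(d, "t0_scaling_applied")), logical(1)))
  pars <- "G0"
  pars <- c(pars, "k0", "a")
  if (!peak_only) pars <- c(pars, "t0", "S0")
  pars <- c(pars, switch(variant, zero = NULL, constant = "lambda0",
                         linear = "k", saturating = "lambda0"))
  has_persisters <- variant != "zero" || !identical(f0_mode, "zero")
  if (has_persisters) pars <- c(pars, "Dp")
  if (identical(f0_mode, "free")) pars <- c(pars, "f0")
  c(pars, paste0("sigma_", seq_along(datasets)))
}

#' Flat prior bounds for the TP fit
#'
#' Broad physical ranges used as the support of independent flat priors:
#' rates in `[0, 5]` per day, the switching slope `k` in `[0, 1]`,
#' `f0` in `[0, 1]`, the drug-effect delay `t0` in `[0, 5]` days,
#' `a` in `(0, 10]` per concentration unit, noise scales in
#' `(0.005, 2]`.  Any bound can be overridden, and collapsing a bound to
#' a point (`min == max`) fixes that parameter.
#'
#' @param parameters character vector of parameter names (see
#'   [fit_tp()]); defaults cover all supported names.
#' @param overrides named list of `c(min, max)` replacements.
#' @return Named list of `c(min, max)` bounds, class `"prior_bounds"`.
#' @export
prior_bounds <- function(parameters = NULL, overrides = list()) {
  defaults <- list(G0 = c(0, 5), k0 = c(0, 5), a = c(1e-3, 10),
                   t0 = c(0, 5), S0 = c(0, 5), lambda0 = c(0, 5),
                   k = c(0, 1), Dp = c(1e-4, 5), f0 = c(0, 1))
  sig <- c(0.005, 2)
  if (is.null(parameters)) parameters <- names(defaults)
  out <- lapply(parameters, function(nm) {
    if (nm %in% names(overrides)) {
      b <- overrides[[nm]]
    } else if (startsWith(nm, "sigma_")) {
      b <- sig
    } else if (nm %in% names(defaults)) {
      b <- defaults[[nm]]
    } else stop("no default prior for parameter '", nm, "'", call. = FALSE)
    if (length(b) != 2L || b[1] > b[2])
      stop("invalid bounds for '", nm, "'", call. = FALSE)
    b
  })
  names(out) <- parameters
  structure(out, class = "prior_bounds")
}

#' Physiologically informed prior bounds
#'
#' [prior_bounds()] restricted to ranges plausible for cultured cancer
#' cell lines, the recommended support for data analysis: net growth
#' below 1.5/day (doubling time above ~11 h), drug-induced kill below
#' 2.5/day, switching slope below 0.05/day per concentration unit,
#' persister death in `[0.001, 0.3]`/day, drug-effect delay below 3
#' days (cell counts start declining within 1-3 days of treatment),
#' pre-delay growth below 1/day, `a` in `[0.01, 2]`, and noise scales
#' in `[0.01, 0.5]`.  Constraining the flat priors to such ranges
#' removes a spurious high-rate mode in which implausibly fast birth
#' and death nearly cancel.
#'
#' @inheritParams prior_bounds
#' @return A [prior_bounds()] list.
#' @export
physiological_bounds <- function(parameters = NULL, overrides = list()) {
  phys <- list(G0 = c(0, 1.5), k0 = c(0, 2.5), a = c(0.01, 2),
               t0 = c(0, 3), S0 = c(0, 1), lambda0 = c(0, 0.5),
               k = c(0, 0.05), Dp = c(1e-3, 0.3), f0 = c(0, 1))
  phys[names(overrides)] <- overrides
  if (is.null(parameters)) parameters <- names(phys)
  sig <- setdiff(parameters, names(phys))
  phys <- c(phys, stats::setNames(rep(list(c(0.01, 0.5)), length(sig)),
                                  sig))
  prior_bounds(parameters, overrides = phys)
}

## joint log-likelihood over one or more datasets given a named theta
theta_log_lik <- function(theta, datasets, variant, f0_value) {
  p <- try(tp_from_theta(theta, variant, f0_value), silent = TRUE)
  if (inherits(p, "try-error")) return(-Inf)
  ll <- 0
  for (i in seq_along(datasets)) {
    s <- theta[[paste0("sigma_", i)]]
    li <- tp_log_likelihood(p, datasets[[i]], s)
    if (!is.finite(li)) return(-Inf)
    ll <- ll + li
  }
  ll
}

## Precompile the datasets into flat groups so the sampler's inner loop
## avoids all data-frame machinery: one group per (dataset, dose) with
## the unique times, the observation map, and the observed log folds.
compile_gc_data <- function(datasets) {
  groups <- list()
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    peak <- isTRUE(attr(d, "t0_scaling_applied"))
    for (conc in unique(d$conc)) {
      sub <- d[d$conc == conc, ]
      tt <- sort(unique(sub$time_d))
      groups[[length(groups) + 1L]] <- list(
        dataset = i, conc = conc, times = tt,
        idx = match(sub$time_d, tt), logy = log(sub$viability),
        peak = peak)
    }
  }
  groups
}

## direct closed-form log fold-change at one constant dose (hot path;
## mirrors solve_tp, validated against it in the tests)
fold_at <- function(th, variant, conc, times, peak) {
  sat <- th$a * conc / (1 + th$a * conc)
  lam <- switch(variant, zero = 0, constant = th$lambda0,
                linear = th$k * conc, saturating = th$lambda0 * sat)
  g <- th$G0 - th$k0 * sat - lam
  t0 <- if (peak) 0 else th$t0
  S0 <- if (peak) 0 else th$S0
  f0 <- th$f0
  N <- numeric(length(times))
  pre <- times < t0
  N[pre] <- exp(S0 * times[pre])
  tau <- times[!pre] - t0
  A <- exp(S0 * t0)
  X0 <- (1 - f0) * A
  Z0 <- f0 * A
  X <- X0 * exp(g * tau)
  den <- g + th$Dp
  Z <- if (abs(den) < 1e-10)
    Z0 * exp(-th$Dp * tau) + lam * X0 * tau * exp(-th$Dp * tau)
  else
    Z0 * exp(-th$Dp * tau) + lam * X0 * (exp(g * tau) - exp(-th$Dp * tau)) / den
  N[!pre] <- X + Z
  N
}

LOG_2PI <- log(2 * pi)

## profiled objective: the Gaussian noise scales maximise analytically at
## sigma_i^2 = SS_i / n_i, so the MAP search runs over the model
## parameters only (exact for the maximum, and a much easier search
## space); sigma_at() recovers the profiled scales
make_profiled_objective <- function(datasets, variant, f0_value,
                                    free_model, fixed) {
  groups <- compile_gc_data(datasets)
  n_ds <- length(datasets)
  n_i <- vapply(seq_len(n_ds), function(i)
    sum(vapply(groups, function(g)
      if (g$dataset == i) length(g$logy) else 0L, numeric(1))),
    numeric(1))
  defaults <- list(G0 = 0, k0 = 0, a = 1, t0 = 0, S0 = 0, lambda0 = 0,
                   k = 0, Dp = 1e-3,
                   f0 = if (is.numeric(f0_value)) f0_value else 0)
  ss_at <- function(x) {
    th <- defaults
    xv <- c(stats::setNames(x, free_model), unlist(fixed))
    for (nm in names(xv)) th[[nm]] <- xv[[nm]]
    if (th$Dp <= 0 || th$a <= 0) return(NULL)
    ss <- numeric(n_ds)
    for (gr in groups) {
      N <- fold_at(th, variant, gr$conc, gr$times, gr$peak)
      if (any(!is.finite(N)) || any(N <= 0)) return(NULL)
      res <- gr$logy - log(N)[gr$idx]
      ss[gr$dataset] <- ss[gr$dataset] + sum(res^2)
    }
    ss
  }
  obj <- function(x) {
    ss <- ss_at(x)
    if (is.null(ss)) return(-Inf)
    sig2 <- pmax(ss / n_i, 1e-12)
    sum(-n_i / 2 * (log(sig2) + 1 + LOG_2PI))
  }
  sigma_at <- function(x) {
    ss <- ss_at(x)
    if (is.null(ss)) return(rep(NA_real_, n_ds))
    sqrt(pmax(ss / n_i, 1e-12))
  }
  list(obj = obj, sigma_at = sigma_at)
}

make_objective <- function(datasets, variant, f0_value, free, fixed) {
  groups <- compile_gc_data(datasets)
  defaults <- list(G0 = 0, k0 = 0, a = 1, t0 = 0, S0 = 0, lambda0 = 0,
                   k = 0, Dp = 1e-3,
                   f0 = if (is.numeric(f0_value)) f0_value else 0)
  fixed <- fixed[order(match(names(fixed), names(defaults)))]
  function(x) {
    th <- defaults
    xv <- c(stats::setNames(x, free), unlist(fixed))
    for (nm in names(xv)) th[[nm]] <- xv[[nm]]
    if (th$Dp <= 0 || th$a <= 0) return(-Inf)
    ll <- 0
    for (gr in groups) {
      s <- xv[[paste0("sigma_", gr$dataset)]]
      if (is.null(s) || s <= 0) return(-Inf)
      N <- fold_at(th, variant, gr$conc, gr$times, gr$peak)
      if (any(!is.finite(N)) || any(N <= 0)) return(-Inf)
      res <- gr$logy - log(N)[gr$idx]
      ll <- ll - 0.5 * sum(res^2) / s^2 -
        length(res) * (log(s) + 0.5 * LOG_2PI)
    }
    ll
  }
}

## bounded differential evolution (rand/1/bin with dithered F); the
## posterior surface couples (G0, k0, a) along curved ridges that defeat
## plain multi-start local search, while DE at this evaluation cost
## (~0.1 ms) is affordable and reliable
de_optimize <- function(obj, lo, hi, np = 80, iter = 400, CR = 0.9,
                        seeds = NULL) {
  d <- length(lo)
  pop <- matrix(stats::runif(np * d, lo, hi), nrow = np, byrow = TRUE)
  if (!is.null(seeds)) {
    seeds <- seeds[seq_len(min(nrow(seeds), np)), , drop = FALSE]
    pop[seq_len(nrow(seeds)), ] <- pmin(pmax(seeds, lo), hi)
  }
  fit <- apply(pop, 1, obj)
  for (g in seq_len(iter)) {
    FF <- stats::runif(1, 0.5, 1.0)
    for (i in seq_len(np)) {
      idx <- sample.int(np, 3)
      while (any(idx == i)) idx <- sample.int(np, 3)
      mut <- pmin(pmax(pop[idx[1], ] + FF * (pop[idx[2], ] - pop[idx[3], ]),
                       lo), hi)
      cross <- stats::runif(d) < CR
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, mut, pop[i, ])
      ft <- obj(trial)
      if (ft >= fit[i]) {
        pop[i, ] <- trial
        fit[i] <- ft
      }
    }
  }
  ord <- order(fit, decreasing = TRUE)
  list(pop = pop[ord, , drop = FALSE], fit = fit[ord])
}

nm_polish <- function(obj, x0, lo, hi, restarts = 2, maxit = 1200) {
  eps <- (hi - lo) * 1e-4
  x <- pmin(pmax(x0, lo + eps), hi - eps)
  val <- NA_real_
  for (r in seq_len(restarts)) {
    f <- try(stats::optim(x, function(z) {
      if (any(z < lo) || any(z > hi)) return(1e12)
      -obj(z)
    }, method = "Nelder-Mead", control = list(maxit = maxit)),
    silent = TRUE)
    if (inherits(f, "try-error") || !is.finite(f$value)) break
    x <- f$par
    val <- -f$value
  }
  g <- try(stats::optim(pmin(pmax(x, lo + eps), hi - eps),
                        function(z) -obj(z), method = "L-BFGS-B",
                        lower = lo + eps, upper = hi - eps,
                        control = list(maxit = 60)), silent = TRUE)
  if (!inherits(g, "try-error") && is.finite(g$value) &&
      -g$value >= val %||% -Inf) {
    x <- g$par
    val <- -g$value
  }
  list(par = x, value = val)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

## fill a partial warm start: known parameter values carry over, newly
## introduced parameters get small plausible magnitudes
complete_init <- function(init, free, lo, hi) {
  defaults <- c(f0 = 0.01, lambda0 = 0.01, k = 0.005, Dp = 0.05)
  out <- (lo + hi) / 2
  names(out) <- free
  for (nm in intersect(names(defaults), free))
    out[nm] <- min(max(defaults[[nm]], lo[match(nm, free)]),
                   hi[match(nm, free)])
  keep <- intersect(names(init), free)
  out[keep] <- unlist(init)[keep]
  pmin(pmax(out, lo), hi)
}

## global MAP search: DE over the prior box, then Nelder-Mead +
## L-BFGS-B polish from the top DE members.  With a warm start the
## global stage shrinks to a seeded mini-DE plus local polish from the
## start and jittered copies.
map_fit <- function(obj, lo, hi, init = NULL, n_polish = 3,
                    de_np = 80, de_iter = 400) {
  d <- length(lo)
  best <- NULL
  consider <- function(cand) {
    if (is.finite(cand$value %||% NA) &&
        (is.null(best) || cand$value > best$value)) best <<- cand
  }
  if (!is.null(init)) {
    init <- pmin(pmax(init, lo), hi)
    jit <- t(vapply(seq_len(3), function(i)
      pmin(pmax(init + stats::rnorm(d) * (hi - lo) / 50, lo), hi),
      numeric(d)))
    seeds <- rbind(init, jit)
    de <- de_optimize(obj, lo, hi, np = max(30, 6 * d), iter = 100,
                      seeds = seeds)
    for (x0 in list(init, de$pop[1, ]))
      consider(nm_polish(obj, x0, lo, hi, restarts = 1, maxit = 800))
  } else {
    de <- de_optimize(obj, lo, hi, np = de_np, iter = de_iter)
    for (i in seq_len(min(n_polish, nrow(de$pop))))
      consider(nm_polish(obj, de$pop[i, ], lo, hi))
  }
  if (is.null(best)) stop("MAP optimisation failed", call. = FALSE)
  H <- try(stats::optimHess(best$par, function(x) -obj(x)), silent = TRUE)
  list(par = best$par, logpost = best$value,
       hessian = if (inherits(H, "try-error")) NULL else H)
}

## MAP over (model parameters, noise scales): global search on the
## sigma-profiled surface, then a short joint polish; falls back to the
## full search when a noise scale has been fixed by a collapsed prior
map_stage <- function(obj_full, prof, lo, hi, free, fixed, init = NULL) {
  sig_idx <- grep("^sigma_", free)
  if (!length(sig_idx) || any(startsWith(names(fixed), "sigma_")))
    return(map_fit(obj_full, lo, hi, init = init))
  mp <- map_fit(prof$obj, lo[-sig_idx], hi[-sig_idx],
                init = if (!is.null(init)) init[-sig_idx] else NULL,
                de_np = 50, de_iter = 200)
  sig <- pmin(pmax(prof$sigma_at(mp$par), lo[sig_idx]), hi[sig_idx])
  par <- numeric(length(free))
  par[-sig_idx] <- mp$par
  par[sig_idx] <- sig
  pol <- nm_polish(obj_full, par, lo, hi, restarts = 1, maxit = 600)
  if (!is.finite(pol$value %||% NA))
    pol <- list(par = par, value = obj_full(par))
  H <- try(stats::optimHess(pol$par, function(x) -obj_full(x)),
           silent = TRUE)
  list(par = pol$par, logpost = pol$value,
       hessian = if (inherits(H, "try-error")) NULL else H)
}

laplace_cov <- function(H, lo, hi) {
  d <- length(lo)
  fallback <- diag(((hi - lo) / 20)^2, d)
  if (is.null(H)) return(fallback)
  S <- try(solve(H + diag(1e-8, d)), silent = TRUE)
  if (inherits(S, "try-error")) return(fallback)
  ev <- eigen(S, symmetric = TRUE)
  if (any(ev$values <= 0)) return(fallback)
  ## cap proposal scales at the prior width so a flat direction cannot blow up
  cap <- (hi - lo)^2
  if (any(diag(S) > cap)) {
    sc <- sqrt(pmin(1, cap / diag(S)))
    S <- diag(sc) %*% S %*% diag(sc)
  }
  S
}

## highest-density interval: the shortest interval holding mass p, the
## convention of standard MCMC summaries (narrower than equal-tailed
## quantiles on the skewed side)
hdi_interval <- function(x, p = 0.95) {
  x <- sort(x)
  n <- length(x)
  w <- ceiling(p * n)
  if (w >= n) return(c(x[1], x[n]))
  widths <- x[(w + 1):n] - x[seq_len(n - w)]
  i <- which.min(widths)
  c(x[i], x[i + w])
}

split_rhat <- function(draw_list) {
  ## Gelman-Rubin on split chains, per parameter
  halves <- list()
  for (ch in draw_list) {
    n <- nrow(ch)
    h <- floor(n / 2)
    halves <- c(halves, list(ch[seq_len(h), , drop = FALSE],
                             ch[(h + 1):(2 * h), , drop = FALSE]))
  }
  m <- length(halves)
  n <- nrow(halves[[1]])
  sapply(seq_len(ncol(halves[[1]])), function(j) {
    means <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    vars <- vapply(halves, function(h) stats::var(h[, j]), numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
}

#' Bayesian fit of the TP model to growth-curve data
#'
#' Samples the posterior of the TP parameters given one or more
#' normalised growth-curve datasets (a joint fit sums their
#' log-likelihoods), under independent flat priors.  The sampler is a
#' multi-chain random-walk Metropolis initialised at the posterior mode
#' with a Laplace-approximation proposal covariance and global scale
#' adaptation during burn-in.  Convergence is monitored with the split-R
#' statistic; summaries use equal-tailed 2.5%/97.5% posterior intervals.
#'
#' @param data a `growth_curve_dataset` or a list of them.
#' @param variant switching-rate form: `"zero"`, `"constant"`,
#'   `"linear"`, `"saturating"`.
#' @param f0 `"zero"` (no pre-existing persisters), `"free"` (sampled),
#'   or a number fixing the initial persister fraction.
#' @param priors a [prior_bounds()] list covering the variant's
#'   parameters; collapsed bounds (`min == max`) fix a parameter.
#' @param n_chains,n_iter,n_burn sampler settings (post-burn-in draws
#'   per chain are `n_iter`).
#' @param seed integer seed; identical seeds and settings give identical
#'   summaries.
#' @param rhat_warn,rhat_fail split-R thresholds: above `rhat_warn` the
#'   summary is flagged, above `rhat_fail` a warning is raised.
#' @return An object of class `"tp_posterior"`: list with `summary`
#'   (data frame: `parameter`, `mean`, `sd`, `hdi_2.5`, `hdi_97.5`,
#'   `r_hat`), `draws` (per-chain matrices), `map` (mode), `logL_map`,
#'   `variant`, `f0_mode`, `n_obs`, `converged`.
#' @export
fit_tp <- function(data, variant = c("linear", "zero", "constant",
                                     "saturating"),
                   f0 = "zero", priors = NULL,
                   n_chains = 4, n_iter = 1500, n_burn = 750,
                   seed = 1L, rhat_warn = 1.01, rhat_fail = 1.05,
                   init = NULL) {
  variant <- match.arg(variant)
  datasets <- if (is.data.frame(data)) list(data) else data
  if (!length(datasets) || !all(vapply(datasets, nrow, integer(1)) > 0))
    stop("datasets must be nonempty", call. = FALSE)
  f0_mode <- if (is.numeric(f0)) f0 else match.arg(f0, c("zero", "free"))
  pars <- active_parameters(variant, f0_mode, datasets)
  if (is.null(priors)) priors <- prior_bounds(pars)
  if (!all(pars %in% names(priors)))
    stop("priors must cover parameters: ", paste(pars, collapse = ", "),
         call. = FALSE)
  priors <- priors[pars]
  lo <- vapply(priors, `[`, numeric(1), 1)
  hi <- vapply(priors, `[`, numeric(1), 2)
  fixed_mask <- hi - lo <= 0
  free <- pars[!fixed_mask]
  fixed <- as.list(lo[fixed_mask])
  set.seed(as.integer(seed))
  obj <- make_objective(datasets, variant, f0_mode, free, fixed)
  n_obs <- sum(vapply(datasets, nrow, integer(1)))

  if (!length(free)) {  # fully collapsed prior: posterior is the point
    theta <- unlist(fixed)
    summ <- data.frame(parameter = names(theta), mean = unname(theta),
                       sd = 0, hdi_2.5 = unname(theta),
                       hdi_97.5 = unname(theta), r_hat = 1)
    return(structure(list(summary = summ, draws = list(), map = theta,
                          logL_map = obj(numeric(0)), variant = variant,
                          f0_mode = f0_mode, n_obs = n_obs,
                          converged = TRUE),
                     class = "tp_posterior"))
  }

  lo_f <- lo[!fixed_mask]; hi_f <- hi[!fixed_mask]
  ini <- if (!is.null(init)) complete_init(init, free, lo_f, hi_f)
         else NULL
  prof <- make_profiled_objective(datasets, variant, f0_mode,
                                  setdiff(free, grep("^sigma_", free,
                                                     value = TRUE)),
                                  fixed)
  mp <- map_stage(obj, prof, lo_f, hi_f, free, fixed, init = ini)
  S <- laplace_cov(mp$hessian, lo_f, hi_f)
  L <- t(chol(S))
  d <- length(free)

  ## two-phase burn-in: phase 1 uses the Laplace proposal; phase 2
  ## re-estimates the proposal covariance from the pooled phase-1 draws
  ## (Haario-style adaptation), after which sampling is fixed
  run_chain <- function(x, lx, L, n_keep, n_adapt) {
    scale <- 2.38 / sqrt(d)
    acc_win <- 0L
    keep <- matrix(NA_real_, nrow = n_keep, ncol = d,
                   dimnames = list(NULL, free))
    total <- n_adapt + n_keep
    for (it in seq_len(total)) {
      prop <- x + scale * as.numeric(L %*% stats::rnorm(d))
      lp <- if (all(prop >= lo_f & prop <= hi_f)) obj(prop) else -Inf
      if (is.finite(lp) && log(stats::runif(1)) < lp - lx) {
        x <- prop; lx <- lp; acc_win <- acc_win + 1L
      }
      if (it <= n_adapt && it %% 50L == 0L) {
        scale <- scale * exp(acc_win / 50 - 0.234)
        acc_win <- 0L
      }
      if (it > n_adapt) keep[it - n_adapt, ] <- x
    }
    list(keep = keep, x = x, lx = lx)
  }
  starts <- lapply(seq_len(n_chains), function(ch) {
    x <- mp$par + as.numeric(L %*% stats::rnorm(d)) * 0.5
    x <- pmin(pmax(x, lo_f), hi_f)
    lx <- obj(x)
    if (!is.finite(lx)) { x <- mp$par; lx <- mp$logpost }
    list(x = x, lx = lx)
  })
  phase1 <- lapply(starts, function(s)
    run_chain(s$x, s$lx, L, n_keep = n_burn, n_adapt = n_burn))
  pool <- do.call(rbind, lapply(phase1, `[[`, "keep"))
  S2 <- stats::cov(pool) + diag(1e-10 + 1e-6 * diag(S), d)
  L2 <- tryCatch(t(chol(S2)), error = function(e) L)
  draws <- lapply(phase1, function(s)
    run_chain(s$x, s$lx, L2, n_keep = n_iter, n_adapt = n_burn))
  draws <- lapply(draws, `[[`, "keep")
  all_draws <- do.call(rbind, draws)
  rhat <- split_rhat(draws)
  hdis <- apply(all_draws, 2, hdi_interval)
  summ <- data.frame(
    parameter = free,
    mean = colMeans(all_draws),
    sd = apply(all_draws, 2, stats::sd),
    hdi_2.5 = hdis[1, ],
    hdi_97.5 = hdis[2, ],
    r_hat = rhat, row.names = NULL)
  if (length(fixed))
    summ <- rbind(summ, data.frame(parameter = names(fixed),
                                   mean = unlist(fixed), sd = 0,
                                   hdi_2.5 = unlist(fixed),
                                   hdi_97.5 = unlist(fixed), r_hat = 1))
  converged <- all(rhat < rhat_warn)
  if (any(rhat >= rhat_fail))
    warning(sprintf("sampler not converged: max split-R = %.3f",
                    max(rhat)), call. = FALSE)
  structure(list(summary = summ, draws = draws,
                 map = stats::setNames(mp$par, free), logL_map = mp$logpost,
                 variant = variant, f0_mode = f0_mode, n_obs = n_obs,
                 converged = converged),
            class = "tp_posterior")
}

#' @export
print.tp_posterior <- function(x, ...) {
  cat(sprintf("TP posterior (variant %s, f0 %s), n_obs = %d\n",
              x$variant, format(x$f0_mode), x$n_obs))
  s <- x$summary
  s[, -1] <- round(s[, -1], 4)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Maximum-likelihood score of one TP model variant
#'
#' Optimises the log-likelihood over the variant's free parameters and
#' returns the information-criterion score used for model selection:
#' `BIC = k log(n) - 2 logL`, `AIC = 2 k - 2 logL`.
#'
#' @inheritParams fit_tp
#' @return A one-row data frame of class `"model_score"`: `variant`,
#'   `f0_mode`, `logL`, `n_params`, `n_obs`, `BIC`, `AIC`.
#' @export
model_score <- function(data, variant, f0 = "zero", priors = NULL,
                        seed = NULL, init = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  datasets <- if (is.data.frame(data)) list(data) else data
  f0_mode <- if (is.numeric(f0)) f0 else match.arg(f0, c("zero", "free"))
  pars <- active_parameters(variant, f0_mode, datasets)
  if (is.null(priors)) priors <- prior_bounds(pars)
  priors <- priors[pars]
  lo <- vapply(priors, `[`, numeric(1), 1)
  hi <- vapply(priors, `[`, numeric(1), 2)
  fixed_mask <- hi - lo <= 0
  free <- pars[!fixed_mask]
  obj <- make_objective(datasets, variant, f0_mode, free,
                        as.list(lo[fixed_mask]))
  ini <- if (!is.null(init))
    complete_init(init, free, lo[!fixed_mask], hi[!fixed_mask]) else NULL
  fixed <- as.list(lo[fixed_mask])
  prof <- make_profiled_objective(datasets, variant, f0_mode,
                                  setdiff(free, grep("^sigma_", free,
                                                     value = TRUE)),
                                  fixed)
  mp <- map_stage(obj, prof, lo[!fixed_mask], hi[!fixed_mask], free,
                  fixed, init = ini)
  k <- length(free)
  n <- sum(vapply(datasets, nrow, integer(1)))
  out <- data.frame(variant = variant,
                    f0_mode = format(f0_mode), logL = mp$logpost,
                    n_params = k, n_obs = n,
                    BIC = k * log(n) - 2 * mp$logpost,
                    AIC = 2 * k - 2 * mp$logpost)
  attr(out, "map") <- stats::setNames(mp$par, free)
  class(out) <- c("model_score", "data.frame")
  out
}

#' Score the full variant grid
#'
#' Computes [model_score()] for every switching-rate form crossed with
#' the two persister-initialisation scenarios (f0 = 0 and f0 free),
#' the grid used for BIC/AIC selection.
#'
#' @inheritParams fit_tp
#' @param variants switching-rate forms to include.
#' @return Row-bound `model_score` data frame.
#' @export
score_variant_grid <- function(data, priors = NULL,
                               variants = c("zero", "constant", "linear",
                                            "saturating"),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  grid <- expand.grid(f0 = c("zero", "free"), variant = variants,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  warm <- list()
  merge_warm <- function() {
    init <- NULL
    for (w in warm) {
      if (is.null(init)) init <- unlist(w)
      init[names(w)] <- unlist(w)[names(w)]
    }
    init
  }
  ## warm-start each variant from the modes already found: the shared
  ## parameters transfer across variants, so only the first fit pays for
  ## the full global search
  for (i in seq_len(nrow(grid))) {
    sc <- model_score(data, grid$variant[i], grid$f0[i], priors,
                      init = merge_warm())
    warm[[length(warm) + 1L]] <- attr(sc, "map")
    out[[i]] <- sc
  }
  ## nesting consistency: the free-f0 model contains its f0 = 0 twin, so
  ## its maximised likelihood is at least the twin's; if the search fell
  ## short, the twin's optimum (an admissible free-model point) stands in
  for (v in unique(grid$variant)) {
    iz <- which(grid$variant == v & grid$f0 == "zero")
    ifr <- which(grid$variant == v & grid$f0 == "free")
    ## if the free twin found a clearly better basin, give the zero twin
    ## a polish from that mode projected onto f0 = 0
    if (out[[ifr]]$logL > out[[iz]]$logL + 0.5) {
      sc <- model_score(data, v, "zero", priors,
                        init = attr(out[[ifr]], "map"))
      if (sc$logL > out[[iz]]$logL) out[[iz]] <- sc
    }
    if (out[[ifr]]$logL < out[[iz]]$logL) {
      k <- out[[ifr]]$n_params
      n <- out[[ifr]]$n_obs
      out[[ifr]]$logL <- out[[iz]]$logL
      out[[ifr]]$BIC <- k * log(n) - 2 * out[[iz]]$logL
      out[[ifr]]$AIC <- 2 * k - 2 * out[[iz]]$logL
    }
  }
  out <- do.call(rbind, out)
  class(out) <- c("model_score", "data.frame")
  out
}

#' Rank model variants by information criteria
#'
#' Ranks a set of [model_score()] rows by BIC (primary criterion) and
#' reports the AIC ranking alongside; flags any disagreement between the
#' two criteria on the best model.
#'
#' @param scores a `model_score` data frame (rows from [model_score()] or
#'   [score_variant_grid()]).
#' @return List of class `"model_comparison"`: `table` (scores with
#'   `rank_BIC`, `rank_AIC`, sorted by BIC), `selected` (variant/f0 of
#'   the BIC argmin), `criteria_agree`.
#' @export
compare_models <- function(scores) {
  if (length(unique(scores$n_obs)) != 1L)
    stop("model scores were computed on different datasets (n_obs differ)",
         call. = FALSE)
  scores$rank_BIC <- rank(scores$BIC, ties.method = "min")
  scores$rank_AIC <- rank(scores$AIC, ties.method = "min")
  scores <- scores[order(scores$BIC), , drop = FALSE]
  rownames(scores) <- NULL
  sel <- scores[1, c("variant", "f0_mode")]
  agree <- which.min(scores$AIC) == 1L
  structure(list(table = scores, selected = sel, criteria_agree = agree),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model selection (ranked by BIC)\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("selected: variant %s, f0 %s%s\n", x$selected$variant,
              x$selected$f0_mode,
              if (x$criteria_agree) " (BIC and AIC agree)"
              else " (AIC disagrees; both reported)"))
  invisible(x)
}
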