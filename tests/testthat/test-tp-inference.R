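make_raw <- function(values) {
  data.frame(assay = "dose_response", time_d = seq_along(values) - 1,
             conc = 5, replicate = 1, viability = values)
}

test_that("normalisation divides by the reference reading", {
  raw <- make_raw(c(100, 80, 50))
  out <- normalize_growth_curves(raw)
  expect_equal(out$viability, c(1, 0.8, 0.5))
  ## constant raw viability gives all-ones
  expect_equal(normalize_growth_curves(make_raw(rep(7, 4)))$viability,
               rep(1, 4))
  ## missing day-0 reading is an error
  raw2 <- make_raw(c(100, 50))
  raw2$time_d <- c(1, 2)
  expect_error(normalize_growth_curves(raw2), "day-0")
  ## peak scaling puts the maximum at time zero with value one
  raw3 <- make_raw(c(50, 100, 40, 20))
  pk <- normalize_growth_curves(raw3, reference = "peak")
  expect_equal(pk$time_d[1], 0)
  expect_equal(pk$viability[1], 1)
  expect_true(isTRUE(attr(pk, "t0_scaling_applied")))
})

test_that("likelihood is exact at zero residuals and decreases with misfit", {
  p <- widr$fit
  dat <- normalize_growth_curves(
    gen_dose_response(p, replicates = 2, noise = noise_model(0),
                      seed = 1))
  sigma <- 0.07
  ll0 <- tp_log_likelihood(p, dat, sigma)
  ## zero residuals: the Gaussian normalisation constant only
  expect_equal(ll0, nrow(dat) * dnorm(0, 0, sigma, log = TRUE))
  ## doubling residuals (by scaling the data) lowers the likelihood
  worse <- dat
  worse$viability <- worse$viability * exp(0.05)
  ll1 <- tp_log_likelihood(p, worse, sigma)
  worse$viability <- dat$viability * exp(0.1)
  ll2 <- tp_log_likelihood(p, worse, sigma)
  expect_true(ll0 > ll1 && ll1 > ll2)
  expect_error(tp_log_likelihood(p, dat, 0), "sigma")
})

test_that("compiled objective agrees with the reference likelihood", {
  p <- widr$fit
  dr <- normalize_growth_curves(gen_dose_response(p, seed = 2))
  sd1 <- normalize_growth_curves(gen_single_dose(p, seed = 3))
  free <- c("G0", "k0", "a", "t0", "S0", "k", "Dp", "sigma_1", "sigma_2")
  obj <- persisterdyn:::make_objective(list(dr, sd1), "linear", "zero",
                                       free, list())
  theta <- c(p$B - p$D0, p$k0, p$a, p$t0, p$S0, p$k, p$Dp, 0.12, 0.09)
  ref <- tp_log_likelihood(p, dr, 0.12) + tp_log_likelihood(p, sd1, 0.09)
  expect_equal(obj(theta), ref, tolerance = 1e-10)
})

test_that("maximised grid likelihood matches brute-force grid search", {
  ## 3-parameter toy problem: G0, k, sigma with everything else fixed
  p <- widr$fit
  dat <- normalize_growth_curves(gen_single_dose(p, replicates = 2,
                                                 seed = 4))
  fixed <- list(k0 = p$k0, a = p$a, t0 = p$t0, S0 = p$S0, Dp = p$Dp)
  obj <- persisterdyn:::make_objective(list(dat), "linear", "zero",
                                       c("G0", "k", "sigma_1"), fixed)
  G0s <- seq(0.3, 0.7, by = 0.02)
  ks <- seq(0, 0.01, by = 5e-4)
  sig <- seq(0.05, 0.2, by = 0.01)
  grid <- expand.grid(G0 = G0s, k = ks, sigma = sig)
  vals <- apply(grid, 1, function(r) obj(unname(r)))
  brute <- grid[which.max(vals), ]
  ## polishing the brute-force winner must not move it by more than one
  ## grid cell, and can only improve the objective
  fit <- stats::optim(as.numeric(brute), function(x) -obj(x),
                      method = "L-BFGS-B",
                      lower = c(0.3, 0, 0.05), upper = c(0.7, 0.01, 0.2))
  expect_lt(abs(fit$par[1] - brute$G0), 0.021)
  expect_lt(abs(fit$par[2] - brute$k), 5.1e-4)
  expect_lt(abs(fit$par[3] - brute$sigma), 0.011)
  expect_gte(-fit$value, max(vals) - 1e-6)
})

test_that("information criteria follow their defining formulas", {
  sc <- data.frame(variant = "x", f0_mode = "zero", logL = -10,
                   n_params = 3, n_obs = 50,
                   BIC = 3 * log(50) + 20, AIC = 26)
  expect_equal(sc$BIC, 3 * log(50) - 2 * (-10))
  expect_equal(sc$AIC, 2 * 3 - 2 * (-10))
  ## equal logL, different complexity: simpler model wins both criteria
  s2 <- rbind(sc, data.frame(variant = "y", f0_mode = "zero", logL = -10,
                             n_params = 5, n_obs = 50,
                             BIC = 5 * log(50) + 20, AIC = 30))
  class(s2) <- c("model_score", "data.frame")
  cmp <- compare_models(s2)
  expect_equal(cmp$selected$variant, "x")
  expect_true(cmp$criteria_agree)
  s2$n_obs[2] <- 60
  expect_error(compare_models(s2), "n_obs")
})

test_that("a collapsed prior fixes the posterior at the point", {
  p <- widr$fit
  dat <- normalize_growth_curves(gen_single_dose(p, seed = 6))
  pars <- persisterdyn:::active_parameters("linear", "zero", list(dat))
  pr <- prior_bounds(pars)
  for (nm in pars) pr[[nm]] <- c(0.25, 0.25)
  fit <- fit_tp(dat, variant = "linear", f0 = "zero", priors = pr,
                seed = 1)
  expect_equal(fit$summary$mean, rep(0.25, length(pars)))
  expect_equal(fit$summary$sd, rep(0, length(pars)))
})

test_that("fixing f0 well above zero degrades the fit of f0 = 0 data", {
  p <- widr$fit
  dr <- normalize_growth_curves(gen_dose_response(p, seed = 7))
  sd1 <- normalize_growth_curves(gen_single_dose(p, seed = 8))
  data <- list(dr, sd1)
  score_at_f0 <- function(f0) {
    set.seed(42)
    model_score(data, "linear", f0 = f0,
                priors = physiological_bounds(
                  persisterdyn:::active_parameters("linear", f0, data)))
  }
  s0 <- score_at_f0(0)
  s10 <- score_at_f0(0.1)
  expect_gt(s0$logL, s10$logL + 5)
})

test_that("posterior summaries are reproducible and ordered", {
  p <- widr$fit
  dat <- normalize_growth_curves(gen_single_dose(p, seed = 9))
  pars <- persisterdyn:::active_parameters("linear", "zero", list(dat))
  pr <- physiological_bounds(pars)
  fit1 <- suppressWarnings(fit_tp(dat, variant = "linear", priors = pr,
                                  n_chains = 2, n_iter = 300,
                                  n_burn = 200, seed = 33))
  fit2 <- suppressWarnings(fit_tp(dat, variant = "linear", priors = pr,
                                  n_chains = 2, n_iter = 300,
                                  n_burn = 200, seed = 33))
  expect_identical(fit1$summary, fit2$summary)
  s <- fit1$summary
  expect_true(all(s$hdi_2.5 <= s$mean + 1e-9))
  expect_true(all(s$mean <= s$hdi_97.5 + 1e-9))
  expect_true(all(s$r_hat > 0))
})
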