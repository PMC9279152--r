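m_std <- establishment_model(b = 0.65, d = 0.15)

test_that("establishment probability has the birth-death limits", {
  expect_equal(establishment_probability(m_std, 0), 1)
  expect_equal(establishment_probability(m_std, Inf), 1 - 0.15 / 0.65)
  psi <- establishment_probability(m_std, seq(0, 40, by = 0.2))
  expect_true(all(diff(psi) < 0))
  pure_birth <- establishment_model(b = 0.5, d = 0)
  expect_equal(establishment_probability(pure_birth, c(0, 3, 1e6)),
               c(1, 1, 1))
  expect_error(establishment_model(b = 0.3, d = 0.4), "supercritical")
  expect_error(establishment_probability(m_std, -1), "nonnegative")
})

test_that("expected established mutants match closed-form integrals", {
  ## constant population, no death: mu * X0 * T
  m0 <- establishment_model(b = 0.5, d = 0)
  tt <- seq(0, 12, by = 0.01)
  em <- expected_mutants(1e-6, tt, rep(1000, length(tt)), m0)
  expect_equal(em$value, 1e-6 * 1000 * 12, tolerance = 1e-10)
  ## exponentially decaying persisters with psi == 1:
  ## mu * Z0 * (1 - exp(-Dp T)) / Dp
  Dp <- 0.05
  em2 <- expected_mutants_persisters(2e-5, tt, 500 * exp(-Dp * tt), m0)
  expect_equal(em2$value, 2e-5 * 500 * (1 - exp(-Dp * 12)) / Dp,
               tolerance = 1e-5)
  expect_equal(expected_mutants(0, tt, rep(10, length(tt)), m_std)$value, 0)
})

test_that("quadrature converges under grid refinement", {
  X <- function(t) 200 * exp(0.4 * t)
  vals <- vapply(c(0.2, 0.005), function(h) {
    tt <- seq(0, 10, by = h)
    expected_mutants(1e-6, tt, X(tt), m_std)$value
  }, numeric(1))
  tt <- seq(0, 10, by = 1e-4)  # near-exact Riemann reference
  ref <- expected_mutants(1e-6, tt, X(tt), m_std)$value
  expect_equal(vals[2], ref, tolerance = 1e-6)
  expect_lt(abs(vals[2] - ref), abs(vals[1] - ref))
})

test_that("resistance probability is the Poisson positive mass", {
  expect_equal(p_resistant(0), 0)
  expect_equal(p_resistant(log(2)), 0.5)
  expect_true(all(diff(p_resistant(seq(0, 5, by = 0.1))) > 0))
  tt <- seq(0, 5, by = 0.01)
  em <- expected_mutants(1e-5, tt, rep(100, length(tt)), m_std)
  expect_equal(p_resistant(em), 1 - exp(-em$value))
})

test_that("rate inversion undoes the positive-fraction map", {
  expect_equal(estimate_mutation_rate(0, 100, I = 1e4)$estimate, 0)
  est <- estimate_mutation_rate(1 - exp(-1), NULL, I = 1)
  expect_equal(est$estimate, 1, tolerance = 1e-12)
  ## round trip through a Poisson well count
  mu <- 3e-6
  I <- 2.4e4
  p <- 1 - exp(-mu * I)
  est2 <- estimate_mutation_rate(round(p * 1e6), 1e6, I = I)
  expect_equal(est2$estimate, mu, tolerance = 0.05)
  expect_true(est2$lower < mu && est2$upper > mu)
  ## all wells positive: lower bound only
  expect_warning(est3 <- estimate_mutation_rate(50, 50, I = 1e4),
                 "lower bound")
  expect_true(is.na(est3$estimate) && is.finite(est3$lower))
})

test_that("colony visibility rises from 0 to the establishment limit", {
  V <- colony_visibility(m_std, seq(-5, 60, by = 0.5), threshold = 50)
  expect_equal(V[1], 0)
  expect_true(all(diff(V) >= -1e-12))
  expect_equal(V[length(V)], 1 - m_std$d / m_std$b, tolerance = 1e-6)
  ## visibility crossing happens around the deterministic lag
  lag <- colony_detection_lag(m_std, 50)
  ss <- seq(-5, 60, by = 0.5)
  half <- ss[which(V >= max(V) / 2)[1]]
  expect_lt(abs(half - lag), 3)
})

test_that("fold ratio is invariant to a common integral rescaling", {
  a <- estimate_mutation_rate(30, 480, I = 3e4)
  b <- estimate_mutation_rate(12, 480, I = 1.5e3)
  fold1 <- b$estimate / a$estimate
  a2 <- estimate_mutation_rate(30, 480, I = 3e4 * 7)
  b2 <- estimate_mutation_rate(12, 480, I = 1.5e3 * 7)
  expect_equal(b2$estimate / a2$estimate, fold1, tolerance = 1e-12)
})

test_that("inferred rates are robust to the resistant division rate", {
  ## +/- 25% on the resistant b perturbs the establishment-weighted
  ## integrals, hence the single-class inversions mu = -log(1-p)/I, by
  ## < 20%
  des <- experiment_design(n_plates = 1, wells_per_plate = 480)
  base <- widr$assay
  ints_at <- function(f) persisterdyn:::assay_integrals(
    des, base, m = establishment_model(base$b * f, base$d))
  ref <- ints_at(1)
  mu_s_ref <- estimate_mutation_rate(60, 480, I = ref$I_s)$estimate
  mu_p_ref <- estimate_mutation_rate(14, 480, I = ref$I_p_late)$estimate
  for (f in c(0.75, 1.25)) {
    ints <- ints_at(f)
    mu_s <- estimate_mutation_rate(60, 480, I = ints$I_s)$estimate
    mu_p <- estimate_mutation_rate(14, 480, I = ints$I_p_late)$estimate
    expect_lt(abs(mu_s - mu_s_ref) / mu_s_ref, 0.2)
    expect_lt(abs(mu_p - mu_p_ref) / mu_p_ref, 0.2)
  }
})

test_that("count validation and error paths work", {
  des <- experiment_design(n_plates = 1, wells_per_plate = 10)
  expect_error(estimate_rates_from_outcomes(
    list(wells = 10, early_positives = 12, late_positives = 0),
    des, widr$assay), "exceed")
  expect_error(joint_posterior_fold(
    list(wells = 10, early_positives = 12, late_positives = 0),
    des, widr$assay), "exceed")
  expect_error(joint_posterior_fold(
    list(wells = 10, early_positives = 1, late_positives = 0),
    des, widr$assay, f0_grid = c(0, 1)), "f0_grid")
})

test_that("joint posterior normalises and reduces on a point grid", {
  des <- experiment_design(n_plates = 1, wells_per_plate = 480)
  counts <- list(wells = 480, early_positives = 62, late_positives = 15)
  jp <- joint_posterior_fold(counts, des, widr$assay,
                             f0_grid = c(0, 0.001, 0.005),
                             fold_grid = 10^seq(-1, 3, length.out = 41))
  expect_equal(sum(jp$mass), 1, tolerance = 1e-9)
  expect_equal(rowSums(jp$mass), jp$marginal_f0, tolerance = 1e-12)
  expect_equal(colSums(jp$mass), jp$marginal_fold, tolerance = 1e-12)
  ## degenerate f0 grid: a pure fold profile
  jp0 <- joint_posterior_fold(counts, des, widr$assay, f0_grid = 0,
                              fold_grid = 10^seq(-1, 3, length.out = 41))
  expect_equal(dim(jp0$mass), c(1L, 41L))
  expect_equal(sum(jp0$mass), 1, tolerance = 1e-9)
  ## the data were generated at fold 10: mass should sit above fold 1
  expect_gt(sum(jp$marginal_fold[jp$fold > 1]), 0.95)
})
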