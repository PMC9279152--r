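test_that("parameter and design invariants are enforced", {
  expect_error(mcld_parameters(b = 0.3, d = 0.4, mu_s = 0, mu_p = 0,
                               tp = tiny_tp, dose = 1), "b > d")
  expect_error(mcld_parameters(b = 3, d = 0.1, mu_s = 0, mu_p = 0,
                               tp = tiny_tp, dose = 1, dt = 0.05),
               "step-size")
  expect_error(experiment_design(early_cutoff_days = 80,
                                 late_cutoff_days = 70), "early_cutoff")
  expect_error(experiment_design(wells_per_plate = 0), "positive integers")
  d <- experiment_design()
  expect_equal(d$n_plates * d$wells_per_plate, 1920L)
})

test_that("a step with all rates zero leaves the state unchanged", {
  st <- well_state(c(10L, 250L, 3L), persisters = c(1L, 0L, 7L))
  st2 <- step_wells(st, "expansion", tiny_params,
                    rates = list(b = 0, d = 0, mu_s = 0, nu_pre = 0))
  expect_identical(st2$S, st$S)
  expect_identical(st2$P, st$P)
  expect_equal(length(st2$lin$size), 0L)
})

test_that("per-cell event probabilities above 1 are a step-size error", {
  st <- well_state(rep(100L, 4))
  expect_error(step_wells(st, "expansion", tiny_params, dt = 5,
                          rates = list(b = 0.3, d = 0.1, mu_s = 0,
                                       nu_pre = 0)),
               "reduce dt")
})

test_that("pure-birth growth matches the analytic mean", {
  set.seed(41)
  n <- 1000
  st <- well_state(rep(20L, n))
  p <- mcld_parameters(b = 0.4, d = 0, mu_s = 0, mu_p = 0, tp = tiny_tp,
                       dose = 0, dt = 0.02)
  for (i in seq_len(150)) st <- step_wells(st, "expansion", p)
  t_end <- 150 * 0.02
  expected <- 20 * exp(0.4 * t_end)
  se <- stats::sd(st$S) / sqrt(n)
  expect_lt(abs(mean(st$S) - expected), 3 * se + 0.02 * expected)
})

test_that("zero mutation rates give colony class none everywhere", {
  set.seed(7)
  out <- run_well(tiny_design, tiny_params)
  expect_equal(out$colony_class, "none")
  expect_true(is.na(out$colony_time_d))
  set.seed(8)
  sim <- simulate_experiment(tiny_design, tiny_params, master_seed = 3)
  expect_true(all(sim$outcomes$colony_class == "none"))
  expect_true(all(sim$outcomes$colony_origin == "none"))
})

test_that("expansion stops at the per-well target", {
  set.seed(9)
  sim <- persisterdyn:::sim_wells(50, tiny_design, tiny_params)
  s0 <- sim$outcomes$sensitive_at_treatment
  expect_true(all(s0 >= tiny_design$expansion_target_cells))
  expect_true(all(s0 <= 2 * tiny_design$expansion_target_cells))
  expect_true(all(is.finite(sim$t_hit)))
})

test_that("identical master seeds reproduce the outcome table exactly", {
  p <- widr$assay
  des <- experiment_design(n_plates = 2, wells_per_plate = 12,
                           seed_cells_per_well = 100,
                           expansion_target_cells = 2000, T_obs = 40,
                           early_cutoff_days = 15, late_cutoff_days = 30)
  a <- simulate_experiment(des, p, master_seed = 11)
  b <- simulate_experiment(des, p, master_seed = 11)
  c <- simulate_experiment(des, p, master_seed = 12)
  expect_identical(a$outcomes, b$outcomes)
  expect_false(identical(a$outcomes, c$outcomes))
  expect_equal(nrow(a$outcomes), 24L)
  expect_equal(nrow(a$summary), 2L)
})

test_that("counts stay nonnegative integers through a long run", {
  set.seed(10)
  p <- widr$assay
  des <- experiment_design(n_plates = 1, wells_per_plate = 30,
                           seed_cells_per_well = 100,
                           expansion_target_cells = 1500, T_obs = 30,
                           early_cutoff_days = 10, late_cutoff_days = 25)
  sim <- persisterdyn:::sim_wells(30, des, p)
  o <- sim$outcomes
  for (col in c("final_sensitive", "final_persisters", "final_resistant",
                "established_sensitive_derived",
                "established_persister_derived")) {
    expect_true(all(o[[col]] >= 0))
    expect_true(all(o[[col]] == round(o[[col]])))
  }
  cls <- o$colony_class
  tm <- o$colony_time_d
  expect_true(all(is.na(tm[cls == "none"])))
  expect_true(all(tm[cls == "early"] <= des$early_cutoff_days))
  expect_true(all(tm[cls == "late"] >= des$late_cutoff_days))
  mid <- cls == "intermediate"
  expect_true(all(tm[mid] > des$early_cutoff_days &
                    tm[mid] < des$late_cutoff_days))
})

test_that("with only spontaneous mutation, colonies are sensitive-derived
           and early", {
  p <- widr$assay
  p$mu_s <- 4e-5  # enough mutants at this small scale
  p$mu_p <- 0
  des <- experiment_design(n_plates = 1, wells_per_plate = 150,
                           seed_cells_per_well = 200,
                           expansion_target_cells = 5000, T_obs = 60,
                           early_cutoff_days = 20, late_cutoff_days = 45)
  set.seed(21)
  o <- persisterdyn:::sim_wells(150, des, p)$outcomes
  with_col <- o[o$colony_class != "none", ]
  expect_gt(nrow(with_col), 5)
  expect_true(all(with_col$colony_origin == "sensitive-derived"))
  expect_true(mean(with_col$colony_class == "early") > 0.9)
})

test_that("established persister-derived mutants are Poisson across wells", {
  p <- widr$assay
  p$mu_s <- 0
  p$mu_p <- 4e-4  # boosted so counts are informative at 400 wells
  des <- experiment_design(n_plates = 1, wells_per_plate = 400,
                           seed_cells_per_well = 200,
                           expansion_target_cells = 4000, T_obs = 40,
                           early_cutoff_days = 15, late_cutoff_days = 30)
  set.seed(31)
  o <- persisterdyn:::sim_wells(400, des, p)$outcomes
  counts <- o$established_persister_derived
  expect_gt(mean(counts), 0.05)
  res <- dispersion_test(counts)
  expect_equal(res$verdict, "poisson-consistent")
})

test_that("halving dt leaves summary fractions within Monte-Carlo error", {
  p <- widr$assay
  p$mu_s <- 2e-5
  des <- experiment_design(n_plates = 1, wells_per_plate = 300,
                           seed_cells_per_well = 200,
                           expansion_target_cells = 4000, T_obs = 40,
                           early_cutoff_days = 15, late_cutoff_days = 30)
  frac <- function(dtv, seed) {
    p2 <- p
    p2$dt <- dtv
    set.seed(seed)
    o <- persisterdyn:::sim_wells(300, des, p2)$outcomes
    mean(o$colony_class != "none")
  }
  f1 <- frac(0.05, 51)
  f2 <- frac(0.025, 52)
  se <- sqrt(f1 * (1 - f1) / 300 + f2 * (1 - f2) / 300)
  expect_lt(abs(f1 - f2), 3 * se + 0.02)
})
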