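test_that("death rate interpolates between D0 and D0 + k0", {
  p <- tp_parameters(B = 0.5, D0 = 0.1, k0 = 1.2, a = 0.25, Dp = 0.03)
  expect_equal(death_rate(p, 0), 0.1)
  expect_equal(death_rate(p, Inf), 1.3)
  expect_equal(death_rate(p, 1 / p$a), 0.1 + 1.2 / 2)  # half-saturation
  M <- seq(0, 50, by = 0.5)
  D <- death_rate(p, M)
  expect_true(all(diff(D) >= 0))
  expect_true(all(D >= 0.1 & D <= 1.3))
  expect_error(death_rate(p, -1), "nonnegative")
})

test_that("switching-rate variants follow their functional forms", {
  base <- list(B = 0.5, D0 = 0.1, k0 = 1, a = 0.2, Dp = 0.03)
  pz <- do.call(tp_parameters, c(base, lambda_variant = "zero"))
  pc <- do.call(tp_parameters, c(base, lambda_variant = "constant",
                                 lambda0 = 0.04))
  pl <- do.call(tp_parameters, c(base, lambda_variant = "linear",
                                 k = 0.01))
  ps <- do.call(tp_parameters, c(base, lambda_variant = "saturating",
                                 lambda0 = 0.04))
  expect_equal(transition_rate(pz, c(0, 7, 100)), c(0, 0, 0))
  expect_equal(transition_rate(pc, c(0, 7)), c(0.04, 0.04))
  expect_equal(transition_rate(pl, 0), 0)
  expect_equal(transition_rate(pl, 50), 0.5)  # k * M
  expect_equal(transition_rate(ps, 1 / base$a), 0.02)
  for (p in list(pc, pl, ps)) {
    lam <- transition_rate(p, seq(0, 30, by = 0.5))
    expect_true(all(lam >= 0) && all(diff(lam) >= -1e-12))
  }
})

test_that("parameter and schedule validation rejects bad input", {
  expect_error(tp_parameters(B = 0.5, D0 = 0.1, k0 = 1, a = 0, Dp = 0.03),
               "'a'")
  expect_error(tp_parameters(B = 0.5, D0 = 0.1, k0 = 1, a = 1, Dp = 0),
               "Dp")
  expect_error(tp_parameters(B = 0.5, D0 = 0.1, k0 = 1, a = 1, Dp = 0.1,
                             f0 = 1.2), "f0")
  expect_error(tp_parameters(B = NA, D0 = 0.1, k0 = 1, a = 1, Dp = 0.1),
               "finite")
  expect_error(dose_schedule(c(0, 1, 1), c(1, 1, 1)), "increasing")
  expect_error(dose_schedule(c(0, 1), c(1, -1)), "nonnegative")
  expect_error(solve_tp(random_tp(1), schedule_constant(1), N_init = 0,
                        t_grid = 0:5), "N_init")
})

test_that("with no switching and f0 = 0 the model is a pure exponential", {
  p <- tp_parameters(B = 0.4, D0 = 0.1, k0 = 1, a = 0.5, t0 = 0, S0 = 0,
                     lambda_variant = "zero", Dp = 0.05, f0 = 0)
  tr <- solve_tp(p, schedule_constant(4), N_init = 100, t_grid = 0:20)
  g <- p$B - death_rate(p, 4)
  expect_equal(tr$Z, rep(0, 21))
  expect_equal(tr$X, 100 * exp(g * (0:20)), tolerance = 1e-12)
  expect_equal(tr$N, tr$X + tr$Z)
})

test_that("closed form agrees with adaptive ODE integration", {
  ## random parameter draws, 30-day grid, relative tolerance 1e-6
  for (s in 1:8) {
    p <- random_tp(s)
    sch <- schedule_constant(5)
    tt <- seq(0, 30, by = 0.5)
    a <- solve_tp(p, sch, N_init = 1, t_grid = tt)
    b <- solve_tp(p, sch, N_init = 1, t_grid = tt, method = "ode")
    expect_lt(max(abs(a$N - b$N) / pmax(b$N, 1e-300)), 1e-6)
    expect_lt(max(abs(a$Z - b$Z) / pmax(b$N, 1e-300)), 1e-6)
  }
  ## and under a time-varying (ramp) schedule
  p <- random_tp(99)
  sch <- schedule_ramp(0, 8, 20, step = 1)
  tt <- seq(0, 20, by = 0.25)
  a <- solve_tp(p, sch, N_init = 1, t_grid = tt)
  b <- solve_tp(p, sch, N_init = 1, t_grid = tt, method = "ode")
  expect_lt(max(abs(a$N - b$N) / pmax(b$N, 1e-300)), 1e-6)
})

test_that("solutions compose over time (semigroup property)", {
  for (s in 1:5) {
    p <- random_tp(10 + s)
    sch <- schedule_constant(6)
    full <- solve_tp(p, sch, N_init = 1, t_grid = c(0, 12, 25))
    part <- solve_tp(p, sch, N_init = 1, t_grid = 12)
    ## restart at t = 12: shift the schedule origin and undo the delay
    p2 <- p
    p2$t0 <- 0
    p2$S0 <- 0
    p2$f0 <- part$Z / part$N
    stopifnot(12 > p$t0)
    part2 <- solve_tp(p2, sch, N_init = part$N, t_grid = 13)
    expect_equal(part2$N, full$N[3], tolerance = 1e-8)
    expect_equal(part2$Z, full$Z[3], tolerance = 1e-8)
  }
})

test_that("final persisters increase with lambda0 and X decreases with dose", {
  lam0 <- seq(0, 0.2, by = 0.05)
  zf <- vapply(lam0, function(l) {
    p <- tp_parameters(B = 0.4, D0 = 0.1, k0 = 1, a = 0.5, t0 = 0,
                       lambda_variant = "constant", lambda0 = l,
                       Dp = 0.05, f0 = 0)
    solve_tp(p, schedule_constant(5), 1, 20)$Z
  }, numeric(1))
  expect_true(all(diff(zf) > 0))
  doses <- c(0, 1, 5, 20)
  xf <- vapply(doses, function(M) {
    p <- tp_parameters(B = 0.4, D0 = 0.1, k0 = 1, a = 0.5, t0 = 0,
                       lambda_variant = "constant", lambda0 = 0.02,
                       Dp = 0.05, f0 = 0)
    solve_tp(p, schedule_constant(M), 1, 20)$X
  }, numeric(1))
  expect_true(all(diff(xf) < 0))
})

test_that("log N shows two slopes when persisters outlive sensitive cells", {
  ## switching small relative to the kill rate, so the early log-N slope
  ## is -(D + lambda - B) to within the 5% check tolerance
  p <- tp_parameters(B = 0.4, D0 = 0.1, k0 = 1.5, a = 1, t0 = 0, S0 = 0,
                     lambda_variant = "constant", lambda0 = 0.005,
                     Dp = 0.02, f0 = 0)
  tr <- solve_tp(p, schedule_constant(20), 1, seq(0, 40, by = 0.1))
  slope <- function(sel) {
    unname(coef(lm(log(tr$N[sel]) ~ tr$time_d[sel]))[2])
  }
  early <- slope(tr$time_d <= 2)
  late <- slope(tr$time_d >= 30)
  expect_equal(early, -(death_rate(p, 20) + 0.005 - p$B), tolerance = 0.05)
  expect_equal(late, -p$Dp, tolerance = 0.05)
})

test_that("piecewise schedules match sequential single-dose solves", {
  p <- tp_parameters(B = 0.4, D0 = 0.1, k0 = 1, a = 0.5, t0 = 0, S0 = 0,
                     lambda_variant = "linear", k = 0.01, Dp = 0.04,
                     f0 = 0.05)
  two <- dose_schedule(c(0, 8), c(2, 9))
  full <- solve_tp(p, two, N_init = 1, t_grid = c(8, 15))
  ## second leg by hand from the state at the switch
  st <- solve_tp(p, schedule_constant(2), N_init = 1, t_grid = 8)
  p2 <- p
  p2$f0 <- st$Z / st$N
  leg2 <- solve_tp(p2, schedule_constant(9), N_init = st$N, t_grid = 7)
  expect_equal(leg2$N, full$N[2], tolerance = 1e-8)
  expect_equal(leg2$Z, full$Z[2], tolerance = 1e-8)
})

test_that("schedule comparison returns finite persister burdens", {
  p <- preset_parameters("widr")$fit
  out <- predict_persisters_under_schedule(
    p, list(constant = schedule_constant(5),
            ramp = schedule_ramp(0, 5, 30)), horizon = 30)
  expect_equal(out$schedule, c("constant", "ramp"))
  expect_true(all(is.finite(out$Z_final)) && all(out$Z_final > 0))
  ## zero dose with f0 = 0 gives no persisters at all
  none <- predict_persisters_under_schedule(
    p, list(off = schedule_constant(0)), horizon = 30)
  expect_equal(none$Z_final, 0)
  expect_error(predict_persisters_under_schedule(p, list(), 30), "empty")
})
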