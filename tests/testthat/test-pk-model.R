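test_that("derivative matches the compartment balance equations", {
  p <- ref_params

  # zero state with no infusion is an equilibrium
  expect_equal(pk_derivative(c(0, 0, 0), p, 0), c(0, 0, 0))

  # reference constants, unit blood concentration, no infusion
  d <- pk_derivative(c(1, 0, 0), p, 0)
  expect_equal(d, c(-(1.55 + 0.22 + 0.07), 1.55, 0.22))

  # the algebraic steady state zeroes the derivative at any constant rate
  rate <- 2
  x_ss <- steady_state(p, rate)
  expect_equal(pk_derivative(unname(x_ss), p, rate), c(0, 0, 0),
               tolerance = 1e-12)

  # linearity in state and rate
  s <- c(1.3, 0.4, 2.2)
  expect_equal(pk_derivative(2 * s, p, 6),
               2 * pk_derivative(s, p, 3), tolerance = 1e-12)

  expect_error(pk_derivative(c(1, 0, 0), p, -1), "nonnegative")
  expect_error(pk_derivative(c(NA, 0, 0), p, 0), "finite")
})

test_that("adaptive integration agrees with the exact LTI propagator", {
  p <- ref_params
  tt <- c(3, 6, 9, 30, 120, 600, 1800, 3600)
  for (sch in list(bolus_schedule(), constant_schedule(2, 3600))) {
    a <- simulate_pk(p, sch, tt)
    b <- simulate_lti(p, sch, tt)
    expect_lt(max(abs(a$x2 - b$x2) / pmax(b$x2, 1e-9)), 1e-6)
    expect_lt(max(abs(a$x1 - b$x1) / pmax(b$x1, 1e-9)), 1e-6)
  }
})

test_that("zero schedule from zero state stays identically zero", {
  sch <- infusion_schedule(rep(0, 10), 10)
  tr <- simulate_lti(ref_params, sch, seq(0, 100, 10))
  expect_true(all(tr$x1 == 0 & tr$x2 == 0 & tr$x3 == 0))
  tr2 <- simulate_pk(ref_params, sch, seq(0, 100, 10))
  expect_true(all(abs(as.matrix(tr2[, 2:4])) < 1e-12))
})

test_that("constant infusion approaches the closed-form steady state", {
  p <- ref_params
  ss <- steady_state(p, 2)
  expect_equal(unname(ss["x1"]), 2 / (0.35 * 0.07))
  expect_equal(unname(ss["x2"] / ss["x1"]), 1.55 / 2.71)
  expect_equal(unname(ss["x3"] / ss["x1"]), 0.22 / 0.04)
  # slowest eigenvalue has a ~2-h time constant; 2500 min is fully settled
  t_end <- 2500 * 60
  x <- unlist(simulate_lti(p, constant_schedule(2, duration = t_end),
                           t_end)[1, 2:4])
  expect_equal(unname(x), unname(ss), tolerance = 1e-6)
})

test_that("superposition and time-invariance hold for the LTI core", {
  set.seed(11)
  for (i in 1:5) {
    p <- random_params()
    a <- random_schedule()
    b <- random_schedule()
    tt <- seq(10, 300, 10)
    sum_tr <- simulate_lti(p, infusion_schedule(a$rates + b$rates, 10), tt)
    sep <- simulate_lti(p, a, tt)$x2 + simulate_lti(p, b, tt)$x2
    expect_equal(sum_tr$x2, sep, tolerance = 1e-9)

    # shifting the input shifts the response
    shift <- infusion_schedule(c(0, 0, 0, a$rates), 10)
    base <- simulate_lti(p, a, tt)$x2
    shifted <- simulate_lti(p, shift, tt + 30)$x2
    expect_equal(shifted, base, tolerance = 1e-9)
  }
})

test_that("concentrations stay nonnegative for nonnegative inputs", {
  set.seed(21)
  for (i in 1:10) {
    p <- random_params()
    sch <- random_schedule(n = 50)
    tr <- simulate_lti(p, sch, seq(5, 500, 5), x0 = runif(3, 0, 5))
    expect_true(all(as.matrix(tr[, 2:4]) >= -1e-12))
  }
})

test_that("washout decays to zero with elimination, stays bounded without", {
  p <- ref_params
  sch <- bolus_schedule(horizon = 6)
  far <- simulate_lti(p, sch, c(600, 6e4, 6e5))
  expect_true(all(diff(far$x2) < 0))
  expect_lt(far$x2[3], 1e-6)

  p0 <- pk_params(k10 = 0, k12 = 1.55, k13 = 0.22, k21 = 2.71, k31 = 0.04,
                  s_inf = 0.35)
  tr <- simulate_lti(p0, sch, c(1e4, 1e5, 1e6))
  expect_true(all(is.finite(as.matrix(tr[, 2:4]))))
  # converges to the no-elimination equilibrium: compartments stop changing
  expect_equal(unlist(tr[2, 2:4]), unlist(tr[3, 2:4]), tolerance = 1e-6)
})

test_that("degenerate rate constants integrate but have no steady state", {
  p <- pk_params(k10 = 0.07, k12 = 1.55, k13 = 0.22, k21 = 0, k31 = 0,
                 s_inf = 0.35)
  tr <- simulate_lti(p, constant_schedule(2, 600), c(60, 600))
  expect_true(all(is.finite(as.matrix(tr[, 2:4]))))
  expect_error(steady_state(p, 2), "no finite steady state")
})

test_that("impulse response is linear and convolution-consistent", {
  p <- ref_params
  imp <- impulse_response(p, step = 10, horizon = 600)
  expect_true(all(imp$brain >= 0) && all(imp$blood >= 0))

  # scaling: response to rate c equals c * h
  tr <- simulate_lti(p, infusion_schedule(c(3, rep(0, 59)), 10), imp$times)
  expect_equal(tr$x2, 3 * imp$brain, tolerance = 1e-12)

  # convolving h with a constant-rate sequence reproduces the exact solution
  sch <- constant_schedule(2, 600)
  conv <- predict_brain(sch, imp)
  lti <- simulate_lti(p, sch, imp$times)$x2
  expect_equal(conv, lti, tolerance = 1e-9)

  # blood response peaks at the first grid point, then decreases
  expect_equal(which.max(imp$blood), 1L)
  expect_true(all(diff(imp$blood) < 0))
})

test_that("parameter validation rejects invalid constant sets", {
  expect_error(pk_params(0.07, 1.55, 0.22, 2.71, 0.04, s_inf = 0),
               "positive")
  expect_error(pk_params(-0.1, 1.55, 0.22, 2.71, 0.04, 0.35), "nonnegative")
  expect_error(pk_params(NA, 1.55, 0.22, 2.71, 0.04, 0.35), "finite")
  expect_error(infusion_schedule(c(1, -1), 10), "nonnegative")
  expect_error(infusion_schedule(numeric(0), 10), "nonempty")
  expect_error(infusion_schedule(1, step = 0), "positive")
})

test_that("file formats round-trip: params JSON, schedule and trajectory CSV", {
  tmp <- withr::local_tempdir()

  pj <- file.path(tmp, "params.json")
  write_pk_params(ref_params, pj)
  expect_equal(read_pk_params(pj), ref_params)

  sc <- file.path(tmp, "schedule.csv")
  sch <- infusion_schedule(c(1.25, 0, 3.5, 0.0625), 10)
  write_schedule(sch, sc)
  expect_equal(read_schedule(sc), sch)

  tc <- file.path(tmp, "traj.csv")
  tr <- simulate_lti(ref_params, sch, c(10, 20, 30, 40))
  write_trajectory(tr, tc)
  back <- read_trajectory(tc)
  expect_equal(back$x2, tr$x2)
  expect_equal(back$time_s, tr$time_s)
})
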