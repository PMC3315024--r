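# Period extraction and limit-cycle observables.

test_that("zero horizon returns the initial state only", {
  sys <- make_hopf_normal_form(omega = 1)
  sim <- simulate(sys, init = c(0.3, -0.2), t_end = 0)
  expect_equal(nrow(sim), 1)
  expect_equal(unlist(sim[1, c("x", "y")]), c(x = 0.3, y = -0.2))
})

test_that("normal-form period equals 2*pi/omega", {
  omega <- 2 * pi / 100
  sys <- make_hopf_normal_form(omega = omega)
  sys <- set_par(sys, "alpha", 0.25)
  res <- oscillation_period(sys, init = c(0.1, 0), species = "x",
                            transient = 300, window = 800, t_max = 2000,
                            dt = 0.25)
  expect_true(res$converged)
  expect_true(res$sustained)
  expect_equal(res$period, 100, tolerance = 1e-5)
  # envelope: cycle radius sqrt(alpha)
  expect_equal(res$x_max, sqrt(0.25), tolerance = 1e-3)
  expect_equal(res$x_min, -sqrt(0.25), tolerance = 1e-3)
})

test_that("unstimulated model damps to steady state", {
  p <- nfkb_params(TR = 0)
  sim <- simulate(nfkb_system(p), init = nfkb_initial_state(p),
                  t_end = 30000, n_out = 3000)
  res <- extract_period(sim, transient = 10000)
  expect_false(isTRUE(res$sustained))
  endpoint <- as.numeric(sim[nrow(sim), nfkb_species()])
  drift <- max(abs(nfkb_rhs(endpoint, p)))
  expect_lt(drift, 1e-8)
})

test_that("below the bifurcation the period curve flags non-oscillation", {
  p <- nfkb_params()
  pc <- period_curve(nfkb_system(p), "TR", c(0.2, 0.8),
                     init = nfkb_initial_state(p), t_max = 20000)
  expect_false(pc$sustained[1])   # damped focus side
  expect_true(pc$sustained[2])    # limit-cycle side
  expect_true(pc$oscillatory[2])
  expect_gt(pc$period[2], 80)
})

test_that("period approaches 2*pi/omega at a supercritical Hopf point", {
  # normal form: exact statement, tight tolerance
  omega <- 0.9
  sys <- make_hopf_normal_form(omega = omega)
  sys <- set_par(sys, "alpha", 1e-3)
  res <- oscillation_period(sys, init = c(1e-3, 0), species = "x",
                            transient = 2000, window = 6000, t_max = 30000,
                            dt = 0.5)
  expect_equal(res$period, 2 * pi / omega, tolerance = 2e-2)

  # NF-kB model just past the detected bifurcation
  hp <- nfkb_hopf_slice(nfkb_params())
  tr_star <- max(hp$param_value)
  omega_hb <- hp$omega[which.max(hp$param_value)]
  p <- nfkb_params(TR = tr_star + 1e-3)
  res2 <- oscillation_period(nfkb_system(p), init = nfkb_initial_state(p),
                             transient = 3000, window = 3000,
                             t_max = 12000)
  expect_lt(abs(res2$period - 2 * pi / omega_hb) / (2 * pi / omega_hb),
            0.02)
})

test_that("period is independent of the initial condition", {
  p <- nfkb_params(TR = 0.6)
  sys <- nfkb_system(p)
  r1 <- oscillation_period(sys, init = nfkb_initial_state(p),
                           t_max = 20000)
  eq <- settle_equilibrium(0.6)
  init2 <- as.numeric(eq$state) * 1.25
  r2 <- oscillation_period(sys, init = init2, t_max = 20000)
  expect_true(r1$converged && r2$converged)
  expect_lt(abs(r1$period - r2$period) / r1$period, 1e-3)
})
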