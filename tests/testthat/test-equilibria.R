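# Newton equilibria, stability classes, continuation, Hopf refinement and
# the criticality probe, validated on the analytic fixtures.

test_that("unstimulated system settles to a stable equilibrium", {
  eq <- settle_equilibrium(0)
  expect_true(eq$converged)
  expect_lt(eq$residual, 1e-10)
  expect_true(eq$stability %in% c("stable-focus", "stable-node"))
})

test_that("Newton equilibrium agrees with long-time integration", {
  p <- nfkb_params(TR = 0.2)
  sys <- set_par(nfkb_system(p), "TR", 0.2)
  sim <- simulate(sys, init = nfkb_initial_state(p), t_end = 5e4,
                  n_out = 100)
  endpoint <- as.numeric(sim[nrow(sim), nfkb_species()])
  eq <- find_equilibrium(sys, endpoint)
  expect_true(eq$converged)
  expect_lt(eq$residual, 1e-10)
  expect_equal(as.numeric(eq$state), endpoint, tolerance = 1e-6)
  # below the bifurcation the equilibrium is a focus (damped oscillations)
  expect_identical(eq$stability, "stable-focus")
})

test_that("non-convergence is reported, not raised", {
  # a hopeless guess far outside the physical domain, no fallback
  sys <- nfkb_system(nfkb_params())
  bad <- rep(1e6, 11)
  eq <- find_equilibrium(sys, bad)
  expect_false(eq$converged)
})

test_that("stability classification follows the eigenvalue sign pattern", {
  expect_identical(classify_stability(c(-1, -2 + 3i, -2 - 3i)),
                   "stable-focus")
  expect_identical(classify_stability(c(-1, -2, -0.5)), "stable-node")
  expect_identical(classify_stability(c(0.1, -2 + 1i, -2 - 1i)),
                   "unstable")
  expect_identical(classify_stability(c(1i, -1i)), "non-hyperbolic")
})

test_that("continuation keeps the normal-form equilibrium at the origin", {
  sys <- make_hopf_normal_form(omega = 1)
  br <- continue_branch(sys, "alpha", c(-1, 1), guess = c(0, 0))
  expect_false(attr(br, "truncated"))
  expect_lt(max(abs(br$x)), 1e-9)
  expect_lt(max(abs(br$y)), 1e-9)
  expect_true(all(range(br$param_value) == c(-1, 1)))
})

test_that("NF-kB branch over the unit interval has one stability change", {
  br <- nfkb_branch(tr_range = c(1e-3, 1))
  expect_true(all(diff(br$param_value) > 0))        # no folds
  stable <- grepl("stable-", br$stability, fixed = TRUE)
  expect_equal(sum(diff(stable) != 0), 1)
  # all stable equilibria along the branch are foci
  expect_true(all(br$stability[stable] == "stable-focus"))
})

test_that("Hopf detection recovers analytic locations and frequencies", {
  omega <- 2 * pi / 100
  sys <- make_hopf_normal_form(omega = omega)
  br <- continue_branch(sys, "alpha", c(-1, 1), guess = c(0, 0))
  hp <- detect_hopf(br)
  expect_equal(nrow(hp), 1)
  expect_lt(abs(hp$param_value), 1e-6)
  expect_lt(abs(hp$omega - omega), 1e-6)
  expect_equal(hp$n_critical, 2L)

  for (a in c(1, 2)) {
    bru <- make_brusselator(a = a)
    br2 <- continue_branch(bru, "b", c(0.5, a^2 + 2),
                           guess = c(a, 0.5 / a))
    hp2 <- detect_hopf(br2)
    expect_equal(nrow(hp2), 1)
    expect_lt(abs(hp2$param_value - (1 + a^2)), 1e-6)
    expect_lt(abs(hp2$omega - a), 1e-6)
  }
})

test_that("refinement is independent of the continuation step size", {
  sys <- make_hopf_normal_form(omega = 0.7)
  b1 <- continue_branch(sys, "alpha", c(-0.8, 0.8), guess = c(0, 0),
                        step0 = 0.08)
  b2 <- continue_branch(sys, "alpha", c(-0.8, 0.8), guess = c(0, 0),
                        step0 = 0.04)
  h1 <- detect_hopf(b1, sys, "alpha")
  h2 <- detect_hopf(b2, sys, "alpha")
  expect_lt(abs(h1$param_value - h2$param_value), 1e-6)

  hb1 <- detect_hopf(nfkb_branch(tr_range = c(0.2, 0.6), step0 = 0.02))
  hb2 <- detect_hopf(nfkb_branch(tr_range = c(0.2, 0.6), step0 = 0.01))
  expect_lt(abs(hb1$param_value - hb2$param_value), 1e-6)
})

test_that("real-eigenvalue crossings are excluded from Hopf detection", {
  # x' = mu*x - x^3, y' = -y: eigenvalues (mu, -1), all real; the zero
  # crossing at mu = 0 is not a Hopf point
  sys <- ode_system(
    rhs = function(y, p) c(p$mu * y[1] - y[1]^3, -y[2]),
    jac = function(y, p) matrix(c(p$mu - 3 * y[1]^2, 0, 0, -1), 2, 2),
    pars = list(mu = -1), state_names = c("x", "y"))
  br <- continue_branch(sys, "mu", c(-1, 1), guess = c(0, 0))
  hp <- detect_hopf(br, sys, "mu")
  expect_equal(nrow(hp), 0)
})

test_that("pseudo-arclength fallback traverses a fold", {
  # x' = mu - x^2: equilibria x = +-sqrt(mu), fold at mu = 0. Natural
  # stepping from the upper branch toward negative mu must fail at the
  # fold; the arclength corrector carries the branch around onto x < 0.
  sys <- ode_system(
    rhs = function(y, p) p$mu - y[1]^2,
    jac = function(y, p) matrix(-2 * y[1], 1, 1),
    pars = list(mu = 1), state_names = "x")
  br <- suppressMessages(
    continue_branch(sys, "mu", c(1, -0.5), guess = 1, step0 = 0.05,
                    max_points = 200))
  expect_true(any(br$x > 0.5) && any(br$x < -0.05))
  expect_gt(min(br$param_value), -1e-6)   # never leaves mu >= 0
})

test_that("criticality probe matches the normal forms", {
  sup <- make_hopf_normal_form(omega = 1, s = -1)
  br <- continue_branch(sup, "alpha", c(-0.5, 0.5), guess = c(0, 0))
  hp <- detect_hopf(br)
  hp <- classify_criticality(sup, hp, delta = 0.01)
  expect_identical(hp$criticality, "supercritical")

  sub <- make_hopf_normal_form(omega = 1, s = +1)
  br2 <- continue_branch(sub, "alpha", c(-0.5, 0.5), guess = c(0, 0))
  hp2 <- detect_hopf(br2)
  hp2 <- classify_criticality(sub, hp2, delta = 0.01)
  expect_identical(hp2$criticality, "subcritical")
})

test_that("supercritical cycle amplitude scales as sqrt(alpha)", {
  sys <- make_hopf_normal_form(omega = 1, s = -1)
  sys <- set_par(sys, "alpha", 0.04)
  sim <- simulate(sys, init = c(0.01, 0), t_end = 600, n_out = 3000)
  r <- sqrt(sim$x^2 + sim$y^2)
  expect_equal(mean(tail(r, 300)), sqrt(0.04), tolerance = 1e-4)
})
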