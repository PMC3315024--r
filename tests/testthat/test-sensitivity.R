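# The interpolation step and the slope-score quadrature.

test_that("pchip interpolation passes through knots without overshoot", {
  pts <- data.frame(mu = c(1, 2, 3, 4), val = c(0, 0.5, 0.9, 1))
  f <- interpolate_curve(pts)
  expect_equal(f(pts$mu), pts$val)
  xx <- seq(1, 4, length.out = 400)
  yy <- f(xx)
  expect_true(all(diff(yy) >= -1e-12))          # monotone preserved
  expect_true(all(yy >= 0 - 1e-12 & yy <= 1 + 1e-12))
  # two points degenerate to the straight line
  g <- interpolate_curve(data.frame(mu = c(0, 2), val = c(1, 5)))
  expect_equal(g(1), 3)
  expect_error(interpolate_curve(data.frame(mu = c(1, 1), val = c(0, 1))),
               "duplicate")
  expect_error(interpolate_curve(data.frame(mu = 1, val = 0)),
               "at least 2")
})

test_that("score is zero for constant and exact for linear curves", {
  const <- function(x) rep(0.37, length(x))
  expect_equal(sensitivity_score(const, mu0 = 2, reference = 0.37)$score, 0)
  a <- 0.1; b <- -0.8; mu0 <- 1.7; ref <- 0.42
  lin <- function(x) a + b * x
  sc <- sensitivity_score(lin, mu0 = mu0, theta = 0.1, m = 21,
                          reference = ref)
  expect_equal(sc$score, b * mu0 / ref, tolerance = 1e-12)
  expect_equal(sc$l, 10)
})

test_that("quadrature telescopes to the chord slope on uniform samples", {
  set.seed(7)
  mu <- seq(0.9, 1.1, length.out = 9)
  val <- cumsum(runif(9, -1, 1))
  f <- interpolate_curve(data.frame(mu, val))
  sc <- sensitivity_score(f, mu0 = 1, theta = 0.1, m = 21, reference = 2)
  lo <- 0.9; hi <- 1.1
  chord <- (f(hi) - f(lo)) / (hi - lo)
  expect_equal(sc$score, chord * 1 / 2, tolerance = 1e-12)
})

test_that("score sign equals the sign of the mean slope", {
  set.seed(11)
  for (rep in 1:5) {
    mu <- seq(0.5, 1.5, length.out = 11)
    val <- cumsum(rnorm(11))
    f <- interpolate_curve(data.frame(mu, val))
    sc <- sensitivity_score(f, mu0 = 1, theta = 0.3, m = 21, reference = 1)
    mean_slope <- (f(1.3) - f(0.7)) / 0.6
    expect_equal(sign(sc$score), sign(mean_slope))
  }
})

test_that("scores converge in the number of samples", {
  f <- interpolate_curve(data.frame(mu = seq(0.8, 1.2, length.out = 9),
                                    val = log(seq(0.8, 1.2,
                                                  length.out = 9))))
  s21 <- sensitivity_score(f, 1, theta = 0.1, m = 21, reference = 1)$score
  s41 <- sensitivity_score(f, 1, theta = 0.1, m = 41, reference = 1)$score
  expect_lt(abs(s21 - s41) / abs(s41), 0.01)
})

test_that("invalid sampling and out-of-window requests are rejected", {
  f <- interpolate_curve(data.frame(mu = c(0.9, 1, 1.1), val = c(1, 2, 3)))
  expect_error(sensitivity_score(f, 1, m = 4, reference = 1), "odd")
  expect_error(sensitivity_score(f, 1, m = 1, reference = 1), "odd")
  expect_error(sensitivity_score(f, 1, theta = 0.5, reference = 1),
               "lower edge")
  expect_error(sensitivity_score(f, 1.05, theta = 0.1, reference = 1),
               "upper edge")
})

test_that("Hopf-location curve tracks the default branch smoothly", {
  crv <- hopf_location_curve(nfkb_params(), "kc2", n_points = 5)
  expect_equal(nrow(crv), 5)
  expect_true(all(is.finite(crv$TR_star)))
  # the default value is a knot and carries the default Hopf location
  i0 <- which.min(abs(crv$mu - 0.074))
  expect_equal(crv$TR_star[i0], 0.3664, tolerance = 1e-3)
  # near-linear over +-10%: quadratic residual of the three inner points
  expect_lt(max(abs(diff(diff(crv$TR_star)))), 0.05 * diff(range(crv$TR_star)) + 1e-6)
})

test_that("a period-sensitivity row computes and stays finite", {
  ps <- period_sensitivity_all(names = "kc2", m = 3, t_max = 6000)
  expect_true(ps$ok)
  expect_true(is.finite(ps$score))
  expect_lt(abs(ps$score), 0.5)
})
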