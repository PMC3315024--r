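# The analytic fixtures are the correctness gate for the continuation
# machinery, plus the deterministic parameter-perturbation generator.

test_that("every fixture's Hopf facts are recovered to 1e-6", {
  cases <- list(
    list(sys = make_hopf_normal_form(omega = 0.31), range = c(-0.6, 0.6),
         guess = c(0, 0)),
    list(sys = make_hopf_normal_form(omega = 3), range = c(-0.6, 0.6),
         guess = c(0, 0)),
    list(sys = make_brusselator(a = 1), range = c(1, 3.5),
         guess = c(1, 1)),
    list(sys = make_brusselator(a = 2), range = c(3, 6.5),
         guess = c(2, 1.5))
  )
  for (cs in cases) {
    known <- attr(cs$sys, "known")
    br <- continue_branch(cs$sys, known$hopf_par, cs$range,
                          guess = cs$guess)
    hp <- detect_hopf(br)
    expect_equal(nrow(hp), 1)
    expect_lt(abs(hp$param_value - known$hopf_at), 1e-6)
    expect_lt(abs(hp$omega - known$omega), 1e-6)
  }
})

test_that("Brusselator equilibrium is (a, b/a) for any parameters", {
  for (a in c(0.5, 1, 2)) for (b in c(0.8, 2.5)) {
    sys <- make_brusselator(a = a, b = b)
    eq <- find_equilibrium(sys, guess = c(a + 0.1, b / a - 0.1))
    expect_true(eq$converged)
    expect_equal(as.numeric(eq$state), c(a, b / a), tolerance = 1e-9)
  }
})

test_that("parameter perturbations are deterministic and bounded", {
  p <- nfkb_params()
  expect_identical(perturb_parameters(p, 0, 1), p)
  a <- perturb_parameters(p, 0.1, 123)
  b <- perturb_parameters(p, 0.1, 123)
  expect_identical(unlist(a), unlist(b))
  c2 <- perturb_parameters(p, 0.1, 124)
  expect_false(identical(unlist(a), unlist(c2)))
  expect_identical(a$TR, p$TR)   # stimulation intensity untouched

  # factors live in [0.9, 1.1]
  ratio <- unlist(a)[setdiff(names(unlist(p)), "TR")] /
    unlist(p)[setdiff(names(unlist(p)), "TR")]
  expect_true(all(ratio >= 0.9 & ratio <= 1.1))

  # perturbed values stay inside the published ranges for parameters whose
  # range is wider than +-10% around the default
  tab <- param_table()
  wide <- tab[tab$lo <= 0.9 * tab$default & tab$hi >= 1.1 * tab$default &
                tab$name != "TR", ]
  for (seed in 1:20) {
    q <- unlist(perturb_parameters(p, 0.1, seed))
    expect_true(all(q[wide$name] >= wide$lo & q[wide$name] <= wide$hi))
  }

  # the global RNG stream is not consumed
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(perturb_parameters(p, 0.1, 5)); after <- runif(1)
  expect_identical(before, after)
})
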