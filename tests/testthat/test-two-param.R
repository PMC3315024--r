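# Slicing, curve tracing and the range survey on systems with known answers.

test_that("slice recovers a constructed Hopf locus exactly", {
  fam <- make_hopf_locus_family(omega = 1)
  for (mu in c(0.3, 0.5, 0.8)) {
    sys <- set_par(fam, "mu", mu)
    sl <- hopf_slice(sys, "TR", range = c(0.01, 1), guess = c(0, 0))
    expect_equal(nrow(sl), 1)
    expect_lt(abs(sl$param_value - mu), 1e-6)
  }
})

test_that("degenerate survey range scores a single slice", {
  sv <- survey_range(nfkb_params(), "kc2",
                     range = c(0.074, 0.074), n_grid = 51)
  expect_equal(sv$n_grid, 1)
  expect_equal(sv$pct_one_hb, 100)
})

test_that("curve points reproduce themselves under re-detection", {
  curve <- trace_hopf_curve(nfkb_params(), "totalIKK", c(0.05, 0.12),
                            n_slices = 5)
  expect_true(all(curve$branch == "main"))
  for (i in c(1, nrow(curve))) {
    sl <- nfkb_hopf_slice(nfkb_params(), "totalIKK", curve$mu[i])
    expect_lt(min(abs(sl$param_value - curve$TR[i])), 1e-6)
  }
})

test_that("totalIKK Hopf curve is monotone above the fold", {
  curve <- trace_hopf_curve(nfkb_params(), "totalIKK", c(0.03, 0.2),
                            n_slices = 7)
  main <- curve[curve$branch == "main", ]
  main <- main[order(main$mu), ]
  expect_true(all(diff(main$TR) > 0))   # higher totalIKK needs stronger TR
})

test_that("oscillatory and non-oscillatory regions match the Hopf curve", {
  # region 1 (above the curve in TR): sustained oscillations
  osc <- list(c(0.6, 0.08), c(0.9, 0.12), c(0.5, 0.05))
  # region 2 (below the curve): damped, no sustained oscillation
  damp <- list(c(0.2, 0.08), c(0.05, 0.02), c(0.3, 0.15))
  for (pt in osc) {
    p <- nfkb_params(TR = pt[1], totalIKK = pt[2])
    r <- oscillation_period(nfkb_system(p), init = nfkb_initial_state(p),
                            t_max = 20000)
    expect_true(r$sustained,
                label = sprintf("sustained at TR=%g totalIKK=%g",
                                pt[1], pt[2]))
  }
  for (pt in damp) {
    p <- nfkb_params(TR = pt[1], totalIKK = pt[2])
    r <- oscillation_period(nfkb_system(p), init = nfkb_initial_state(p),
                            t_max = 12000)
    expect_false(isTRUE(r$sustained),
                 label = sprintf("damped at TR=%g totalIKK=%g",
                                 pt[1], pt[2]))
  }
})

test_that("island and main branches are labelled by connectivity", {
  curve <- trace_hopf_curve(nfkb_params(), "totalNFkB", c(0.1, 0.16),
                            n_slices = 7, min_rel_spacing = 0.02)
  expect_true(all(c("main", "island") %in% curve$branch))
  isl <- curve[curve$branch == "island", ]
  expect_true(all(isl$TR < 0.05))          # low-dose oscillations
  expect_gt(min(isl$mu), 0.10)   # island onset just above 0.1
})
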