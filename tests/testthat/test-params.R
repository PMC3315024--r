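test_that("defaults match the published parameter table exactly", {
  p <- nfkb_params()
  tab <- param_table()
  expect_equal(nrow(tab), 29)
  for (i in seq_len(nrow(tab))) {
    expect_identical(p[[tab$name[i]]], tab$default[i])
  }
  # a few spot values as printed
  expect_identical(p$kbA20, 0.0018)
  expect_identical(p$ke1f, 52e-6)
  expect_identical(p$kitria, 1.4e-7)
  expect_identical(p$k, 0.065)
  expect_identical(p$h, 2)
  # every default lies inside its published survey range
  expect_true(all(tab$default >= tab$lo & tab$default <= tab$hi))
})

test_that("construction validates overrides", {
  expect_error(nfkb_params(nonsense = 1), "unknown parameter")
  expect_error(nfkb_params(ka = -1), "strictly positive")
  expect_error(nfkb_params(TR = -0.1), "TR")
  p <- nfkb_params(totalNFkB = 0.15, TR = 0)
  expect_equal(p$totalNFkB, 0.15)
  expect_equal(p$TR, 0)
})

test_that("parameter configs round-trip through JSON and YAML", {
  p <- nfkb_params(totalNFkB = 0.123456789, kitria = 1.23456789e-7)
  fj <- tempfile(fileext = ".json")
  fy <- tempfile(fileext = ".yaml")
  write_params(p, fj)
  write_params(p, fy)
  expect_identical(unlist(read_params(fj)), unlist(p))
  expect_equal(unlist(read_params(fy)), unlist(p), tolerance = 1e-12)
  # aliases accepted on read
  cfg <- jsonlite::read_json(fj)
  names(cfg)[names(cfg) == "totalIKK"] <- "totIKK"
  names(cfg)[names(cfg) == "totalNFkB"] <- "totNFkB"
  jsonlite::write_json(cfg, fj, auto_unbox = TRUE, digits = NA)
  expect_equal(unlist(read_params(fj)), unlist(p), tolerance = 1e-12)
  unlink(c(fj, fy))
})
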