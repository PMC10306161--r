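test_that("defaults reproduce the published base case", {
  p <- default_parameters()
  expect_equal(p$testing$frac_tissue, 0.60)
  expect_equal(p$testing$p_insufficient_blood, 0.003)
  expect_equal(p$scenario_proposed$frac_inhouse, 0.75)
  expect_equal(p$scenario_current$frac_inhouse, 0)
  expect_equal(p$money$cost_inhouse_test, 600)
  expect_equal(p$tat$tat_inhouse, 3)
  # residual mass at the nontargeted node is the second-opinion default
  residual <- 1 - with(p$splits, p_immuno_nontargeted + p_chemo_nontargeted +
                         p_chemoimmuno_nontargeted)
  expect_equal(residual, 0.10, tolerance = 1e-12)
  expect_equal(p$gaps$p_second_opinion_sendout, residual)
})

test_that("default parameters validate cleanly and ranges bracket points", {
  p <- default_parameters()
  expect_identical(nrow(validate_parameters(p)), 0L)
  for (i in seq_len(nrow(p$uncertainty))) {
    r <- p$uncertainty[i, ]
    pt <- if (r$parameter == "tat.sendout_midpoint") {
      (p$tat$tat_sendout_low + p$tat$tat_sendout_high) / 2
    } else param_get(p, r$parameter)
    expect_gte(pt, r$low)
    expect_lte(pt, r$high)
  }
})

test_that("validation reports violations as data, naming the field", {
  p <- default_parameters()
  p$splits$p_immuno_nontargeted <- 0.40 # 0.40 + 0.29 + 0.36 = 1.05
  rep <- validate_parameters(p)
  expect_true(any(grepl("splits", rep$field)))

  p <- default_parameters()
  p$clinical$os_1yr$chemo <- 0.10 # below PFS 0.173
  rep <- validate_parameters(p)
  expect_true(any(rep$field == "clinical.os_1yr.chemo"))

  p <- default_parameters()
  p$money$retest_multiplier <- 1.5
  expect_true(any(validate_parameters(p)$field == "money.retest_multiplier"))
})

test_that("config file round-trips losslessly", {
  f <- withr::local_tempfile(fileext = ".yaml")
  g <- withr::local_tempfile(fileext = ".yaml")
  p <- default_parameters()
  write_parameters(p, f)
  p2 <- load_parameters(f)
  expect_equal(unclass(p2), unclass(p))
  # canonical serialization: write(load(x)) is bit-for-bit identical
  write_parameters(p2, g)
  expect_identical(readLines(g), readLines(f))
})

test_that("packaged base-case config equals default_parameters()", {
  f <- system.file("extdata", "basecase.yaml", package = "ngsbia")
  expect_true(nzchar(f))
  expect_equal(unclass(load_parameters(f)), unclass(default_parameters()))
})

test_that("partial configs fall back to defaults with auto-complement", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("testing:\n  frac_tissue: 0.7", f)
  p <- load_parameters(f)
  expect_equal(p$testing$frac_tissue, 0.7)
  expect_equal(p$testing$frac_blood, 0.3)
  expect_equal(p$money$cost_inhouse_test, 600) # untouched default
})

test_that("out-of-range config values raise an error citing the field", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("testing:\n  frac_tissue: 1.2", f)
  expect_error(load_parameters(f), "frac_tissue")
  expect_error(load_parameters("no/such/file.yaml"), "not found")
})

test_that("tidy() flattens a parameter set to a long tibble", {
  td <- tidy(default_parameters())
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("parameter", "value"))
  expect_equal(td$value[td$parameter == "testing.frac_tissue"], 0.60)
  expect_true("clinical.pfs_1yr.targeted" %in% td$parameter)
})

test_that("param_get/param_set address nested values by dotted path", {
  p <- default_parameters()
  expect_equal(param_get(p, "clinical.os_1yr.targeted"), 0.86)
  p2 <- param_set(p, "money.cost_sendout_test", 310)
  expect_equal(p2$money$cost_sendout_test, 310)
  expect_error(param_get(p, "no.such.path"), "unknown parameter path")
})
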