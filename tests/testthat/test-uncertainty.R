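test_that("single-target calibration matches the linear-inversion closed form", {
  # lost = 2500 * nontargeted_mass * p_so  =>  p_so = 173 / (2500 * 0.77523976)
  spec <- default_calibration_spec()[2, ] # second-opinion step only
  fit <- calibrate(default_parameters(), spec)
  expect_equal(fit$report$fitted, 173 / (2500 * 0.77523976), tolerance = 1e-6)
  # forward run at the fitted value returns the target
  lost <- second_opinion_loss(fit$parameters, "current", 500) * 5
  expect_equal(lost, 173, tolerance = 1e-6)
})

test_that("an empty calibration ladder is the identity", {
  spec <- default_calibration_spec()[0, ]
  fit <- calibrate(default_parameters(), spec)
  expect_identical(nrow(fit$report), 0L)
  expect_equal(unclass(fit$parameters), unclass(default_parameters()))
})

test_that("the full ladder is forward-consistent and labels residuals per target", {
  fit <- calibrated_fixture()
  expect_named(fit$report,
               c("parameter", "fitted", "observable", "target", "achieved",
                 "residual", "rel_residual", "within_tol"))
  expect_true(all(fit$report$within_tol))
  # re-running the pipeline at fitted parameters reproduces each target
  p <- fit$parameters
  for (i in seq_len(nrow(fit$report))) {
    again <- ngsbia:::observable_value(p, fit$report$observable[i])
    expect_equal(again, fit$report$achieved[i], tolerance = 1e-9)
  }
  # fitted retest multiplier respects its published-cost bracket
  m <- fit$report$fitted[fit$report$parameter == "money.retest_multiplier"]
  expect_gte(m, 1.000)
  expect_lte(m, 1.010)
})

test_that("PSA is reproducible bit-for-bit and collapses with degenerate ranges", {
  p <- calibrated_params()
  a <- run_psa(p, n_draws = 25, seed = 99)
  b <- run_psa(p, n_draws = 25, seed = 99)
  expect_identical(a$draws, b$draws)
  expect_identical(a$param_draws, b$param_draws)
  c <- run_psa(p, n_draws = 25, seed = 100)
  expect_false(identical(a$draws, c$draws))

  # ranges collapsed to points: every draw equals the base case
  p0 <- p
  p0$uncertainty$low <- vapply(p0$uncertainty$parameter,
                               function(pa) ngsbia:::uncertainty_point(p0, pa), numeric(1))
  p0$uncertainty$high <- p0$uncertainty$low
  d <- run_psa(p0, n_draws = 5, seed = 1)
  expect_equal(d$summaries$hi95 - d$summaries$lo95, rep(0, nrow(d$summaries)),
               tolerance = 1e-9)
  expect_error(run_psa(p, n_draws = 1), "n_draws")
})

test_that("PSA summaries match an independent sort-based percentile computation", {
  p <- calibrated_params()
  psa <- run_psa(p, n_draws = 40, seed = 7)
  x <- sort(psa$draws$roi_disc)
  manual_q <- function(q) {
    h <- (length(x) - 1) * q + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  s <- psa$summaries[psa$summaries$outcome == "roi_disc", ]
  expect_equal(s$median, manual_q(0.5), tolerance = 1e-9)
  expect_equal(s$lo95, manual_q(0.025), tolerance = 1e-9)
  expect_equal(s$hi95, manual_q(0.975), tolerance = 1e-9)
})

test_that("tornado ranks by span, puts zero-width ranges last, and is order-invariant", {
  p <- calibrated_params()
  # keep a small set of rows for speed, add one degenerate row
  keep <- c("money.cost_inhouse_test", "money.reimb_inhouse_test",
            "scenario_proposed.frac_inhouse", "tat.tat_inhouse")
  p$uncertainty <- dplyr::filter(p$uncertainty, parameter %in% keep)
  p$uncertainty$low[p$uncertainty$parameter == "tat.tat_inhouse"] <- 3
  p$uncertainty$high[p$uncertainty$parameter == "tat.tat_inhouse"] <- 3
  tor <- one_way_sa(p, "roi")
  expect_equal(tor$rank, seq_len(nrow(tor)))
  expect_true(all(diff(tor$span) <= 1e-9))
  expect_equal(tor$parameter[nrow(tor)], "tat.tat_inhouse")
  expect_equal(tor$span[nrow(tor)], 0)

  p_shuf <- p
  p_shuf$uncertainty <- p_shuf$uncertainty[c(3, 1, 4, 2), ]
  tor2 <- one_way_sa(p_shuf, "roi")
  expect_equal(tibble::as_tibble(tor2), tibble::as_tibble(tor))
})

test_that("widening a cost range weakly increases its tornado span", {
  p <- calibrated_params()
  keep <- c("money.cost_inhouse_test", "money.cost_sendout_test")
  p$uncertainty <- dplyr::filter(p$uncertainty, parameter %in% keep)
  t1 <- one_way_sa(p, "roi")
  s1 <- t1$span[t1$parameter == "money.cost_inhouse_test"]
  mid <- 600
  p$uncertainty$low[1] <- mid - 2 * (mid - 578)
  p$uncertainty$high[1] <- mid + 2 * (908 - mid)
  t2 <- one_way_sa(p, "roi")
  s2 <- t2$span[t2$parameter == "money.cost_inhouse_test"]
  expect_gte(s2, s1)
})

test_that("scenario sweeps are consistent with the base case and validate inputs", {
  p <- calibrated_params()
  base_roi <- bia_compare(p)$roi$cumulative_roi_disc
  sw <- scenario_sweep(p, "inhouse_pct", grid = c(50, 75))
  expect_equal(sw$roi_disc[sw$setting == 75], base_roi, tolerance = 1e-6)
  expect_true(all(diff(sw$setting) > 0))
  expect_error(scenario_sweep(p, "inhouse_pct", grid = c(-5)), "\\[0, 100\\]")
  expect_error(scenario_sweep(p, "patient_volume", grid = c(-1)), "nonnegative")
  sg <- scenario_sweep(p, "single_gene_comparator")
  expect_identical(nrow(sg), 1L)
})
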