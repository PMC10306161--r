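# frozen conversion values: direct evaluation of 1 - s^(30/365.25), verified
# by compounding back over 365.25/30 cycles to recover 1 - s

test_that("annual-to-cycle conversion matches direct evaluation and compounds back", {
  expect_equal(annual_prob_to_cycle(1), 0)
  expect_equal(annual_prob_to_cycle(0.494), 0.0562779, tolerance = 1e-6)
  expect_equal(annual_prob_to_cycle(0.86), 0.0123115, tolerance = 1e-6)
  for (s in c(0.05, 0.2, 0.494, 0.86, 0.999)) {
    pc <- annual_prob_to_cycle(s)
    expect_equal(1 - (1 - pc)^(365.25 / 30), 1 - s, tolerance = 1e-12)
  }
  expect_error(annual_prob_to_cycle(0), "infinite hazard")
})

test_that("competing split decomposes PFS events into progression and death", {
  # pfs = os: every PFS event is a death
  cs <- competing_split(0.5, 0.5)
  expect_equal(cs[["p_progression"]], 0)
  # targeted therapy, base case
  cs <- competing_split(0.40, 0.86)
  expect_equal(cs[["p_death"]], 0.0123115, tolerance = 1e-6)
  expect_equal(cs[["p_progression"]], 0.0601862, tolerance = 1e-6)
  # chemotherapy, base case
  cs <- competing_split(0.173, 0.494)
  expect_equal(cs[["p_death"]], 0.0562779, tolerance = 1e-6)
  expect_equal(cs[["p_progression"]], 0.0779242, tolerance = 1e-6)
  expect_error(competing_split(0.6, 0.5), "PFS events include deaths")
})

test_that("transition matrix is row-stochastic with the published structure", {
  p <- default_parameters()
  M <- build_transition_matrix(p)
  expect_equal(dim(M), c(8, 8))
  expect_equal(rowSums(M), stats::setNames(rep(1, 8), markov_states()),
               tolerance = 1e-12)
  expect_equal(M["dead", "dead"], 1) # absorbing
  expect_equal(M["progression", "next_line"], 0.1933314, tolerance = 1e-6)
  expect_equal(M["next_line", "progression"], 0.2036592, tolerance = 1e-6)
  expect_true(all(M >= 0))
})

test_that("interim lasts one cycle: 34/66 split to targeted/progression net of death", {
  p <- immortal_params() # zero death everywhere
  p$clinical$p_prog_to_nextline_3mo <- 0.48 # restore for structure only
  M <- build_transition_matrix(p)
  expect_equal(M["interim", "targeted"], 0.34)
  expect_equal(M["interim", "progression"], 0.66)
  expect_equal(M["interim", "interim"], 0)
})

test_that("with unit survival and no progression all non-interim rows are identity", {
  p <- immortal_params()
  p$splits$p_interim_switch <- 0
  M <- build_transition_matrix(p)
  keep <- setdiff(markov_states(), "interim")
  expect_equal(M[keep, keep], diag(7)[, ], ignore_attr = TRUE)
  # interim still empties into progression after its single cycle
  expect_equal(M["interim", "progression"], 1)
})

test_that("cohorts enter yearly and the trace conserves mass", {
  p <- default_parameters()
  tr <- run_cohorts(p, "current")
  expect_equal(attr(tr, "entered_total"), 2500)
  expect_length(attr(tr, "entry_cycles"), 5)
  lost <- attr(tr, "lost_per_cohort")
  df <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(tr), cohort, cycle),
                         total = sum(count), .groups = "drop")
  expect_true(all(abs(df$total - (500 - lost)) < 1e-6))
})

test_that("immortal cohort occupancy is constant across cycles", {
  p <- immortal_params()
  p$scenario_current$horizon_years <- 1L
  tr <- run_cohorts(p, "current")
  df <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(tr), state),
                         lo = min(count), hi = max(count), .groups = "drop")
  expect_true(all(df$hi - df$lo < 1e-9))
})

test_that("a pure-death chain decays geometrically", {
  # per-cycle death probability of 1/2: survival s with s^(30/365.25) = 0.5
  p <- immortal_params()
  s_half <- 0.5^(365.25 / 30)
  for (th in c("chemo", "immuno", "chemo_immuno", "targeted")) {
    p$clinical$pfs_1yr[[th]] <- s_half
    p$clinical$os_1yr[[th]] <- s_half
  }
  p$scenario_current$horizon_years <- 1L
  tr <- run_cohorts(p, "current")
  S <- attr(tr, "trajectory")
  alive <- rowSums(S[, 1:7])
  expect_equal(alive, alive[1] * 0.5^(seq_along(alive) - 1), tolerance = 1e-9)
})

test_that("dead-state occupancy is nondecreasing for random parameter sets", {
  for (seed in 1:25) {
    tr <- run_cohorts(random_parameter_set(seed), "proposed")
    S <- attr(tr, "trajectory")
    expect_true(all(diff(S[, "dead"]) >= -1e-9))
  }
})

test_that("targeted-only cohorts outlive chemo-only cohorts at base-case survival", {
  p <- default_parameters()
  surv_frac <- function(state_name) {
    M <- build_transition_matrix(p)
    v <- stats::setNames(numeric(8), markov_states())
    v[state_name] <- 1
    for (i in 1:61) v <- v %*% M
    1 - v[, "dead"]
  }
  expect_gt(surv_frac("targeted"), surv_frac("chemo"))
})

test_that("pct_on_targeted handles edge cases and denominators", {
  p <- default_parameters()
  tr <- run_cohorts(p, "current")
  expect_error(pct_on_targeted(tr, at = 10000), "beyond horizon")
  expect_lt(pct_on_targeted(tr, denominator = "entered"),
            pct_on_targeted(tr, denominator = "alive"))
  # no targeted inflow -> 0%
  p0 <- default_parameters()
  p0$testing$p_actionable_tissue <- 0
  p0$testing$p_actionable_blood <- 0
  expect_equal(pct_on_targeted(run_cohorts(p0, "current")), 0)
})
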