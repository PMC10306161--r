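# frozen closed-form masses: products of the base-case branch probabilities
# (hand multiplication: 0.60*0.95*0.988, 0.40*0.997*0.995, then actionable
# = conclusive_tissue*0.23 + conclusive_blood*0.24)

test_that("send-out arm reproduces the closed-form branch masses", {
  p <- default_parameters()
  alloc <- pathway_distribution(p, "current") # 100% send-out
  actionable <- alloc$mass_targeted_direct + alloc$mass_interim
  expect_equal(actionable, 0.22476024, tolerance = 1e-9)
  # conclusive tissue mass recoverable from the actionable decomposition
  expect_equal(0.56316 * 0.23 + 0.396806 * 0.24, actionable, tolerance = 1e-9)
  # therapy masses + lost mass account for the whole cohort
  total <- actionable + alloc$mass_chemo + alloc$mass_immuno +
    alloc$mass_chemoimmuno + alloc$mass_lost_second_opinion
  expect_equal(total, 1, tolerance = 1e-9)
})

test_that("in-house re-acquisition raises the conclusive tissue mass", {
  p <- default_parameters()
  p$scenario_proposed$frac_inhouse <- 1
  p$scenario_proposed$frac_sendout <- 0
  alloc <- pathway_distribution(p, "proposed")
  actionable <- alloc$mass_targeted_direct + alloc$mass_interim
  # 0.60*(0.95 + 0.05*0.95)*0.988*0.23 + 0.396806*0.24
  expect_equal(actionable, 0.23123658, tolerance = 1e-9)
})

test_that("degenerate tree: no failures and no actionable mutations", {
  p <- default_parameters()
  p$testing$p_insufficient_tissue <- 0
  p$testing$p_insufficient_blood <- 0
  p$testing$p_fail_tissue <- 0
  p$testing$p_fail_blood <- 0
  p$testing$p_actionable_tissue <- 0
  p$testing$p_actionable_blood <- 0
  alloc <- pathway_distribution(p, "current")
  nontargeted <- alloc$mass_chemo + alloc$mass_immuno + alloc$mass_chemoimmuno
  expect_equal(nontargeted + alloc$mass_lost_second_opinion, 1, tolerance = 1e-12)
  expect_equal(alloc$mass_targeted_direct + alloc$mass_interim, 0)
  expect_equal(alloc$dispatches, 1)
})

test_that("mean turnaround uses the send-out midpoint and arm weighting", {
  p <- default_parameters()
  expect_equal(mean_turnaround(p, "current"), 19.06, tolerance = 1e-9)
  # pure in-house with no retests: exactly the in-house turnaround
  p1 <- p
  p1$testing$p_insufficient_tissue <- 0
  p1$scenario_proposed$frac_inhouse <- 1
  p1$scenario_proposed$frac_sendout <- 0
  expect_equal(mean_turnaround(p1, "proposed"), 3, tolerance = 1e-12)
  # 50/50 mix, no retest contributions: linear in arm weights
  p2 <- p1
  p2$scenario_proposed$frac_inhouse <- 0.5
  p2$scenario_proposed$frac_sendout <- 0.5
  expect_equal(mean_turnaround(p2, "proposed"), 11.03, tolerance = 1e-9)
  # naive value excludes the re-acquisition delay
  expect_lt(mean_turnaround(p, "proposed", include_retest_delay = FALSE),
            mean_turnaround(p, "proposed"))
})

test_that("second-opinion loss follows the closed form", {
  p <- default_parameters()
  expect_equal(second_opinion_loss(p, "current", 500),
               500 * 0.77523976 * 0.10, tolerance = 1e-8)
  p$gaps$p_second_opinion_sendout <- 0
  expect_equal(second_opinion_loss(p, "current", 500), 0)
})

test_that("test counts reflect arm mix, multiplier, and comparator mode", {
  p <- default_parameters()
  t1 <- tests_performed(p, "current")
  expect_equal(t1$tests_sendout, 1) # multiplier 1 -> exactly 1 priced test
  expect_equal(t1$tests_inhouse, 0)
  p$money$retest_multiplier <- 1.00417
  expect_equal(tests_performed(p, "current")$tests_sendout, 1.00417)
  p2 <- default_parameters()
  p2$scenario_current$comparator_mode <- "single_gene"
  t2 <- tests_performed(p2, "current")
  expect_gt(t2$tests_singlegene, 0)
  expect_equal(t2$tests_sendout, 0)
  expect_equal(t2$tests_singlegene, p2$gaps$genes_per_singlegene_panel)
})

test_that("node conservation holds across random parameter sets", {
  for (seed in 1:150) {
    p <- random_parameter_set(seed)
    for (sc in c("current", "proposed")) {
      alloc <- pathway_distribution(p, sc)
      total <- alloc$mass_targeted_direct + alloc$mass_interim + alloc$mass_chemo +
        alloc$mass_immuno + alloc$mass_chemoimmuno + alloc$mass_lost_second_opinion
      expect_equal(total, 1, tolerance = 1e-9)
      expect_true(all(c(alloc$mass_targeted_direct, alloc$mass_interim,
                        alloc$mass_chemo, alloc$mass_immuno,
                        alloc$mass_chemoimmuno, alloc$mass_lost_second_opinion) >= 0))
    }
  }
})

test_that("actionable probability monotonically feeds the targeted masses", {
  p <- default_parameters()
  targ <- vapply(seq(0, 0.5, by = 0.05), function(pa) {
    p$testing$p_actionable_tissue <- pa
    a <- pathway_distribution(p, "current")
    a$mass_targeted_direct + a$mass_interim
  }, numeric(1))
  expect_true(all(diff(targ) >= 0))
})

test_that("in-house arm loses no more patients than send-out at equal parameters", {
  p <- default_parameters()
  p$gaps$p_second_opinion_inhouse <- p$gaps$p_second_opinion_sendout
  p$gaps$interim_tat_scaling <- FALSE
  cur <- pathway_distribution(p, "current") # 100% send-out
  p$scenario_proposed$frac_inhouse <- 1
  p$scenario_proposed$frac_sendout <- 0
  prop <- pathway_distribution(p, "proposed") # 100% in-house
  expect_lte(prop$mass_lost_second_opinion, cur$mass_lost_second_opinion)
})
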