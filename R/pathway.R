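#' Decision-tree testing pathway
#'
#' The testing pathway distributes each annual cohort across therapy
#' assignments and second-opinion loss. Node order: sample type (tissue vs
#' blood) -> sample sufficiency -> test success -> actionable mutation. An
#' inconclusive branch (insufficient sample, failed test, or no actionable
#' mutation) reaches the nontargeted node, where a fraction `p_second_opinion`
#' leaves the hospital and the retained mass is split across immunotherapy,
#' chemotherapy, and chemo+immuno by the normalized 25/29/36 weights. The
#' actionable branch splits into direct targeted therapy and interim
#' (nontargeted bridging) therapy.
#'
#' Arm differences: with in-house testing an insufficient tissue sample
#' triggers exactly one re-acquisition (a second sufficiency draw); a second
#' insufficiency routes to the nontargeted node. With send-out testing there
#' is no re-acquisition. When turnaround scaling is enabled
#' (`gaps$interim_tat_scaling`), the in-house interim fraction is the printed
#' interim probability scaled by the turnaround ratio
#' `tat_inhouse / midpoint(send-out range)` - faster results mean fewer
#' patients need bridging therapy.
#'
#' Test accounting: each tested patient consumes one priced test in their arm
#' (an insufficient sample means the sequencing run never took place;
#' re-acquisition repeats sampling, not a billed run), scaled by the
#' calibrated `retest_multiplier` that absorbs repeat runs after failures.
#' Dispatch counts (including re-acquisition attempts) are reported
#' separately.
#'
#' @name testing_pathway
NULL

# Allocation for a single testing arm. `arm` is "inhouse", "sendout" or
# "single_gene" (external single-gene panel; pathway probabilities as send-out).
arm_allocation <- function(params, arm) {
  t <- params$testing
  g <- params$gaps
  s <- params$splits

  reacquire <- arm == "inhouse"
  # probability a tissue sample is eventually sufficient
  p_suff_tissue <- if (reacquire) {
    (1 - t$p_insufficient_tissue) + t$p_insufficient_tissue * (1 - t$p_insufficient_tissue)
  } else {
    1 - t$p_insufficient_tissue
  }
  conclusive_tissue <- t$frac_tissue * p_suff_tissue * (1 - t$p_fail_tissue)
  conclusive_blood <- t$frac_blood * (1 - t$p_insufficient_blood) * (1 - t$p_fail_blood)

  actionable <- conclusive_tissue * t$p_actionable_tissue +
    conclusive_blood * t$p_actionable_blood
  nontargeted_node <- 1 - actionable

  p_so <- if (arm == "inhouse") g$p_second_opinion_inhouse else g$p_second_opinion_sendout
  lost <- nontargeted_node * p_so
  retained_nt <- nontargeted_node - lost
  wsum <- s$p_immuno_nontargeted + s$p_chemo_nontargeted + s$p_chemoimmuno_nontargeted
  w <- c(immuno = s$p_immuno_nontargeted, chemo = s$p_chemo_nontargeted,
         chemo_immuno = s$p_chemoimmuno_nontargeted) / wsum

  mid <- sendout_tat_midpoint(params)
  p_interim <- s$p_interim
  if (arm == "inhouse" && isTRUE(g$interim_tat_scaling) && mid > 0) {
    p_interim <- p_interim * min(1, params$tat$tat_inhouse / mid)
  }

  # expected re-acquisition attempts per patient (tissue only, in-house only)
  reacq <- if (reacquire) t$frac_tissue * t$p_insufficient_tissue else 0

  # turnaround: base TAT for the arm plus the extra wait of re-acquired patients
  tat_base <- if (arm == "inhouse") params$tat$tat_inhouse else mid
  tat_retest <- if (arm == "inhouse") reacq * params$tat$tat_inhouse else 0

  m <- params$money$retest_multiplier
  tibble::tibble(
    arm = arm,
    mass_targeted_direct = actionable * (1 - p_interim),
    mass_interim = actionable * p_interim,
    mass_chemo = retained_nt * w[["chemo"]],
    mass_immuno = retained_nt * w[["immuno"]],
    mass_chemoimmuno = retained_nt * w[["chemo_immuno"]],
    mass_lost_second_opinion = lost,
    tests_inhouse = if (arm == "inhouse") m else 0,
    tests_sendout = if (arm == "sendout") m else 0,
    tests_singlegene = if (arm == "single_gene") m * g$genes_per_singlegene_panel else 0,
    dispatches = 1 + reacq,
    mean_tat = tat_base,
    mean_tat_retest = tat_base + tat_retest
  )
}

# which arm the non-in-house fraction uses under the scenario's comparator mode
comparator_arm <- function(scenario) {
  if (identical(scenario$comparator_mode, "single_gene")) "single_gene" else "sendout"
}

#' Distribute a cohort through the testing pathway
#'
#' Computes the expected per-patient allocation across decision-tree terminal
#' nodes for a scenario's arm mix, together with expected test counts and mean
#' turnaround time.
#'
#' @param params a validated [bia_parameters] object.
#' @param scenario `"current"`, `"proposed"`, or a scenario parameter list.
#' @return one-row tibble with therapy masses (`mass_targeted_direct`,
#'   `mass_interim`, `mass_chemo`, `mass_immuno`, `mass_chemoimmuno`,
#'   `mass_lost_second_opinion`, summing to 1), expected priced test counts per
#'   patient by type, dispatch counts, and mean turnaround (`mean_tat`, with
#'   and without retest delay as `mean_tat_naive`). The per-arm breakdown is
#'   attached as attribute `"by_arm"`.
#' @examples
#' pathway_distribution(default_parameters(), "current")
#' @export
pathway_distribution <- function(params, scenario) {
  assert_valid_parameters(params)
  sc <- resolve_scenario(params, scenario)
  arms <- dplyr::bind_rows(
    arm_allocation(params, "inhouse"),
    arm_allocation(params, comparator_arm(sc))
  )
  wts <- c(sc$frac_inhouse, sc$frac_sendout)
  num <- names(arms)[vapply(arms, is.numeric, logical(1))]
  combined <- tibble::as_tibble(as.list(colSums(arms[num] * wts)))
  combined <- dplyr::mutate(
    combined,
    mean_tat_naive = sum(c(arms$mean_tat) * wts),
    mean_tat = sum(c(arms$mean_tat_retest) * wts),
    mean_tat_retest = NULL
  )
  out <- dplyr::bind_cols(tibble::tibble(scenario = if (is.character(scenario)) scenario else "custom"),
                          combined)
  attr(out, "by_arm") <- dplyr::mutate(arms, weight = wts)
  class(out) <- c("bia_allocation", class(out))
  out
}

#' Mean result turnaround time
#'
#' Patient-weighted expected days from test dispatch to result. The send-out
#' point value is the midpoint of the published turnaround range; the in-house
#' value is the published 3 days. With `include_retest_delay = TRUE` (default)
#' in-house patients whose tissue sample was insufficient contribute one extra
#' in-house turnaround for the re-acquired sample.
#'
#' @inheritParams pathway_distribution
#' @param include_retest_delay include the re-acquisition delay contribution?
#' @return mean turnaround in days.
#' @examples
#' mean_turnaround(default_parameters(), "current") # ~19 days
#' @export
mean_turnaround <- function(params, scenario, include_retest_delay = TRUE) {
  alloc <- pathway_distribution(params, scenario)
  if (include_retest_delay) alloc$mean_tat else alloc$mean_tat_naive
}

#' Expected patients lost to second opinion
#'
#' Patients reaching the nontargeted node may leave the hospital for a second
#' opinion; they incur testing costs but generate no downstream visit revenue.
#'
#' @inheritParams pathway_distribution
#' @param cohort_size patients entering in one cohort.
#' @return expected number of patients lost from one cohort.
#' @export
second_opinion_loss <- function(params, scenario, cohort_size) {
  alloc <- pathway_distribution(params, scenario)
  cohort_size * alloc$mass_lost_second_opinion
}

#' Expected test counts per patient
#'
#' @inheritParams pathway_distribution
#' @return one-row tibble of priced test counts per patient
#'   (`tests_inhouse`, `tests_sendout`, `tests_singlegene`, including the
#'   retest multiplier) and raw dispatch counts (`dispatches`, including
#'   re-acquisition attempts).
#' @export
tests_performed <- function(params, scenario) {
  alloc <- pathway_distribution(params, scenario)
  dplyr::select(tibble::as_tibble(alloc), dplyr::all_of(
    c("scenario", "tests_inhouse", "tests_sendout", "tests_singlegene", "dispatches")))
}
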