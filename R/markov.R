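#' Eight-state Markov disease model
#'
#' Disease progression from therapy initiation until death is modeled with
#' eight states - chemotherapy, immunotherapy, chemo+immuno, interim therapy,
#' targeted therapy, disease progression, next-line treatment, and death - on
#' a 30-day cycle. Published 1-year survival proportions are converted to
#' per-cycle probabilities under a constant-hazard assumption; death is
#' reachable from every state and is absorbing.
#'
#' @name disease_model
NULL

#' Markov state names
#' @return character vector of the 8 state names, death last.
#' @export
markov_states <- function() {
  c("chemo", "immuno", "chemo_immuno", "interim", "targeted",
    "progression", "next_line", "dead")
}

#' Convert an annual survival proportion to a per-cycle event probability
#'
#' Constant-hazard conversion: a 1-year survival `s` implies hazard
#' `-log(s)` per year, so the event probability over one cycle of
#' `cycle_days` is `1 - s^(cycle_days / days_per_year)`. Compounding over
#' `days_per_year / cycle_days` cycles recovers `1 - s` exactly.
#'
#' @param survival_1yr surviving (event-free) proportion at 1 year, in (0, 1].
#' @param cycle_days cycle length in days.
#' @param days_per_year calendar-year convention (365.25 by default).
#' @return per-cycle event probability.
#' @examples
#' annual_prob_to_cycle(0.494) # chemotherapy OS -> per-30-day death prob
#' @export
annual_prob_to_cycle <- function(survival_1yr, cycle_days = 30, days_per_year = 365.25) {
  if (any(survival_1yr <= 0))
    stop("survival_1yr must be > 0 (zero survival implies infinite hazard)", call. = FALSE)
  if (any(survival_1yr > 1)) stop("survival_1yr must be <= 1", call. = FALSE)
  if (cycle_days <= 0) stop("cycle_days must be positive", call. = FALSE)
  1 - survival_1yr^(cycle_days / days_per_year)
}

# convert an event probability over ref_days to one over cycle_days
prob_rescale <- function(p_event, ref_days, cycle_days) {
  1 - (1 - p_event)^(cycle_days / ref_days)
}

#' Split progression-free survival into progression and death probabilities
#'
#' PFS events include deaths, so the per-cycle progression probability is the
#' PFS event probability minus the death probability derived from overall
#' survival, floored at zero.
#'
#' @param pfs_1yr 1-year progression-free survival, in (0, 1].
#' @param os_1yr 1-year overall survival, must be >= `pfs_1yr`.
#' @inheritParams annual_prob_to_cycle
#' @return named numeric vector `c(p_progression, p_death)` per cycle.
#' @export
competing_split <- function(pfs_1yr, os_1yr, cycle_days = 30, days_per_year = 365.25) {
  if (pfs_1yr > os_1yr + 1e-12)
    stop("pfs_1yr exceeds os_1yr: PFS events include deaths", call. = FALSE)
  p_death <- annual_prob_to_cycle(os_1yr, cycle_days, days_per_year)
  p_event <- annual_prob_to_cycle(pfs_1yr, cycle_days, days_per_year)
  c(p_progression = max(0, p_event - p_death), p_death = p_death)
}

#' Build the per-cycle transition matrix
#'
#' Therapy rows (chemo, immuno, chemo+immuno, targeted) use
#' [competing_split()] on that therapy's survival pair. The interim row lasts
#' exactly one cycle: of the patients surviving the cycle,
#' `p_interim_switch` move to targeted therapy and the rest to disease
#' progression; interim mortality is the 25/29/36-weighted nontargeted mix.
#' Progression and next-line exchange mass at the published 3-month
#' probabilities rescaled to the cycle length, with death probabilities from
#' their (overridable, chemotherapy-default) 1-year OS. Death is absorbing.
#'
#' @param params a validated [bia_parameters] object.
#' @return 8x8 row-stochastic matrix with dimnames [markov_states()].
#' @export
build_transition_matrix <- function(params) {
  cl <- params$clinical
  g <- params$gaps
  st <- markov_states()
  M <- matrix(0, 8, 8, dimnames = list(st, st))
  conv <- function(s) annual_prob_to_cycle(s, g$cycle_days, g$days_per_year)

  for (th in c("chemo", "immuno", "chemo_immuno", "targeted")) {
    cs <- competing_split(cl$pfs_1yr[[th]], cl$os_1yr[[th]], g$cycle_days, g$days_per_year)
    M[th, th] <- 1 - cs[["p_progression"]] - cs[["p_death"]]
    M[th, "progression"] <- cs[["p_progression"]]
    M[th, "dead"] <- cs[["p_death"]]
  }

  # interim: one-cycle bridging therapy on the nontargeted mix
  s <- params$splits
  wsum <- s$p_immuno_nontargeted + s$p_chemo_nontargeted + s$p_chemoimmuno_nontargeted
  p_death_interim <- (s$p_immuno_nontargeted * conv(cl$os_1yr$immuno) +
                        s$p_chemo_nontargeted * conv(cl$os_1yr$chemo) +
                        s$p_chemoimmuno_nontargeted * conv(cl$os_1yr$chemo_immuno)) / wsum
  M["interim", "targeted"] <- s$p_interim_switch * (1 - p_death_interim)
  M["interim", "progression"] <- (1 - s$p_interim_switch) * (1 - p_death_interim)
  M["interim", "dead"] <- p_death_interim

  quarter <- g$days_per_year / 4
  p_pn <- prob_rescale(cl$p_prog_to_nextline_3mo, quarter, g$cycle_days)
  p_np <- prob_rescale(cl$p_nextline_to_prog_3mo, quarter, g$cycle_days)
  d_prog <- conv(cl$os_1yr_progression)
  d_next <- conv(cl$os_1yr_next_line)
  if (p_pn + d_prog > 1 || p_np + d_next > 1)
    stop("progression/next-line transition and death probabilities exceed 1", call. = FALSE)
  M["progression", "next_line"] <- p_pn
  M["progression", "dead"] <- d_prog
  M["progression", "progression"] <- 1 - p_pn - d_prog
  M["next_line", "progression"] <- p_np
  M["next_line", "dead"] <- d_next
  M["next_line", "next_line"] <- 1 - p_np - d_next

  M["dead", "dead"] <- 1

  if (any(M < -1e-12))
    stop("negative transition probability after competing-risk floor", call. = FALSE)
  if (any(abs(rowSums(M) - 1) > 1e-12))
    stop("transition matrix rows do not sum to 1", call. = FALSE)
  M
}

# entry state vector (per entering patient, lost mass excluded) from an allocation
entry_vector <- function(alloc) {
  v <- stats::setNames(numeric(8), markov_states())
  v["chemo"] <- alloc$mass_chemo
  v["immuno"] <- alloc$mass_immuno
  v["chemo_immuno"] <- alloc$mass_chemoimmuno
  v["interim"] <- alloc$mass_interim
  v["targeted"] <- alloc$mass_targeted_direct
  v
}

# cycle indices (0-based) at which annual cohorts enter, and horizon length
cohort_entry_cycles <- function(scenario, gaps) {
  cpy <- gaps$days_per_year / gaps$cycle_days
  round((seq_len(scenario$horizon_years) - 1) * cpy)
}

horizon_cycles <- function(scenario, gaps) {
  round(scenario$horizon_years * gaps$days_per_year / gaps$cycle_days)
}

#' Propagate annual cohorts through the Markov model
#'
#' One cohort of `patients_per_year` enters at the start of each model year
#' (cycle indices rounded from 12.175 cycles/year), initialized across the
#' therapy states from the decision-tree allocation with lost-to-second-
#' opinion patients excluded, and is propagated in 30-day cycles to the end of
#' the horizon.
#'
#' @param params a validated [bia_parameters] object.
#' @param scenario `"current"`, `"proposed"`, or a scenario parameter list.
#' @param alloc optional precomputed [pathway_distribution()] result.
#' @return a `bia_trace`: tibble (`cohort`, `cycle`, `state`, `count`) of
#'   expected patient counts at every cycle boundary from each cohort's entry
#'   cycle to the horizon end, with attributes `n_cycles`, `entry_cycles`,
#'   `cohort_size`, `lost_per_cohort`, and `entered_total`.
#' @examples
#' tr <- run_cohorts(default_parameters(), "current")
#' dplyr::filter(tr, cycle == max(cycle), state == "targeted")
#' @export
run_cohorts <- function(params, scenario, alloc = NULL) {
  assert_valid_parameters(params)
  sc <- resolve_scenario(params, scenario)
  if (sc$horizon_years < 1) stop("horizon_years must be >= 1", call. = FALSE)
  if (is.null(alloc)) alloc <- pathway_distribution(params, scenario)
  M <- build_transition_matrix(params)

  n_cyc <- horizon_cycles(sc, params$gaps)
  entries <- cohort_entry_cycles(sc, params$gaps)
  v0 <- entry_vector(alloc) * sc$patients_per_year

  # all cohorts share the same entry vector and matrix: compute one
  # trajectory and reuse it shifted per cohort
  S <- matrix(0, n_cyc + 1, 8, dimnames = list(NULL, markov_states()))
  S[1, ] <- v0
  for (t in seq_len(n_cyc)) S[t + 1, ] <- S[t, ] %*% M

  rows <- purrr::imap(entries, function(e, i) {
    len <- n_cyc - e + 1
    tibble::tibble(
      cohort = i,
      cycle = rep(e:n_cyc, times = 8),
      state = rep(markov_states(), each = len),
      count = c(S[seq_len(len), ])
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "trajectory") <- S # single-cohort trajectory, row t+1 = cycle t since entry
  attr(out, "n_cycles") <- n_cyc
  attr(out, "entry_cycles") <- entries
  attr(out, "cohort_size") <- sc$patients_per_year
  attr(out, "lost_per_cohort") <- sc$patients_per_year * alloc$mass_lost_second_opinion
  attr(out, "entered_total") <- sc$patients_per_year * length(entries)
  attr(out, "scenario") <- if (is.character(scenario)) scenario else "custom"
  class(out) <- c("bia_trace", class(out))
  out
}

# total occupancy by state at one cycle, summed over cohorts present
occupancy_at <- function(trace, at) {
  tr <- dplyr::filter(tibble::as_tibble(trace), .data$cycle == at)
  x <- tapply(tr$count, factor(tr$state, levels = markov_states()), sum, default = 0)
  as.numeric(x)
}

#' Percentage of patients on targeted therapy
#'
#' Share of patients occupying the targeted-therapy state at a given cycle.
#' The default denominator is the patients alive and retained at that cycle
#' (the reported "patients on targeted therapy" share); `"entered"` divides by
#' all patients ever entered instead.
#'
#' @param trace a [run_cohorts()] trace.
#' @param at cycle index (default: end of horizon).
#' @param denominator `"alive"` (default) or `"entered"`.
#' @return percentage (0-100).
#' @export
pct_on_targeted <- function(trace, at = NULL, denominator = c("alive", "entered")) {
  denominator <- match.arg(denominator)
  n_cyc <- attr(trace, "n_cycles")
  at <- at %||% n_cyc
  if (at < 0 || at > n_cyc) stop("cycle index beyond horizon", call. = FALSE)
  occ <- occupancy_at(trace, at)
  names(occ) <- markov_states()
  denom <- if (denominator == "alive") sum(occ) - occ[["dead"]] else attr(trace, "entered_total")
  if (denom <= 0) return(0)
  100 * occ[["targeted"]] / denom
}
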