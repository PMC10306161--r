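#' Patient-level microsimulation oracle
#'
#' Simulates individual patients through the identical decision-tree and
#' Markov rules as the cohort engine (Bernoulli draws at tree nodes,
#' categorical draws per 30-day cycle) and checks agreement with the cohort
#' trace cell by cell. Also generates random valid parameter sets for
#' property tests. All randomness is drawn up front into patient x cycle
#' matrices from one seeded generator, so results do not depend on the order
#' patients are processed.
#'
#' @name microsim_validator
NULL

#' Simulate individual patients through pathway and Markov model
#'
#' Patients are split evenly across the annual entry cohorts. Each patient
#' draws a testing arm, a sample type, sufficiency (with one in-house
#' re-acquisition), test failure, actionability, the second-opinion decision,
#' and a therapy assignment, then walks the Markov chain on the shared 30-day
#' grid until the horizon.
#'
#' @param params a validated [bia_parameters] object.
#' @param scenario `"current"`, `"proposed"`, or a scenario list.
#' @param n number of patients (>= 1).
#' @param seed integer RNG seed.
#' @param keep_histories also return per-patient records?
#' @return a `bia_microsim` list: `occupancy` (tibble cycle x state: patient
#'   counts), `totals` (lost, deaths, dispatches by arm), `n`, `seed`, and
#'   optionally `histories` (tibble of per-patient pathway outcomes and
#'   state sequences in wide matrix attribute).
#' @export
simulate_patients <- function(params, scenario, n, seed = 1L, keep_histories = FALSE) {
  assert_valid_parameters(params)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  sc <- resolve_scenario(params, scenario)
  t <- params$testing
  g <- params$gaps
  s <- params$splits
  M <- build_transition_matrix(params)
  cumM <- t(apply(M, 1, cumsum))
  states <- markov_states()
  n_cyc <- horizon_cycles(sc, g)
  entries <- cohort_entry_cycles(sc, g)

  set.seed(seed)
  cohort <- rep_len(seq_along(entries), n) # evenly split across entry years
  entry_cycle <- entries[cohort]

  arm2 <- comparator_arm(sc)
  inhouse <- stats::runif(n) < sc$frac_inhouse
  tissue <- stats::runif(n) < t$frac_tissue
  # sufficiency: one re-acquisition attempt for in-house tissue samples
  ins1 <- stats::runif(n) < ifelse(tissue, t$p_insufficient_tissue, t$p_insufficient_blood)
  ins2 <- stats::runif(n) < ifelse(tissue, t$p_insufficient_tissue, t$p_insufficient_blood)
  reacquired <- inhouse & tissue & ins1
  sufficient <- ifelse(inhouse & tissue, !ins1 | !ins2, !ins1)
  failed <- sufficient & (stats::runif(n) < ifelse(tissue, t$p_fail_tissue, t$p_fail_blood))
  conclusive <- sufficient & !failed
  actionable <- conclusive &
    (stats::runif(n) < ifelse(tissue, t$p_actionable_tissue, t$p_actionable_blood))

  # nontargeted node: second opinion then normalized therapy weights
  p_so <- ifelse(inhouse, g$p_second_opinion_inhouse, g$p_second_opinion_sendout)
  lost <- !actionable & (stats::runif(n) < p_so)
  w <- c(s$p_chemo_nontargeted, s$p_immuno_nontargeted, s$p_chemoimmuno_nontargeted)
  w <- cumsum(w / sum(w))
  u_nt <- stats::runif(n)
  nt_state <- ifelse(u_nt < w[1], "chemo", ifelse(u_nt < w[2], "immuno", "chemo_immuno"))

  # actionable node: interim fraction, turnaround-scaled for in-house
  mid <- sendout_tat_midpoint(params)
  p_int_ih <- if (isTRUE(g$interim_tat_scaling) && mid > 0) {
    s$p_interim * min(1, params$tat$tat_inhouse / mid)
  } else s$p_interim
  p_int <- ifelse(inhouse, p_int_ih, s$p_interim)
  interim <- actionable & (stats::runif(n) < p_int)

  state0 <- ifelse(lost, NA_character_,
                   ifelse(actionable, ifelse(interim, "interim", "targeted"), nt_state))
  state_idx <- match(state0, states)

  # Markov walk: one uniform per patient per cycle, drawn up front
  U <- matrix(stats::runif(n * n_cyc), n, n_cyc)
  S <- matrix(NA_integer_, n, n_cyc + 1) # column t+1 = state at cycle t
  alive_mask <- !lost
  S[cbind(which(alive_mask), entry_cycle[alive_mask] + 1L)] <- state_idx[alive_mask]
  cur <- state_idx
  for (cyc in seq_len(n_cyc)) {
    act <- which(alive_mask & entry_cycle < cyc)
    if (length(act) > 0) {
      cur[act] <- 1L + rowSums(U[act, cyc, drop = TRUE] > cumM[cur[act], , drop = FALSE])
      S[act, cyc + 1L] <- cur[act]
    }
  }

  occ <- purrr::map_dfr(0:n_cyc, function(cyc) {
    counts <- tabulate(S[, cyc + 1L], nbins = 8L)
    tibble::tibble(cycle = cyc, state = states, count = counts)
  })

  n_lost <- sum(lost)
  n_dead <- sum(cur == 8L & !lost, na.rm = TRUE)
  totals <- tibble::tibble(
    n = n, lost = n_lost, deaths = n_dead,
    dispatches_inhouse = sum(inhouse) + sum(reacquired),
    dispatches_comparator = sum(!inhouse),
    comparator_arm = arm2,
    actionable = sum(actionable)
  )

  out <- list(occupancy = occ, totals = totals, n = n, seed = seed,
              entry_cycles = entries, cohort = cohort, n_cycles = n_cyc)
  if (keep_histories) {
    out$histories <- tibble::tibble(
      patient = seq_len(n), cohort = cohort, entry_cycle = entry_cycle,
      arm = ifelse(inhouse, "inhouse", arm2),
      sample = ifelse(tissue, "tissue", "blood"),
      reacquired = reacquired, sufficient = sufficient, failed = failed,
      actionable = actionable, lost = lost, entry_state = state0
    )
    attr(out$histories, "state_matrix") <- S
  }
  structure(out, class = "bia_microsim")
}

#' Compare microsimulation occupancy with the cohort trace
#'
#' Per (cycle, state) cell the cohort model gives the expected occupancy
#' probability p of one entering patient; with n simulated patients the
#' microsim count is approximately Binomial(n_cell, p), so the z-score
#' `(micro - n_cell p) / sqrt(n_cell p (1-p))` should rarely exceed 3 in
#' magnitude. Cells with expected probability 0 or 1 are checked exactly.
#'
#' @param micro a [simulate_patients()] result.
#' @param trace the matching [run_cohorts()] trace (same parameters,
#'   scenario, horizon).
#' @return a `bia_discrepancy` list: `cells` tibble (cycle, state, expected,
#'   observed, se, z, flagged), `n_cells`, `n_flagged`, `flag_rate`, and
#'   `pass` (flag rate <= 1%).
#' @export
compare_with_cohort <- function(micro, trace) {
  n_cyc <- attr(trace, "n_cycles")
  if (!identical(n_cyc, micro$n_cycles))
    stop("microsim and cohort trace cover different horizons", call. = FALSE)
  entered <- attr(trace, "entered_total")
  states <- markov_states()

  # expected per-patient probability of occupying each cell, including the
  # not-yet-entered and lost mass handled identically on both sides
  n_per_cohort <- tabulate(micro$cohort, nbins = length(micro$entry_cycles))
  cohort_scale <- n_per_cohort / attr(trace, "cohort_size")

  tr <- tibble::as_tibble(trace)
  cells <- purrr::map_dfr(0:n_cyc, function(cyc) {
    at <- tr[tr$cycle == cyc, ]
    exp_counts <- numeric(8)
    n_present <- 0
    for (co in unique(at$cohort)) {
      sub <- at[at$cohort == co, ]
      exp_counts <- exp_counts + cohort_scale[co] *
        sub$count[match(states, sub$state)]
      n_present <- n_present + n_per_cohort[co]
    }
    tibble::tibble(cycle = cyc, state = states, expected = exp_counts,
                   n_present = n_present)
  })
  obs <- micro$occupancy
  cells$observed <- obs$count[match(paste(cells$cycle, cells$state),
                                    paste(obs$cycle, obs$state))]
  p <- ifelse(cells$n_present > 0, cells$expected / cells$n_present, 0)
  cells$se <- sqrt(pmax(cells$n_present * p * (1 - p), 0))
  cells$z <- ifelse(cells$se > 0, (cells$observed - cells$expected) / cells$se, 0)
  degenerate_bad <- cells$se == 0 & abs(cells$observed - cells$expected) > 1e-9
  cells$flagged <- abs(cells$z) > 3 | degenerate_bad
  structure(list(cells = cells, n_cells = nrow(cells),
                 n_flagged = sum(cells$flagged),
                 flag_rate = mean(cells$flagged),
                 pass = mean(cells$flagged) <= 0.01),
            class = "bia_discrepancy")
}

#' Random valid parameter set
#'
#' Draws every input uniformly within +/-50% of its default, clipped to legal
#' ranges, with complement and ordering invariants restored (tissue/blood
#' mix, direct/interim split, OS >= PFS, nontargeted splits <= 1). Used by
#' property tests; the result always passes [validate_parameters()].
#'
#' @param seed integer RNG seed.
#' @return a valid [bia_parameters] object.
#' @export
random_parameter_set <- function(seed) {
  set.seed(seed)
  p <- default_parameters()
  jit <- function(x, lo = 0, hi = 1) pmin(pmax(x * stats::runif(length(x), 0.5, 1.5), lo), hi)

  p$testing$frac_tissue <- jit(p$testing$frac_tissue, 0.05, 0.95)
  p$testing$frac_blood <- 1 - p$testing$frac_tissue
  for (f in c("p_insufficient_tissue", "p_insufficient_blood", "p_fail_tissue",
              "p_fail_blood", "p_actionable_tissue", "p_actionable_blood"))
    p$testing[[f]] <- jit(p$testing[[f]], 0, 0.95)

  sp <- vapply(c("p_immuno_nontargeted", "p_chemo_nontargeted", "p_chemoimmuno_nontargeted"),
               function(f) jit(p$splits[[f]]), numeric(1))
  if (sum(sp) > 0.99) sp <- sp * 0.9 / sum(sp)
  p$splits$p_immuno_nontargeted <- sp[[1]]
  p$splits$p_chemo_nontargeted <- sp[[2]]
  p$splits$p_chemoimmuno_nontargeted <- sp[[3]]
  p$splits$p_interim <- jit(p$splits$p_interim, 0, 1)
  p$splits$p_direct_targeted <- 1 - p$splits$p_interim
  p$splits$p_interim_switch <- jit(p$splits$p_interim_switch, 0, 1)

  for (f in c("cost_inhouse_test", "cost_sendout_test", "cost_singlegene_test",
              "cost_machine_acquisition", "reimb_inhouse_test", "revenue_hospital_visit"))
    p$money[[f]] <- jit(p$money[[f]], 0, Inf)
  p$money$retest_multiplier <- stats::runif(1, 1.0, 1.01)
  p$money$visits_per_cycle <- jit(p$money$visits_per_cycle, 0.05, 10)

  p$tat$tat_inhouse <- jit(p$tat$tat_inhouse, 0.5, Inf)
  lohi <- sort(jit(c(p$tat$tat_sendout_low, p$tat$tat_sendout_high), 1, Inf))
  p$tat$tat_sendout_low <- lohi[1]
  p$tat$tat_sendout_high <- lohi[2]

  for (th in c("chemo", "immuno", "chemo_immuno", "targeted")) {
    os <- jit(p$clinical$os_1yr[[th]], 0.05, 0.99)
    pfs <- min(jit(p$clinical$pfs_1yr[[th]], 0.01, 0.99), os)
    p$clinical$os_1yr[[th]] <- os
    p$clinical$pfs_1yr[[th]] <- pfs
  }
  p$clinical$os_1yr_progression <- jit(p$clinical$os_1yr_progression, 0.05, 0.99)
  p$clinical$os_1yr_next_line <- jit(p$clinical$os_1yr_next_line, 0.05, 0.99)
  p$clinical$p_prog_to_nextline_3mo <- jit(p$clinical$p_prog_to_nextline_3mo, 0, 0.9)
  p$clinical$p_nextline_to_prog_3mo <- jit(p$clinical$p_nextline_to_prog_3mo, 0, 0.9)

  p$gaps$p_second_opinion_sendout <- jit(p$gaps$p_second_opinion_sendout, 0, 1)
  p$gaps$p_second_opinion_inhouse <- jit(p$gaps$p_second_opinion_inhouse, 0, 1)

  frac <- jit(p$scenario_proposed$frac_inhouse, 0, 1)
  p$scenario_proposed$frac_inhouse <- frac
  p$scenario_proposed$frac_sendout <- 1 - frac

  p$uncertainty <- default_uncertainty(p)
  # ranges must bracket the jittered points: rebuild as +/-10% of new values
  p$uncertainty <- dplyr::mutate(
    p$uncertainty,
    point = vapply(.data$parameter, function(pa) uncertainty_point(p, pa), numeric(1)),
    low = pmin(.data$low, 0.9 * .data$point),
    high = pmax(.data$high, 1.1 * .data$point),
    high = ifelse(.data$dist == "beta", pmin(.data$high, 1), .data$high),
    point = NULL
  )
  assert_valid_parameters(p)
  p
}

#' @export
print.bia_microsim <- function(x, ...) {
  cat(sprintf("<bia_microsim: %d patients, seed %d>\n", x$n, x$seed))
  print(x$totals)
  invisible(x)
}

#' @export
print.bia_discrepancy <- function(x, ...) {
  cat(sprintf("<bia_discrepancy: %d/%d cells flagged (%.2f%%) -> %s>\n",
              x$n_flagged, x$n_cells, 100 * x$flag_rate,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
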