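#' Budget engine
#'
#' Converts pathway test counts and the cohort trace into yearly cost and
#' revenue ledgers (discounted and undiscounted), the return on investment
#' (ROI) of the proposed vs the current scenario, and the payback period.
#' Convention: end-of-year discounting from year 1; the machine acquisition is
#' a time-0 outlay and is not discounted.
#'
#' @name budget_engine
NULL

#' End-of-year discount factor
#'
#' @param year_index model year (1-based); year-0 outlays are undiscounted.
#' @param rate annual discount rate as a fraction (e.g. 0.035).
#' @return `(1 + rate)^(-year_index)`.
#' @export
discount_factor <- function(year_index, rate) {
  if (any(rate < 0)) stop("discount rate must be nonnegative", call. = FALSE)
  (1 + rate)^(-year_index)
}

# calendar year (1..horizon) a cycle boundary falls in
cycle_calendar_year <- function(cycle, gaps, horizon_years) {
  pmin(pmax(ceiling(cycle * gaps$cycle_days / gaps$days_per_year), 1L), horizon_years)
}

#' Run one scenario end to end
#'
#' Builds the pathway allocation, the cohort trace, and the yearly budget
#' ledger for one scenario. Ledger streams: testing cost (priced tests x unit
#' cost x retest multiplier per entering cohort), machine acquisition (year 0,
#' proposed-style scenarios with in-house testing only), in-house test
#' reimbursement, and hospital-visit revenue (retained alive occupancy per
#' cycle x visits per cycle x visit price).
#'
#' @param params a validated [bia_parameters] object.
#' @param scenario `"current"` or `"proposed"` (or a scenario list).
#' @return a `bia_scenario` list: `scenario`, `alloc`, `trace`, `ledger`
#'   (tibble year 0..horizon with undiscounted and discounted streams), and
#'   `totals` (one-row tibble of discounted/undiscounted totals plus
#'   turnaround, % targeted, and lost patients).
#' @examples
#' cur <- run_scenario(default_parameters(), "current")
#' cur$totals
#' @export
run_scenario <- function(params, scenario) {
  assert_valid_parameters(params)
  sc <- resolve_scenario(params, scenario)
  alloc <- pathway_distribution(params, scenario)
  trace <- run_cohorts(params, scenario, alloc)
  g <- params$gaps
  m <- params$money
  yrs <- seq_len(sc$horizon_years)

  unit_cost <- alloc$tests_inhouse * m$cost_inhouse_test +
    alloc$tests_sendout * m$cost_sendout_test +
    alloc$tests_singlegene * m$cost_singlegene_test
  testing_cost <- rep(sc$patients_per_year * unit_cost, sc$horizon_years)

  reimb_per_patient <- alloc$tests_inhouse * m$reimb_inhouse_test
  if (!isTRUE(g$reimburse_inhouse_only)) {
    reimb_per_patient <- reimb_per_patient + alloc$tests_sendout * m$reimb_inhouse_test
  }
  reimbursement <- rep(sc$patients_per_year * reimb_per_patient, sc$horizon_years)

  # visit revenue accrues on survivors at the end of each cycle; assembled
  # from the shared single-cohort trajectory shifted per entry cycle
  n_cyc <- attr(trace, "n_cycles")
  S <- attr(trace, "trajectory")
  alive_by_age <- rowSums(S[, seq_len(7), drop = FALSE])
  alive <- numeric(n_cyc)
  for (e in attr(trace, "entry_cycles")) {
    idx <- seq.int(e + 1, n_cyc) # cycles this cohort completes
    alive[idx] <- alive[idx] + alive_by_age[idx - e + 1]
  }
  cyc_year <- cycle_calendar_year(seq_len(n_cyc), g, sc$horizon_years)
  visit_cycle <- alive * m$visits_per_cycle * m$revenue_hospital_visit
  visit_revenue <- as.numeric(tapply(visit_cycle, factor(cyc_year, levels = yrs), sum, default = 0))

  acquisition <- if (sc$frac_inhouse > 0) m$cost_machine_acquisition else 0
  df <- discount_factor(yrs, sc$discount_rate_annual)

  ledger <- tibble::tibble(
    year = c(0L, yrs),
    testing_cost = c(0, testing_cost),
    acquisition_cost = c(acquisition, rep(0, sc$horizon_years)),
    reimbursement_revenue = c(0, reimbursement),
    visit_revenue = c(0, visit_revenue),
    discount = c(1, df)
  )
  ledger <- dplyr::mutate(
    ledger,
    cost = .data$testing_cost + .data$acquisition_cost,
    revenue = .data$reimbursement_revenue + .data$visit_revenue,
    cost_disc = .data$cost * .data$discount,
    revenue_disc = .data$revenue * .data$discount
  )

  totals <- tibble::tibble(
    scenario = attr(trace, "scenario"),
    testing_cost = sum(ledger$cost),
    testing_cost_disc = sum(ledger$cost_disc),
    revenue = sum(ledger$revenue),
    revenue_disc = sum(ledger$revenue_disc),
    mean_tat = alloc$mean_tat,
    pct_targeted = pct_on_targeted(trace),
    patients_lost = attr(trace, "lost_per_cohort") * sc$horizon_years
  )

  structure(
    list(scenario = attr(trace, "scenario"), scenario_params = sc,
         alloc = alloc, trace = trace, ledger = ledger, totals = totals),
    class = "bia_scenario")
}

#' Incremental ROI timeline of proposed vs current scenario
#'
#' ROI in year t is the incremental revenue minus the incremental cost of the
#' proposed scenario relative to the current one; the time-0 machine
#' acquisition is charged at the start. Payback is computed on the monthly
#' undiscounted incremental net stream (yearly flows spread uniformly across
#' their 12 months).
#'
#' @param current,proposed `bia_scenario` results over the same horizon.
#' @return a `bia_roi` list: `yearly` tibble (year, incremental cost/revenue
#'   and ROI, discounted and undiscounted), `cumulative_roi_disc`,
#'   `cumulative_roi_undisc`, `monthly` tibble of the cumulative monthly net
#'   stream, and `payback_months` (`Inf` when break-even is beyond the
#'   horizon).
#' @export
roi_timeline <- function(current, proposed) {
  lc <- current$ledger
  lp <- proposed$ledger
  if (!identical(lc$year, lp$year))
    stop("ledgers cover different horizons", call. = FALSE)
  yearly <- tibble::tibble(
    year = lc$year,
    d_cost = lp$cost - lc$cost,
    d_revenue = lp$revenue - lc$revenue,
    d_cost_disc = lp$cost_disc - lc$cost_disc,
    d_revenue_disc = lp$revenue_disc - lc$revenue_disc
  )
  yearly$roi <- yearly$d_revenue - yearly$d_cost
  yearly$roi_disc <- yearly$d_revenue_disc - yearly$d_cost_disc

  horizon <- max(yearly$year)
  net0 <- yearly$roi[yearly$year == 0]
  per_month <- rep(yearly$roi[yearly$year > 0] / 12, each = 12)
  monthly <- tibble::tibble(
    month = 0:(12 * horizon),
    cumulative_net = cumsum(c(net0, per_month))
  )
  structure(
    list(yearly = yearly,
         cumulative_roi_disc = sum(yearly$roi_disc),
         cumulative_roi_undisc = sum(yearly$roi),
         monthly = monthly,
         payback_months = payback_period(monthly$cumulative_net)),
    class = "bia_roi")
}

#' Payback period from a cumulative monthly net stream
#'
#' First month at which the cumulative incremental net cash flow reaches zero,
#' linearly interpolated between months and rounded to whole months. The first
#' element of the stream is the month-0 position (after any upfront outlay).
#'
#' @param cumulative_monthly_net numeric vector of cumulative net cash at
#'   months `0, 1, 2, ...`.
#' @return payback in months, or `Inf` if break-even is beyond the horizon.
#' @examples
#' payback_period(cumsum(c(-100, rep(10, 24)))) # 10 months
#' @export
payback_period <- function(cumulative_monthly_net) {
  x <- cumulative_monthly_net
  if (length(x) == 0) stop("empty cumulative stream", call. = FALSE)
  if (x[1] >= 0) return(0)
  idx <- which(x >= 0)[1]
  if (is.na(idx)) return(Inf)
  # months are 0-based: element idx is month idx - 1
  m_hi <- idx - 1
  frac <- x[idx - 1] / (x[idx - 1] - x[idx]) # in (0, 1]
  round(m_hi - 1 + frac)
}

#' Compare the proposed scenario against the current one
#'
#' Runs both scenarios end to end and assembles the headline results table:
#' testing cost, revenue, ROI, payback period, mean turnaround time,
#' percentage of patients on targeted therapy, and patients lost to second
#' opinion, for each scenario and their difference.
#'
#' @param params a validated [bia_parameters] object.
#' @return a `bia_comparison` list: `current` and `proposed`
#'   (`bia_scenario`), `roi` (`bia_roi`), and `summary` (tibble metric x
#'   current/proposed/difference).
#' @examples
#' \donttest{
#' cmp <- bia_compare(calibrated_parameters())
#' cmp$summary
#' }
#' @export
bia_compare <- function(params) {
  cur <- run_scenario(params, "current")
  prop <- run_scenario(params, "proposed")
  roi <- roi_timeline(cur, prop)
  s <- function(metric, a, b, d = b - a) {
    tibble::tibble(metric = metric, current = a, proposed = b, difference = d)
  }
  summary <- dplyr::bind_rows(
    s("testing_cost_disc", cur$totals$testing_cost_disc, prop$totals$testing_cost_disc),
    s("revenue_disc", cur$totals$revenue_disc, prop$totals$revenue_disc),
    s("roi_disc", NA_real_, roi$cumulative_roi_disc, NA_real_),
    s("roi_undisc", NA_real_, roi$cumulative_roi_undisc, NA_real_),
    s("payback_months", NA_real_, roi$payback_months, NA_real_),
    s("mean_tat_days", cur$totals$mean_tat, prop$totals$mean_tat),
    s("pct_targeted", cur$totals$pct_targeted, prop$totals$pct_targeted),
    s("patients_lost", cur$totals$patients_lost, prop$totals$patients_lost)
  )
  structure(list(current = cur, proposed = prop, roi = roi, summary = summary),
            class = "bia_comparison")
}

#' @export
print.bia_scenario <- function(x, ...) {
  cat(sprintf("<bia_scenario: %s>\n", x$scenario))
  print(x$totals)
  invisible(x)
}

#' @export
print.bia_roi <- function(x, ...) {
  cat("<bia_roi>\n")
  cat(sprintf("  cumulative ROI: $%s discounted, $%s undiscounted\n",
              format(round(x$cumulative_roi_disc), big.mark = ","),
              format(round(x$cumulative_roi_undisc), big.mark = ",")))
  pb <- if (is.finite(x$payback_months)) paste0(x$payback_months, " months")
        else "beyond horizon"
  cat(sprintf("  payback period: %s\n", pb))
  invisible(x)
}

#' @export
print.bia_comparison <- function(x, ...) {
  cat("<bia_comparison>\n")
  print(x$summary, n = Inf)
  invisible(x)
}
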