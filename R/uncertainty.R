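#' Sensitivity analyses and calibration
#'
#' Probabilistic sensitivity analysis (parameter draws -> full pipeline),
#' one-way sensitivity analysis with tornado ranking, scenario sweeps over the
#' in-house proportion, the patient volume, and the single-gene comparator,
#' and a deterministic calibration ladder fitting the unpublished plumbing
#' parameters (retest multiplier, second-opinion probabilities, visits per
#' cycle) to published headline outputs.
#'
#' @name uncertainty
NULL

#' Default calibration ladder
#'
#' Four univariate steps, each pairing one free parameter with the published
#' observable it dominates; later steps hold earlier fits fixed:
#' 1. `money.retest_multiplier` (bounds 1.000-1.010) vs the current-scenario
#'    5-year discounted testing cost, $680,080;
#' 2. `gaps.p_second_opinion_sendout` vs 173 patients lost (current);
#' 3. `gaps.p_second_opinion_inhouse` vs 64 patients lost (proposed);
#' 4. `money.visits_per_cycle` vs the current-scenario discounted revenue,
#'    $11,741,432.
#'
#' @return tibble with columns `parameter`, `lower`, `upper`, `observable`,
#'   `target`, `weight`.
#' @export
default_calibration_spec <- function() {
  tibble::tribble(
    ~parameter, ~lower, ~upper, ~observable, ~target, ~weight,
    "money.retest_multiplier", 1.000, 1.010, "testing_cost_current_disc", 680080, 1,
    "gaps.p_second_opinion_sendout", 0, 0.5, "patients_lost_current", 173, 1,
    "gaps.p_second_opinion_inhouse", 0, 0.5, "patients_lost_proposed", 64, 1,
    "money.visits_per_cycle", 0.05, 10, "revenue_current_disc", 11741432, 1
  )
}

# evaluate a named calibration observable from the pipeline
observable_value <- function(params, name) {
  switch(
    name,
    testing_cost_current_disc = {
      sc <- params$scenario_current
      alloc <- pathway_distribution(params, "current")
      unit <- alloc$tests_inhouse * params$money$cost_inhouse_test +
        alloc$tests_sendout * params$money$cost_sendout_test +
        alloc$tests_singlegene * params$money$cost_singlegene_test
      acq <- if (sc$frac_inhouse > 0) params$money$cost_machine_acquisition else 0
      acq + sc$patients_per_year * unit *
        sum(discount_factor(seq_len(sc$horizon_years), sc$discount_rate_annual))
    },
    patients_lost_current = {
      sc <- params$scenario_current
      second_opinion_loss(params, "current", sc$patients_per_year) * sc$horizon_years
    },
    patients_lost_proposed = {
      sc <- params$scenario_proposed
      second_opinion_loss(params, "proposed", sc$patients_per_year) * sc$horizon_years
    },
    revenue_current_disc = run_scenario(params, "current")$totals$revenue_disc,
    stop("unknown calibration observable: ", name, call. = FALSE)
  )
}

# deterministic univariate fit: coarse grid then bisection on the residual
# (all default observables are monotone in their paired parameter)
fit_univariate <- function(params, path, lower, upper, observable, target,
                           grid_n = 21, tol = 1e-10, max_iter = 80) {
  f <- function(x) {
    p_x <- apply_parameter_values(params, stats::setNames(list(x), path))
    observable_value(p_x, observable) - target
  }
  xs <- seq(lower, upper, length.out = grid_n)
  fs <- vapply(xs, f, numeric(1))
  sgn <- which(fs[-1] * fs[-grid_n] <= 0)
  if (length(sgn) == 0) {
    # target unreachable within bounds: clip to the closest bound/grid point
    best <- xs[which.min(abs(fs))]
    return(list(value = best, residual = fs[which.min(abs(fs))]))
  }
  lo <- xs[sgn[1]]; hi <- xs[sgn[1] + 1]
  flo <- fs[sgn[1]]
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fmid <- f(mid)
    if (abs(fmid) < tol || (hi - lo) < tol) break
    if (flo * fmid <= 0) hi <- mid else { lo <- mid; flo <- fmid }
  }
  list(value = mid, residual = fmid)
}

#' Calibrate unpublished parameters to published outputs
#'
#' Runs the calibration ladder (see [default_calibration_spec()]): each step
#' fits one parameter to one published target by a deterministic grid +
#' bisection search, holding earlier fits fixed. Residuals above `tol_rel`
#' are flagged in the report (a warning column, not an error). Uncertainty
#' ranges of fitted parameters are refreshed to +/-10% around the fitted
#' value so that ranges keep bracketing their points.
#'
#' @param params starting [bia_parameters] (default base case).
#' @param spec calibration ladder tibble.
#' @param tol_rel relative residual above which a step is flagged.
#' @return a `bia_calibration` list: `parameters` (fitted set) and `report`
#'   (tibble: parameter, fitted, observable, target, achieved, residual,
#'   rel_residual, within_tol).
#' @examples
#' \donttest{
#' fit <- calibrate(default_parameters())
#' fit$report
#' }
#' @export
calibrate <- function(params = default_parameters(), spec = default_calibration_spec(),
                      tol_rel = 0.01) {
  assert_valid_parameters(params)
  rows <- list()
  for (i in seq_len(nrow(spec))) {
    r <- spec[i, ]
    fit <- fit_univariate(params, r$parameter, r$lower, r$upper, r$observable, r$target)
    params <- apply_parameter_values(params, stats::setNames(list(fit$value), r$parameter))
    achieved <- fit$residual + r$target
    rows[[i]] <- tibble::tibble(
      parameter = r$parameter, fitted = fit$value, observable = r$observable,
      target = r$target, achieved = achieved, residual = fit$residual,
      rel_residual = abs(fit$residual) / max(abs(r$target), 1),
      within_tol = abs(fit$residual) / max(abs(r$target), 1) <= tol_rel
    )
  }
  # refresh +/-10% ranges around fitted values so they bracket the point
  unc <- params$uncertainty
  for (i in seq_len(nrow(spec))) {
    j <- which(unc$parameter == spec$parameter[i])
    if (length(j) == 1) {
      v <- param_get(params, spec$parameter[i])
      unc$low[j] <- 0.9 * v
      unc$high[j] <- 1.1 * v
    }
  }
  params$uncertainty <- unc
  structure(list(parameters = params, report = dplyr::bind_rows(rows)),
            class = "bia_calibration")
}

#' Base-case parameters after calibration
#'
#' Convenience wrapper: `calibrate(default_parameters())$parameters`.
#'
#' @inheritParams calibrate
#' @return fitted [bia_parameters].
#' @export
calibrated_parameters <- function(spec = default_calibration_spec()) {
  calibrate(default_parameters(), spec)$parameters
}

# ---- PSA ------------------------------------------------------------------

# moment-matched draws for one uncertainty row
draw_parameter <- function(n, point, low, high, dist) {
  sd <- (high - low) / (2 * stats::qnorm(0.975))
  if (sd <= 0) return(rep(point, n))
  switch(
    dist,
    beta = {
      mu <- point
      if (mu <= 0 || mu >= 1) return(rep(point, n))
      v <- min(sd^2, 0.9 * mu * (1 - mu))
      nu <- mu * (1 - mu) / v - 1
      stats::rbeta(n, mu * nu, (1 - mu) * nu)
    },
    gamma = {
      shape <- (point / sd)^2
      stats::rgamma(n, shape = shape, rate = shape / point)
    },
    uniform = stats::runif(n, low, high),
    stop("unknown distribution: ", dist, call. = FALSE)
  )
}

#' Probabilistic sensitivity analysis
#'
#' Draws every PSA-eligible uncertain parameter independently (Beta for
#' probabilities, Gamma for monetary values, Uniform for turnaround times;
#' all moment-matched so the published range spans ~95% of the mass around
#' the point estimate), re-runs the full pipeline for both scenarios per
#' draw, and records outcome differences. Calibrated plumbing constants stay
#' fixed at their fitted values. Reproducible bit-for-bit given a seed.
#'
#' @param params a calibrated [bia_parameters] object.
#' @param n_draws number of simulations (>= 2).
#' @param seed integer RNG seed.
#' @return a `bia_psa` list: `draws` (tibble: draw, roi_disc, roi_undisc,
#'   payback_months, tat_reduction_days, pct_targeted_diff), `param_draws`
#'   (tibble of sampled parameter values), `summaries` (median and 2.5/97.5
#'   percentiles per outcome), `seed`, `n_draws`.
#' @export
run_psa <- function(params, n_draws = 1000, seed = 1L) {
  assert_valid_parameters(params)
  if (n_draws < 2) stop("n_draws must be >= 2", call. = FALSE)
  unc <- dplyr::filter(params$uncertainty, .data$in_psa)

  set.seed(seed)
  param_draws <- purrr::map(seq_len(nrow(unc)), function(j) {
    r <- unc[j, ]
    draw_parameter(n_draws, uncertainty_point(params, r$parameter),
                   r$low, r$high, r$dist)
  })
  names(param_draws) <- unc$parameter
  param_draws <- tibble::as_tibble(param_draws)

  one_draw <- function(i) {
    p_i <- apply_parameter_values(params, as.list(param_draws[i, ]))
    cmp <- bia_compare(p_i)
    tibble::tibble(
      draw = i,
      roi_disc = cmp$roi$cumulative_roi_disc,
      roi_undisc = cmp$roi$cumulative_roi_undisc,
      payback_months = cmp$roi$payback_months,
      tat_reduction_days = cmp$current$totals$mean_tat - cmp$proposed$totals$mean_tat,
      pct_targeted_diff = cmp$proposed$totals$pct_targeted - cmp$current$totals$pct_targeted
    )
  }
  draws <- dplyr::bind_rows(purrr::map(seq_len(n_draws), one_draw))
  structure(list(draws = draws, param_draws = param_draws,
                 summaries = psa_summaries(draws), seed = seed, n_draws = n_draws),
            class = "bia_psa")
}

# median and 95% percentile interval (linear interpolation between order stats)
psa_summaries <- function(draws) {
  outcomes <- setdiff(names(draws), "draw")
  purrr::map_dfr(outcomes, function(o) {
    x <- draws[[o]]
    q <- stats::quantile(x[is.finite(x)], c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    tibble::tibble(outcome = o, median = q[2], lo95 = q[1], hi95 = q[3])
  })
}

# ---- one-way sensitivity analysis -----------------------------------------

#' One-way sensitivity analysis (tornado)
#'
#' Sets each uncertain parameter to its low then high bound, all else at base
#' case, re-runs the pipeline, and ranks parameters by the absolute span of
#' the outcome (ties broken alphabetically).
#'
#' @param params a calibrated [bia_parameters] object.
#' @param outcome `"roi"` (discounted cumulative ROI) or `"payback"` (months).
#' @return a `bia_tornado` tibble: `parameter`, `low`, `high`,
#'   `outcome_at_low`, `outcome_at_high`, `span`, `rank`, plus attributes
#'   `outcome` and `base_value`.
#' @export
one_way_sa <- function(params, outcome = c("roi", "payback")) {
  assert_valid_parameters(params)
  outcome <- match.arg(outcome)
  eval_outcome <- function(p) {
    cmp <- bia_compare(p)
    if (outcome == "roi") cmp$roi$cumulative_roi_disc else cmp$roi$payback_months
  }
  unc <- params$uncertainty
  rows <- purrr::map_dfr(seq_len(nrow(unc)), function(j) {
    r <- unc[j, ]
    at_low <- eval_outcome(apply_parameter_values(params, stats::setNames(list(r$low), r$parameter)))
    at_high <- eval_outcome(apply_parameter_values(params, stats::setNames(list(r$high), r$parameter)))
    tibble::tibble(parameter = r$parameter, low = r$low, high = r$high,
                   outcome_at_low = at_low, outcome_at_high = at_high,
                   span = abs(at_high - at_low))
  })
  rows <- dplyr::arrange(rows, dplyr::desc(.data$span), .data$parameter)
  rows$rank <- seq_len(nrow(rows))
  attr(rows, "outcome") <- outcome
  attr(rows, "base_value") <- eval_outcome(params)
  class(rows) <- c("bia_tornado", class(rows))
  rows
}

# ---- scenario sweeps ------------------------------------------------------

#' Scenario sweeps
#'
#' Re-runs the pipeline over a grid of one structural setting:
#' * `inhouse_pct` - the proposed scenario's in-house testing percentage;
#' * `patient_volume` - annual metastatic NSCLC patients (both scenarios);
#' * `single_gene_comparator` - the current scenario uses single-gene testing
#'   instead of send-out NGS (single row; `grid` ignored).
#'
#' @param params a calibrated [bia_parameters] object.
#' @param axis sweep axis.
#' @param grid settings to evaluate (defaults: 0-100% by 5 for `inhouse_pct`;
#'   50, 100, 200, ..., 800 for `patient_volume`).
#' @return a `bia_sweep` tibble: `axis`, `setting`, `roi_disc`, `roi_undisc`,
#'   `payback_months`.
#' @export
scenario_sweep <- function(params,
                           axis = c("inhouse_pct", "patient_volume", "single_gene_comparator"),
                           grid = NULL) {
  assert_valid_parameters(params)
  axis <- match.arg(axis)
  grid <- grid %||% switch(axis,
    inhouse_pct = seq(0, 100, by = 5),
    patient_volume = c(50, seq(100, 800, by = 100)),
    single_gene_comparator = NA_real_)

  run_one <- function(g) {
    p <- params
    if (axis == "inhouse_pct") {
      if (g < 0 || g > 100) stop("inhouse_pct grid values must lie in [0, 100]", call. = FALSE)
      p <- apply_parameter_values(p, list("scenario_proposed.frac_inhouse" = g / 100))
    } else if (axis == "patient_volume") {
      if (g < 0) stop("patient_volume grid values must be nonnegative", call. = FALSE)
      p$scenario_current$patients_per_year <- g
      p$scenario_proposed$patients_per_year <- g
    } else {
      p$scenario_current$comparator_mode <- "single_gene"
    }
    cmp <- bia_compare(p)
    tibble::tibble(axis = axis, setting = g,
                   roi_disc = cmp$roi$cumulative_roi_disc,
                   roi_undisc = cmp$roi$cumulative_roi_undisc,
                   payback_months = cmp$roi$payback_months)
  }
  out <- dplyr::bind_rows(purrr::map(sort(grid, na.last = TRUE), run_one))
  class(out) <- c("bia_sweep", class(out))
  out
}

#' @export
print.bia_psa <- function(x, ...) {
  cat(sprintf("<bia_psa: %d draws, seed %d>\n", x$n_draws, x$seed))
  print(x$summaries)
  invisible(x)
}

#' @export
print.bia_calibration <- function(x, ...) {
  cat("<bia_calibration>\n")
  print(x$report)
  invisible(x)
}
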