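#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Broom-style tidiers for model result objects
#'
#' `tidy()` returns the per-unit table of a result (PSA outcome summaries,
#' tornado rows, calibration report, yearly ROI ledger, long parameter table);
#' `glance()` returns a one-row summary.
#'
#' @param x a result object.
#' @param ... unused.
#' @return a tibble.
#' @name tidy.bia_psa
NULL

#' @rdname tidy.bia_psa
#' @export
tidy.bia_psa <- function(x, ...) x$summaries

#' @rdname tidy.bia_psa
#' @export
glance.bia_psa <- function(x, ...) {
  roi <- x$summaries[x$summaries$outcome == "roi_disc", ]
  tibble::tibble(n_draws = x$n_draws, seed = x$seed,
                 roi_median = roi$median, roi_lo95 = roi$lo95, roi_hi95 = roi$hi95)
}

#' @rdname tidy.bia_psa
#' @export
tidy.bia_tornado <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.bia_psa
#' @export
tidy.bia_calibration <- function(x, ...) x$report

#' @rdname tidy.bia_psa
#' @export
glance.bia_calibration <- function(x, ...) {
  tibble::tibble(n_fitted = nrow(x$report),
                 max_rel_residual = max(x$report$rel_residual),
                 all_within_tol = all(x$report$within_tol))
}

#' @rdname tidy.bia_psa
#' @export
tidy.bia_roi <- function(x, ...) x$yearly

#' @rdname tidy.bia_psa
#' @export
glance.bia_roi <- function(x, ...) {
  tibble::tibble(roi_disc = x$cumulative_roi_disc,
                 roi_undisc = x$cumulative_roi_undisc,
                 payback_months = x$payback_months)
}

#' @rdname tidy.bia_psa
#' @export
tidy.bia_comparison <- function(x, ...) x$summary

#' @rdname tidy.bia_psa
#' @export
glance.bia_comparison <- function(x, ...) {
  tibble::tibble(
    roi_disc = x$roi$cumulative_roi_disc,
    roi_undisc = x$roi$cumulative_roi_undisc,
    payback_months = x$roi$payback_months,
    tat_reduction_days = x$current$totals$mean_tat - x$proposed$totals$mean_tat,
    pct_targeted_diff = x$proposed$totals$pct_targeted - x$current$totals$pct_targeted,
    patients_retained = x$current$totals$patients_lost - x$proposed$totals$patients_lost
  )
}

#' @rdname tidy.bia_psa
#' @export
tidy.bia_scenario <- function(x, ...) x$ledger

#' @rdname tidy.bia_psa
#' @export
glance.bia_scenario <- function(x, ...) x$totals
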