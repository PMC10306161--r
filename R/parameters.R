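#' Model parameter sets
#'
#' A `bia_parameters` object is a validated nested list holding every input of
#' the budget-impact model, mirroring the YAML config schema:
#'
#' * `testing` — sample-type mix and per-sample-type probabilities of an
#'   insufficient sample, a failed test, and an actionable mutation.
#' * `splits` — therapy-assignment probabilities at the decision-tree nodes
#'   (nontargeted mix, direct-targeted vs interim, interim-to-targeted switch).
#' * `money` — unit costs and revenues (2021 USD) plus the retest multiplier
#'   and hospital visits per 30-day cycle.
#' * `tat` — turnaround times in days (send-out range, in-house point).
#' * `clinical` — 1-year progression-free and overall survival by therapy and
#'   the 3-month progression/next-line probabilities.
#' * `scenario_current`, `scenario_proposed` — horizon, discount rate, annual
#'   volume, testing-arm mix, comparator mode.
#' * `gaps` — quantities the model needs but the published tables do not
#'   print: arm-specific second-opinion probabilities, the interim turnaround
#'   scaling toggle, calendar conventions, the single-gene panel size.
#' * `uncertainty` — a tibble of (parameter path, low, high, dist, in_psa)
#'   ranges driving the probabilistic and one-way sensitivity analyses.
#'
#' @name bia_parameters
NULL

new_bia_parameters <- function(x) {
  structure(x, class = c("bia_parameters", "list"))
}

#' Base-case model parameters
#'
#' Returns the complete published base case: a hospital managing 500
#' metastatic NSCLC patients per year over a 5-year horizon at a 3.5% annual
#' discount rate, comparing exclusively send-out NGS (current scenario) with a
#' 75/25 in-house/send-out mix (proposed scenario).
#'
#' Second-opinion probabilities, the retest multiplier, and visits per cycle
#' are plumbing parameters the publication uses implicitly; their defaults
#' here are pre-calibration values (see [calibrate()]).
#'
#' @return a [bia_parameters] object.
#' @examples
#' p <- default_parameters()
#' p$testing$frac_tissue
#' @export
default_parameters <- function() {
  p <- list(
    testing = list(
      frac_tissue = 0.60,
      frac_blood = 0.40,
      p_insufficient_tissue = 0.05,
      p_insufficient_blood = 0.003,
      p_fail_tissue = 0.012,
      p_fail_blood = 0.005,
      p_actionable_tissue = 0.23,
      p_actionable_blood = 0.24
    ),
    splits = list(
      p_immuno_nontargeted = 0.25,
      p_chemo_nontargeted = 0.29,
      p_chemoimmuno_nontargeted = 0.36,
      p_direct_targeted = 0.73,
      p_interim = 0.27,
      p_interim_switch = 0.34
    ),
    money = list(
      cost_inhouse_test = 600,
      cost_sendout_test = 300,
      cost_singlegene_test = 141,
      cost_machine_acquisition = 200000,
      reimb_inhouse_test = 580,
      revenue_hospital_visit = 124,
      retest_multiplier = 1.0,
      visits_per_cycle = 1.0
    ),
    tat = list(
      tat_sendout_low = 10.32,
      tat_sendout_high = 27.80,
      tat_inhouse = 3
    ),
    clinical = list(
      pfs_1yr = list(chemo = 0.173, immuno = 0.279, chemo_immuno = 0.341, targeted = 0.40),
      os_1yr = list(chemo = 0.494, immuno = 0.673, chemo_immuno = 0.692, targeted = 0.86),
      # progression / next-line survival is unpublished; both default to the
      # chemotherapy 1-year OS (most conservative printed therapy).
      os_1yr_progression = 0.494,
      os_1yr_next_line = 0.494,
      p_prog_to_nextline_3mo = 0.48,
      p_nextline_to_prog_3mo = 0.50
    ),
    scenario_current = list(
      horizon_years = 5L,
      discount_rate_annual = 0.035,
      patients_per_year = 500,
      frac_inhouse = 0,
      frac_sendout = 1,
      comparator_mode = "sendout_ngs"
    ),
    scenario_proposed = list(
      horizon_years = 5L,
      discount_rate_annual = 0.035,
      patients_per_year = 500,
      frac_inhouse = 0.75,
      frac_sendout = 0.25,
      comparator_mode = "sendout_ngs"
    ),
    gaps = list(
      # residual mass at the nontargeted node: 1 - (0.25 + 0.29 + 0.36)
      p_second_opinion_sendout = 0.10,
      p_second_opinion_inhouse = 0.02,
      interim_tat_scaling = TRUE,
      cycle_days = 30,
      days_per_year = 365.25,
      genes_per_singlegene_panel = 5,
      reimburse_inhouse_only = TRUE
    )
  )
  p$uncertainty <- default_uncertainty(p)
  new_bia_parameters(p)
}

#' Default uncertainty ranges
#'
#' Builds the (low, high) range table for the sensitivity analyses: published
#' ranges are used verbatim (test costs, reimbursement, visit price, send-out
#' turnaround, survival confidence intervals); every other input gets a
#' symmetric +/-10% band. Probabilities sample from moment-matched Beta
#' distributions, monetary values from Gamma, and turnaround times from
#' Uniform. The proposed-scenario in-house proportion enters the one-way
#' analysis over the 0.50-1.00 adoption range but is excluded from PSA
#' (`in_psa = FALSE`): it is a structural setting, not a sampled input.
#'
#' @param p a parameter list (point values).
#' @return tibble with columns `parameter`, `low`, `high`, `dist`, `in_psa`.
#' @export
default_uncertainty <- function(p) {
  pm10 <- function(x) c(0.9 * x, 1.1 * x)
  row <- function(parameter, low, high, dist, in_psa = TRUE) {
    tibble::tibble(parameter = parameter, low = low, high = high,
                   dist = dist, in_psa = in_psa)
  }
  rows <- list(
    row("testing.frac_tissue", pm10(0.60)[1], pm10(0.60)[2], "beta"),
    row("testing.p_insufficient_tissue", 0.045, 0.055, "beta"),
    row("testing.p_insufficient_blood", 0.0027, 0.0033, "beta"),
    row("testing.p_fail_tissue", 0.0108, 0.0132, "beta"),
    row("testing.p_fail_blood", 0.0045, 0.0055, "beta"),
    row("testing.p_actionable_tissue", 0.207, 0.253, "beta"),
    row("testing.p_actionable_blood", 0.216, 0.264, "beta"),
    row("splits.p_immuno_nontargeted", 0.225, 0.275, "beta"),
    row("splits.p_chemo_nontargeted", 0.261, 0.319, "beta"),
    row("splits.p_chemoimmuno_nontargeted", 0.324, 0.396, "beta"),
    row("splits.p_interim", 0.243, 0.297, "beta"),
    row("splits.p_interim_switch", 0.306, 0.374, "beta"),
    row("money.cost_inhouse_test", 578, 908, "gamma"),
    row("money.cost_sendout_test", 270, 330, "gamma"),
    row("money.cost_singlegene_test", 126.9, 155.1, "gamma"),
    row("money.cost_machine_acquisition", 180000, 220000, "gamma"),
    row("money.reimb_inhouse_test", 522, 638, "gamma"),
    row("money.revenue_hospital_visit", 112, 136, "gamma"),
    row("tat.sendout_midpoint", 10.32, 27.80, "uniform"),
    row("tat.tat_inhouse", 2.7, 3.3, "uniform"),
    row("clinical.pfs_1yr.chemo", 0.120, 0.235, "beta"),
    row("clinical.pfs_1yr.immuno", 0.2511, 0.3069, "beta"),
    row("clinical.pfs_1yr.chemo_immuno", 0.288, 0.395, "beta"),
    row("clinical.pfs_1yr.targeted", 0.28, 0.52, "beta"),
    row("clinical.os_1yr.chemo", 0.421, 0.562, "beta"),
    row("clinical.os_1yr.immuno", 0.6057, 0.7403, "beta"),
    row("clinical.os_1yr.chemo_immuno", 0.641, 0.738, "beta"),
    row("clinical.os_1yr.targeted", 0.807, 0.899, "beta"),
    row("clinical.p_prog_to_nextline_3mo", 0.432, 0.528, "beta"),
    row("clinical.p_nextline_to_prog_3mo", 0.45, 0.55, "beta"),
    row("gaps.p_second_opinion_sendout",
        0.9 * p$gaps$p_second_opinion_sendout,
        1.1 * p$gaps$p_second_opinion_sendout, "beta"),
    row("gaps.p_second_opinion_inhouse",
        0.9 * p$gaps$p_second_opinion_inhouse,
        1.1 * p$gaps$p_second_opinion_inhouse, "beta"),
    row("scenario_proposed.frac_inhouse", 0.50, 1.00, "uniform", in_psa = FALSE)
  )
  dplyr::bind_rows(rows)
}

# point value for an uncertainty row (midpoint for the send-out TAT range)
uncertainty_point <- function(p, path) {
  if (path == "tat.sendout_midpoint") return(sendout_tat_midpoint(p))
  param_get(p, path)
}

#' Validate a parameter set
#'
#' Checks every schema invariant and returns the violations as data (an empty
#' tibble means the set is valid): probabilities within \[0, 1\], the
#' tissue/blood and in-house/send-out mixes summing to one, the nontargeted
#' therapy splits not exceeding unit mass, nonnegative monetary values, the
#' retest multiplier within \[1.0, 1.1\], ordered turnaround bounds, overall
#' survival at least progression-free survival for each therapy, and
#' uncertainty ranges bracketing their point estimates.
#'
#' @param params a [bia_parameters] object.
#' @param include_uncertainty also check that uncertainty ranges bracket their
#'   point estimates? The range table is advisory (it drives the sensitivity
#'   analyses), so run-time gates inside the pipeline skip this check: editing
#'   a point value without re-deriving its range must not block a model run.
#' @return tibble with columns `field` and `message`; zero rows iff valid.
#' @export
validate_parameters <- function(params, include_uncertainty = TRUE) {
  v <- list()
  bad <- function(field, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(field = field, message = message)
  }
  chk_prob <- function(field) {
    x <- param_get(params, field)
    if (!is.numeric(x) || is.na(x) || x < 0 || x > 1)
      bad(field, sprintf("must be a probability in [0, 1], got %s", format(x)))
  }
  probs <- c(
    "testing.frac_tissue", "testing.frac_blood",
    "testing.p_insufficient_tissue", "testing.p_insufficient_blood",
    "testing.p_fail_tissue", "testing.p_fail_blood",
    "testing.p_actionable_tissue", "testing.p_actionable_blood",
    "splits.p_immuno_nontargeted", "splits.p_chemo_nontargeted",
    "splits.p_chemoimmuno_nontargeted", "splits.p_direct_targeted",
    "splits.p_interim", "splits.p_interim_switch",
    "clinical.pfs_1yr.chemo", "clinical.pfs_1yr.immuno",
    "clinical.pfs_1yr.chemo_immuno", "clinical.pfs_1yr.targeted",
    "clinical.os_1yr.chemo", "clinical.os_1yr.immuno",
    "clinical.os_1yr.chemo_immuno", "clinical.os_1yr.targeted",
    "clinical.os_1yr_progression", "clinical.os_1yr_next_line",
    "clinical.p_prog_to_nextline_3mo", "clinical.p_nextline_to_prog_3mo",
    "scenario_current.frac_inhouse", "scenario_current.frac_sendout",
    "scenario_proposed.frac_inhouse", "scenario_proposed.frac_sendout",
    "gaps.p_second_opinion_sendout", "gaps.p_second_opinion_inhouse"
  )
  for (f in probs) chk_prob(f)

  if (abs(params$testing$frac_tissue + params$testing$frac_blood - 1) > 1e-9)
    bad("testing.frac_tissue", "frac_tissue + frac_blood must equal 1")
  s3 <- params$splits$p_immuno_nontargeted + params$splits$p_chemo_nontargeted +
    params$splits$p_chemoimmuno_nontargeted
  if (s3 > 1 + 1e-9)
    bad("splits.p_immuno_nontargeted",
        sprintf("nontargeted therapy splits sum to %.4f > 1", s3))
  if (abs(params$splits$p_direct_targeted + params$splits$p_interim - 1) > 1e-9)
    bad("splits.p_direct_targeted", "p_direct_targeted + p_interim must equal 1")

  for (f in c("money.cost_inhouse_test", "money.cost_sendout_test",
              "money.cost_singlegene_test", "money.cost_machine_acquisition",
              "money.reimb_inhouse_test", "money.revenue_hospital_visit",
              "money.visits_per_cycle")) {
    x <- param_get(params, f)
    if (!is.numeric(x) || is.na(x) || x < 0) bad(f, "must be nonnegative")
  }
  rm_ <- params$money$retest_multiplier
  if (!is.numeric(rm_) || is.na(rm_) || rm_ < 1 || rm_ > 1.1)
    bad("money.retest_multiplier", "must lie in [1.0, 1.1]")

  if (params$tat$tat_sendout_low > params$tat$tat_sendout_high)
    bad("tat.tat_sendout_low", "send-out turnaround low bound exceeds high bound")
  for (f in c("tat.tat_sendout_low", "tat.tat_sendout_high", "tat.tat_inhouse"))
    if (param_get(params, f) < 0) bad(f, "turnaround times must be nonnegative")

  for (th in c("chemo", "immuno", "chemo_immuno", "targeted")) {
    pfs <- params$clinical$pfs_1yr[[th]]
    os <- params$clinical$os_1yr[[th]]
    if (is.numeric(pfs) && is.numeric(os) && os < pfs - 1e-12)
      bad(paste0("clinical.os_1yr.", th),
          sprintf("1-year OS (%.3f) below 1-year PFS (%.3f)", os, pfs))
  }

  for (sc in c("scenario_current", "scenario_proposed")) {
    s <- params[[sc]]
    if (abs(s$frac_inhouse + s$frac_sendout - 1) > 1e-9)
      bad(paste0(sc, ".frac_inhouse"), "frac_inhouse + frac_sendout must equal 1")
    if (s$horizon_years < 1) bad(paste0(sc, ".horizon_years"), "must be >= 1")
    if (s$patients_per_year < 0) bad(paste0(sc, ".patients_per_year"), "must be >= 0")
    if (!s$comparator_mode %in% c("sendout_ngs", "single_gene"))
      bad(paste0(sc, ".comparator_mode"),
          "must be one of 'sendout_ngs', 'single_gene'")
  }
  if (params$gaps$cycle_days <= 0) bad("gaps.cycle_days", "must be positive")
  if (params$gaps$days_per_year <= 0) bad("gaps.days_per_year", "must be positive")
  if (params$gaps$genes_per_singlegene_panel < 1)
    bad("gaps.genes_per_singlegene_panel", "must be >= 1")

  if (include_uncertainty && !is.null(params$uncertainty) && nrow(params$uncertainty) > 0) {
    for (i in seq_len(nrow(params$uncertainty))) {
      r <- params$uncertainty[i, ]
      pt <- tryCatch(uncertainty_point(params, r$parameter), error = function(e) NA)
      if (is.na(pt)) {
        bad(r$parameter, "uncertainty row refers to unknown parameter")
      } else if (pt < r$low - 1e-9 || pt > r$high + 1e-9) {
        bad(r$parameter,
            sprintf("uncertainty range (%.4g, %.4g) does not bracket point %.4g",
                    r$low, r$high, pt))
      }
    }
  }
  if (length(v) == 0)
    return(tibble::tibble(field = character(), message = character()))
  dplyr::bind_rows(v)
}

# stop() with a readable message if invalid
assert_valid_parameters <- function(params) {
  rep <- validate_parameters(params, include_uncertainty = FALSE)
  if (nrow(rep) > 0) {
    stop("invalid model parameters:\n",
         paste0("  - ", rep$field, ": ", rep$message, collapse = "\n"),
         call. = FALSE)
  }
  invisible(params)
}

#' Write a parameter set to a YAML config file
#'
#' The serialization is canonical (15 significant digits, uncertainty table as
#' a list of rows) so that `write_parameters(load_parameters(f), g)` is
#' bit-for-bit identical to the original file produced by this writer.
#'
#' @param params a [bia_parameters] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  x <- unclass(params)
  if (!is.null(x$uncertainty)) {
    x$uncertainty <- purrr::pmap(x$uncertainty, function(parameter, low, high, dist, in_psa) {
      list(parameter = parameter, low = low, high = high, dist = dist, in_psa = in_psa)
    })
  }
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Load a parameter set from a YAML config file
#'
#' Fields absent from the file fall back to [default_parameters()]. Complement
#' fields may be omitted: setting only `testing.frac_tissue` auto-complements
#' `frac_blood` (and analogously `frac_sendout` from `frac_inhouse`, and
#' `splits.p_direct_targeted` from `p_interim`). The merged set is validated;
#' violations raise an error naming the offending field.
#'
#' @param path config file path.
#' @param base parameter set supplying defaults for unspecified fields.
#' @return a validated [bia_parameters] object.
#' @export
load_parameters <- function(path, base = default_parameters()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop("config file does not parse to a mapping: ", path, call. = FALSE)

  p <- unclass(base)
  unc <- p$uncertainty
  if (!is.null(user$uncertainty)) {
    unc <- dplyr::bind_rows(lapply(user$uncertainty, tibble::as_tibble))
    unc$in_psa <- as.logical(unc$in_psa)
  }
  user$uncertainty <- NULL
  p$uncertainty <- NULL
  p <- utils::modifyList(p, user, keep.null = FALSE)

  # auto-complement pairs the user specified only half of
  compl <- function(grp, a, b) {
    ua <- !is.null(user[[grp]][[a]]); ub <- !is.null(user[[grp]][[b]])
    if (ua && !ub) p[[grp]][[b]] <<- 1 - p[[grp]][[a]]
    if (ub && !ua) p[[grp]][[a]] <<- 1 - p[[grp]][[b]]
  }
  compl("testing", "frac_tissue", "frac_blood")
  compl("splits", "p_interim", "p_direct_targeted")
  compl("scenario_current", "frac_inhouse", "frac_sendout")
  compl("scenario_proposed", "frac_inhouse", "frac_sendout")

  p$uncertainty <- unc
  p <- new_bia_parameters(p)
  assert_valid_parameters(p)
  p
}

#' @export
print.bia_parameters <- function(x, ...) {
  cat("<bia_parameters>\n")
  cat(sprintf("  horizon: %d years, %d patients/year, discount %.1f%%\n",
              x$scenario_proposed$horizon_years,
              x$scenario_proposed$patients_per_year,
              100 * x$scenario_proposed$discount_rate_annual))
  cat(sprintf("  current: %.0f%% in-house / %.0f%% %s\n",
              100 * x$scenario_current$frac_inhouse,
              100 * x$scenario_current$frac_sendout,
              x$scenario_current$comparator_mode))
  cat(sprintf("  proposed: %.0f%% in-house / %.0f%% send-out\n",
              100 * x$scenario_proposed$frac_inhouse,
              100 * x$scenario_proposed$frac_sendout))
  cat(sprintf("  uncertainty ranges: %d\n", nrow(x$uncertainty)))
  invisible(x)
}

#' @rdname tidy.bia_psa
#' @export
tidy.bia_parameters <- function(x, ...) {
  flat <- function(lst, prefix = character()) {
    out <- list()
    for (nm in names(lst)) {
      val <- lst[[nm]]
      key <- c(prefix, nm)
      if (is.list(val)) {
        out <- c(out, flat(val, key))
      } else if (is.numeric(val) || is.logical(val)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          parameter = paste(key, collapse = "."), value = as.numeric(val))
      }
    }
    out
  }
  x2 <- unclass(x)
  x2$uncertainty <- NULL
  dplyr::bind_rows(flat(x2))
}
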