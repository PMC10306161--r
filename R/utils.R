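#' @importFrom rlang %||%
#' @keywords internal
NULL

#' Get a parameter by dotted path
#'
#' Parameter sets are nested lists; many routines (PSA draws, tornado rows,
#' calibration) address individual values by a dotted path such as
#' `"money.cost_inhouse_test"` or `"clinical.pfs_1yr.targeted"`.
#'
#' @param params a [bia_parameters] object (or plain nested list).
#' @param path dotted path string.
#' @return the value stored at `path`.
#' @export
param_get <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  out <- params
  for (k in keys) {
    if (is.null(out[[k]])) stop("unknown parameter path: ", path, call. = FALSE)
    out <- out[[k]]
  }
  out
}

#' Set a parameter by dotted path
#'
#' @inheritParams param_get
#' @param value replacement value.
#' @return the modified parameter object (invariant complements such as
#'   `frac_blood = 1 - frac_tissue` are *not* re-derived here; see
#'   [apply_parameter_values()]).
#' @export
param_set <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(x, keys) {
    if (length(keys) == 1L) {
      x[[keys]] <- value
      return(x)
    }
    if (is.null(x[[keys[1L]]])) stop("unknown parameter path: ", path, call. = FALSE)
    x[[keys[1L]]] <- rec(x[[keys[1L]]], keys[-1L])
    x
  }
  rec(params, keys)
}

#' Set several parameters and restore complement invariants
#'
#' Applies a named vector/list of dotted-path values to a parameter set and
#' then re-derives the complements that the schema keeps in lockstep:
#' `testing.frac_blood = 1 - testing.frac_tissue`, each scenario's
#' `frac_sendout = 1 - frac_inhouse`, and
#' `splits.p_direct_targeted = 1 - splits.p_interim`. The special path
#' `tat.sendout_midpoint` collapses the send-out turnaround range onto a
#' single drawn value.
#'
#' @inheritParams param_get
#' @param values named list or vector; names are dotted paths.
#' @return modified parameter set.
#' @export
apply_parameter_values <- function(params, values) {
  nm <- names(values)
  for (i in seq_along(values)) {
    if (nm[i] == "tat.sendout_midpoint") {
      params$tat$tat_sendout_low <- as.numeric(values[[i]])
      params$tat$tat_sendout_high <- as.numeric(values[[i]])
    } else {
      params <- param_set(params, nm[i], as.numeric(values[[i]]))
    }
  }
  params$testing$frac_blood <- 1 - params$testing$frac_tissue
  params$splits$p_direct_targeted <- 1 - params$splits$p_interim
  params$scenario_current$frac_sendout <- 1 - params$scenario_current$frac_inhouse
  params$scenario_proposed$frac_sendout <- 1 - params$scenario_proposed$frac_inhouse
  # stretch uncertainty ranges so they keep bracketing the applied values
  # (tail draws from Gamma/Beta can fall outside the published range)
  if (!is.null(params$uncertainty) && length(values) > 0) {
    u <- params$uncertainty
    hit <- which(u$parameter %in% nm)
    for (j in hit) {
      pt <- uncertainty_point(params, u$parameter[j])
      u$low[j] <- min(u$low[j], pt)
      u$high[j] <- max(u$high[j], pt)
    }
    params$uncertainty <- u
  }
  params
}

# Resolve a scenario argument ("current"/"proposed" or a scenario list).
resolve_scenario <- function(params, scenario) {
  if (is.character(scenario)) {
    scenario <- match.arg(scenario, c("current", "proposed"))
    return(params[[paste0("scenario_", scenario)]])
  }
  stopifnot(is.list(scenario))
  scenario
}

# Midpoint of the send-out turnaround range (point estimate used throughout).
sendout_tat_midpoint <- function(params) {
  (params$tat$tat_sendout_low + params$tat$tat_sendout_high) / 2
}
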