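# shared fixtures, built once per test run

# calibrated base case (calibration is deterministic; cache it)
.fixture_env <- new.env(parent = emptyenv())

calibrated_fixture <- function() {
  if (is.null(.fixture_env$calibrated)) {
    .fixture_env$calibrated <- calibrate(default_parameters())
  }
  .fixture_env$calibrated
}

calibrated_params <- function() calibrated_fixture()$parameters

# a parameter set with no stochastic events: everyone survives, nothing
# progresses, nobody is lost; useful for degenerate-path checks
immortal_params <- function() {
  p <- default_parameters()
  for (th in c("chemo", "immuno", "chemo_immuno", "targeted")) {
    p$clinical$pfs_1yr[[th]] <- 1
    p$clinical$os_1yr[[th]] <- 1
  }
  p$clinical$os_1yr_progression <- 1
  p$clinical$os_1yr_next_line <- 1
  p$clinical$p_prog_to_nextline_3mo <- 0
  p$clinical$p_nextline_to_prog_3mo <- 0
  p$gaps$p_second_opinion_sendout <- 0
  p$gaps$p_second_opinion_inhouse <- 0
  # no interim entry: the interim state empties after one cycle by design,
  # so a truly static cohort must enter therapies directly
  p$splits$p_interim <- 0
  p$splits$p_direct_targeted <- 1
  p
}
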