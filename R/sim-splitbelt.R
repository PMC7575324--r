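#' Generate a synthetic split-belt adaptation series
#'
#' Produces per-trial asymmetry values (fast - slow) following the
#' classic single-rate exponential picture of split-belt adaptation:
#' baseline trials fluctuate around zero; the first split trial imposes
#' `initial_error`, which then decays by a fraction `learning_rate` on
#' every subsequent split trial; on return to tied belts an aftereffect of
#' opposite sign appears, equal to `retention` times the amount adapted,
#' and washes out at the same per-trial rate.
#'
#' With `n` split trials and rate `r`, the noise-free split-phase value at
#' split trial `i` is `initial_error * (1 - r)^(i-1)`, so the change over
#' the split period (last minus first split trial) is
#' `initial_error * ((1 - r)^(n-1) - 1)`.
#'
#' @param config A [splitbelt_sim_config()].
#' @return An `adaptation_series` data frame: the protocol columns plus
#'   `asymmetry`.
#' @examples
#' cfg <- splitbelt_sim_config(noise_sd = 0, seed = 42)
#' s <- gen_splitbelt_series(cfg)
#' phase_metrics(s)
#' @export
gen_splitbelt_series <- function(config) {
  if (!inherits(config, "splitbelt_sim_config"))
    stopf("`config` must be a splitbelt_sim_config")
  proto <- config$protocol
  r <- config$learning_rate
  n_split <- sum(proto$phase == "split")
  if (n_split == 0L) stopf("protocol has no split trials")
  clean <- numeric(nrow(proto))
  split_idx <- which(proto$phase == "split")
  clean[split_idx] <- config$initial_error * (1 - r)^(seq_len(n_split) - 1)
  adapted <- config$initial_error * (1 - (1 - r)^(n_split - 1))
  wash_idx <- which(proto$phase == "washout")
  if (length(wash_idx))
    clean[wash_idx] <- -adapted * config$retention *
      (1 - r)^(seq_along(wash_idx) - 1)
  set.seed(config$seed)
  out <- as.data.frame(proto)
  out$asymmetry <- clean + rnorm(nrow(proto), 0, config$noise_sd)
  class(out) <- c("adaptation_series", "data.frame")
  out
}

#' Closed-form phase metrics implied by a split-belt simulation config
#'
#' Noise-free expectations of the [phase_metrics()] of a series generated
#' by [gen_splitbelt_series()]; used for parameter-recovery checks.
#'
#' @param config A [splitbelt_sim_config()].
#' @return A list with `initial_error`, `change_over_split`, `aftereffect`.
#' @export
splitbelt_expected_metrics <- function(config) {
  n_split <- sum(config$protocol$phase == "split")
  r <- config$learning_rate
  adapted <- config$initial_error * (1 - (1 - r)^(n_split - 1))
  list(initial_error = config$initial_error,
       change_over_split = config$initial_error * ((1 - r)^(n_split - 1) - 1),
       aftereffect = -adapted * config$retention)
}
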