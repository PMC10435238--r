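# Reference measurements of the model's headline quantities. Each function
# sets up the corresponding experiment from scratch (conditions, protocol),
# runs the model and extracts the measured number. The test suite and
# scripts/acceptance.R both consume these, so the measurement conventions
# (fit windows, sample counts) are defined in exactly one place.

#' Headline model measurements
#'
#' @name measurements
#' @details All fits use [fit_decay()] (single exponential, tail-baseline
#'   subtraction). Channel deactivation constants are fitted from the
#'   open-probability peak after a standard 1 ms vesicular pulse; enzyme decay
#'   constants from the post-stimulation peak of the sample-averaged activity
#'   trace.
NULL

#' @describeIn measurements Initial vesicle release probability (percent) for
#'   the first spike from rest at the given extracellular calcium.
#' @param ca_o Extracellular calcium (mM).
#' @export
measure_initial_release_probability <- function(ca_o = 2.5) {
  100 * release_probability(ca_pre = 1, ca_o = ca_o, docked = 25)
}

#' @describeIn measurements Dendritic BaP amplitude at the 30th pulse of a
#'   1Pre1Post10 pairing train at 5 Hz, as percent of the first pulse
#'   (deterministic electrical subsystem).
#' @export
measure_bap_attenuation_30 <- function() {
  cond <- experimental_conditions(deterministic_sources = "all")
  sim <- simulate_synapse(build_protocol("1Pre1Post10, 30 at 5 Hz"), cond,
                          n_samples = 1, seed = 1, relax = 0.5,
                          control = list(warmup_det = 30, warmup_stoch = 0))
  amp <- sim$pulse_peaks$v_dend_peak - synapse_params(cond)$e_leak
  100 * amp[30] / amp[1]
}

#' @describeIn measurements Receptor deactivation time constant (ms) after a
#'   1 ms, 1 mM transmitter pulse at 35 C, from deterministic occupancy
#'   propagation.
#' @param channel One of `"ampa"`, `"glun2a"`, `"glun2b"`, `"gaba"`.
#' @export
measure_channel_decay_ms <- function(channel) {
  cond <- experimental_conditions()
  p <- synapse_params(cond)
  tmax <- switch(channel, ampa = 0.02, gaba = 0.15, glun2a = 0.6, glun2b = 2.5)
  dt <- switch(channel, ampa = 1e-5, gaba = 2e-5, glun2a = 2e-4, glun2b = 5e-4)
  1e3 * channel_decay_tau(channel, temperature = 35, t_max = tmax, dt = dt,
                          params = p)
}

#' @describeIn measurements Post-stimulation decay time constants of the
#'   sample-averaged enzyme activities after 30 pairings of 1Pre1Post10 at
#'   5 Hz under adult physiological conditions. Returns a list with `cam_ms`
#'   (calcium-bound free CaM, ms), `camkii_s` and `can_s` (seconds).
#' @param n_samples Number of stochastic samples (>= 20 for reporting).
#' @param seed Base seed.
#' @export
measure_enzyme_decays <- function(n_samples = 20, seed = 1) {
  cond <- experimental_conditions()
  proto <- build_protocol("1Pre1Post10, 30 at 5 Hz")
  sim <- simulate_synapse(proto, cond, n_samples = n_samples, seed = seed,
                          relax = 450,
                          control = list(warmup_det = 100, warmup_stoch = 2))
  tr <- sim$trajectory |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(cam = mean(.data$cam_ca), camkii = mean(.data$camkii),
                     can = mean(.data$can))
  t_last <- max(proto$post_times)
  fit_from_peak <- function(y, t0) {
    i <- which(tr$time >= t0)
    i <- i[which.max(y[i])]
    fit_decay(tr$time[i:nrow(tr)], y[i:nrow(tr)])$tau
  }
  w <- which(tr$time >= t_last + 0.05 & tr$time <= t_last + 30)
  list(cam_ms = 1e3 * fit_decay(tr$time[w], tr$cam[w])$tau,
       camkii_s = fit_from_peak(tr$camkii, 6),
       can_s = fit_from_peak(tr$can, 6))
}

#' @describeIn measurements CaN activity decay time constant (s) under the
#'   uncaging-style drive (100 presynaptic pulses at 20 Hz, release forced,
#'   2 mM calcium, magnesium-free, immature tissue) at the given temperature.
#' @param temperature Bath temperature (C), 25 or 35 in the reference
#'   experiments.
#' @export
measure_uncaging_can_decay <- function(temperature = 25, n_samples = 20,
                                       seed = 1) {
  cond <- experimental_conditions(age = 12, temperature = temperature,
                                  ca_o = 2, mg_o = 0, glu_cv_mode = "none")
  proto <- build_protocol("1Pre, 100 at 20 Hz")
  sim <- simulate_synapse(proto, cond, n_samples = n_samples, seed = seed,
                          relax = 300, force_release = TRUE,
                          control = list(warmup_det = 100, warmup_stoch = 2))
  tr <- sim$trajectory |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(can = mean(.data$can))
  i <- which(tr$time >= max(proto$pre_times))
  i <- i[which.max(tr$can[i])]
  fit_decay(tr$time[i:nrow(tr)], tr$can[i:nrow(tr)])$tau
}

#' @describeIn measurements Mean peak spine calcium (uM) for a single
#'   successful vesicle release under default physiological conditions.
#' @export
measure_epsp_calcium_peak <- function(n_samples = 50, seed = 1) {
  cond <- experimental_conditions()
  sim <- simulate_synapse(build_protocol("1Pre"), cond, n_samples = n_samples,
                          seed = seed, relax = 0.5, force_release = TRUE,
                          control = list(warmup_det = 50, warmup_stoch = 2))
  mean(sim$outcomes$max_ca)
}
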