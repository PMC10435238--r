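# Stimulation protocol construction: the "aPre bPost delay, N at f Hz"
# grammar, theta-burst builder, jitter/sparsity/Poisson variants and named
# experimental presets.

new_protocol <- function(pre_times, post_times, name = "",
                         repetitions = NA_integer_, frequency = NA_real_) {
  stopifnot(!is.unsorted(pre_times), !is.unsorted(post_times),
            all(pre_times >= 0), all(post_times >= 0),
            all(is.finite(pre_times)), all(is.finite(post_times)))
  structure(list(pre_times = as.numeric(pre_times),
                 post_times = as.numeric(post_times),
                 name = name, repetitions = repetitions, frequency = frequency),
            class = "synapse_protocol")
}

#' @export
print.synapse_protocol <- function(x, ...) {
  cat(sprintf("<synapse_protocol> %s: %d pre, %d post spikes",
              if (nzchar(x$name)) x$name else "(unnamed)",
              length(x$pre_times), length(x$post_times)))
  if (length(x$pre_times) || length(x$post_times)) {
    cat(sprintf(", duration %.3g s",
                max(c(x$pre_times, x$post_times), 0)))
  }
  cat("\n")
  invisible(x)
}

#' Build a stimulation protocol from its conventional name
#'
#' Parses the spike-timing grammar used to name plasticity induction
#' protocols, e.g. `"1Pre1Post10, 300 at 5 Hz"` (a presynaptic spike followed
#' 10 ms later by a postsynaptic spike, repeated 300 times at 5 Hz),
#' `"2Post1Pre50"` (anticausal: postsynaptic doublet, then a presynaptic spike
#' 50 ms after the last post), `"2Pre50, 900 at 3 Hz"` (presynaptic doublets,
#' 50 ms apart). Within a multi-spike group, spikes are separated by
#' `doublet_isi_ms` (the intra-doublet interval is not part of the printed
#' grammar; 10 ms by default) unless the group carries its own interval as in
#' `2Pre50`.
#'
#' @param spec Protocol name string.
#' @param doublet_isi_ms Interval between spikes of a postsynaptic doublet
#'   (ms).
#' @return A `synapse_protocol` object with sorted `pre_times` and
#'   `post_times` in seconds.
#' @examples
#' build_protocol("1Pre2Post10, 300 at 5 Hz")
#' build_protocol("2Pre50, 900 at 3 Hz")
#' @export
build_protocol <- function(spec, doublet_isi_ms = 10) {
  s <- gsub("\\s+", "", spec)
  m <- regmatches(s, regexec(
    "^(?:(\\d+)Post(\\d+)?)?(\\d+)Pre(\\d+)?(?:(\\d+)Post(\\d+)?)?(?:,(\\d+)at([0-9.]+)Hz)?$",
    s))[[1]]
  if (!length(m)) stop("cannot parse protocol spec: '", spec, "'")
  num <- function(x, default = NA_real_) if (nzchar(x)) as.numeric(x) else default
  n_post_lead <- num(m[2], 0)
  lead_delay <- num(m[3])        # delay from last leading post to the pre spike
  n_pre <- num(m[4])
  pre_int <- num(m[5])           # intra-group interval for nPre groups (ms)
  n_post_trail <- num(m[6], 0)
  trail_delay <- num(m[7])       # delay from (last) pre to first trailing post
  reps <- num(m[8], 1)
  freq <- num(m[9], NA_real_)
  if (n_post_lead > 0 && is.na(lead_delay)) {
    # "2Post1Pre50" puts the delay after "Pre"; it belongs to the lead block
    lead_delay <- pre_int
    pre_int <- NA_real_
  }
  isi <- doublet_isi_ms / 1e3
  pre_isi <- if (is.na(pre_int)) isi else pre_int / 1e3

  pre <- numeric(0); post <- numeric(0); t0 <- 0
  if (n_post_lead > 0) {
    post <- t0 + (seq_len(n_post_lead) - 1) * isi
    t0 <- max(post) + lead_delay / 1e3
  }
  pre <- t0 + (seq_len(n_pre) - 1) * pre_isi
  if (n_post_trail > 0) {
    if (is.na(trail_delay)) stop("missing post delay in spec: '", spec, "'")
    p0 <- pre[length(pre)] + trail_delay / 1e3
    post <- c(post, p0 + (seq_len(n_post_trail) - 1) * isi)
  }
  if (reps > 1) {
    if (is.na(freq)) stop("repetitions given without a frequency: '", spec, "'")
    onsets <- (seq_len(reps) - 1) / freq
    pre <- as.vector(outer(pre, onsets, `+`))
    post <- as.vector(outer(post, onsets, `+`))
  }
  new_protocol(sort(pre), sort(post), name = spec,
               repetitions = as.integer(reps), frequency = freq)
}

#' Build a theta-burst stimulation (TBS) protocol
#'
#' Nested presynaptic burst structure: `n_spikes` at `spike_freq` per burst,
#' `n_bursts` bursts at `burst_freq`, repeated in `n_epochs` epochs at
#' `epoch_freq`. The default corresponds to 4 pre-spikes at 100 Hz repeated
#' 10 times at 5 Hz, given in 6 epochs at 0.1 Hz (240 presynaptic spikes).
#'
#' @param n_spikes,spike_freq Spikes per burst and intra-burst rate (Hz).
#' @param n_bursts,burst_freq Bursts per epoch and burst rate (Hz).
#' @param n_epochs,epoch_freq Epochs and epoch rate (Hz).
#' @return A `synapse_protocol` with presynaptic spikes only.
#' @examples
#' length(build_tbs()$pre_times) # 240
#' @export
build_tbs <- function(n_spikes = 4, spike_freq = 100,
                      n_bursts = 10, burst_freq = 5,
                      n_epochs = 6, epoch_freq = 0.1) {
  spikes <- (seq_len(n_spikes) - 1) / spike_freq
  bursts <- as.vector(outer(spikes, (seq_len(n_bursts) - 1) / burst_freq, `+`))
  all <- as.vector(outer(bursts, (seq_len(n_epochs) - 1) / epoch_freq, `+`))
  new_protocol(sort(all), numeric(0),
               name = sprintf("TBS %dx%dx%d", n_spikes, n_bursts, n_epochs))
}

#' Add Gaussian timing jitter to a protocol
#'
#' Each pre- and postsynaptic spike time is independently perturbed by
#' zero-mean Gaussian noise; resulting times are re-sorted and negative times
#' clamped at zero.
#'
#' @param protocol A `synapse_protocol`.
#' @param sigma_ms Jitter standard deviation in ms.
#' @return A jittered `synapse_protocol`.
#' @export
apply_jitter <- function(protocol, sigma_ms) {
  stopifnot(sigma_ms >= 0)
  if (sigma_ms == 0) return(protocol)
  s <- sigma_ms / 1e3
  jit <- function(t) sort(pmax(0, t + stats::rnorm(length(t), 0, s)))
  new_protocol(jit(protocol$pre_times), jit(protocol$post_times),
               name = sprintf("%s + jitter %g ms", protocol$name, sigma_ms),
               repetitions = protocol$repetitions, frequency = protocol$frequency)
}

#' Randomly drop spikes from a protocol
#'
#' Each spike (pre and post independently) is removed with probability
#' `p_remove`, modelling release/backpropagation failures and sparse firing.
#'
#' @param protocol A `synapse_protocol`.
#' @param p_remove Removal probability in `[0, 1]`.
#' @return A thinned `synapse_protocol`.
#' @export
apply_sparsity <- function(protocol, p_remove) {
  stopifnot(p_remove >= 0, p_remove <= 1)
  keep <- function(t) t[stats::runif(length(t)) >= p_remove]
  new_protocol(keep(protocol$pre_times), keep(protocol$post_times),
               name = sprintf("%s + sparsity %g", protocol$name, p_remove),
               repetitions = protocol$repetitions, frequency = protocol$frequency)
}

#' Independent pre/post Poisson spike-train protocol
#'
#' @param rate_pre,rate_post Rates in Hz (>= 0).
#' @param duration Train duration in seconds.
#' @return A `synapse_protocol`.
#' @export
poisson_protocol <- function(rate_pre, rate_post, duration) {
  stopifnot(rate_pre >= 0, rate_post >= 0, duration >= 0)
  draw <- function(rate) {
    n <- stats::rpois(1, rate * duration)
    sort(stats::runif(n, 0, duration))
  }
  new_protocol(draw(rate_pre), draw(rate_post),
               name = sprintf("Poisson pre %g Hz / post %g Hz, %g s",
                              rate_pre, rate_post, duration))
}

#' Spike times of a protocol as a tidy tibble
#'
#' @param protocol A `synapse_protocol`.
#' @return Tibble with columns `time` (s) and `side` (`"pre"`/`"post"`).
#' @export
protocol_spikes <- function(protocol) {
  tibble::tibble(
    time = c(protocol$pre_times, protocol$post_times),
    side = rep(c("pre", "post"),
               c(length(protocol$pre_times), length(protocol$post_times)))
  ) |> dplyr::arrange(.data$time)
}

#' Named experimental presets (conditions + protocol)
#'
#' Bundles the experimental-condition/protocol pairs of the classic plasticity
#' datasets the model addresses: timing-based pairings in adult tissue
#' (Tigaret-style), frequency-dependent plasticity trains (Dudek & Bear),
#' developmental series, Ca/Mg titrations (Inglebert-style), room-temperature
#' STDP in young tissue, and the CaMKII/CaN imaging conditions.
#'
#' @param name Preset name; with no argument, lists available presets.
#' @return A list with elements `conditions` (a [experimental_conditions()])
#'   and `protocol` (a `synapse_protocol`), or a character vector of names.
#' @examples
#' experiment_preset()
#' experiment_preset("tigaret_ltp")$conditions
#' @export
experiment_preset <- function(name = NULL) {
  presets <- list(
    tigaret_ltp = list(
      conditions = experimental_conditions(age = 52, temperature = 35,
                                           ca_o = 2.5, mg_o = 1.3, d_soma = 200),
      protocol = build_protocol("1Pre2Post10, 300 at 5 Hz")),
    tigaret_ltd = list(
      conditions = experimental_conditions(age = 52, temperature = 35,
                                           ca_o = 2.5, mg_o = 1.3, d_soma = 200),
      protocol = build_protocol("2Pre50, 900 at 3 Hz")),
    dudek_bear_lfs = list(
      conditions = experimental_conditions(age = 35, temperature = 35,
                                           ca_o = 2.5, mg_o = 1.5, d_soma = 200,
                                           evoked_ap = TRUE),
      protocol = build_protocol("1Pre, 900 at 1 Hz")),
    dudek_bear_hfs = list(
      conditions = experimental_conditions(age = 35, temperature = 35,
                                           ca_o = 2.5, mg_o = 1.5, d_soma = 200,
                                           evoked_ap = TRUE),
      protocol = build_protocol("1Pre, 900 at 50 Hz")),
    dudek_bear_dev = list(
      conditions = experimental_conditions(age = 14, temperature = 35,
                                           ca_o = 2.5, mg_o = 1.5, d_soma = 200,
                                           evoked_ap = TRUE),
      protocol = build_protocol("1Pre, 900 at 1 Hz")),
    dudek_bear_tbs = list(
      conditions = experimental_conditions(age = 35, temperature = 35,
                                           ca_o = 2.5, mg_o = 1.5, d_soma = 200,
                                           evoked_ap = TRUE),
      protocol = build_tbs()),
    inglebert_causal = list(
      conditions = experimental_conditions(age = 18, temperature = 30,
                                           ca_o = 1.8, mg_o = 1.2, d_soma = 200),
      protocol = build_protocol("1Pre1Post10, 100 at 0.3 Hz")),
    inglebert_anticausal = list(
      conditions = experimental_conditions(age = 18, temperature = 30,
                                           ca_o = 1.8, mg_o = 1.2, d_soma = 200),
      protocol = build_protocol("1Post1Pre10, 150 at 0.3 Hz")),
    meredith_young = list(
      conditions = experimental_conditions(age = 10, temperature = 25,
                                           ca_o = 2, mg_o = 2, d_soma = 200),
      protocol = build_protocol("1Pre1Post10, 60 at 5 Hz")),
    chang_camkii = list(
      conditions = experimental_conditions(age = 7, temperature = 25,
                                           ca_o = 1, mg_o = 2, d_soma = 200,
                                           glu_cv_mode = "none"),
      protocol = build_protocol("1Pre, 30 at 0.49 Hz")),
    fujii_can = list(
      conditions = experimental_conditions(age = 12, temperature = 25,
                                           ca_o = 2, mg_o = 0, d_soma = 200,
                                           glu_cv_mode = "none"),
      protocol = build_protocol("1Pre, 100 at 20 Hz"))
  )
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; see experiment_preset() for choices")
  }
  presets[[name]]
}
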