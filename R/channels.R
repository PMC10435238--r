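# Markov-chain schemes for the stochastic receptors and channels, and the
# deterministic SK channel. Builders return transition-rate templates as
# matrices Q with Q[i, j] = rate of the i -> j transition (s^-1, off-diagonal,
# zero diagonal). The C++ engine carries its own copy of these rates for the
# hot loop; equality of the two is asserted in the test suite.

#' AMPA receptor transition-rate matrix
#'
#' Sixteen-state scheme with four sequential glutamate binding steps
#' (C0..C4), three sub-conductance open states (O2, O3, O4), a desensitised
#' row (D0..D4) with slow glutamate unbinding, and three deep-desensitised
#' states (D22..D24). Temperature scales glutamate binding (forward factor)
#' and unbinding plus channel closing (backward factor); desensitisation
#' ("vertical") transitions and opening are temperature-insensitive, so
#' recovery from desensitisation matches room-temperature behaviour.
#'
#' @param glu Cleft glutamate concentration (uM).
#' @param temperature Temperature in C.
#' @param params A [synapse_params()] list.
#' @return 16 x 16 rate matrix with state labels as dimnames.
#' @export
ampar_rates <- function(glu, temperature, params = synapse_params()) {
  stopifnot(glu >= 0)
  tf <- effective_factors(temperature, "AMPA")
  states <- c("C0", "C1", "C2", "C3", "C4", "O2", "O3", "O4",
              "D0", "D1", "D2", "D3", "D4", "D22", "D23", "D24")
  Q <- matrix(0, 16, 16, dimnames = list(states, states))
  kon <- params$ampa_k1 * glu * tf$rho_f
  koff1 <- params$ampa_km1 * tf$rho_b
  koff2 <- params$ampa_km2 * tf$rho_b
  # closed-row binding with statistical factors 4:3:2:1
  for (i in 1:4) {
    Q[i, i + 1] <- (5 - i) * kon
    Q[i + 1, i] <- i * koff1
  }
  # openings from the 2-, 3- and 4-liganded closed states; closing carries the
  # backward temperature factor (the printed decay pair 0.95/0.6 ms at 25/35 C
  # identifies closing, not opening, as temperature-sensitive)
  for (i in 3:5) {
    Q[i, i + 3] <- params$ampa_beta
    Q[i + 3, i] <- params$ampa_alpha * tf$rho_b
  }
  # desensitisation: C0<->D0 slow, C1..C4 <-> D1..D4
  Q["C0", "D0"] <- params$ampa_delta0; Q["D0", "C0"] <- params$ampa_gamma0
  for (i in 2:5) {
    Q[i, i + 8] <- params$ampa_delta1
    Q[i + 8, i] <- params$ampa_gamma1
  }
  # desensitised-row binding (slow unbinding koff2)
  for (i in 9:12) {
    Q[i, i + 1] <- (13 - i) * kon
    Q[i + 1, i] <- (i - 8) * koff2
  }
  # deep desensitisation from D2..D4
  for (i in 11:13) {
    Q[i, i + 3] <- params$ampa_delta2
    Q[i + 3, i] <- params$ampa_gamma2
  }
  Q
}

#' NMDA receptor transition-rate matrix (GluN2A or GluN2B)
#'
#' Seven-state linear scheme: two glutamate binding steps, three
#' conformational steps, two open states. The GluN2B chain is the GluN2A
#' scheme with forward rates scaled by 0.25 and backward rates by 0.23,
#' reproducing its ~5x slower deactivation. Both chains carry the NMDA
#' temperature factors on every forward/backward rate.
#'
#' @param glu Cleft glutamate concentration (uM).
#' @param temperature Temperature in C.
#' @param subtype `"glun2a"` or `"glun2b"`.
#' @param params A [synapse_params()] list.
#' @return 7 x 7 rate matrix.
#' @export
nmdar_rates <- function(glu, temperature, subtype = c("glun2a", "glun2b"),
                        params = synapse_params()) {
  stopifnot(glu >= 0)
  subtype <- match.arg(subtype)
  tf <- effective_factors(temperature, "NMDA")
  sf <- if (subtype == "glun2b") params$glun2b_fwd else 1
  sb <- if (subtype == "glun2b") params$glun2b_bwd else 1
  fwd <- c(params$nmda_ka * glu, params$nmda_kb * glu, params$nmda_kc,
           params$nmda_kd, params$nmda_ke, params$nmda_kf) * sf * tf$rho_f
  bwd <- c(params$nmda_kma, params$nmda_kmb, params$nmda_kmc,
           params$nmda_kmd, params$nmda_kme, params$nmda_kmf) * sb * tf$rho_b
  pre <- if (subtype == "glun2a") "A" else "B"
  states <- paste0(pre, c("0", "1", "2", "3", "4", "O1", "O2"))
  Q <- matrix(0, 7, 7, dimnames = list(states, states))
  for (i in 1:6) {
    Q[i, i + 1] <- fwd[i]
    Q[i + 1, i] <- bwd[i]
  }
  Q
}

#' GABA(A) receptor transition-rate matrix
#'
#' Five states: unbound (C0), singly (C1) and doubly (C2) bound closed states,
#' and open states O1 (from C1) and O2 (from C2). Temperature acts only on
#' the closing rates (slower closing, hence slower IPSC decay, at room
#' temperature).
#'
#' @param gaba Cleft GABA concentration (uM).
#' @param temperature Temperature in C.
#' @param params A [synapse_params()] list.
#' @return 5 x 5 rate matrix.
#' @export
gabar_rates <- function(gaba, temperature, params = synapse_params()) {
  stopifnot(gaba >= 0)
  tf <- effective_factors(temperature, "GABA")
  states <- c("C0", "C1", "C2", "O1", "O2")
  Q <- matrix(0, 5, 5, dimnames = list(states, states))
  Q["C0", "C1"] <- params$gaba_rb1 * gaba
  Q["C1", "C0"] <- params$gaba_ru1
  Q["C1", "C2"] <- params$gaba_rb2 * gaba
  Q["C2", "C1"] <- params$gaba_ru2
  Q["C1", "O1"] <- params$gaba_ro1
  Q["O1", "C1"] <- params$gaba_rc1 * tf$rho_b
  Q["C2", "O2"] <- params$gaba_ro2
  Q["O2", "C2"] <- params$gaba_rc2 * tf$rho_b
  Q
}

#' Voltage-gated calcium channel rates
#'
#' T- and R-type channels factorise into independent activation (m) and
#' inactivation (h) two-state gates; a channel conducts when m is open and h
#' available. The L-type channel has one closed and two open states capturing
#' its two closing timescales. All activation rates carry the common VGCC
#' forward temperature factor, deactivation/inactivation rates the backward
#' factor.
#'
#' @param v Membrane potential (mV).
#' @param temperature Temperature in C.
#' @param subtype `"T"`, `"R"` or `"L"`.
#' @param params A [synapse_params()] list.
#' @return For T/R: named list with gate rates `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h` (s^-1). For L: a 3 x 3 rate matrix over states C, O1, O2.
#' @export
vgcc_rates <- function(v, temperature, subtype = c("T", "R", "L"),
                       params = synapse_params()) {
  subtype <- match.arg(subtype)
  tf <- temperature_factors(temperature, "VGCC")
  if (subtype == "L") {
    aL <- 0.83 / (1 + exp((13.7 - v) / 6.1))
    b1 <- 0.53 / (1 + exp((v - 11.5) / 6.4))
    b2 <- 1.86 / (1 + exp((v - 18.8) / 6.17))
    states <- c("C", "O1", "O2")
    Q <- matrix(0, 3, 3, dimnames = list(states, states))
    Q["C", "O1"] <- 1e3 * aL * tf$rho_f
    Q["O1", "C"] <- 1e3 * b1 * tf$rho_b
    Q["C", "O2"] <- 1e3 * aL * tf$rho_f
    Q["O2", "C"] <- 1e3 * b2 * tf$rho_b
    return(Q)
  }
  if (subtype == "T") {
    minf <- 1 / (1 + exp((-32 - v) / 7))
    minf_star <- 1 / (1 + exp((-32 + 20) / 7))
    tau_m <- 1 / (minf_star / (1 - minf_star) + 1)        # beta* = 1 ms^-1
    hinf <- 1 / (1 + exp((v + 70) / 6.5))
    tau_h <- 50
  } else {
    minf <- 1 / (1 + exp((3 - v) / 8))
    minf_star <- 1 / (1 + exp((3 - 10) / 8))
    tau_m <- 1 / (40 * minf_star / (1 - minf_star) + 40)  # beta* = 40 ms^-1
    hinf <- 1 / (1 + exp((v + 39) / 9.2))
    tau_h <- 100
  }
  list(alpha_m = 1e3 * minf / tau_m * tf$rho_f,
       beta_m = 1e3 * (1 - minf) / tau_m * tf$rho_b,
       alpha_h = 1e3 * hinf / tau_h * tf$rho_f,
       beta_h = 1e3 * (1 - hinf) / tau_h * tf$rho_b)
}

#' Magnesium block of the NMDA receptor
#'
#' Voltage-dependent fraction of unblocked NMDA receptors.
#'
#' @param v Spine membrane potential (mV).
#' @param mg_o Extracellular magnesium (mM).
#' @return Fraction in (0, 1].
#' @examples
#' mg_block(-70, 1) # ~0.045: nearly full block at rest
#' @export
mg_block <- function(v, mg_o) {
  stopifnot(mg_o >= 0)
  1 / (1 + mg_o / 3.57 * exp(-0.062 * v))
}

#' AMPA receptor current
#'
#' @param open Counts in the three sub-conductance open states, in order
#'   (O2, O3, O4).
#' @param v Spine membrane potential (mV).
#' @param params A [synapse_params()] list.
#' @return Current in pA (positive = depolarizing).
#' @export
ampar_current <- function(open, v, params = synapse_params()) {
  stopifnot(length(open) == 3, all(open >= 0))
  (params$erev_ampa - v) *
    (params$gamma_a2 * open[1] + params$gamma_a3 * open[2] + params$gamma_a4 * open[3])
}

#' GABA(A) receptor current
#'
#' Sign follows the age-dependent chloride reversal potential: depolarizing in
#' young tissue, hyperpolarizing in adults.
#'
#' @param open Total open count (O1 + O2).
#' @param v_dend Dendritic membrane potential (mV).
#' @param age Age in days (sets the chloride reversal).
#' @param params A [synapse_params()] list.
#' @return Current in pA.
#' @export
gabar_current <- function(open, v_dend, age, params = synapse_params()) {
  open * (erev_chloride(age) - v_dend) * params$gamma_gaba
}

#' SK channel activation derivative and current
#'
#' Deterministic calcium-activated potassium channel: Hill activation by spine
#' calcium (exponent 6, half-activation 0.333 uM), first-order relaxation to
#' the (temperature-gain-shifted, capped) activation target with a
#' temperature-scaled time constant.
#'
#' @param m_sk Activation fraction in `[0, 1]`.
#' @param ca Spine calcium (uM).
#' @param temperature Temperature in C.
#' @param params A [synapse_params()] list.
#' @return `sk_derivative`: dm/dt (s^-1).
#' @export
sk_derivative <- function(m_sk, ca, temperature, params = synapse_params()) {
  stopifnot(ca >= 0)
  tf <- temperature_factors(temperature, "SK")
  r <- ca^params$sk_hill / (ca^params$sk_hill + params$sk_half^params$sk_hill)
  (min(1, r * tf$rho_f) - m_sk) / (params$tau_sk / tf$rho_b)
}

#' @rdname sk_derivative
#' @param n_open Effective open fraction times channel count
#'   (`m_sk * n_sk`), computed internally.
#' @return `sk_current`: current in pA.
#' @export
sk_current <- function(m_sk, v, params = synapse_params()) {
  params$gamma_sk * (params$erev_sk - v) * m_sk * params$n_sk
}

# generator (Q - diag(rowsums)) from a rate template
rate_generator <- function(Q) Q - diag(rowSums(Q))

#' Deterministic occupancy propagation of a receptor chain
#'
#' Propagates the master equation of a single receptor's Markov chain through
#' a square neurotransmitter pulse and the subsequent decay, returning the
#' total open probability on a time grid. Used to measure the model's
#' receptor deactivation time constants.
#'
#' @param channel `"ampa"`, `"glun2a"`, `"glun2b"` or `"gaba"`.
#' @param temperature Temperature in C.
#' @param pulse_amp Pulse amplitude (uM; vesicular default 1000).
#' @param pulse_width Pulse duration (s).
#' @param t_max Total propagated time (s).
#' @param dt Output grid step (s).
#' @param params A [synapse_params()] list.
#' @return Tibble with columns `time` (s) and `open` (probability).
#' @examples
#' tr <- channel_open_trace("gaba", 35, t_max = 0.05)
#' @export
channel_open_trace <- function(channel = c("ampa", "glun2a", "glun2b", "gaba"),
                               temperature = 35, pulse_amp = 1000,
                               pulse_width = 1e-3, t_max = 0.5, dt = 1e-4,
                               params = synapse_params()) {
  channel <- match.arg(channel)
  build <- function(conc) {
    switch(channel,
      ampa = ampar_rates(conc, temperature, params),
      glun2a = nmdar_rates(conc, temperature, "glun2a", params),
      glun2b = nmdar_rates(conc, temperature, "glun2b", params),
      gaba = gabar_rates(conc, temperature, params))
  }
  open_idx <- switch(channel,
    ampa = 6:8, glun2a = 6:7, glun2b = 6:7, gaba = 4:5)
  Q_on <- rate_generator(build(pulse_amp))
  Q_off <- rate_generator(build(0))
  n <- nrow(Q_on)
  p <- numeric(n); p[1] <- 1
  times <- seq(0, t_max, by = dt)
  # transition matrices over one grid step (uniformized via matrix exponential)
  P_on <- as.matrix(Matrix::expm(Matrix::Matrix(t(Q_on) * dt)))
  P_off <- as.matrix(Matrix::expm(Matrix::Matrix(t(Q_off) * dt)))
  open <- numeric(length(times))
  open[1] <- sum(p[open_idx])
  for (k in 2:length(times)) {
    P <- if (times[k] <= pulse_width + 1e-12) P_on else P_off
    p <- as.vector(P %*% p)
    open[k] <- sum(p[open_idx])
  }
  tibble::tibble(time = times, open = open)
}

#' Receptor deactivation time constant
#'
#' Single-exponential decay constant of the open probability after a standard
#' vesicular neurotransmitter pulse, from deterministic occupancy propagation
#' ([channel_open_trace()]) and [fit_decay()].
#'
#' @inheritParams channel_open_trace
#' @param ... Passed to [channel_open_trace()].
#' @return Decay time constant in seconds.
#' @examples
#' channel_decay_tau("glun2a", 35) # ~0.05 s
#' @export
channel_decay_tau <- function(channel, temperature = 35, ...) {
  tr <- channel_open_trace(channel, temperature, ...)
  peak_i <- which.max(tr$open)
  fit_decay(tr$time[peak_i:nrow(tr)], tr$open[peak_i:nrow(tr)])$tau
}
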