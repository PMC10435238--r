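# Three-compartment electrical model helpers: somatic spike gates, BaP
# injection and use-dependent attenuation. The C++ engine integrates these;
# the functions here expose the rate expressions and algebra for direct use
# and for cross-checking the engine.

#' Somatic Na+/K+ gate rates
#'
#' Hodgkin-Huxley-style rate functions of the soma spike generator, with the
#' removable singularities of the x/(1 - exp(-x/k)) forms evaluated by their
#' series limit. The printed ms^-1 rates are converted to s^-1; the
#' potassium time constant carries its 2 ms floor.
#'
#' @param v Somatic membrane potential (mV).
#' @return Named list: `alpha_m`, `beta_m`, `alpha_h`, `beta_h` (s^-1),
#'   `n_inf` (dimensionless), `n_tau` (s).
#' @examples
#' soma_gate_rates(-30)$alpha_m # limit value 2880 s^-1
#' @export
soma_gate_rates <- function(v) {
  vtrap <- function(x, k) ifelse(abs(x) < 1e-4 * k, k * (1 + x / (2 * k)),
                                 x / (1 - exp(-x / k)))
  an <- exp(-0.11 * (v - 13))
  bn <- exp(-0.08 * (v - 13))
  list(alpha_m = 1e3 * 0.4 * vtrap(v + 30, 7.2),
       beta_m = 1e3 * 0.124 * vtrap(-(v + 30), 7.2),
       alpha_h = 1e3 * 0.01 * vtrap(-(v + 45), 1.5),
       beta_h = 1e3 * 0.03 * vtrap(v + 45, 1.5),
       n_inf = 1 / (1 + an),
       n_tau = pmax(50 * bn / (1 + an), 2) * 1e-3)
}

#' Dendro-somatic coupling conductance under BaP adaptation
#'
#' The axial conductance between soma and dendrite is the product of the
#' use-dependent attenuation resource, the dendritic axial conductance and
#' the distance-dependent attenuation factor.
#'
#' @param lambda Attenuation resource in (0, 1].
#' @param d_soma Spine distance from soma (um).
#' @param g_diff Dendritic axial conductance (nS).
#' @return Conductance in nS.
#' @examples
#' g_bap_adapt(1, 230.3) # 40 nS at the distance midpoint
#' @export
g_bap_adapt <- function(lambda, d_soma, g_diff = 50) {
  stopifnot(lambda > 0, lambda <= 1)
  lambda * g_diff * phi_dist(d_soma)
}

#' BaP injection current
#'
#' Rectangular somatic current pulses of width `delta_inj` at each
#' postsynaptic spike time; overlapping pulses sum.
#'
#' @param t Time (s), vectorised.
#' @param post_times Postsynaptic spike times (s).
#' @param i_amp Pulse amplitude (pA).
#' @param delta_inj Pulse width (s).
#' @return Current in pA.
#' @export
bap_injection <- function(t, post_times, i_amp = 1000, delta_inj = 2e-3) {
  vapply(t, function(tt)
    i_amp * sum(tt >= post_times & tt < post_times + delta_inj), numeric(1))
}

#' BaP attenuation resource derivatives
#'
#' Use-dependent resources in (0, 1]: each recovers to 1 with its time
#' constant and is consumed in proportion to the injected BaP current. The
#' main resource `lambda` scales the dendro-somatic conductance; the
#' auxiliary resource modulates the step size of `lambda`; the age resource
#' attenuates the somatic sodium and injection currents.
#'
#' @param lambda,lambda_aux,lambda_age Current resource values.
#' @param i_bap Injected current (pA).
#' @param params A [synapse_params()] list.
#' @return Named vector of derivatives (s^-1).
#' @export
bap_adaptation_derivatives <- function(lambda, lambda_aux, lambda_age, i_bap,
                                       params = synapse_params()) {
  c(d_lambda = (1 - lambda) / params$tau_rec_lambda -
      params$delta_decay / lambda_aux * lambda * i_bap,
    d_lambda_aux = (1 - lambda_aux) / params$tau_rec_lambda -
      params$delta_aux * lambda_aux * i_bap,
    d_lambda_age = (1 - lambda_age) / params$tau_rec_age -
      params$delta_age * lambda_age * i_bap)
}

#' Membrane potential derivatives of the three compartments
#'
#' Passive-cable balance of the spine (coupled to the dendrite through the
#' neck), the dendrite (coupled to soma and spine, receiving GABA current)
#' and the soma (leak, Na+/K+ spike currents and BaP injection, with the
#' age resource scaling sodium and injection). Synaptic and calcium-source
#' currents are supplied in pA.
#'
#' @param v A named list or vector with `v_sp`, `v_dend`, `v_soma` (mV).
#' @param gates Named list with `m`, `h`, `n` somatic gate states.
#' @param currents Named list of synaptic currents in pA: `i_sp` (total into
#'   the spine: AMPA + NMDA + SK + VGCC), `i_gaba` (into the dendrite),
#'   `i_bap` (somatic injection).
#' @param adaptation Named list with `lambda`, `lambda_age`.
#' @param params A [synapse_params()] list.
#' @return Named vector of dV/dt in mV/s.
#' @export
membrane_derivatives <- function(v, gates, currents, adaptation,
                                 params = synapse_params()) {
  g_bap <- g_bap_adapt(adaptation$lambda, params$conditions$d_soma, params$g_diff)
  i_na <- params$g_na * gates$m^3 * gates$h * (params$e_na - v$v_soma)
  i_k <- params$g_k * gates$n * (params$e_k - v$v_soma)
  d_sp <- (params$g_neck * (v$v_dend - v$v_sp) +
             params$g_leak_sp * (params$e_leak - v$v_sp) + currents$i_sp) /
    params$c_sp * 1e3
  d_dend <- (g_bap * (v$v_soma - v$v_dend) + params$g_neck * (v$v_sp - v$v_dend) +
               params$g_leak_dend * (params$e_leak - v$v_dend) + currents$i_gaba) /
    params$c_dend * 1e3
  d_soma <- (g_bap * (v$v_dend - v$v_soma) +
               params$g_leak_soma * (params$e_leak - v$v_soma) +
               adaptation$lambda_age * (currents$i_bap + i_na) + i_k) /
    params$c_soma * 1e3
  c(d_v_sp = d_sp, d_v_dend = d_dend, d_v_soma = d_soma)
}

#' EPSP-evoked action potential test
#'
#' Decides whether a presynaptic volley evokes a somatic action potential:
#' 25 afferent synapses each draw a release with probability given by the
#' release-probability function evaluated at the EPSP accumulator, and an AP
#' is evoked when more than 80% succeed. The evoked AP is scheduled 15 ms
#' after the presynaptic spike.
#'
#' @param v_evoke EPSP accumulator value (increments by 1 per presynaptic
#'   spike, decays with 40 ms time constant).
#' @param ca_o Extracellular calcium (mM).
#' @param docked Docked-vesicle count (gates release).
#' @param n_synapses,threshold Test ensemble size and success fraction.
#' @return Logical: evoke an AP.
#' @export
evoked_ap_test <- function(v_evoke, ca_o, docked, n_synapses = 25,
                           threshold = 0.8) {
  p <- release_probability(v_evoke, ca_o, docked)
  sum(stats::runif(n_synapses) < p) / n_synapses > threshold
}
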