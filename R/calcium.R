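# Spine calcium mass balance: GHK flux, leak to baseline, neck diffusion,
# generic buffer and optional dye. The engine integrates these in C++; the R
# functions here expose the same expressions for direct use and testing.

#' Goldman-Hodgkin-Katz calcium flux
#'
#' Constant-field flux through the spine membrane given voltage and the
#' internal/external calcium concentrations. Positive values denote influx;
#' the flux vanishes exactly at the calcium Nernst potential and is continuous
#' at 0 mV (series limit).
#'
#' @param v Membrane potential (mV).
#' @param ca_i Internal calcium (uM).
#' @param ca_o External calcium (mM).
#' @param temperature Temperature (C).
#' @param p_ca Permeability scale (um/s).
#' @return Signed flux factor; multiplied by a channel's open conductance
#'   weight it gives the calcium source current (pA).
#' @examples
#' ghk_flux(-70, 0.05, 2.5, 35)
#' @export
ghk_flux <- function(v, ca_i, ca_o, temperature, p_ca = 45) {
  stopifnot(ca_i >= 0, ca_o > 0)
  vapply(v, cpp_ghk_flux, numeric(1), cai = ca_i, cao = ca_o,
         temperature = temperature, p_ca = p_ca)
}

#' Calcium, buffer and dye derivatives
#'
#' Mass balance of free spine calcium: relaxation to the resting
#' concentration, channel influx, dampened diffusion to the dendrite through
#' the neck (the dendrite is assumed to sit at one-third of spine calcium, or
#' at baseline, whichever is larger), first-order buffer and optional dye
#' binding, and the net calcium consumed by the CaM reactions.
#'
#' @param ca Free calcium (uM).
#' @param buff_ca Bound buffer (uM).
#' @param dye_ca Bound dye (uM).
#' @param influx Channel calcium influx (uM/s).
#' @param enzyme_flux Net calcium flux from the CaM network (uM/s).
#' @param params A [synapse_params()] list.
#' @return Named vector of derivatives `d_ca`, `d_buff`, `d_dye` (uM/s).
#' @export
calcium_derivatives <- function(ca, buff_ca, dye_ca = 0, influx = 0,
                                enzyme_flux = 0, params = synapse_params()) {
  stopifnot(ca >= 0, buff_ca >= 0, dye_ca >= 0)
  d_buff <- params$kon_buff * (params$buff_total - buff_ca) * ca -
    params$koff_buff * buff_ca
  d_dye <- if (params$dye_total > 0) {
    params$kon_dye * (params$dye_total - dye_ca) * ca - params$koff_dye * dye_ca
  } else 0
  d_ca <- (params$ca_inf - ca) / params$tau_ca + influx +
    (max(params$ca_inf, ca / 3) - ca) / params$tau_ca_diff -
    d_buff - d_dye + enzyme_flux
  c(d_ca = d_ca, d_buff = d_buff, d_dye = d_dye)
}
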