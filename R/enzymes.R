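# Coarse-grained CaM - CaMKII - CaN reaction network. Calcium binds and
# unbinds in pairs from the two calmodulin lobes (C, N); CaM in any loading
# state can bind free monomeric CaMKII (mKCaM); CaMKII-bound CaM (KCaM) loads
# calcium with its own lobe rates and can become phosphorylated (PCaM), then
# autonomous (P, P2). CaN binds fully loaded CaM4 only. The network is
# deterministic; stochasticity enters only through the calcium input.

enzyme_species <- c("cam0", "cam2c", "cam2n", "cam4", "mcan", "can4", "mkcam",
                    "kcam0", "kcam2c", "kcam2n", "kcam4",
                    "pcam0", "pcam2c", "pcam2n", "pcam4", "p", "p2")

#' Resting enzyme state (all species free)
#'
#' @param params A [synapse_params()] list.
#' @return Named numeric vector over the 17 network species (uM).
#' @export
enzyme_init <- function(params = synapse_params()) {
  y <- stats::setNames(numeric(17), enzyme_species)
  y["cam0"] <- params$cam_total
  y["mcan"] <- params$can_total
  y["mkcam"] <- params$kcam_total
  y
}

#' Lumped rate adaptation of the coarse-grained scheme
#'
#' The pairwise (2 Ca) binding steps use lumped rates
#' `adapt(a, b, c, d, Ca) = a * b / (c + d * Ca)`; forward lumped rates carry
#' uM^-2 s^-1 so that the flux `kf * species * Ca^2` is in uM/s.
#'
#' @param a,b,c,d Positive rate constants of the underlying two-step reaction.
#' @param ca Calcium concentration (uM).
#' @return Lumped rate.
#' @examples
#' adapt_rate(5, 10, 50, 10, 0) # kf2C at zero calcium
#' @export
adapt_rate <- function(a, b, c, d, ca) {
  stopifnot(a > 0, b > 0, c > 0, d > 0, ca >= 0)
  a * b / (c + d * ca)
}

#' Enzyme network derivatives
#'
#' Mass-action derivatives of the 17-species network at the given calcium
#' concentration and temperature scaling. The three totals (CaM-containing 30
#' uM, kinase-containing 70 uM, CaN 20 uM) are conserved exactly.
#'
#' @param state Named vector over [enzyme_init()] species (uM).
#' @param ca Free calcium (uM).
#' @param params A [synapse_params()] list (carries the temperature factors).
#' @return Named vector of derivatives (uM/s) with attribute `ca_flux`, the
#'   net calcium flux into free calcium from the CaM reactions.
#' @examples
#' d <- enzyme_derivatives(enzyme_init(), ca = 1)
#' @export
enzyme_derivatives <- function(state, ca, params = synapse_params()) {
  stopifnot(length(state) == 17, ca >= 0)
  out <- cpp_enzyme_deriv(as.numeric(state[enzyme_species]), ca, params)
  d <- stats::setNames(out[1:17], enzyme_species)
  attr(d, "ca_flux") <- out[18]
  d
}

#' Active enzyme observables
#'
#' Active CaN is the CaM4-bound species; active CaMKII is the sum of all
#' CaM-bound kinase states plus the autonomous phosphorylated states.
#'
#' @param state Named enzyme state vector (uM).
#' @return Named vector `c(can_active, camkii_active)` in uM.
#' @examples
#' active_pair(enzyme_init())
#' @export
active_pair <- function(state) {
  kin <- c("kcam0", "kcam2c", "kcam2n", "kcam4",
           "pcam0", "pcam2c", "pcam2n", "pcam4", "p", "p2")
  c(can_active = unname(state["can4"]),
    camkii_active = sum(state[kin]))
}

#' Conserved totals of the enzyme network
#'
#' @param state Named enzyme state vector (uM).
#' @return Named vector of the CaM, kinase and CaN totals (uM).
#' @export
enzyme_totals <- function(state) {
  cam <- c("cam0", "cam2c", "cam2n", "cam4", "can4",
           "kcam0", "kcam2c", "kcam2n", "kcam4",
           "pcam0", "pcam2c", "pcam2n", "pcam4")
  kin <- c("mkcam", "kcam0", "kcam2c", "kcam2n", "kcam4",
           "pcam0", "pcam2c", "pcam2n", "pcam4", "p", "p2")
  c(cam = sum(state[cam]), kinase = sum(state[kin]),
    can = sum(state[c("mcan", "can4")]))
}
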