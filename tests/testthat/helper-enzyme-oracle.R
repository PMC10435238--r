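# Independent mass-action oracle: the reaction network is written here as an
# explicit (reactants, products, rate-law) table and converted to derivatives
# generically, then compared against the package's derivative function.

oracle_reactions <- function(p, ca) {
  tf_ck <- spinesim:::effective_factors(p$temperature_eff, "CaMKII")
  tf_cn <- spinesim:::effective_factors(p$temperature_eff, "CaN")
  adapt <- function(a, b, c, d) a * b / (c + d * ca)
  kf2c <- adapt(p$kon1c, p$kon2c, p$koff1c, p$kon2c)
  kb2c <- adapt(p$koff1c, p$koff2c, p$koff1c, p$kon2c)
  kf2n <- adapt(p$kon1n, p$kon2n, p$koff1n, p$kon2n)
  kb2n <- adapt(p$koff1n, p$koff2n, p$koff1n, p$kon2n)
  kfk2c <- adapt(p$konk1c, p$konk2c, p$koffk1c, p$konk2c)
  kbk2c <- adapt(p$koffk1c, p$koffk2c, p$koffk1c, p$konk2c)
  kfk2n <- adapt(p$konk1n, p$konk2n, p$koffk1n, p$konk2n)
  kbk2n <- adapt(p$koffk1n, p$koffk2n, p$koffk1n, p$konk2n)
  k2 <- p$k2 * tf_ck$rho_b; k3 <- p$k3 * tf_ck$rho_b; k5 <- p$k5 * tf_ck$rho_b
  # columns: from, to, rate multiplier, calcium stoichiometry (+2 release/-2 bind)
  list(
    list("cam0", "cam2c", kf2c * ca^2, -2), list("cam2n", "cam4", kf2c * ca^2, -2),
    list("cam2c", "cam0", kb2c, +2),        list("cam4", "cam2n", kb2c, +2),
    list("cam0", "cam2n", kf2n * ca^2, -2), list("cam2c", "cam4", kf2n * ca^2, -2),
    list("cam2n", "cam0", kb2n, +2),        list("cam4", "cam2c", kb2n, +2),
    list("kcam0", "kcam2c", kfk2c * ca^2, -2), list("kcam2n", "kcam4", kfk2c * ca^2, -2),
    list("kcam2c", "kcam0", kbk2c, +2),     list("kcam4", "kcam2n", kbk2c, +2),
    list("kcam0", "kcam2n", kfk2n * ca^2, -2), list("kcam2c", "kcam4", kfk2n * ca^2, -2),
    list("kcam2n", "kcam0", kbk2n, +2),     list("kcam4", "kcam2c", kbk2n, +2),
    list(c("cam0", "mkcam"), "kcam0", p$kf_cam0, 0),
    list(c("cam2c", "mkcam"), "kcam2c", p$kf_cam2c, 0),
    list(c("cam2n", "mkcam"), "kcam2n", p$kf_cam2n, 0),
    list(c("cam4", "mkcam"), "kcam4", p$kf_cam4, 0),
    list("kcam0", c("cam0", "mkcam"), p$kb_cam0, 0),
    list("kcam2c", c("cam2c", "mkcam"), p$kb_cam2c, 0),
    list("kcam2n", c("cam2n", "mkcam"), p$kb_cam2n, 0),
    list("kcam4", c("cam4", "mkcam"), p$kb_cam4, 0),
    list("kcam0", "pcam0", NA, 0), list("kcam2c", "pcam2c", NA, 0),
    list("kcam2n", "pcam2n", NA, 0), list("kcam4", "pcam4", NA, 0),
    list("pcam0", c("p", "cam0"), k2, 0), list("pcam2c", c("p", "cam2c"), k2, 0),
    list("pcam2n", c("p", "cam2n"), k2, 0), list("pcam4", c("p", "cam4"), k2, 0),
    list("p", "mkcam", k3, 0), list("p", "p2", p$k4, 0), list("p2", "p", k5, 0),
    list(c("cam4", "mcan"), "can4", p$kf_can * tf_cn$rho_f, 0),
    list("can4", c("cam4", "mcan"), p$kb_can * tf_cn$rho_b, 0)
  )
}

oracle_deriv <- function(state, ca, p) {
  rx <- oracle_reactions(p, ca)
  kin <- c("kcam0", "kcam2c", "kcam2n", "kcam4",
           "pcam0", "pcam2c", "pcam2n", "pcam4", "p", "p2")
  Ffrac <- sum(state[kin]) / p$kcam_total
  k1f <- p$k1 * Ffrac
  d <- stats::setNames(numeric(length(state)), names(state))
  ca_flux <- 0
  for (r in rx) {
    rate <- if (is.na(r[[3]])) k1f else r[[3]]
    flux <- rate * prod(state[r[[1]]])
    d[r[[1]]] <- d[r[[1]]] - flux
    d[r[[2]]] <- d[r[[2]]] + flux
    ca_flux <- ca_flux + r[[4]] * flux
  }
  attr(d, "ca_flux") <- ca_flux
  d
}

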