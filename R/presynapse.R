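# Stochastic two-pool vesicle dynamics and release-probability model.
#
# Vesicles sit in a docked pool (D, capacity 25) with fast release and a
# reserve pool (R, capacity 30) that refills it. Each presynaptic spike
# updates a phenomenological presynaptic calcium resource and may release one
# vesicle with probability p_rel; glutamate (and co-released GABA) pulse
# amplitudes are gamma-distributed around 1 mM. The whole presynaptic side is
# simulated ahead of the postsynaptic run and depends only on the protocol,
# the conditions and its own random stream.

#' Release-probability half-activation threshold
#'
#' @param ca_o Extracellular calcium in mM.
#' @return Dimensionless threshold h, decreasing in `ca_o`, bounded in
#'   (0.654, 2.003).
#' @examples
#' release_threshold(2.5)
#' @export
release_threshold <- function(ca_o) {
  stopifnot(all(ca_o > 0))
  0.654 + 1.349 / (1 + exp(4 * (ca_o - 1.708)))
}

#' Vesicle release probability
#'
#' Hill function (exponent 2) of the presynaptic calcium resource with
#' calcium-dependent threshold, gated by docked-pool availability.
#'
#' @param ca_pre Presynaptic calcium resource (dimensionless; 1 immediately
#'   after a first spike from rest).
#' @param ca_o Extracellular calcium in mM.
#' @param docked Number of docked vesicles.
#' @return Probability in `[0, 1)`.
#' @examples
#' release_probability(1, 2.5, 25) # ~0.67, the "initial release probability"
#' @export
release_probability <- function(ca_pre, ca_o, docked) {
  h <- release_threshold(ca_o)
  ifelse(docked > 0, ca_pre^2 / (ca_pre^2 + h^2), 0)
}

#' Transition propensities of the two-pool vesicle system
#'
#' @param docked,reserve Current pool occupancies.
#' @param params A [synapse_params()] list.
#' @return Named numeric vector of rates (s^-1): `refill` (reserve -> docked),
#'   `mixing` (docked -> reserve), `replenish` (external -> reserve).
#' @export
pool_propensities <- function(docked, reserve, params = synapse_params()) {
  stopifnot(docked >= 0, docked <= params$d0, reserve >= 0, reserve <= params$r0)
  c(refill = (params$d0 - docked) * reserve / params$tau_docked,
    mixing = (params$r0 - reserve) * docked / params$tau_reserve,
    replenish = (params$r0 - reserve) / params$tau_reserve_ref)
}

# advance the (docked, reserve) jump process by `dt` with Gillespie sampling
advance_pools <- function(docked, reserve, dt, params) {
  t <- 0
  repeat {
    a <- pool_propensities(docked, reserve, params)
    total <- sum(a)
    if (total <= 0) break
    t <- t + stats::rexp(1, total)
    if (t > dt) break
    u <- stats::runif(1) * total
    if (u < a[1]) {
      docked <- docked + 1; reserve <- reserve - 1
    } else if (u < a[1] + a[2]) {
      docked <- docked - 1; reserve <- reserve + 1
    } else {
      reserve <- reserve + 1
    }
  }
  c(docked, reserve)
}

# integrate the (ca_pre, ca_jump) resource ODE over dt (no spikes inside);
# ca_pre decays exactly; ca_jump by RK4 on its scalar ODE with ca_pre(t) known
advance_ca_pre <- function(ca_pre, ca_jump, dt, params) {
  if (dt <= 0) return(c(ca_pre, ca_jump))
  n <- max(1L, ceiling(dt / 5e-3))
  h <- dt / n
  tp <- params$tau_pre; tr <- params$tau_rec_jump; dca <- params$delta_ca
  for (i in seq_len(n)) {
    cp0 <- ca_pre
    f <- function(cj, cp) (1 - cj) / tr - dca * cj * cp
    k1 <- f(ca_jump, cp0)
    cp_half <- cp0 * exp(-h / (2 * tp))
    k2 <- f(ca_jump + h / 2 * k1, cp_half)
    k3 <- f(ca_jump + h / 2 * k2, cp_half)
    cp1 <- cp0 * exp(-h / tp)
    k4 <- f(ca_jump + h * k3, cp1)
    ca_jump <- ca_jump + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    ca_pre <- cp1
  }
  c(ca_pre, ca_jump)
}

#' Simulate the presynaptic side of a protocol
#'
#' Runs the stochastic two-pool vesicle dynamics and the presynaptic calcium
#' resource over the presynaptic spike train, drawing a release decision and a
#' glutamate amplitude for each spike. When `conditions$evoked_ap` is set, the
#' EPSP-evoked action-potential test is also evaluated at each presynaptic
#' spike (25 release draws, evoke if more than 80% succeed) and successful
#' evocations are returned as extra postsynaptic spike times delayed by 15 ms.
#'
#' @param protocol A [build_protocol()] object (or any list with sorted
#'   numeric `pre_times`).
#' @param conditions A [experimental_conditions()] object.
#' @param params Optional pre-built [synapse_params()].
#' @param force_release Force every spike to release (uncaging-style
#'   stimulation); glutamate amplitude variability follows
#'   `conditions$glu_cv_mode`.
#' @return A tibble with one row per presynaptic spike: `time`, `ca_pre`,
#'   `p_rel`, `released`, `docked`, `reserve` (pool states after the spike),
#'   `glu` (pulse amplitude in uM, 0 if no release), `evoked_ap`. The tibble
#'   carries the evoked AP times in `attr(, "evoked_ap_times")`.
#' @examples
#' set.seed(1)
#' pre <- presyn_simulate(build_protocol("1Pre, 10 at 5 Hz"), experimental_conditions())
#' mean(pre$released)
#' @export
presyn_simulate <- function(protocol, conditions = experimental_conditions(),
                            params = synapse_params(conditions),
                            force_release = FALSE) {
  pre <- protocol$pre_times
  n <- length(pre)
  docked <- params$d0; reserve <- params$r0
  ca_pre <- 0; ca_jump <- 1; v_evoke <- 0
  t_now <- 0
  det_release <- "release" %in% conditions$deterministic_sources
  out <- vector("list", n)
  evoked <- numeric(0)
  for (i in seq_len(n)) {
    dt <- pre[i] - t_now
    ds <- advance_pools(docked, reserve, dt, params)
    docked <- ds[1]; reserve <- ds[2]
    cc <- advance_ca_pre(ca_pre, ca_jump, dt, params)
    ca_pre <- cc[1]; ca_jump <- cc[2]
    v_evoke <- v_evoke * exp(-dt / params$tau_v_evoke) + 1
    t_now <- pre[i]
    # spike: calcium jump, then release test
    ca_pre <- ca_pre + ca_jump
    p <- release_probability(ca_pre, params$ca_o, docked)
    if (force_release) {
      released <- TRUE
    } else if (det_release) {
      released <- p >= 0.5
    } else {
      released <- stats::runif(1) < p
    }
    glu <- 0
    if (released && docked > 0) {
      docked <- docked - 1
      mode <- if (det_release) "none" else conditions$glu_cv_mode
      glu <- params$glu_amp * glu_amplitude_factor(1, mode)
    } else {
      released <- FALSE
    }
    ap <- FALSE
    if (conditions$evoked_ap) {
      ap <- evoked_ap_test(v_evoke, params$ca_o, docked)
      if (ap) evoked <- c(evoked, pre[i] + params$delay_ap)
    }
    out[[i]] <- c(pre[i], ca_pre, p, released, docked, reserve, glu, ap)
  }
  res <- tibble::as_tibble(do.call(rbind, out), .name_repair = "minimal")
  if (n == 0) {
    res <- tibble::tibble(time = numeric(), ca_pre = numeric(), p_rel = numeric(),
                          released = logical(), docked = numeric(),
                          reserve = numeric(), glu = numeric(), evoked_ap = logical())
  } else {
    names(res) <- c("time", "ca_pre", "p_rel", "released", "docked", "reserve",
                    "glu", "evoked_ap")
    res$released <- as.logical(res$released)
    res$evoked_ap <- as.logical(res$evoked_ap)
  }
  attr(res, "evoked_ap_times") <- evoked
  res
}

# gamma-distributed amplitude factor with mean 1
glu_amplitude_factor <- function(n, mode) {
  switch(mode,
    as_printed = stats::rgamma(n, shape = 1 / 0.52, scale = 0.52),
    cv_052 = stats::rgamma(n, shape = 1 / 0.52^2, scale = 0.52^2),
    none = rep(1, n))
}

#' Draw a release event for a single spike
#'
#' Low-level single-spike version of [presyn_simulate()]: Bernoulli release at
#' the supplied probability, gamma-distributed glutamate amplitude on success.
#'
#' @param p_rel Release probability.
#' @param params A [synapse_params()] list.
#' @param glu_cv_mode Amplitude variability mode (see
#'   [experimental_conditions()]).
#' @return List with `released` (logical) and `glu` (amplitude, uM).
#' @export
sample_release <- function(p_rel, params = synapse_params(),
                           glu_cv_mode = "as_printed") {
  released <- stats::runif(1) < p_rel
  list(released = released,
       glu = if (released) params$glu_amp * glu_amplitude_factor(1, glu_cv_mode) else 0)
}
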