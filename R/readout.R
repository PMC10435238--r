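# Geometric plasticity readout: polygonal LTP/LTD regions in the
# (CaN, CaMKII) activity plane, leaky activation variables, sigmoidal
# transition rates and the 100-process plasticity Markov chain.

#' Plasticity-region membership
#'
#' Tests points of the (CaN, CaMKII) plane for membership of the LTP and LTD
#' polygons. Boundary points count as inside; the regions do not overlap, so
#' at most one indicator is 1 for any point.
#'
#' @param can,camkii Active CaN and CaMKII (uM); vectors of equal length.
#' @param ltp,ltd Region polygons (two-column vertex matrices); default the
#'   fitted regions [ltp_region()] and [ltd_region()].
#' @return Tibble with logical columns `in_ltp`, `in_ltd`.
#' @examples
#' region_indicator(8, 15)   # inside LTP
#' region_indicator(2, 12)   # inside LTD
#' @export
region_indicator <- function(can, camkii, ltp = ltp_region(), ltd = ltd_region()) {
  stopifnot(length(can) == length(camkii))
  m <- cpp_region_indicator(as.numeric(can), as.numeric(camkii), ltp, ltd)
  tibble::tibble(in_ltp = m[, 1], in_ltd = m[, 2])
}

#' Leaky activation derivatives
#'
#' The activation variables integrate region occupancy: linear growth at rate
#' `a` while the enzyme trajectory is inside the region, exponential decay at
#' rate `b` outside.
#'
#' @param act_d,act_p Current activation levels (a.u.).
#' @param in_ltd,in_ltp Logical region indicators.
#' @param params A [synapse_params()] list.
#' @return Named vector of derivatives (a.u./s).
#' @export
activation_derivatives <- function(act_d, act_p, in_ltd, in_ltp,
                                   params = synapse_params()) {
  c(d_act_d = params$a_d * as.numeric(in_ltd) -
      params$b_d * (1 - as.numeric(in_ltd)) * act_d,
    d_act_p = params$a_p * as.numeric(in_ltp) -
      params$b_p * (1 - as.numeric(in_ltp)) * act_p)
}

#' Plasticity transition rates
#'
#' Sigmoidal (Hill, exponent 2) functions of the activation variables, bounded
#' by the reciprocal LTP/LTD time constants. The LTP transition is fast
#' (1/13 s^-1 ceiling), the LTD transition slow (1/18 s^-1 ceiling with a much
#' larger half-activation), so depression requires far longer region dwell.
#'
#' @param act_p,act_d Activation levels (a.u.).
#' @param params A [synapse_params()] list.
#' @return Named vector `c(p_rate, d_rate)` in s^-1.
#' @examples
#' plasticity_rates(1.3e4, 0) # p_rate at half activation = 1/(2*13)
#' @export
plasticity_rates <- function(act_p, act_d, params = synapse_params()) {
  c(p_rate = act_p^2 / (act_p^2 + params$k_p^2) / params$t_p,
    d_rate = act_d^2 / (act_d^2 + params$k_d^2) / params$t_d)
}

#' Transition propensities of the plasticity chain
#'
#' The chain LTD <-> NC <-> LTP moves each of its 100 processes toward LTP at
#' `p_rate` (transitions LTD -> NC and NC -> LTP) and toward LTD at `d_rate`
#' (LTP -> NC and NC -> LTD); the total process count is conserved.
#'
#' @param nc,ltp,ltd State counts (sum 100).
#' @param p_rate,d_rate Per-process rates (s^-1).
#' @return Named vector of the four transition propensities (s^-1).
#' @export
chain_propensities <- function(nc, ltp, ltd, p_rate, d_rate) {
  stopifnot(nc >= 0, ltp >= 0, ltd >= 0)
  c(nc_to_ltp = nc * p_rate, ltd_to_nc = ltd * p_rate,
    ltp_to_nc = ltp * d_rate, nc_to_ltd = nc * d_rate)
}

#' Synaptic weight change of a plasticity-chain state
#'
#' Each process represents a 1% change of synaptic strength; the outcome is
#' the LTP count minus the LTD count.
#'
#' @param ltp,ltd Counts of processes in the LTP and LTD states.
#' @return Weight change in percent, in `[-100, 100]`.
#' @export
weight_change <- function(ltp, ltd) ltp - ltd

#' Run the plasticity readout on an enzyme activity trajectory
#'
#' Standalone readout: consumes a (time, CaN, CaMKII) trajectory sampled on a
#' grid (10 ms resolution suffices), integrates the leaky activations exactly
#' over each grid interval, and samples the stochastic plasticity chain with
#' rates frozen per interval. This reproduces what the full simulation engine
#' does internally, and allows the readout to be reused on externally
#' generated enzyme trajectories.
#'
#' @param activity Data frame with columns `time` (s), `can`, `camkii` (uM).
#' @param params A [synapse_params()] list.
#' @param extend_to Optionally continue the readout beyond the last sample
#'   (holding the enzyme state fixed) until this time, letting slow LTD
#'   transitions complete.
#' @return A tibble with per-interval columns `time`, `in_ltp`, `in_ltd`,
#'   `act_p`, `act_d`, `p_rate`, `d_rate`, `nc`, `ltp`, `ltd`, `weight`.
#' @examples
#' act <- tibble::tibble(time = seq(0, 10, 0.01), can = 8, camkii = 15)
#' out <- readout_classify(act)
#' tail(out$weight, 1)
#' @export
readout_classify <- function(activity, params = synapse_params(), extend_to = NULL) {
  stopifnot(all(c("time", "can", "camkii") %in% names(activity)))
  tt <- activity$time
  can <- activity$can
  camkii <- activity$camkii
  if (!is.null(extend_to) && extend_to > max(tt)) {
    dt0 <- if (length(tt) > 1) stats::median(diff(tt)) else 0.01
    extra <- seq(max(tt) + dt0, extend_to, by = dt0)
    tt <- c(tt, extra)
    can <- c(can, rep(can[length(can)], length(extra)))
    camkii <- c(camkii, rep(camkii[length(camkii)], length(extra)))
  }
  ind <- region_indicator(can, camkii, params$ltp_polygon, params$ltd_polygon)
  n <- length(tt)
  act_p <- act_d <- p_r <- d_r <- numeric(n)
  nc <- integer(n); ltp <- integer(n); ltd <- integer(n)
  nc[1] <- params$n_processes
  ap <- 0; ad <- 0; s_nc <- params$n_processes; s_ltp <- 0L; s_ltd <- 0L
  for (i in seq_len(n)) {
    dt <- if (i == 1) 0 else tt[i] - tt[i - 1]
    ap <- if (ind$in_ltp[i]) ap + params$a_p * dt else ap * exp(-params$b_p * dt)
    ad <- if (ind$in_ltd[i]) ad + params$a_d * dt else ad * exp(-params$b_d * dt)
    r <- plasticity_rates(ap, ad, params)
    # frozen-rate jumps over the interval
    if (dt > 0 && (r[1] > 0 || r[2] > 0)) {
      t0 <- 0
      repeat {
        a <- chain_propensities(s_nc, s_ltp, s_ltd, r[1], r[2])
        tot <- sum(a)
        if (tot <= 0) break
        t0 <- t0 + stats::rexp(1, tot)
        if (t0 > dt) break
        u <- stats::runif(1) * tot
        if (u < a[1]) { s_nc <- s_nc - 1; s_ltp <- s_ltp + 1 }
        else if (u < a[1] + a[2]) { s_ltd <- s_ltd - 1; s_nc <- s_nc + 1 }
        else if (u < a[1] + a[2] + a[3]) { s_ltp <- s_ltp - 1; s_nc <- s_nc + 1 }
        else { s_nc <- s_nc - 1; s_ltd <- s_ltd + 1 }
      }
    }
    act_p[i] <- ap; act_d[i] <- ad; p_r[i] <- r[1]; d_r[i] <- r[2]
    nc[i] <- s_nc; ltp[i] <- s_ltp; ltd[i] <- s_ltd
  }
  tibble::tibble(time = tt, in_ltp = ind$in_ltp, in_ltd = ind$in_ltd,
                 act_p = act_p, act_d = act_d, p_rate = p_r, d_rate = d_r,
                 nc = nc, ltp = ltp, ltd = ltd, weight = ltp - ltd)
}
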