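test_that("R and C++ rate matrices agree for every channel", {
  p <- the_params
  for (glu in c(0, 100, 1000)) {
    expect_equal(unname(ampar_rates(glu, 35, p)),
                 spinesim:::cpp_channel_matrix("ampa", glu, -70, p),
                 tolerance = 1e-12)
    expect_equal(unname(nmdar_rates(glu, 35, "glun2a", p)),
                 spinesim:::cpp_channel_matrix("glun2a", glu, -70, p),
                 tolerance = 1e-12)
    expect_equal(unname(nmdar_rates(glu, 35, "glun2b", p)),
                 spinesim:::cpp_channel_matrix("glun2b", glu, -70, p),
                 tolerance = 1e-12)
    expect_equal(unname(gabar_rates(glu, 35, p)),
                 spinesim:::cpp_channel_matrix("gaba", glu, -70, p),
                 tolerance = 1e-12)
  }
  for (v in c(-70, -30, 10)) {
    expect_equal(unname(vgcc_rates(v, 35, "L", p)),
                 spinesim:::cpp_channel_matrix("vgccL", 0, v, p), tolerance = 1e-12)
    g <- vgcc_rates(v, 35, "T", p)
    Q <- spinesim:::cpp_channel_matrix("vgccT", 0, v, p)
    expect_equal(Q[1, 2], g$alpha_m, tolerance = 1e-12)
    expect_equal(Q[2, 1], g$beta_m, tolerance = 1e-12)
    expect_equal(Q[1, 3], g$beta_h, tolerance = 1e-12)
    expect_equal(Q[3, 1], g$alpha_h, tolerance = 1e-12)
  }
})

test_that("AMPAr scheme has glutamate-gated binding and table conductances", {
  Q0 <- ampar_rates(0, 35, the_params)
  expect_true(all(Q0["C0", c("C1")] == 0))
  expect_true(all(Q0[c("D0", "D1"), c("D1", "D2")][c(1, 4)] == 0))
  expect_identical(c(the_params$gamma_a2, the_params$gamma_a3, the_params$gamma_a4),
                   c(0.0155, 0.026, 0.0365))
  # one fully-liganded open receptor at rest
  expect_equal(ampar_current(c(0, 0, 1), -70, the_params), 0.0365 * 70,
               tolerance = 1e-9)
  expect_identical(ampar_current(c(5, 5, 5), 0, the_params), 0)
  expect_identical(ampar_current(c(0, 0, 0), -70, the_params), 0)
})

test_that("AMPAr paired-pulse desensitisation recovers with interval", {
  p <- the_params
  Q_on <- spinesim:::rate_generator(ampar_rates(5000, 35, p))
  Q_off <- spinesim:::rate_generator(ampar_rates(0, 35, p))
  step <- function(pv, Q, dt) as.vector(as.matrix(Matrix::expm(Matrix::Matrix(t(Q) * dt))) %*% pv)
  pulse_peak <- function(pv) {
    peaks <- numeric(0)
    for (k in 1:20) {
      pv <- step(pv, Q_on, 1e-3)
      peaks <- c(peaks, sum(pv[6:8]))
    }
    list(peak = max(peaks), state = pv)
  }
  p0 <- c(1, rep(0, 15))
  first <- pulse_peak(p0)
  peak2 <- vapply(c(0.02, 0.1, 0.3), function(gap) {
    pulse_peak(step(first$state, Q_off, gap))$peak
  }, numeric(1))
  expect_true(all(peak2 < first$peak))
  expect_true(all(diff(peak2) > 0))  # monotone recovery with interval
})

test_that("NMDAr chains use the printed subtype fractions and decay ~5x apart", {
  p <- the_params
  Qa <- nmdar_rates(1000, 35, "glun2a", p)
  Qb <- nmdar_rates(1000, 35, "glun2b", p)
  expect_equal(Qb["B2", "B3"] / Qa["A2", "A3"], 0.25, tolerance = 1e-12)
  expect_equal(Qb["B3", "B2"] / Qa["A3", "A2"], 0.23, tolerance = 1e-12)
  expect_equal(Qb["B2", "B3"], 0.25 * 127 * spinesim:::effective_factors(35, "NMDA")$rho_f,
               tolerance = 1e-9)
  tau_a <- cached("tau_glun2a_35", channel_decay_tau("glun2a", 35, t_max = 0.6,
                                                     dt = 2e-4, params = p))
  tau_b <- cached("tau_glun2b_35", channel_decay_tau("glun2b", 35, t_max = 2.5,
                                                     dt = 5e-4, params = p))
  expect_gt(tau_b / tau_a, 4)
  expect_lt(tau_b / tau_a, 6.5)
})

test_that("magnesium block matches its closed form", {
  expect_identical(mg_block(-70, 0), 1)
  expect_equal(mg_block(0, 1), 0.781, tolerance = 1e-3)
  expect_equal(mg_block(-70, 1), 0.0445, tolerance = 1e-3)
  v <- seq(-90, 20, 5)
  expect_true(all(diff(mg_block(v, 1.3)) > 0))
})

test_that("GABA(A)r current polarity flips across development", {
  # young: chloride reversal above rest -> depolarizing
  expect_gt(gabar_current(5, -70, age = 5, the_params), 0)
  # adult: hyperpolarizing
  expect_lt(gabar_current(5, -70, age = 60, the_params), 0)
  expect_identical(gabar_current(0, -70, 60, the_params), 0)
})

test_that("VGCC gate rates hit their printed midpoints", {
  p <- the_params
  gT <- vgcc_rates(-32, 35, "T", p)
  # m_inf(T) = 0.5 at -32 mV: unscaled alpha and beta are equal there
  tf <- temperature_factors(35, "VGCC")
  expect_equal(gT$alpha_m / tf$rho_f, gT$beta_m / tf$rho_b, tolerance = 1e-9)
  gTh <- vgcc_rates(-70, 35, "T", p)
  expect_equal(gTh$alpha_h / tf$rho_f, gTh$beta_h / tf$rho_b, tolerance = 1e-9)
  QL <- vgcc_rates(13.7, 35, "L", p)
  expect_equal(QL["C", "O1"], 1e3 * 0.83 / 2 * tf$rho_f, tolerance = 1e-6)
})

test_that("SK channel activates on calcium and reverses at -90 mV", {
  p <- the_params
  # Hill midpoint of the activation function
  r_mid <- 0.333^6 / (0.333^6 + 0.333^6)
  expect_identical(r_mid, 0.5)
  expect_identical(sk_current(0.5, -90, p), 0)
  expect_lt(sk_current(0.5, -20, p), 0)    # hyperpolarizing above reversal
  # at zero calcium the activation relaxes to zero
  expect_lt(sk_derivative(0.5, 0, 35, p), 0)
  expect_equal(sk_derivative(0, 0, 35, p), 0, tolerance = 1e-12)
})

test_that("jump-engine stationary occupancancy matches the analytic distribution", {
  p <- the_params
  Q <- gabar_rates(100, 35, p)
  G <- spinesim:::rate_generator(Q)
  # analytic stationary distribution of the 5-state chain
  A <- rbind(t(G), rep(1, 5))
  pi_hat <- as.vector(qr.solve(A, c(rep(0, 5), 1)))
  set.seed(21)
  dw <- spinesim:::cpp_dwell_times(unname(Q), 0L, t_end = 60, dt = 5e-4)
  occ <- tapply(dw[, "dwell"], factor(dw[, "state"], levels = 0:4), sum)
  occ[is.na(occ)] <- 0
  occ <- occ / sum(occ)
  expect_gt(nrow(dw), 1e4)
  # time-fraction occupancy within 2% absolute of the stationary law
  expect_lt(max(abs(occ - pi_hat)), 0.02)
})
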