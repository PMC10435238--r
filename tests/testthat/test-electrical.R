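test_that("soma gate rates evaluate their singular points by series limit", {
  r <- soma_gate_rates(-30)
  expect_equal(r$alpha_m, 1e3 * 0.4 * 7.2, tolerance = 1e-6)
  expect_equal(soma_gate_rates(13)$n_inf, 0.5, tolerance = 1e-12)
  v <- seq(-100, 60, by = 1)
  taus <- soma_gate_rates(v)$n_tau
  expect_true(all(taus >= 2e-3))  # printed 2 ms floor
  rates <- soma_gate_rates(v)
  expect_true(all(rates$alpha_m >= 0 & rates$beta_m >= 0 &
                    rates$alpha_h >= 0 & rates$beta_h >= 0))
  # continuity across the removable singularity at -30 mV
  expect_equal(soma_gate_rates(-30 + 1e-7)$alpha_m, r$alpha_m, tolerance = 1e-4)
})

test_that("R and engine soma gate rates agree", {
  for (v in c(-80, -45.000001, -30, 0, 40)) {
    r <- soma_gate_rates(v)
    cpp <- spinesim:::cpp_soma_rates(v)
    expect_equal(r$alpha_m, cpp$alpha_m, tolerance = 1e-10)
    expect_equal(r$beta_h, cpp$beta_h, tolerance = 1e-10)
    expect_equal(r$n_tau, cpp$n_tau, tolerance = 1e-10)
  }
})

test_that("the BaP coupling conductance follows its product form", {
  expect_equal(g_bap_adapt(1, 230.3), 40, tolerance = 1e-6)
  expect_equal(g_bap_adapt(0.7, 230.3), 28, tolerance = 1e-6)
  expect_equal(g_bap_adapt(1, 1e6), 5, tolerance = 1e-6)
})

test_that("BaP injection is a sum of rectangular pulses", {
  posts <- c(0.1, 0.101)
  expect_identical(bap_injection(0.05, posts, 1000, 2e-3), 0)
  expect_identical(bap_injection(0.1005, posts, 1000, 2e-3), 1000)
  expect_identical(bap_injection(0.1015, posts, 1000, 2e-3), 2000)  # overlap sums
})

test_that("attenuation resources rest at 1 and recover as printed", {
  p <- the_params
  d <- bap_adaptation_derivatives(1, 1, 1, i_bap = 0, p)
  expect_equal(unname(d), c(0, 0, 0))
  d2 <- bap_adaptation_derivatives(0.5, 1, 1, 0, p)
  expect_equal(unname(d2["d_lambda"]), 0.25, tolerance = 1e-12)  # (1-0.5)/2 s
  expect_lt(unname(bap_adaptation_derivatives(1, 1, 1, 1000, p)["d_lambda"]), 0)
})

test_that("membrane potentials rest at the leak reversal with no input", {
  p <- the_params
  v <- list(v_sp = -70, v_dend = -70, v_soma = -70)
  r <- soma_gate_rates(-70)
  gates <- list(m = r$alpha_m / (r$alpha_m + r$beta_m),
                h = r$alpha_h / (r$alpha_h + r$beta_h), n = r$n_inf)
  cur <- list(i_sp = 0, i_gaba = 0, i_bap = 0)
  adapt <- list(lambda = 1, lambda_age = 1)
  d <- membrane_derivatives(v, gates, cur, adapt, p)
  expect_equal(unname(d["d_v_sp"]), 0, tolerance = 1e-9)
  expect_equal(unname(d["d_v_dend"]), 0, tolerance = 1e-9)
  # soma has a small standing gate leak; bounded drift
  expect_lt(abs(unname(d["d_v_soma"])), 600)
  # a 10 mV dendrite-spine gradient drives ~39.2 pA through the neck
  v2 <- list(v_sp = -70, v_dend = -60, v_soma = -70)
  d2 <- membrane_derivatives(v2, gates, cur, adapt, p)
  expect_equal(unname(d2["d_v_sp"]) * p$c_sp / 1e3, 3.92 * 10, tolerance = 1e-6)
})

test_that("evoked-AP decisions follow the exact binomial tail", {
  # degenerate probabilities
  expect_true(evoked_ap_test(1e9, 2.5, 10))
  set.seed(19)
  expect_false(any(vapply(1:50, function(i) evoked_ap_test(0, 2.5, 10), logical(1))))
  # p = 0.9: evoke probability is P(Bin(25, 0.9) >= 21)
  p_target <- 0.9
  h <- release_threshold(2.5)
  v_evoke <- h * sqrt(p_target / (1 - p_target))  # invert the Hill form
  expect_equal(release_probability(v_evoke, 2.5, 10), p_target, tolerance = 1e-9)
  hits <- mean(vapply(1:4000, function(i) evoked_ap_test(v_evoke, 2.5, 10),
                      logical(1)))
  exact <- 1 - stats::pbinom(20, 25, p_target)
  expect_equal(hits, exact, tolerance = 0.05)
})

test_that("dendritic BaP amplitude attenuates with distance from the soma", {
  amps <- vapply(c(50, 200, 400), function(d) {
    cond <- experimental_conditions(d_soma = d, deterministic_sources = "all")
    sim <- cached(paste0("bap_d", d), {
      simulate_synapse(spinesim:::new_protocol(numeric(0), 0.02), cond,
                       n_samples = 1, seed = 1, relax = 0.1,
                       control = fast_ctrl)
    })
    max(sim$trajectory$v_dend) + 70
  }, numeric(1))
  expect_true(all(diff(amps) < 0))
})

test_that("repeated BaPs at 100 Hz attenuate successively at the soma", {
  cond <- experimental_conditions(deterministic_sources = "all")
  proto <- spinesim:::new_protocol(numeric(0), seq(0.02, by = 0.01, length.out = 5))
  sim <- cached("bap_5x100", {
    simulate_synapse(proto, cond, n_samples = 1, seed = 1, relax = 0.1,
                     control = fast_ctrl)
  })
  pk <- sim$pulse_peaks$v_soma_peak
  expect_length(pk, 5)
  expect_lt(pk[5], pk[1])
  # lambda stays in (0, 1] and recovers toward 1 afterwards
  lam <- sim$trajectory$lambda
  expect_true(all(lam > 0 & lam <= 1 + 1e-9))
})
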