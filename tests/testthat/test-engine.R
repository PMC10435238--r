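test_that("simulations are fully reproducible from the seed", {
  proto <- build_protocol("1Pre1Post10, 3 at 5 Hz")
  s1 <- simulate_synapse(proto, the_cond, n_samples = 1, seed = 99, relax = 2,
                         control = fast_ctrl)
  s2 <- simulate_synapse(proto, the_cond, n_samples = 1, seed = 99, relax = 2,
                         control = fast_ctrl)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$outcomes$weight, s2$outcomes$weight)
  s3 <- simulate_synapse(proto, the_cond, n_samples = 1, seed = 100, relax = 2,
                         control = fast_ctrl)
  expect_false(identical(s1$trajectory$ca, s3$trajectory$ca))
})

test_that("constant-rate dwell times from the jump sampler are exponential", {
  kon <- 40; koff <- 90
  Q <- matrix(c(0, kon, koff, 0), 2, 2, byrow = TRUE)
  set.seed(12)
  dw <- spinesim:::cpp_dwell_times(Q, 0L, t_end = 160, dt = 1e-3)
  dw <- dw[-nrow(dw), , drop = FALSE]  # drop the censored terminal sojourn
  d0 <- dw[dw[, "state"] == 0, "dwell"]
  d1 <- dw[dw[, "state"] == 1, "dwell"]
  expect_gt(length(d0), 1e3)
  expect_gt(stats::ks.test(d0, "pexp", rate = kon)$p.value, 0.01)
  expect_gt(stats::ks.test(d1, "pexp", rate = koff)$p.value, 0.01)
  expect_equal(mean(d0), 1 / kon, tolerance = 0.05)
  expect_equal(mean(d1), 1 / koff, tolerance = 0.05)
})

test_that("an empty protocol stays at rest with zero weight change", {
  sim <- cached("empty_rest", {
    simulate_synapse(spinesim:::new_protocol(numeric(0), numeric(0)), the_cond,
                     n_samples = 2, seed = 8, duration = 5, relax = 0,
                     control = fast_ctrl)
  })
  tr <- sim$trajectory
  expect_true(all(abs(tr$v_sp + 70) < 2))
  expect_true(all(abs(tr$v_soma + 70) < 2))
  expect_true(all(sim$outcomes$weight == 0))
  expect_true(all(sim$outcomes$counts_conserved))
  # gates/fractions within bounds
  expect_true(all(tr$m_sk >= 0 & tr$m_sk <= 1))
  expect_true(all(tr$lambda > 0 & tr$lambda <= 1 + 1e-9))
})

test_that("voltages and counts stay bounded through strong stimulation", {
  sim <- cached("pair_run", {
    simulate_synapse(build_protocol("1Pre1Post10, 10 at 5 Hz"), the_cond,
                     n_samples = 2, seed = 13, relax = 2, control = fast_ctrl)
  })
  tr <- sim$trajectory
  expect_true(all(abs(tr$v_sp) < 200 & abs(tr$v_dend) < 200 & abs(tr$v_soma) < 200))
  expect_true(all(tr$ampa_open >= 0 & tr$ampa_open <= 120))
  expect_true(all(tr$glun2a_open + tr$glun2b_open <= 16))
  expect_true(all(tr$gaba_open >= 0 & tr$gaba_open <= 34))
  expect_true(all(tr$vgcc_t_open <= 3 & tr$vgcc_r_open <= 3 & tr$vgcc_l_open <= 3))
  expect_true(all(tr$ca >= 0))
  expect_true(all(sim$outcomes$counts_conserved))
  expect_identical(sum(sim$outcomes$neg_ca_events), 0L)
})

test_that("deterministic sources remove run-to-run variability", {
  cond_det <- experimental_conditions(deterministic_sources = "all")
  proto <- build_protocol("1Pre1Post10, 3 at 5 Hz")
  a <- simulate_synapse(proto, cond_det, n_samples = 1, seed = 1, relax = 1,
                        control = fast_ctrl)
  b <- simulate_synapse(proto, cond_det, n_samples = 1, seed = 2, relax = 1,
                        control = fast_ctrl)
  # different seeds, same mean-field trajectory
  expect_equal(a$trajectory$ca, b$trajectory$ca, tolerance = 1e-10)
  expect_equal(a$outcomes$weight, b$outcomes$weight)
})

test_that("halving the integration steps barely changes the outcome", {
  proto <- build_protocol("1Pre1Post10, 10 at 5 Hz")
  base <- simulate_synapse(proto, the_cond, n_samples = 3, seed = 4, relax = 30,
                           control = list(warmup_det = 50, warmup_stoch = 1))
  fine <- simulate_synapse(proto, the_cond, n_samples = 3, seed = 4, relax = 30,
                           control = list(warmup_det = 50, warmup_stoch = 1,
                                          dt_stim = 2.5e-5, dt_ap = 5e-6,
                                          dt_relax = 2.5e-4))
  expect_lt(abs(mean(base$outcomes$weight) - mean(fine$outcomes$weight)), 1.5)
  # enzyme trajectories track closely between resolutions
  i <- seq(1, nrow(base$trajectory), by = 25)
  expect_equal(base$trajectory$camkii[i], fine$trajectory$camkii[i],
               tolerance = 0.15)
})

test_that("a causal pairing yields a calcium transient larger than either input", {
  pre_only <- cached("ca_pre_only", {
    simulate_synapse(build_protocol("1Pre"), the_cond, n_samples = 6, seed = 31,
                     relax = 0.4, force_release = TRUE, control = fast_ctrl)
  })
  post_only <- cached("ca_post_only", {
    simulate_synapse(spinesim:::new_protocol(numeric(0), 0.0), the_cond,
                     n_samples = 6, seed = 31, relax = 0.4, control = fast_ctrl)
  })
  paired <- cached("ca_paired", {
    simulate_synapse(build_protocol("1Pre1Post10"), the_cond, n_samples = 6,
                     seed = 31, relax = 0.4, force_release = TRUE,
                     control = fast_ctrl)
  })
  expect_gt(mean(paired$outcomes$max_ca), mean(pre_only$outcomes$max_ca))
  expect_gt(mean(paired$outcomes$max_ca), mean(post_only$outcomes$max_ca))
})
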