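test_that("release threshold and probability match their closed forms", {
  expect_equal(release_threshold(1.708), 0.654 + 1.349 / 2, tolerance = 1e-6)
  expect_equal(release_threshold(2.5), 0.7085, tolerance = 1e-3)
  expect_equal(release_threshold(100), 0.654, tolerance = 1e-4)
  # gating by the docked pool
  expect_identical(release_probability(1, 2.5, docked = 0), 0)
  # design point: first spike from rest at 2.5 mM external calcium
  expect_equal(release_probability(1, 2.5, 25), 0.6658, tolerance = 1e-3)
  # Hill midpoint when the resource equals the threshold
  for (ca_o in c(1, 1.8, 2.5)) {
    expect_equal(release_probability(release_threshold(ca_o), ca_o, 5), 0.5,
                 tolerance = 1e-12)
  }
})

test_that("vesicle pool propensities vanish at capacity and match table values", {
  p <- the_params
  expect_equal(unname(pool_propensities(25, 30, p)), c(0, 0, 0))
  expect_equal(unname(pool_propensities(0, 30, p)[1]), 25 * 30 / 5)
  a <- pool_propensities(25, 0, p)
  expect_equal(unname(a[["mixing"]]), 30 * 25 / 45, tolerance = 1e-9)
  expect_equal(unname(a[["replenish"]]), 30 / 40, tolerance = 1e-9)
  expect_error(pool_propensities(26, 30, p))
})

test_that("presynaptic calcium resource jumps and decays as specified", {
  # one spike from rest: Capre = Cajump(0) = 1
  cc <- spinesim:::advance_ca_pre(0, 1, 0.5, the_params)
  expect_equal(cc[1], 0, tolerance = 1e-12)   # decayed from 0 stays 0
  # decay of the resource 10 ms after a lone spike
  cc <- spinesim:::advance_ca_pre(1, 1, 0.01, the_params)
  expect_equal(cc[1], exp(-0.01 / 0.02), tolerance = 1e-6)
  # (ca_pre = 0, ca_jump = 1) is a fixed point of the jump-size ODE
  cc <- spinesim:::advance_ca_pre(0, 1, 1.0, the_params)
  expect_equal(cc[2], 1, tolerance = 1e-9)
})

test_that("release sampling is Bernoulli with gamma-distributed amplitudes", {
  set.seed(42)
  expect_false(sample_release(0, the_params)$released)
  hits <- mean(vapply(1:10000, function(i) sample_release(0.5, the_params)$released,
                      logical(1)))
  expect_equal(hits, 0.5, tolerance = 0.025)
  amps <- replicate(4000, {
    r <- sample_release(1, the_params)
    r$glu
  })
  expect_equal(mean(amps), 1000, tolerance = 0.05)
  # as-printed gamma parameterisation: CV = sqrt(0.52)
  expect_equal(stats::sd(amps) / mean(amps), sqrt(0.52), tolerance = 0.1)
})

test_that("pool bounds hold along simulated paths and pools refill at rest", {
  set.seed(1)
  proto <- build_protocol("1Pre, 60 at 10 Hz")
  pre <- presyn_simulate(proto, the_cond, the_params)
  expect_true(all(pre$docked >= 0 & pre$docked <= 25))
  expect_true(all(pre$reserve >= 0 & pre$reserve <= 30))
  # a long quiescent gap refills the docked pool
  gap <- spinesim:::new_protocol(c(seq(0, 0.9, 0.1), 60), numeric(0))
  refilled <- vapply(1:40, function(i) {
    utils::tail(presyn_simulate(gap, the_cond, the_params)$docked, 1)
  }, numeric(1))
  expect_gte(mean(refilled >= 24), 0.8)
})

test_that("release probability depresses through a 5 Hz train", {
  set.seed(7)
  proto <- build_protocol("1Pre, 300 at 5 Hz")
  p_rel <- rowMeans(vapply(1:5, function(i)
    presyn_simulate(proto, the_cond, the_params)$p_rel, numeric(300)))
  early <- mean(p_rel[1:30])
  late <- mean(p_rel[271:300])
  expect_lt(late, early)
  # roughly monotone decline of the block means
  blocks <- colMeans(matrix(p_rel, nrow = 50))
  expect_true(all(diff(blocks) < 0.02))
})

test_that("deterministic release mode thresholds the release probability", {
  cond <- experimental_conditions(deterministic_sources = "release")
  set.seed(9)
  pre <- presyn_simulate(build_protocol("1Pre, 10 at 1 Hz"), cond,
                         synapse_params(cond))
  expect_identical(pre$released, pre$p_rel >= 0.5)
  # fixed amplitude under deterministic release
  expect_true(all(pre$glu[pre$released] == 1000))
})
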