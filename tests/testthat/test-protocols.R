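test_that("the protocol grammar lays out spike times exactly", {
  p <- build_protocol("1Pre1Post10, 300 at 5 Hz")
  expect_length(p$pre_times, 300)
  expect_equal(diff(p$pre_times), rep(0.2, 299))
  expect_equal(p$post_times, p$pre_times + 0.010)

  p2 <- build_protocol("1Pre2Post10, 2 at 5 Hz")
  expect_equal(p2$post_times, c(0.010, 0.020, 0.210, 0.220))

  p3 <- build_protocol("2Pre50, 900 at 3 Hz")
  expect_length(p3$pre_times, 1800)
  expect_equal(p3$pre_times[2] - p3$pre_times[1], 0.05)
  expect_equal(p3$pre_times[3], 1 / 3, tolerance = 1e-9)
  expect_length(p3$post_times, 0)

  # anticausal: delay measured from the last post spike to the pre spike
  p4 <- build_protocol("2Post1Pre50")
  expect_equal(p4$post_times, c(0, 0.010))
  expect_equal(p4$pre_times, 0.060)

  expect_error(build_protocol("Nonsense"), "cannot parse")
  expect_error(build_protocol("1Pre, 300"), "cannot parse")
})

test_that("theta-burst nesting yields the full spike count", {
  tbs <- build_tbs()
  expect_length(tbs$pre_times, 4 * 10 * 6)
  expect_equal(tbs$pre_times[1:4], c(0, 0.01, 0.02, 0.03))
  expect_equal(tbs$pre_times[5], 0.2)           # next burst at 5 Hz
  expect_equal(tbs$pre_times[41], 10)           # next epoch at 0.1 Hz
})

test_that("protocol builders are pure", {
  expect_identical(build_protocol("1Pre2Post50, 300 at 5 Hz"),
                   build_protocol("1Pre2Post50, 300 at 5 Hz"))
})

test_that("jitter perturbs spikes unbiasedly and inverts causality as predicted", {
  p <- build_protocol("1Pre1Post10, 300 at 5 Hz")
  expect_identical(apply_jitter(p, 0)$pre_times, p$pre_times)
  set.seed(11)
  n_inv <- 0; n_tot <- 0; shift <- numeric(0)
  for (k in 1:20) {
    j <- apply_jitter(p, 50)
    # pair i-th pre with i-th post of the unjittered layout via order statistics
    d <- sort(j$post_times) - sort(j$pre_times)
    n_inv <- n_inv + sum(d < 0); n_tot <- n_tot + length(d)
    shift <- c(shift, j$pre_times - p$pre_times)
  }
  # sorting re-pairs some spikes, so compare against the normal-difference
  # prediction P(N(10 ms, 2 * 50^2) < 0) = 0.444 with a generous band
  expect_equal(n_inv / n_tot, stats::pnorm(-10 / sqrt(2) / 50), tolerance = 0.12)
  expect_lt(abs(mean(shift)), 3 * 0.05 / sqrt(length(shift)))
})

test_that("sparsity removes spikes binomially", {
  p <- build_protocol("1Pre, 500 at 5 Hz")
  expect_length(apply_sparsity(p, 1)$pre_times, 0)
  expect_identical(apply_sparsity(p, 0)$pre_times, p$pre_times)
  set.seed(3)
  kept <- vapply(1:50, function(i) length(apply_sparsity(p, 0.3)$pre_times),
                 numeric(1))
  expect_equal(mean(kept), 0.7 * 500, tolerance = 0.03)
})

test_that("Poisson protocols have Poisson counts and exponential intervals", {
  expect_length(poisson_protocol(0, 0, 10)$pre_times, 0)
  set.seed(5)
  counts <- vapply(1:200, function(i)
    length(poisson_protocol(10, 0, 10)$pre_times), numeric(1))
  expect_equal(mean(counts), 100, tolerance = 0.05)
  expect_equal(stats::var(counts) / mean(counts), 1, tolerance = 0.3)
  isi <- diff(poisson_protocol(40, 0, 200)$pre_times)
  # suppress the KS tie warning: double-precision interval ties are spurious
  expect_gt(suppressWarnings(stats::ks.test(isi, "pexp", rate = 40)$p.value), 0.01)
})

test_that("experiment presets bundle conditions with protocols", {
  expect_true("tigaret_ltp" %in% experiment_preset())
  pr <- experiment_preset("fujii_can")
  expect_s3_class(pr$conditions, "synapse_conditions")
  expect_identical(pr$conditions$mg_o, 0)
  expect_length(pr$protocol$pre_times, 100)
  expect_error(experiment_preset("nope"), "unknown preset")
})
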