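test_that("region indicators classify probe points of the activity plane", {
  expect_identical(unlist(region_indicator(8, 15)), c(in_ltp = TRUE, in_ltd = FALSE))
  expect_identical(unlist(region_indicator(0.05, 0.1)),
                   c(in_ltp = FALSE, in_ltd = FALSE))
  expect_identical(unlist(region_indicator(11, 15)),
                   c(in_ltp = FALSE, in_ltd = FALSE))
  expect_identical(unlist(region_indicator(2, 12)), c(in_ltp = FALSE, in_ltd = TRUE))
  # boundary points count as inside
  expect_true(region_indicator(10, 15)$in_ltp)
})

test_that("the regions are simple polygons that never overlap", {
  set.seed(31)
  pts <- region_indicator(stats::runif(4000, 0, 12), stats::runif(4000, 0, 35))
  expect_identical(sum(pts$in_ltp & pts$in_ltd), 0L)
  # both regions are non-trivially populated by the random probe
  expect_gt(sum(pts$in_ltp), 100)
  expect_gt(sum(pts$in_ltd), 100)
})

test_that("leaky activations grow linearly inside and decay exponentially outside", {
  p <- the_params
  d_in <- activation_derivatives(act_d = 0, act_p = 0, in_ltd = FALSE, in_ltp = TRUE, p)
  expect_identical(unname(d_in["d_act_p"]), 200)
  d_out <- activation_derivatives(act_d = 0, act_p = 5, in_ltd = FALSE, in_ltp = FALSE, p)
  expect_identical(unname(d_out["d_act_p"]), -0.1 * 5)
  d_ltd <- activation_derivatives(act_d = 7, act_p = 0, in_ltd = FALSE, in_ltp = FALSE, p)
  expect_identical(unname(d_ltd["d_act_d"]), -2e-2 * 7)
})

test_that("alternating occupancy matches the closed-form telescoping sum", {
  # 1 s inside, 1 s outside, repeated 10 times
  grid <- seq(0, 20, by = 0.01)
  inside <- (floor(grid) %% 2) == 0
  act <- tibble::tibble(time = grid,
                        can = ifelse(inside, 8, 0.1),
                        camkii = ifelse(inside, 15, 0.1))
  out <- readout_classify(act, the_params)
  # closed form: a(k+1) = (a(k) + aP*1) * exp(-bP*1)
  a <- 0
  for (k in 1:10) a <- (a + 200 * 1) * exp(-0.1 * 1)
  # the grid puts the last inside-sample at t = 19; compare at trace end
  expect_equal(utils::tail(out$act_p, 1), a, tolerance = 0.02)
})

test_that("plasticity rates are sigmoidal with the printed constants", {
  r <- plasticity_rates(act_p = 1.3e4, act_d = 0, the_params)
  expect_equal(unname(r["p_rate"]), 1 / (2 * 13), tolerance = 1e-12)
  expect_identical(unname(r["d_rate"]), 0)
  r2 <- plasticity_rates(0, 1e12, the_params)
  expect_equal(unname(r2["d_rate"]), 1 / 18, tolerance = 1e-6)
  expect_lt(unname(plasticity_rates(1e12, 0, the_params)["p_rate"]), 1 / 13 + 1e-9)
})

test_that("chain propensities conserve processes and respect the topology", {
  a <- chain_propensities(nc = 50, ltp = 30, ltd = 20, p_rate = 0.1, d_rate = 0.01)
  expect_equal(unname(a), c(50 * 0.1, 20 * 0.1, 30 * 0.01, 50 * 0.01))
  expect_identical(weight_change(30, 20), 10)
  expect_identical(weight_change(0, 100), -100)
  expect_identical(weight_change(0, 0), 0)
})

test_that("zero rates freeze the chain and sustained LTP absorbs it", {
  act0 <- tibble::tibble(time = seq(0, 5, 0.01), can = 0.1, camkii = 0.1)
  out0 <- readout_classify(act0, the_params)
  expect_true(all(out0$nc == 100))
  expect_identical(utils::tail(out0$weight, 1), 0L)
  set.seed(41)
  act1 <- tibble::tibble(time = seq(0, 600, 0.05), can = 8, camkii = 15)
  out1 <- readout_classify(act1, the_params)
  expect_gt(utils::tail(out1$ltp, 1), 90)
  expect_true(all(out1$nc + out1$ltp + out1$ltd == 100))
})

test_that("chain occupancy under constant rates matches the CTMC matrix exponential", {
  p_rate <- 0.05; d_rate <- 0.02; t_end <- 20
  Q <- matrix(c(0, p_rate, d_rate,
                d_rate, 0, 0,
                p_rate, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("nc", "ltp", "ltd"), c("nc", "ltp", "ltd")))
  G <- Q - diag(rowSums(Q))
  probs <- as.vector(as.matrix(Matrix::expm(Matrix::Matrix(t(G) * t_end))) %*% c(1, 0, 0))
  set.seed(43)
  final_state <- vapply(1:600, function(i) {
    dw <- spinesim:::cpp_dwell_times(unname(Q), 0L, t_end, dt = 0.05)
    dw[nrow(dw), "state"]  # last row is the (censored) terminal sojourn
  }, numeric(1))
  emp <- tabulate(final_state + 1, nbins = 3) / length(final_state)
  expect_gt(stats::chisq.test(table(factor(final_state, levels = 0:2)),
                              p = probs)$p.value, 0.001)
  expect_lt(max(abs(emp - probs)), 0.06)
})
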