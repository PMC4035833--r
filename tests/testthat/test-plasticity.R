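test_that("trace updates match the printed micro-examples", {
  # pure decay of a unit trace over one silent step
  e <- update_eligibility(matrix(1, 1, 1), 0, 0, f = 1, tau_e = 2.5)
  expect_equal(as.numeric(e), 0.6)

  # pre at t-1, post at t: potentiation by one
  e <- update_eligibility(matrix(0, 1, 1), x_post_prev = 0, x_post_now = 1,
                          x_pre_prev = 1, x_pre_now = 0, f = 1, tau_e = 2.5)
  expect_equal(as.numeric(e), 1)

  # post at t-1, pre at t: depression by f (decision-synapse value)
  e <- update_eligibility(matrix(0, 1, 1), x_post_prev = 1, x_post_now = 0,
                          x_pre_prev = 0, x_pre_now = 1, f = 0.01, tau_e = 2.5)
  expect_equal(as.numeric(e), -0.01)

  # both neurons active at both steps with f = 1: events cancel
  e <- update_eligibility(matrix(0.5, 1, 1), x_post_prev = 1, x_post_now = 1,
                          x_pre_prev = 1, x_pre_now = 1, f = 1, tau_e = 2.5)
  expect_equal(as.numeric(e), 0.5 * 0.6)

  expect_error(update_eligibility(matrix(0, 2, 2), c(0, 1), c(1, 0, 1),
                                  f = 1, tau_e = 2.5), "dimensions")
})

test_that("matrix trace/update path agrees with the brute-force oracle to 1e-12", {
  set.seed(42)
  for (rep in 1:20) {
    f <- sample(c(1, 0.01), 1)
    r <- sample(c(1, -1), 1)
    eta <- 1e-4
    activity <- matrix(rbinom(4 * 3, 1, 0.5), 4, 3)  # 3 neurons, 4 steps
    w0 <- matrix(runif(9), 3, 3)

    e <- matrix(0, 3, 3)
    for (t in 2:4)
      e <- update_eligibility(e, x_post_prev = activity[t - 1, ],
                              x_post_now = activity[t, ], f = f, tau_e = 2.5)
    w <- apply_reward(w0, e, r, eta)

    ref <- oracle_episode(activity, f, 2.5, r, eta, w0)
    expect_equal(e, ref$e, tolerance = 1e-12)
    expect_equal(w, ref$w, tolerance = 1e-12)
  }
})

test_that("reward commits traces with rectification at zero", {
  expect_equal(apply_reward(0.3, 2.0, 1, 1e-5), 0.30002)
  expect_equal(apply_reward(0.0003, 5.0, -1, 1e-4), 0)   # rectified
  w <- matrix(runif(9), 3, 3)
  expect_equal(apply_reward(w, matrix(0, 3, 3), -1, 1e-4), w)
  expect_error(apply_reward(0.3, 1, 0, 1e-5), "reward")
  expect_error(apply_reward(0.3, 1, 0.5, 1e-5), "reward")
})

test_that("synaptic scaling normalizes incoming weights to one", {
  expect_equal(scale_weights(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  v <- c(0.25, 0.25, 0.5)
  expect_equal(scale_weights(v), v)                       # idempotent
  expect_warning(out <- scale_weights(c(0, 0, 0)), "all-zero")
  expect_equal(out, c(0, 0, 0))

  m <- rbind(c(1, 1, 2), c(2, 2, 4))
  expect_equal(rowSums(scale_weights(m)), c(1, 1))
})

test_that("threshold adaptation follows the homeostatic rules", {
  expect_equal(adapt_threshold_exc(0.5, 1, 0.03, 1e-4) - 0.5, 9.7e-5)
  expect_equal(adapt_threshold_exc(0.5, 0, 0.03, 1e-4) - 0.5, -3e-6)
  expect_equal(adapt_threshold_exc(0.2, 0, 0, 1e-4), 0.2)    # fixed point

  expect_equal(adapt_threshold_inh(0.5, 0.05, 0.03, 1e-5) - 0.5, -2e-7)
  expect_equal(adapt_threshold_inh(0.5, 0.03, 0.03, 1e-5), 0.5)
  expect_equal(adapt_threshold_inh(0.5, 0, 0.03, 1e-5) - 0.5, 3e-7)
})

test_that("reward followed by scaling preserves simplex structure", {
  set.seed(8)
  for (rep in 1:25) {
    w <- matrix(runif(30), 5, 6)
    w <- w / rowSums(w)
    e <- matrix(rnorm(30, sd = 2), 5, 6)
    r <- sample(c(-1, 1), 1)
    w2 <- apply_reward(w, e, r, eta = 1e-2)
    w2 <- suppressWarnings(scale_weights(w2))
    expect_true(all(w2 >= 0))
    s <- rowSums(w2)
    expect_true(all(abs(s[s > 0] - 1) < 1e-12))
  }
})

test_that("traces decay geometrically; ten silent steps fall below 0.01", {
  e <- matrix(1, 1, 1)
  for (k in 1:10) e <- update_eligibility(e, 0, 0, f = 1, tau_e = 2.5)
  expect_lt(as.numeric(e), 0.01)
  expect_equal(as.numeric(e), 0.6^10)
  expect_error(plasticity_params(tau_e = 0.5), "tau_e")
  expect_equal(trace_decay_factor(2.5, "exp"), exp(-0.4))
})

test_that("opposite rewards produce exactly opposite raw weight changes", {
  set.seed(9)
  w <- matrix(runif(16) + 0.5, 4, 4)  # away from the rectification floor
  e <- matrix(rnorm(16), 4, 4) * 0.1
  dplus <- apply_reward(w, e, +1, 1e-3) - w
  dminus <- apply_reward(w, e, -1, 1e-3) - w
  expect_equal(dplus, -dminus, tolerance = 1e-15)
})
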