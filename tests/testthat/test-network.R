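test_that("initialization respects connectivity probabilities and Dale constraints", {
  p <- network_params()
  net <- initialize_network(p, n_inputs = 4L, seed = 11L)
  e <- seq_len(net$n_exc); i <- (net$n_exc + 1L):net$n_total

  expect_equal(sum(net$conn[i, i]), 0)          # p_ii = 0: no I->I synapses
  expect_true(all(net$w_rec >= 0))
  expect_true(all(net$w_dec >= 0))
  expect_false(any(diag(net$conn)))             # no self-connections

  # incoming excitatory and inhibitory weights each sum to one per neuron
  se <- rowSums(net$w_rec[, e])
  si <- rowSums(net$w_rec[, i])
  expect_true(all(abs(se[se > 0] - 1) < 1e-12))
  expect_true(all(abs(si[si > 0] - 1) < 1e-12))
  expect_equal(rowSums(net$w_dec), rep(1, p$n_decision), tolerance = 1e-12)
})

test_that("input channels occupy disjoint leading blocks of the excitatory units", {
  net <- initialize_network(network_params(), n_inputs = 4L, seed = 2L)
  blocks <- net$input_assignment
  expect_equal(unname(unlist(blocks)), 1:20)
  expect_equal(length(unique(unlist(blocks))), 20L)  # pairwise disjoint
})

test_that("initialization is deterministic under a fixed seed and validates inputs", {
  a <- initialize_network(network_params(), n_inputs = 4L, seed = 7L)
  b <- initialize_network(network_params(), n_inputs = 4L, seed = 7L)
  expect_identical(a$w_rec, b$w_rec)
  expect_identical(a$w_dec, b$w_dec)
  expect_identical(a$input_assignment, b$input_assignment)

  expect_error(initialize_network(network_params(), n_inputs = 50L),
               "cannot assign")
  expect_error(network_params(p_ee = 1.4), "probabilities")
  expect_error(network_params(noise_low = 0.2, noise_high = 0.1), "noise_low")
  expect_error(network_params(frac_exc = 1), "frac_exc")
})

test_that("currents sum signed synaptic drive plus noise", {
  net <- tiny_net()
  # all silent, zero noise
  expect_equal(compute_currents(net), rep(0, 5))

  # one excitatory presynaptic unit with weight 0.4
  net$w_rec[3, 1] <- 0.4
  net$x <- c(1L, 0L, 0L, 0L, 0L)
  expect_equal(compute_currents(net)[3], 0.4)

  # excitatory drive 0.6 against inhibitory drive 0.5 (unit 5 is inhibitory)
  net$w_rec[3, 1] <- 0.6
  net$w_rec[3, 5] <- 0.5
  net$x <- c(1L, 0L, 0L, 0L, 1L)
  expect_equal(compute_currents(net)[3], 0.1)
})

test_that("threshold comparison is inclusive and forcing overrides currents", {
  net <- tiny_net()
  net$w_rec[3, 1] <- 0.5           # exactly at threshold 0.5
  net$x <- c(1L, 0L, 0L, 0L, 0L)
  net2 <- step_recurrent(net)
  expect_equal(net2$x[3], 1L)      # current == theta fires

  # forced channel: all its units active despite subthreshold currents
  net$x <- integer(5)
  net3 <- step_recurrent(net, forced_channels = 2L)
  expect_equal(net3$x, c(0L, 1L, 0L, 0L, 0L))
  expect_equal(sum(net3$x), net$params$n_in)

  # nothing above threshold, no forcing: all-zero activity
  expect_equal(step_recurrent(net)$x, integer(5))
  expect_error(step_recurrent(net, forced_channels = 9L), "unknown input channel")
})

test_that("zero-noise dynamics are deterministic and order-independent", {
  p <- network_params(n_total = 40L, n_in = 2L, noise_low = 0, noise_high = 0,
                      n_decision = 2L)
  net <- initialize_network(p, n_inputs = 2L, seed = 3L)
  net$x[net$input_assignment[[1L]]] <- 1L
  traj1 <- traj2 <- list()
  n1 <- n2 <- net
  for (t in 1:6) { n1 <- step_recurrent(n1); traj1[[t]] <- n1$x }
  for (t in 1:6) { n2 <- step_recurrent(n2); traj2[[t]] <- n2$x }
  expect_identical(traj1, traj2)
})

test_that("decision layer emits exactly one winner, ties to the lowest index", {
  net <- tiny_net()
  net$w_dec <- matrix(0, 4, 4)
  net$w_dec[, 1] <- c(0.2, 0.5, 0.3, 0.1)
  net$x <- c(1L, 0L, 0L, 0L, 0L)
  out <- step_decision(net)
  expect_equal(attr(out, "winner"), 2L)          # argmax
  expect_equal(sum(out$x_dec), 1L)

  net$x <- integer(5)                            # all currents zero: tie
  out0 <- step_decision(net)
  expect_equal(attr(out0, "winner"), 1L)

  # with noise on, the winner distribution is non-degenerate
  netn <- tiny_net(noise = c(0, 0.1))
  netn$w_dec <- matrix(0.25, 4, 4)
  set.seed(4)
  winners <- replicate(200, attr(step_decision(netn), "winner"))
  expect_gt(length(unique(winners)), 1L)
  expect_true(all(tabulate(winners, 4L) > 10L))
})
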