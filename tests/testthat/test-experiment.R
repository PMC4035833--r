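test_that("compiled and reference engines agree bit-for-bit in every mode", {
  set.seed(99)
  p <- network_params(n_total = 60L, n_in = 3L, n_decision = 4L)
  net <- initialize_network(p, n_inputs = 4L)
  spec <- task_spec("delayed_response", K = 4L, T_max = 3L)
  pp <- plasticity_params()
  trials <- sample_trials(spec, 30L)
  enc <- wmcircuit:::.encode_trials(trials, spec)

  for (mode in c("rstdp", "stdp", "frozen")) {
    state <- .Random.seed
    fast <- wmcircuit:::.engine_cpp(net, enc, spec, pp, mode, record_from = 1L)
    assign(".Random.seed", state, envir = globalenv())
    slow <- run_trials_r(net, trials, spec, pp, mode, record_from = 1L)

    expect_identical(fast$actions, slow$actions)
    expect_identical(fast$rewards, slow$rewards)
    expect_identical(fast$net$w_rec, slow$net$w_rec)
    expect_identical(fast$net$w_dec, slow$net$w_dec)
    expect_identical(fast$net$theta_exc, slow$net$theta_exc)
    expect_identical(fast$net$theta_inh, slow$net$theta_inh)
    expect_identical(fast$net$theta_dec, slow$net$theta_dec)
    expect_identical(fast$net$x, slow$net$x)
    expect_identical(as.integer(fast$raster), as.integer(slow$raster))
  }
})

test_that("frozen mode leaves recurrent weights untouched; r-STDP changes them at reward only", {
  set.seed(31)
  p <- network_params(n_total = 60L, n_in = 3L, n_decision = 4L)
  net <- initialize_network(p, n_inputs = 4L)
  spec <- task_spec("delayed_response", K = 4L, T_max = 2L)
  trials <- sample_trials(spec, 20L)

  frozen <- run_trials_r(net, trials, spec, recurrent_mode = "frozen")
  expect_identical(frozen$net$w_rec, net$w_rec)
  expect_false(identical(frozen$net$w_dec, net$w_dec))  # readout still learns

  learned <- run_trials_r(net, trials, spec, recurrent_mode = "rstdp")
  expect_false(identical(learned$net$w_rec, net$w_rec))
})

test_that("a full experiment is reproducible from its seed", {
  cfg <- run_config("delayed_response", schedule = 1:2, trials_per_block = 150L,
                    n_repeats = 2L, seed = 5L,
                    network = network_params(n_total = 80L, n_in = 3L,
                                             n_decision = 4L),
                    record_trials = 50L)
  a <- run_experiment(cfg)
  b <- run_experiment(cfg)
  expect_identical(a$trial_log, b$trial_log)
  expect_identical(a$network$w_rec, b$network$w_rec)
  expect_identical(a$raster, b$raster)

  reps <- run_replicates(cfg)
  expect_length(reps, 2L)
  expect_equal(vapply(reps, function(r) r$config$seed, integer(1)), c(5L, 6L))
  expect_false(identical(reps[[1L]]$trial_log$reward, reps[[2L]]$trial_log$reward))
})

test_that("performance summaries aggregate the trial log correctly", {
  log <- data.frame(reward = c(rep(1L, 75L), rep(-1L, 25L)),
                    delay = rep(1:4, 25L))
  pc <- performance_curve(log, window = 100L)
  expect_equal(pc$correct, 0.75)

  log2 <- data.frame(reward = rep(1L, 300L), delay = 1L)
  expect_true(all(performance_curve(log2, 100L)$correct == 1))
  expect_error(performance_curve(log[0, ], 10L), "empty")
  expect_error(performance_curve(log, 0L), "window")

  # random 4-action agent fluctuates around chance
  set.seed(33)
  log3 <- data.frame(reward = ifelse(runif(5000) < 0.25, 1L, -1L), delay = 1L)
  pc3 <- performance_curve(log3, 100L)
  expect_lt(abs(mean(pc3$correct) - 0.25), 0.05)

  pd <- per_delay_performance(log, last = 100L)
  expect_equal(pd$delay, 1:4)
  expect_equal(sum(pd$n), 100L)
  expect_equal(memory_capacity(data.frame(delay = 1:5,
                                          correct = c(.9, .8, .6, .3, .2)),
                               chance = 0.25, margin = 0.05), 3L)
  expect_equal(memory_capacity(data.frame(delay = 1:2, correct = c(.2, .1)),
                               chance = 0.25), 0L)
})

test_that("run_config validates its arguments and applies task defaults", {
  expect_error(run_config(trials_per_block = 0L), "positive")
  expect_error(run_config("delayed_response", schedule = c(2L, 3L)), "start at 1")
  ov <- run_config("multitask_overlap", trials_per_block = 10L)
  expect_equal(ov$network$x0_recurrent, 0.05)  # overlap raises the target rate
  expect_equal(ov$schedule, 1:3)
  expect_equal(ov$network$n_decision, 4L)
  dr <- run_config("delayed_response", trials_per_block = 10L)
  expect_equal(dr$network$x0_recurrent, 0.03)
  expect_equal(dr$schedule, 1:5)
})

test_that("within-block performance is stable once learning has settled", {
  run <- acc_run("delayed_response", seed = 101L)
  pc <- performance_curve(run, 100L)
  n_blocks <- length(run$config$schedule)
  wpb <- nrow(pc) / n_blocks
  for (b in seq_len(n_blocks)) {
    tail_windows <- pc$correct[(b * wpb - 49L):(b * wpb)]
    expect_lt(sd(tail_windows), 0.1)
  }
})
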