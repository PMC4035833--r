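test_that("category maps are balanced and, for the overlap variant, orthogonal", {
  set.seed(21)
  cat8 <- task_spec("categorization")
  expect_equal(tabulate(cat8$maps, 2L), c(4L, 4L))

  dj <- task_spec("multitask_disjoint")
  expect_true(all(vapply(dj$maps, function(m) all(tabulate(m, 2L) == 2L),
                         logical(1))))

  ov <- task_spec("multitask_overlap")
  tab <- table(ov$maps[[1]], ov$maps[[2]])
  expect_true(all(tab == 2L))   # each joint cell holds K/4 stimuli

  expect_error(task_spec("categorization", K = 6), "K = 8")
  expect_error(task_spec("delayed_response", T_max = 9L), "T_max")
})

test_that("trial sampling matches the delay protocol and context scheme", {
  set.seed(22)
  fx <- task_spec("delayed_response", delay_mode = "fixed", T_max = 5L)
  tr <- sample_trials(fx, 500L)
  expect_true(all(tr$delay == 5L))
  expect_equal(tr$correct_action, tr$stimulus)   # identity map, M = K

  vr <- task_spec("delayed_response", delay_mode = "variable", T_max = 3L)
  tr <- sample_trials(vr, 10000L)
  frac <- tabulate(tr$delay, 3L) / nrow(tr)
  expect_true(all(abs(frac - 1 / 3) < 0.02))     # uniform on 1..T_max
  expect_true(all(abs(tabulate(tr$stimulus, 4L) / nrow(tr) - 0.25) < 0.02))

  dj <- task_spec("multitask_disjoint", T_max = 2L)
  tr <- sample_trials(dj, 200L)
  expect_equal(tr$context, ifelse(tr$stimulus <= 4L, 1L, 2L))
  expect_true(all(tr$correct_action[tr$context == 1L] %in% 1:2))
  expect_true(all(tr$correct_action[tr$context == 2L] %in% 3:4))

  ov <- task_spec("multitask_overlap", T_max = 2L)
  tr <- sample_trials(ov, 4000L)
  expect_true(all(abs(tabulate(tr$context, 2L) / nrow(tr) - 0.5) < 0.05))
  # where the two orthogonal maps disagree, the correct action differs by
  # more than the context offset
  dis <- which(ov$maps[[1]] != ov$maps[[2]])
  expect_length(dis, 4L)   # orthogonality: maps disagree on half the stimuli
  s <- dis[1L]
  a1 <- correct_action(ov, s, 1L); a2 <- correct_action(ov, s, 2L)
  expect_false(a2 - a1 == 2L)
})

test_that("the trial schedule places stimulus, delay period and Go cue", {
  spec <- task_spec("delayed_response", T_max = 5L)
  sch <- trial_schedule(list(stimulus = 2L, context = NA, delay = 1L), spec)
  expect_equal(sch$forced_channels, 2L)
  expect_equal(sch$go_step, 2L)            # minimum delay: immediate response
  expect_length(sch$delay_steps, 0L)

  sch5 <- trial_schedule(list(stimulus = 1L, context = NA, delay = 5L), spec)
  expect_equal(sch5$go_step, 6L)
  expect_equal(sch5$delay_steps, 2:5)
  expect_error(trial_schedule(list(stimulus = 1L, context = NA, delay = 9L),
                              spec), "delay out of range")

  ov <- task_spec("multitask_overlap", T_max = 3L)
  scho <- trial_schedule(list(stimulus = 3L, context = 2L, delay = 2L), ov)
  expect_equal(scho$forced_channels, c(3L, 10L))  # stimulus + context channel

  dj <- task_spec("multitask_disjoint", T_max = 3L)
  schd <- trial_schedule(list(stimulus = 6L, context = 2L, delay = 2L), dj)
  expect_equal(schd$allowed_actions, 3:4)
  expect_equal(schd$forced_channels, 6L)   # context cue is not an input here
})

test_that("the reward function is total and symmetric around chance", {
  trial <- list(correct_action = 3L)
  expect_equal(score_decision(3L, trial), 1L)
  expect_equal(score_decision(1L, trial), -1L)
  # uniform action choice at M = 4 earns -0.5 on average
  expect_equal(mean(vapply(1:4, score_decision, integer(1), trial = trial)),
               -0.5)
})

test_that("the incremental-delay curriculum advances and then clamps", {
  expect_equal(advance_curriculum(1L, 1:5), 1L)
  expect_equal(advance_curriculum(5L, 1:5), 5L)
  expect_equal(advance_curriculum(12L, 1:5), 5L)   # schedule exhausted
  expect_error(advance_curriculum(1L, c(2L, 3L)), "start at 1")
  expect_error(advance_curriculum(1L, c(1L, 3L, 2L)), "non-decreasing")
  expect_error(advance_curriculum(0L, 1:5), "block_index")
})
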