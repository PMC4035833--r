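test_that("depth of selectivity matches its closed form", {
  expect_equal(depth_of_selectivity(c(1, 0, 0, 0)), 1)       # exclusive
  expect_equal(depth_of_selectivity(c(0.4, 0.4, 0.4, 0.4)), 0)  # uniform
  expect_equal(depth_of_selectivity(c(2, 1, 1, 0)), 2 / 3)
  expect_true(is.na(depth_of_selectivity(c(0, 0, 0, 0))))    # undefined

  m <- rbind(c(1, 0), c(0.3, 0.3), c(0, 0))
  expect_equal(depth_of_selectivity(m), c(1, 0, NA))
  expect_error(depth_of_selectivity(matrix(1, 2, 1)), "two conditions")
})

test_that("S is scale-invariant and monotone under sharpening", {
  set.seed(41)
  for (rep in 1:20) {
    r <- runif(5)
    expect_equal(depth_of_selectivity(r), depth_of_selectivity(r * runif(1, 0.1, 10)))
    r2 <- r
    r2[-which.max(r2)][1L] <- 0   # zero out one non-maximal rate
    expect_gte(depth_of_selectivity(r2), depth_of_selectivity(r))
  }
})

test_that("delay rates pool binary activity over the delay period", {
  # 3 neurons, 6 steps, 4 trials with delay 3 (delay period = steps 2-3)
  ras <- array(0L, c(3, 6, 4))
  cond <- c("A", "A", "B", "B")
  delays <- rep(3L, 4)
  ras[1, 2:3, 1:2] <- 1L      # active every delay step of condition A
  ras[3, 2, 3] <- 1L          # active in half the delay steps of one B trial
  r <- mean_delay_rates(ras, delays, cond)
  expect_equal(unname(r[1, "A"]), 1)
  expect_equal(unname(r[2, "A"]), 0); expect_equal(unname(r[2, "B"]), 0)
  expect_equal(unname(r[3, "B"]), 0.25)

  # minimum-delay trials contribute no delay steps
  r2 <- mean_delay_rates(ras, c(3L, 1L, 3L, 3L), cond)
  expect_equal(unname(r2[1, "A"]), 1)
  # a condition whose trials all lack a delay period cannot be scored
  expect_error(mean_delay_rates(ras, c(3L, 3L, 1L, 1L), cond), "zero trials")
})

test_that("selective fractions respect thresholds and exclude undefined S", {
  S <- c(0.8, 0.7, 0.9, 0.2)
  expect_equal(as.numeric(selective_fraction(S, 0.75)), 0.5)
  expect_equal(as.numeric(selective_fraction(rep(1, 5), 0.75)), 1)
  Sna <- c(0.8, NA, 0.9, NA)
  out <- selective_fraction(Sna, 0.85)
  expect_equal(as.numeric(out), 0.5)
  expect_equal(attr(out, "n_undefined"), 2L)
  expect_equal(as.numeric(selective_fraction(Sna, 0)), 1)  # all defined count

  # monotone non-increasing in the threshold
  set.seed(42)
  S2 <- runif(100)
  fr <- vapply(seq(0, 1, 0.1), function(th)
    as.numeric(selective_fraction(S2, th)), numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_error(selective_fraction(S, 1.5), "threshold")
  expect_error(selective_fraction(S, 0.5, population = integer(0)), "empty")
})

test_that("multiplexing statistics partition task-specific neurons", {
  S1 <- c(0.9, 0.9, 0.1, 0.3)
  S2 <- c(0.8, 0.1, 0.9, 0.2)
  mx <- multiplexing_stats(S1, S2, 0.75)
  expect_equal(mx$n_specific, 3L)
  expect_equal(mx$both, 1 / 3)
  expect_equal(mx$only1, 1 / 3)
  expect_equal(mx$only2, 1 / 3)
  expect_equal(mx$both_overall, 1 / 4)

  deg <- multiplexing_stats(c(0.1, 0.2), c(0.3, 0.2), 0.75)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$both))
})

test_that("PSTH rows are probabilities ordered by peak time", {
  ras <- array(0L, c(2, 5, 6))
  ras[1, 3, ] <- 1L              # fires only at step 3 in every trial
  ras[2, 1, 1:3] <- 1L
  ps <- psth(ras)
  expect_true(all(ps$p >= 0 & ps$p <= 1))
  expect_equal(ps$p[1, ], c(0, 0, 1, 0, 0))
  expect_equal(ps$peak_time[[1]], 3L)
  expect_equal(ps$order, c(2L, 1L))

  # peakiness: indicator rows beat flat rows
  flat <- matrix(0.2, 4, 5)
  sharp <- diag(5)[1:4, ]
  expect_gt(psth_peakiness(sharp), psth_peakiness(flat))
  expect_equal(psth_peakiness(sharp), 1)
  expect_equal(psth_peakiness(flat), 0.2)
})

test_that("PCA trajectories separate constructed condition clusters", {
  set.seed(43)
  n <- 30
  ras <- array(0L, c(n, 6, 40))
  cond <- rep(c(1L, 2L), 20)
  for (tr in 1:40) {
    units <- if (cond[tr] == 1L) 1:10 else 11:20
    for (t in 2:4) ras[sample(units, 5L), t, tr] <- 1L
  }
  pj <- pca_trajectories(ras, rep(4L, 40), cond)
  expect_false(pj$degenerate)
  sc <- pj$scores
  mu1 <- colMeans(sc[sc$condition == 1L, 1:3])
  mu2 <- colMeans(sc[sc$condition == 2L, 1:3])
  between <- sqrt(sum((mu1 - mu2)^2))
  within <- mean(vapply(split(sc[, 1:3], sc$condition), function(d)
    mean(sqrt(rowSums(sweep(d, 2, colMeans(d))^2))), numeric(1)))
  expect_gt(between, within)

  # identical activity in every state: degenerate, flagged
  ras0 <- array(1L, c(5, 6, 8))
  expect_true(pca_trajectories(ras0, rep(4L, 8), rep(1L, 8))$degenerate)
  expect_error(pca_trajectories(ras[, , 1, drop = FALSE], 2L, 1L),
               "fewer observations")
})

test_that("weight-matrix summary scores chains and symmetric matrices", {
  fake <- function(w) {
    structure(list(n_exc = nrow(w), n_total = nrow(w) + 2L,
                   w_rec = rbind(cbind(w, 0, 0), 0, 0)[1:(nrow(w) + 2),
                                                       1:(nrow(w) + 2)],
                   conn = matrix(TRUE, nrow(w) + 2L, nrow(w) + 2L)),
              class = "wm_network")
  }
  n <- 6L
  chain <- matrix(0, n, n)
  for (i in 1:(n - 1)) chain[i + 1, i] <- 1   # pre i -> post i+1
  expect_equal(weight_matrix_summary(fake(chain))$feedforwardness, 1)

  sym <- matrix(1, n, n); diag(sym) <- 0
  expect_equal(weight_matrix_summary(fake(sym))$feedforwardness, 0.5)
  expect_error(weight_matrix_summary(fake(sym), order = 1:3), "exactly once")
})
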