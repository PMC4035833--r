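#' Configuration of a training experiment
#'
#' Bundles the task, network and plasticity parameters with the curriculum
#' schedule, block size, replication count and ablation mode.  Defaults
#' reproduce the standard study conditions: 2e4 trials per block, five
#' repetitions, curriculum 1..5 (1..3 for the overlapping multitask, which
#' also raises the excitatory target rate to 0.05).
#'
#' @param family Task family, see [task_spec()].
#' @param K Number of stimuli (family default when `NULL`).
#' @param delay_mode `"variable"` or `"fixed"`.
#' @param schedule Curriculum of `T_max` values, one per block.
#' @param trials_per_block Trials per curriculum block.
#' @param n_repeats Number of seeded repetitions for [run_replicates()].
#' @param recurrent_mode `"rstdp"` (reward-modulated), `"stdp"`
#'   (reward-independent recurrent learning, decision layer still
#'   reward-modulated) or `"frozen"` (static recurrent weights).
#' @param seed Base RNG seed.
#' @param network Optional [network_params()]; built from the task when
#'   `NULL`.
#' @param plasticity Optional [plasticity_params()].
#' @param record_trials Number of end-of-training trials whose full activity
#'   raster is kept for analysis.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation; identical results, much slower).
#' @return An object of class `wm_config`.
#' @export
run_config <- function(family = "delayed_response", K = NULL,
                       delay_mode = "variable", schedule = NULL,
                       trials_per_block = 20000L, n_repeats = 5L,
                       recurrent_mode = c("rstdp", "stdp", "frozen"),
                       seed = 1L, network = NULL, plasticity = NULL,
                       record_trials = 1000L, engine = c("cpp", "r")) {
  recurrent_mode <- match.arg(recurrent_mode)
  engine <- match.arg(engine)
  if (trials_per_block < 1L || n_repeats < 1L)
    stop("trials_per_block and n_repeats must be positive")
  template <- task_spec(family, K = K, delay_mode = delay_mode, T_max = 1L)
  if (is.null(schedule))
    schedule <- if (family == "multitask_overlap") 1:3 else 1:5
  advance_curriculum(1L, schedule)  # validates the schedule
  if (is.null(network))
    network <- network_params(
      n_decision = template$M,
      x0_recurrent = if (family == "multitask_overlap") 0.05 else 0.03)
  if (network$n_decision != template$M)
    stop("network n_decision must equal the task's number of actions M = ",
         template$M)
  if (is.null(plasticity)) plasticity <- plasticity_params()
  structure(list(family = family, K = template$K, delay_mode = delay_mode,
                 schedule = as.integer(schedule),
                 trials_per_block = as.integer(trials_per_block),
                 n_repeats = as.integer(n_repeats),
                 recurrent_mode = recurrent_mode,
                 seed = as.integer(seed),
                 network = network, plasticity = plasticity,
                 record_trials = as.integer(record_trials),
                 engine = engine),
            class = "wm_config")
}

#' @export
print.wm_config <- function(x, ...) {
  cat("<wm_config> ", x$family, " (", x$delay_mode, " delay), schedule ",
      paste(x$schedule, collapse = ","), ", ", x$trials_per_block,
      " trials/block, mode ", x$recurrent_mode, ", seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

# encode trials for the engines: stimulus channel, context channel (0 =
# none), delay, correct action, and the first allowed decision unit when the
# Go-step WTA is restricted (0 = unrestricted)
.encode_trials <- function(trials, spec) {
  n <- nrow(trials)
  ctx_ch <- if (spec$family == "multitask_overlap")
    spec$K + trials$context else rep(0L, n)
  allowed <- if (spec$family == "multitask_disjoint")
    (trials$context - 1L) * 2L + 1L else rep(0L, n)
  cbind(stim_ch = trials$stimulus, ctx_ch = as.integer(ctx_ch),
        delay = trials$delay, correct = trials$correct_action,
        allowed_lo = as.integer(allowed))
}

.mode_code <- function(mode) match(mode, c("rstdp", "stdp", "frozen")) - 1L

# run a batch of trials through the compiled engine, updating the network
.engine_cpp <- function(net, enc, spec, pp, recurrent_mode,
                        dec_learn = TRUE, ip_on = TRUE, record_from = 0L) {
  p <- net$params
  d <- trace_decay_factor(pp$tau_e, pp$trace_decay)
  out <- cpp_run_trials(net$w_rec, net$conn, net$w_dec,
                        net$theta_exc, net$theta_inh, net$theta_dec,
                        as.integer(net$x),
                        net$n_exc, p$n_in,
                        enc, spec$T_trial,
                        p$noise_low, p$noise_high,
                        p$x0_recurrent, p$x0_decision,
                        d, pp$f_recurrent, pp$f_decision,
                        pp$eta_recurrent, pp$eta_decision,
                        pp$lambda_exc_recurrent, pp$lambda_exc_decision,
                        pp$lambda_inh,
                        .mode_code(recurrent_mode), dec_learn, ip_on,
                        as.integer(record_from))
  net$w_rec <- out$w_rec; net$w_dec <- out$w_dec
  net$theta_exc <- out$theta_exc; net$theta_inh <- out$theta_inh
  net$theta_dec <- out$theta_dec; net$x <- out$x
  list(net = net, actions = out$actions, rewards = out$rewards,
       rate = out$rate, raster = if (record_from > 0L) out$raster else NULL)
}

#' Run a batch of trials with the pure-R reference engine
#'
#' Slow, transparent implementation of the same per-step dynamics as the
#' compiled engine, kept deliberately independent of it; with identical seed
#' and inputs the two produce identical trial logs and weights.  Intended
#' for verification and for stepping through small networks.
#'
#' @param net A `wm_network`.
#' @param trials Data frame from [sample_trials()].
#' @param spec The `wm_task` the trials were sampled from.
#' @param pp A [plasticity_params()] object.
#' @param recurrent_mode,dec_learn,ip_on Learning switches (see
#'   [run_config()]).
#' @param record_from First trial (1-based) whose activity raster is stored;
#'   0 disables recording.
#' @return A list with the updated network, per-trial `actions`, `rewards`,
#'   mean excitatory `rate`, and the `raster` array (neurons x steps x
#'   recorded trials) when recording.
#' @export
run_trials_r <- function(net, trials, spec, pp = plasticity_params(),
                         recurrent_mode = "rstdp", dec_learn = TRUE,
                         ip_on = TRUE, record_from = 0L) {
  enc <- .encode_trials(trials, spec)
  p <- net$params
  N <- net$n_total; n_exc <- net$n_exc; M <- p$n_decision
  Tt <- spec$T_trial
  d <- trace_decay_factor(pp$tau_e, pp$trace_decay)
  plastic <- net$conn
  plastic[, (n_exc + 1L):N] <- FALSE
  mode <- .mode_code(recurrent_mode)

  w <- net$w_rec; wd <- net$w_dec
  th_e <- net$theta_exc; th_i <- net$theta_inh; th_d <- net$theta_dec
  x <- as.numeric(net$x)
  n <- nrow(enc)
  actions <- integer(n); rewards <- integer(n); rate <- numeric(n)
  n_rec <- if (record_from > 0L) n - record_from + 1L else 0L
  raster <- if (n_rec > 0L) array(0L, c(N, Tt, n_rec)) else NULL

  for (tr in seq_len(n)) {
    stim_ch <- enc[tr, 1L]; ctx_ch <- enc[tr, 2L]
    delay <- enc[tr, 3L]; correct <- enc[tr, 4L]; allowed_lo <- enc[tr, 5L]
    go_step <- delay + 1L
    e_rec <- matrix(0, N, N)
    e_dec <- matrix(0, M, n_exc)
    prev_winner <- -1L
    exc_trial <- 0L

    for (t in seq_len(Tt)) {
      cur <- runif(N, p$noise_low, p$noise_high)
      inh_idx <- (n_exc + 1L):N
      for (j in which(x == 1)) {
        if (j <= n_exc) cur <- cur + w[, j]
        else cur[inh_idx] <- cur[inh_idx] - w[inh_idx, j]  # lagged inh -> inh
      }
      xn <- numeric(N)
      xn[inh_idx] <- as.numeric(cur[inh_idx] >= th_i)
      for (j in inh_idx[xn[inh_idx] == 1])  # fast inhibition of this step's
        cur[seq_len(n_exc)] <- cur[seq_len(n_exc)] - w[seq_len(n_exc), j]
      xn[seq_len(n_exc)] <- as.numeric(cur[seq_len(n_exc)] >= th_e)
      if (t == 1L) {
        xn[((stim_ch - 1L) * p$n_in + 1L):(stim_ch * p$n_in)] <- 1
        if (ctx_ch > 0L)
          xn[((ctx_ch - 1L) * p$n_in + 1L):(ctx_ch * p$n_in)] <- 1
      }
      exc_trial <- exc_trial + sum(xn[seq_len(n_exc)])

      cur_d <- runif(M, p$noise_low, p$noise_high)
      for (j in which(x[seq_len(n_exc)] == 1)) cur_d <- cur_d + wd[, j]
      allowed <- if (t == go_step && allowed_lo > 0L)
        allowed_lo:(allowed_lo + 1L) else seq_len(M)
      winner <- allowed[which.max(cur_d[allowed])]

      if (t >= 2L) {
        if (mode == 0L) {
          evmat <- (outer(xn, x) - pp$f_recurrent * outer(x, xn)) * plastic
          e_rec <- e_rec * d + evmat
        } else if (mode == 1L) {
          dw <- pp$eta_recurrent *
            ((outer(xn, x) - pp$f_recurrent * outer(x, xn)) * plastic)
          if (any(dw != 0)) {
            rows <- which(rowSums(dw != 0) > 0)
            w <- pmax(w + dw, 0)
            s <- rowSums(w[rows, seq_len(n_exc), drop = FALSE])
            s[s == 0] <- 1
            w[rows, seq_len(n_exc)] <- w[rows, seq_len(n_exc), drop = FALSE] / s
          }
        }
      }

      if (dec_learn) {
        e_dec <- e_dec * d
        if (t >= 2L) {
          pot <- outer(seq_len(M) == winner, x[seq_len(n_exc)] == 1)
          dep <- if (prev_winner > 0L)
            outer(seq_len(M) == prev_winner, xn[seq_len(n_exc)] == 1)
          else matrix(FALSE, M, n_exc)
          e_dec <- e_dec + pot - pp$f_decision * dep
        }
      }

      if (ip_on) {
        th_e <- th_e + pp$lambda_exc_recurrent * (xn[seq_len(n_exc)] - p$x0_recurrent)
        mexc <- sum(xn[seq_len(n_exc)]) / n_exc
        th_i <- th_i - pp$lambda_inh * (mexc - p$x0_recurrent)
        xd <- as.numeric(seq_len(M) == winner)
        th_d <- th_d + pp$lambda_exc_decision * (xd - p$x0_decision)
      }

      if (t == go_step) {
        r <- if (winner == correct) 1L else -1L
        actions[tr] <- winner; rewards[tr] <- r
        if (mode == 0L) {
          delta <- (pp$eta_recurrent * r) * e_rec
          if (any(delta != 0)) {
            rows <- which(rowSums(delta != 0) > 0)
            w <- pmax(w + delta, 0)
            s <- rowSums(w[rows, seq_len(n_exc), drop = FALSE])
            s[s == 0] <- 1
            w[rows, seq_len(n_exc)] <- w[rows, seq_len(n_exc), drop = FALSE] / s
          }
        }
        if (dec_learn) {
          wd <- pmax(wd + (pp$eta_decision * r) * e_dec, 0)
          s <- rowSums(wd)
          s[s == 0] <- 1
          wd <- wd / s
        }
      }

      if (n_rec > 0L && tr >= record_from)
        raster[, t, tr - record_from + 1L] <- as.integer(xn)

      x <- xn
      prev_winner <- winner
    }
    rate[tr] <- exc_trial / (n_exc * Tt)
  }

  net$w_rec <- w; net$w_dec <- wd
  net$theta_exc <- th_e; net$theta_inh <- th_i; net$theta_dec <- th_d
  net$x <- as.integer(x)
  list(net = net, actions = actions, rewards = rewards, rate = rate,
       raster = raster)
}

#' Run a single trial (reference engine)
#'
#' Convenience wrapper around [run_trials_r()] for one trial; returns the
#' updated network together with the reward and the trial's activity raster.
#'
#' @param net A `wm_network`.
#' @param trial A trial from [sample_trial()].
#' @param spec The task.
#' @param pp Plasticity parameters.
#' @param recurrent_mode Learning mode for the recurrent layer.
#' @return List with `net`, `action`, `reward`, `raster` (neurons x steps).
#' @export
run_trial <- function(net, trial, spec, pp = plasticity_params(),
                      recurrent_mode = "rstdp") {
  tr <- as.data.frame(trial[c("stimulus", "context", "delay", "correct_action")])
  out <- run_trials_r(net, tr, spec, pp, recurrent_mode, record_from = 1L)
  list(net = out$net, action = out$actions[1L], reward = out$rewards[1L],
       raster = out$raster[, , 1L])
}

#' Train a network on a task with the incremental-delay curriculum
#'
#' Draws the task's category maps and the network from the seed, then runs
#' `trials_per_block` trials at each `T_max` of the curriculum schedule.
#' The activity raster of the last `record_trials` trials of the final block
#' is kept for the selectivity, PSTH and PCA analyses.
#'
#' @param config A [run_config()] object.
#' @return An object of class `wm_run`: the trial log (one row per trial with
#'   block, stimulus, context, delay, action, reward and the trial's mean
#'   excitatory rate), the trained network, the task (with its maps), and the
#'   recorded raster with its trial metadata.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "wm_config"))
  set.seed(config$seed)
  spec <- task_spec(config$family, K = config$K, delay_mode = config$delay_mode,
                    T_max = 1L)
  net <- initialize_network(config$network, n_inputs = spec$n_channels)
  pp <- config$plasticity
  n_blocks <- length(config$schedule)
  nb <- config$trials_per_block
  logs <- vector("list", n_blocks)
  raster <- NULL; rec_trials <- NULL

  for (b in seq_len(n_blocks)) {
    spec$T_max <- advance_curriculum(b, config$schedule)
    trials <- sample_trials(spec, nb)
    record_from <- if (b == n_blocks) max(1L, nb - config$record_trials + 1L) else 0L
    out <- if (config$engine == "cpp")
      .engine_cpp(net, .encode_trials(trials, spec), spec, pp,
                  config$recurrent_mode, record_from = record_from)
    else
      run_trials_r(net, trials, spec, pp, config$recurrent_mode,
                   record_from = record_from)
    net <- out$net
    logs[[b]] <- data.frame(block = b, T_max = spec$T_max, trials,
                            action = out$actions, reward = out$rewards,
                            mean_rate = out$rate)
    if (record_from > 0L) {
      raster <- out$raster
      rec_trials <- trials[record_from:nb, , drop = FALSE]
    }
  }
  log <- do.call(rbind, logs)
  log$trial <- seq_len(nrow(log))
  structure(list(config = config, task = spec, trial_log = log,
                 network = net, raster = raster, raster_trials = rec_trials),
            class = "wm_run")
}

#' @export
print.wm_run <- function(x, ...) {
  n <- nrow(x$trial_log)
  cat("<wm_run> ", x$task$family, ", ", n, " trials in ",
      max(x$trial_log$block), " block(s), mode ", x$config$recurrent_mode,
      "\n", sep = "")
  cat("  final performance (last ", min(1000L, n), " trials): ",
      signif(final_performance(x), 3), "\n", sep = "")
  invisible(x)
}

#' Repeat an experiment with derived seeds
#'
#' Runs `n_repeats` independent replicates, with the seed of replicate `i`
#' equal to `seed + i - 1`.
#'
#' @param config A [run_config()].
#' @param n_repeats Number of replicates (defaults to the config's value).
#' @return List of `wm_run` objects.
#' @export
run_replicates <- function(config, n_repeats = config$n_repeats) {
  lapply(seq_len(n_repeats), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    run_experiment(cfg)
  })
}

#' Run trials without synaptic learning
#'
#' Evaluation / settling helper: the network is driven by the task but no
#' weight changes occur; homeostatic threshold adaptation can be kept on (to
#' settle a fresh network at its operating point) or switched off (pure
#' evaluation).
#'
#' @param net A `wm_network`.
#' @param spec The task.
#' @param n_trials Number of trials.
#' @param pp Plasticity parameters (for the threshold adaptation rates).
#' @param adapt_thresholds Keep intrinsic plasticity on?
#' @param record_trials How many final trials to record.
#' @return Same structure as [run_trials_r()], plus the trials used
#'   (`trials`).
#' @export
run_passive <- function(net, spec, n_trials, pp = plasticity_params(),
                        adapt_thresholds = TRUE, record_trials = 0L) {
  trials <- sample_trials(spec, n_trials)
  record_from <- if (record_trials > 0L)
    max(1L, n_trials - record_trials + 1L) else 0L
  out <- .engine_cpp(net, .encode_trials(trials, spec), spec, pp,
                     recurrent_mode = "frozen", dec_learn = FALSE,
                     ip_on = adapt_thresholds, record_from = record_from)
  out$trials <- trials
  out$raster_trials <- if (record_from > 0L)
    trials[record_from:n_trials, , drop = FALSE] else NULL
  out
}

#' Sliding-block performance curve
#'
#' Fraction of rewarded trials in consecutive non-overlapping windows.
#'
#' @param trial_log Trial log of a `wm_run` (or the run itself).
#' @param window Window size in trials.
#' @return Data frame with the window's last `trial` index and the fraction
#'   `correct`.
#' @export
performance_curve <- function(trial_log, window = 100L) {
  if (inherits(trial_log, "wm_run")) trial_log <- trial_log$trial_log
  if (window < 1L) stop("window must be >= 1")
  n <- nrow(trial_log)
  if (n == 0L) stop("empty trial log")
  k <- n %/% window
  if (k == 0L) { k <- 1L; window <- n }
  idx <- seq_len(k * window)
  grp <- rep(seq_len(k), each = window)
  frac <- tapply((trial_log$reward[idx] + 1) / 2, grp, mean)
  data.frame(trial = seq_len(k) * window, correct = as.numeric(frac))
}

#' Final performance of a run
#'
#' @param run A `wm_run` (or trial log).
#' @param last Number of final trials to average.
#' @return Fraction of correct trials.
#' @export
final_performance <- function(run, last = 1000L) {
  log <- if (inherits(run, "wm_run")) run$trial_log else run
  n <- nrow(log)
  tail_idx <- seq.int(max(1L, n - last + 1L), n)
  mean(log$reward[tail_idx] == 1)
}

#' Per-delay performance table
#'
#' Fraction correct by delay over the final trials of a run; used to read
#' off the memory capacity of the network.
#'
#' @param run A `wm_run` or trial log.
#' @param last Number of final trials considered.
#' @return Data frame with `delay`, `n`, `correct`.
#' @export
per_delay_performance <- function(run, last = 5000L) {
  log <- if (inherits(run, "wm_run")) run$trial_log else run
  n <- nrow(log)
  log <- log[seq.int(max(1L, n - last + 1L), n), ]
  agg <- aggregate(list(correct = log$reward == 1),
                   by = list(delay = log$delay), FUN = mean)
  agg$n <- as.integer(table(factor(log$delay, levels = agg$delay)))
  agg[order(agg$delay), c("delay", "n", "correct")]
}

#' Memory capacity
#'
#' The longest delay at which performance exceeds chance (by `margin`).
#'
#' @param perf Output of [per_delay_performance()].
#' @param chance Chance level (1 / number of actions).
#' @param margin Required excess over chance.
#' @return The capacity in steps (0 if no delay beats chance).
#' @export
memory_capacity <- function(perf, chance, margin = 0) {
  ok <- perf$delay[perf$correct > chance + margin]
  if (length(ok) == 0L) 0L else max(ok)
}
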