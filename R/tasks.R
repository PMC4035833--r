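#' Define a working-memory task family
#'
#' Four families are supported:
#' \describe{
#'   \item{`delayed_response`}{`M = K` actions, identity stimulus-action map.}
#'   \item{`categorization`}{`K = 8` stimuli mapped onto `M = 2` categories by
#'     a balanced random 2-coloring; category boundaries are defined purely by
#'     the reward function.}
#'   \item{`multitask_disjoint`}{`K = 8` stimuli split into two disjoint
#'     4-stimulus domains, each with its own balanced 2-way category map and
#'     its own pair of actions (`M = 4`).  The context (which domain the
#'     stimulus belongs to) is cued directly to the decision layer at the Go
#'     step, implemented by restricting the winner-take-all competition to the
#'     cued domain's two actions.}
#'   \item{`multitask_overlap`}{the same `K = 8` stimuli carry two orthogonal
#'     balanced 2-way maps (`M = 4`); the active context is delivered as an
#'     extra forced input channel together with the stimulus.}
#' }
#'
#' Category maps are drawn from the current RNG state, once per experiment.
#'
#' @param family Task family.
#' @param K Number of stimuli (defaults: 4 for delayed response, 8 otherwise).
#' @param delay_mode `"variable"` (delay uniform on 1..T_max) or `"fixed"`
#'   (delay = T_max for every trial).
#' @param T_max Current maximum delay, in steps.
#' @param T_trial Fixed trial duration in steps.
#' @param maps Optional explicit category map(s) (integer vector of length K
#'   with values 1/2, or a list of two such vectors for the multitask
#'   families); drawn randomly when `NULL`.
#' @return An object of class `wm_task`.
#' @export
task_spec <- function(family = c("delayed_response", "categorization",
                                 "multitask_disjoint", "multitask_overlap"),
                      K = NULL, delay_mode = c("variable", "fixed"),
                      T_max = 1L, T_trial = 10L, maps = NULL) {
  family <- match.arg(family)
  delay_mode <- match.arg(delay_mode)
  T_max <- as.integer(T_max); T_trial <- as.integer(T_trial)
  if (is.null(K)) K <- if (family == "delayed_response") 4L else 8L
  K <- as.integer(K)
  if (family != "delayed_response" && K != 8L)
    stop("the categorization families use K = 8 stimuli")
  if (T_max < 1L || T_max > T_trial - 2L)
    stop("need 1 <= T_max <= T_trial - 2 (room for the stimulus and Go steps)")

  balanced2 <- function(k) sample(rep(1:2, k / 2L))
  spec <- switch(family,
    delayed_response = list(M = K, n_contexts = 0L, maps = NULL),
    categorization = list(M = 2L, n_contexts = 0L,
                          maps = if (is.null(maps)) balanced2(K) else maps),
    multitask_disjoint = {
      mp <- if (is.null(maps)) list(balanced2(4L), balanced2(4L)) else maps
      list(M = 4L, n_contexts = 2L, maps = mp)
    },
    multitask_overlap = {
      mp <- if (is.null(maps)) {
        m1 <- balanced2(K)
        # orthogonal second boundary: balanced within each class of the first
        m2 <- integer(K)
        for (cl in 1:2) m2[m1 == cl] <- sample(rep(1:2, K / 4L))
        list(m1, m2)
      } else maps
      list(M = 4L, n_contexts = 2L, maps = mp)
    })

  out <- structure(c(list(family = family, K = K,
                          delay_mode = delay_mode,
                          T_max = T_max, T_trial = T_trial),
                     spec),
                   class = "wm_task")
  out$n_channels <- K + if (family == "multitask_overlap") 2L else 0L
  .validate_maps(out)
  out
}

.validate_maps <- function(spec) {
  if (spec$family == "categorization") {
    if (!all(tabulate(spec$maps, 2L) == spec$K / 2L))
      stop("category map must be balanced")
  } else if (spec$family == "multitask_disjoint") {
    ok <- vapply(spec$maps, function(m) all(tabulate(m, 2L) == 2L), logical(1))
    if (!all(ok)) stop("each domain map must assign 2 stimuli per category")
  } else if (spec$family == "multitask_overlap") {
    m1 <- spec$maps[[1]]; m2 <- spec$maps[[2]]
    tab <- table(factor(m1, 1:2), factor(m2, 1:2))
    if (!all(tab == spec$K / 4L))
      stop("the two category maps must be balanced and orthogonal")
  }
  invisible(spec)
}

#' @export
print.wm_task <- function(x, ...) {
  cat("<wm_task> ", x$family, ": K = ", x$K, ", M = ", x$M,
      ", ", x$delay_mode, " delay, T_max = ", x$T_max,
      ", T_trial = ", x$T_trial, "\n", sep = "")
  invisible(x)
}

#' Correct action for a stimulus (and context)
#'
#' @param spec A `wm_task`.
#' @param stimulus Stimulus index in 1..K.
#' @param context Context index (1 or 2) for the multitask families; the
#'   disjoint variant derives the context from the stimulus' domain.
#' @return Action index in 1..M.
#' @export
correct_action <- function(spec, stimulus, context = NA_integer_) {
  switch(spec$family,
    delayed_response = stimulus,
    categorization = spec$maps[stimulus],
    multitask_disjoint = {
      dom <- ifelse(stimulus <= 4L, 1L, 2L)
      s <- ifelse(dom == 1L, stimulus, stimulus - 4L)
      m <- vapply(seq_along(dom),
                  function(k) spec$maps[[dom[k]]][s[k]], integer(1))
      (dom - 1L) * 2L + m
    },
    multitask_overlap = {
      m <- vapply(seq_along(stimulus),
                  function(k) spec$maps[[context[k]]][stimulus[k]], integer(1))
      (context - 1L) * 2L + m
    })
}

#' Sample one trial
#'
#' The stimulus is uniform over the K stimuli; for the overlapping multitask
#' the context is uniform over the two tasks (trials of both tasks are
#' interleaved at random), while the disjoint variant derives the context
#' from the stimulus' domain.  The delay equals `T_max` in fixed mode and is
#' uniform on 1..`T_max` in variable mode.
#'
#' @param spec A `wm_task`.
#' @return A list with `stimulus`, `context`, `delay`, `correct_action`.
#' @export
sample_trial <- function(spec) {
  tr <- sample_trials(spec, 1L)
  as.list(tr[1L, ])
}

#' Sample a block of trials
#'
#' Vectorized version of [sample_trial()]; stimuli are drawn first, then
#' contexts (if any), then delays.
#'
#' @param spec A `wm_task`.
#' @param n Number of trials.
#' @return A data frame with columns `stimulus`, `context`, `delay`,
#'   `correct_action`.
#' @export
sample_trials <- function(spec, n) {
  stimulus <- sample.int(spec$K, n, replace = TRUE)
  context <- switch(spec$family,
    multitask_disjoint = ifelse(stimulus <= 4L, 1L, 2L),
    multitask_overlap = sample.int(2L, n, replace = TRUE),
    rep(NA_integer_, n))
  delay <- if (spec$delay_mode == "fixed") rep(spec$T_max, n)
           else sample.int(spec$T_max, n, replace = TRUE)
  data.frame(stimulus = stimulus, context = context, delay = as.integer(delay),
             correct_action = as.integer(correct_action(spec, stimulus, context)))
}

#' Per-step directives for one trial
#'
#' Step 1 forces the stimulus channel (plus the context channel in the
#' overlapping multitask).  The Go cue falls on step `delay + 1` — the delay
#' counts the steps from stimulus onset to the Go cue, so the minimum-delay
#' task (delay 1) is an immediate stimulus-response association and every
#' delay increment adds one retention step.  The decision read at the Go
#' step is based on the network state of the last pre-Go step (synchronous
#' update).  Steps strictly between stimulus and Go (2..delay) are the delay
#' period; remaining steps up to `T_trial` are padding with no forcing and
#' no reward.
#'
#' @param trial A sampled trial (list or one-row data frame).
#' @param spec A `wm_task`.
#' @return A list with `forced_channels` (forced at step 1), `go_step`,
#'   `delay_steps` (the step indices of the delay period; empty for delay 1),
#'   `T_trial`, and for the disjoint multitask the decision units the Go-step
#'   WTA is restricted to (`allowed_actions`).
#' @export
trial_schedule <- function(trial, spec) {
  delay <- trial$delay
  if (is.na(delay) || delay < 1L || delay > spec$T_trial - 2L)
    stop("delay out of range: ", delay)
  forced <- trial$stimulus
  if (spec$family == "multitask_overlap")
    forced <- c(forced, spec$K + trial$context)
  allowed <- if (spec$family == "multitask_disjoint")
    (trial$context - 1L) * 2L + 1:2 else NULL
  list(forced_channels = forced,
       go_step = delay + 1L,
       delay_steps = if (delay > 1L) 2:delay else integer(0),
       T_trial = spec$T_trial,
       allowed_actions = allowed)
}

#' Score a decision
#'
#' @param action Selected action index.
#' @param trial The trial (needs `correct_action`).
#' @return +1 if correct, -1 otherwise.
#' @export
score_decision <- function(action, trial) {
  if (action == trial$correct_action) 1L else -1L
}

#' Maximum delay for a curriculum block
#'
#' The incremental-delay curriculum starts at the minimum delay and
#' lengthens it block by block; past the end of the schedule the last value
#' is held.
#'
#' @param block_index Block number (1-based).
#' @param schedule Non-decreasing integer vector of `T_max` values, starting
#'   at 1.
#' @return `T_max` for that block.
#' @export
advance_curriculum <- function(block_index, schedule) {
  if (length(schedule) < 1L || schedule[1L] != 1L || is.unsorted(schedule))
    stop("schedule must be non-decreasing and start at 1")
  if (block_index < 1L) stop("block_index must be >= 1")
  schedule[min(block_index, length(schedule))]
}
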