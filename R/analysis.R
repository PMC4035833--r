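#' Mean delay-period rates per neuron and condition
#'
#' For each neuron and condition, the mean of its binary activity pooled over
#' all delay steps of all trials belonging to that condition.  The delay
#' period of a trial covers the steps strictly between the stimulus and the
#' Go cue (steps 2..delay); trials with the minimum delay have no delay
#' period and contribute nothing.
#'
#' @param raster Activity array, neurons x steps x trials.
#' @param delays Per-trial delay (in steps).
#' @param conditions Per-trial condition label; trials with `NA` are ignored.
#' @return Matrix neurons x conditions of mean rates.
#' @export
mean_delay_rates <- function(raster, delays, conditions) {
  stopifnot(length(delays) == dim(raster)[3],
            length(conditions) == dim(raster)[3])
  keep <- !is.na(conditions) & delays > 1L
  levels <- sort(unique(conditions[!is.na(conditions)]))
  if (length(levels) < 1L) stop("no trials with a defined condition")
  n <- dim(raster)[1]
  sums <- matrix(0, n, length(levels), dimnames = list(NULL, levels))
  steps <- numeric(length(levels))
  for (tr in which(keep)) {
    k <- match(conditions[tr], levels)
    dsteps <- 2:delays[tr]
    sums[, k] <- sums[, k] + rowSums(raster[, dsteps, tr, drop = FALSE])
    steps[k] <- steps[k] + length(dsteps)
  }
  if (any(steps == 0))
    stop("condition with zero trials: ", paste(levels[steps == 0], collapse = ", "))
  sweep(sums, 2L, steps, "/")
}

#' Depth of selectivity
#'
#' `S = (N_cond - sum(R_i) / R_max) / (N_cond - 1)`, where `R_i` is the mean
#' rate for condition i and `R_max` their maximum.  S is 0 when the neuron
#' responds identically to every condition and 1 when it responds exclusively
#' to one; it is undefined (`NA`) when all rates are zero.
#'
#' @param rates Per-condition rates: a vector (one neuron) or a matrix
#'   (neurons x conditions).
#' @return S value(s) in \[0, 1\] (`NA` where undefined).
#' @export
depth_of_selectivity <- function(rates) {
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = 1L)
  nc <- ncol(rates)
  if (nc < 2L) stop("depth of selectivity needs at least two conditions")
  rmax <- apply(rates, 1L, max)
  s <- (nc - rowSums(rates) / rmax) / (nc - 1)
  s[rmax == 0] <- NA_real_
  as.numeric(s)
}

#' Preferred condition per neuron
#'
#' @param rates Matrix neurons x conditions.
#' @return Column index (or name) of each neuron's maximal rate.
#' @export
preferred_condition <- function(rates) {
  idx <- apply(rates, 1L, which.max)
  if (!is.null(colnames(rates))) colnames(rates)[idx] else idx
}

#' Fraction of selective neurons
#'
#' Fraction of the population with a defined depth of selectivity at or above
#' the threshold; neurons with undefined S (all-zero rates) are excluded from
#' the denominator.
#'
#' @param S Vector of selectivity values (possibly with `NA`).
#' @param threshold Cutoff in \[0, 1\].
#' @param population Optional index vector restricting the population.
#' @return The fraction, plus attribute `"n_undefined"`.
#' @export
selective_fraction <- function(S, threshold, population = NULL) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  if (!is.null(population)) S <- S[population]
  if (length(S) == 0L) stop("empty population")
  defined <- !is.na(S)
  if (!any(defined)) stop("no neuron with a defined selectivity")
  out <- sum(S[defined] >= threshold) / sum(defined)
  attr(out, "n_undefined") <- sum(!defined)
  out
}

#' Multiplexing of two category boundaries
#'
#' Among the neurons that show any task specificity (S at or above
#' `threshold` in at least one task), the fractions selective in both tasks
#' versus exactly one, plus the per-neuron scatter of S values.
#'
#' @param S1,S2 Per-neuron selectivity for the two category boundaries
#'   (same population).
#' @param threshold Task-specificity cutoff.
#' @return List with `n_specific`, fractions `both`, `only1`, `only2`,
#'   the overall fraction `both_overall` (both-selective neurons over the
#'   whole population with defined S), and the `scatter` data frame.  When
#'   no neuron is task-specific the fractions are `NA` and the result carries
#'   `degenerate = TRUE`.
#' @export
multiplexing_stats <- function(S1, S2, threshold = 0.75) {
  stopifnot(length(S1) == length(S2))
  sel1 <- !is.na(S1) & S1 >= threshold
  sel2 <- !is.na(S2) & S2 >= threshold
  specific <- sel1 | sel2
  defined <- !(is.na(S1) & is.na(S2))
  n_spec <- sum(specific)
  if (n_spec == 0L) {
    return(list(n_specific = 0L, both = NA_real_, only1 = NA_real_,
                only2 = NA_real_, both_overall = 0,
                scatter = data.frame(S1 = S1, S2 = S2), degenerate = TRUE))
  }
  list(n_specific = n_spec,
       both = sum(sel1 & sel2) / n_spec,
       only1 = sum(sel1 & !sel2) / n_spec,
       only2 = sum(sel2 & !sel1) / n_spec,
       both_overall = sum(sel1 & sel2) / sum(defined),
       scatter = data.frame(S1 = S1, S2 = S2),
       degenerate = FALSE)
}

#' Post-stimulus time histogram
#'
#' Per-neuron firing probability at each step since stimulus onset, over the
#' trials of one condition (or all trials), with the neuron ordering induced
#' by the time of peak firing (ties broken by neuron index).
#'
#' @param raster Activity array, neurons x steps x trials.
#' @param conditions Optional per-trial labels.
#' @param condition Condition to select (`NULL` pools all trials).
#' @return List with the probability matrix `p` (neurons x steps), the
#'   `peak_time` per neuron and the peak-time `order`.
#' @export
psth <- function(raster, conditions = NULL, condition = NULL) {
  sel <- if (is.null(condition)) seq_len(dim(raster)[3])
         else which(conditions == condition)
  p <- apply(raster[, , sel, drop = FALSE], c(1L, 2L), mean)
  peak <- apply(p, 1L, which.max)
  list(p = p, peak_time = peak, order = order(peak, seq_along(peak)))
}

#' Temporal concentration of a PSTH
#'
#' Mean over neurons of the peak share `max_t p / sum_t p` of each row; 1 for
#' rows concentrated on a single step, `1/n_steps` for flat rows.  Rows with
#' no activity are skipped.  A summary statistic of how reproducibly timed
#' the responses are (higher after training than before).
#'
#' @param p PSTH probability matrix (neurons x steps).
#' @return Scalar concentration.
#' @export
psth_peakiness <- function(p) {
  tot <- rowSums(p)
  keep <- tot > 0
  if (!any(keep)) return(NA_real_)
  mean(apply(p[keep, , drop = FALSE], 1L, max) / tot[keep])
}

#' Low-dimensional population trajectories
#'
#' Pools the delay-period population states across trials, extracts the
#' leading principal components, and projects every state, labelled by
#' condition and time since stimulus onset.
#'
#' @param raster Activity array, neurons x steps x trials.
#' @param delays Per-trial delays.
#' @param conditions Per-trial condition labels.
#' @param n_components Number of components (default 3).
#' @return List with the `scores` data frame (component coordinates, `condition`,
#'   `time`, `trial`), the `rotation`, and `degenerate = TRUE` when the pooled
#'   activity carries no variance.
#' @export
pca_trajectories <- function(raster, delays, conditions, n_components = 3L) {
  n_tr <- dim(raster)[3]
  obs <- list(); lab <- list()
  for (tr in seq_len(n_tr)) {
    if (delays[tr] < 2L) next
    dsteps <- 2:delays[tr]
    obs[[tr]] <- t(raster[, dsteps, tr, drop = FALSE][, , 1L])
    lab[[tr]] <- data.frame(condition = conditions[tr], time = dsteps - 1L,
                            trial = tr)
  }
  X <- do.call(rbind, obs)
  labs <- do.call(rbind, lab)
  if (nrow(X) < n_components)
    stop("fewer observations than requested components")
  if (all(apply(X, 2L, stats::var) == 0))
    return(list(scores = NULL, rotation = NULL, degenerate = TRUE))
  pc <- prcomp(X, center = TRUE, rank. = n_components)
  scores <- as.data.frame(pc$x[, seq_len(min(n_components, ncol(pc$x))), drop = FALSE])
  list(scores = cbind(scores, labs), rotation = pc$rotation,
       degenerate = FALSE)
}

#' Sparsity and feedforwardness of the recurrent excitatory connectivity
#'
#' Sparsity is the fraction of existing excitatory-to-excitatory synapses
#' whose weight fell below a cutoff (default 1e-3 of the mean weight of those
#' synapses).  Feedforwardness orders the excitatory neurons (typically by
#' PSTH peak time) and reports the fraction of total weight mass flowing from
#' earlier- to later-firing neurons: 1 for a perfect chain in that order, 0.5
#' for a symmetric matrix.  The index is a
#' package-level summary of the weight-matrix structure.
#'
#' @param net A trained `wm_network`.
#' @param order Permutation of the excitatory units (defaults to identity).
#' @param cutoff_factor Sparsity cutoff as a fraction of the mean weight.
#' @return List with `sparsity`, `feedforwardness`, and the cutoff used.
#' @export
weight_matrix_summary <- function(net, order = NULL, cutoff_factor = 1e-3) {
  e <- seq_len(net$n_exc)
  w <- net$w_rec[e, e]
  conn <- net$conn[e, e]
  if (is.null(order)) order <- e
  order <- order[order %in% e]  # accept orderings over the full population
  if (length(order) != net$n_exc)
    stop("order must contain each excitatory unit exactly once")
  wo <- w[order, order]
  # weight flows pre (column) -> post (row); "post later than pre" is the
  # lower triangle of the (post, pre) matrix once neurons are sorted by time
  forward <- sum(wo[lower.tri(wo)])
  backward <- sum(wo[upper.tri(wo)])
  ff <- if (forward + backward == 0) NA_real_ else forward / (forward + backward)
  mw <- mean(w[conn])
  cutoff <- cutoff_factor * mw
  list(sparsity = mean(w[conn] < cutoff), feedforwardness = ff,
       cutoff = cutoff)
}

#' Per-trial condition labels for a recorded run
#'
#' Derives the behavioural label of each recorded trial from the run's task:
#' `"stimulus"`, `"category"` (the task's category map), `"category1"` /
#' `"category2"` (the two boundaries of a multitask run; trials outside the
#' relevant domain get `NA` in the disjoint variant), or `"context"`.
#'
#' @param run A `wm_run`.
#' @param what Condition set.
#' @return Vector of labels, one per recorded trial.
#' @export
condition_labels <- function(run, what = c("stimulus", "category",
                                           "category1", "category2",
                                           "context")) {
  what <- match.arg(what)
  tr <- run$raster_trials
  if (is.null(tr)) stop("run has no recorded trials")
  spec <- run$task
  switch(what,
    stimulus = tr$stimulus,
    category = {
      if (spec$family != "categorization")
        stop("'category' labels require a categorization run")
      spec$maps[tr$stimulus]
    },
    category1 = .boundary_label(spec, tr, 1L),
    category2 = .boundary_label(spec, tr, 2L),
    context = {
      if (is.null(spec$n_contexts) || spec$n_contexts == 0L)
        stop("task has no contexts")
      tr$context
    })
}

.boundary_label <- function(spec, tr, which_task) {
  if (spec$family == "multitask_disjoint") {
    out <- rep(NA_integer_, nrow(tr))
    dom <- ifelse(tr$stimulus <= 4L, 1L, 2L)
    in_dom <- dom == which_task
    s <- tr$stimulus[in_dom] - (which_task - 1L) * 4L
    out[in_dom] <- spec$maps[[which_task]][s]
    out
  } else if (spec$family == "multitask_overlap") {
    # a boundary is only in effect on the trials of its own context
    out <- rep(NA_integer_, nrow(tr))
    in_ctx <- tr$context == which_task
    out[in_ctx] <- spec$maps[[which_task]][tr$stimulus[in_ctx]]
    out
  } else stop("task has a single category boundary; use 'category'")
}

#' Depth-of-selectivity report for a recorded run
#'
#' Computes per-neuron delay-period rates for the requested condition set and
#' the resulting depth of selectivity over the excitatory population.
#'
#' @param run A `wm_run` with a recorded raster.
#' @param what Condition set, see [condition_labels()].
#' @param population `"excitatory"` (default: all excitatory recurrent
#'   units), `"excitatory_noninput"` (excluding the input-receiving blocks)
#'   or `"all"`.
#' @return List with `S`, `rates`, `preferred`, the population indices and
#'   the condition set used.
#' @export
selectivity_report <- function(run, what = "stimulus",
                               population = c("excitatory",
                                              "excitatory_noninput", "all")) {
  population <- match.arg(population)
  net <- run$network
  pop <- switch(population,
    excitatory = seq_len(net$n_exc),
    excitatory_noninput = setdiff(seq_len(net$n_exc),
                                  unlist(net$input_assignment)),
    all = seq_len(net$n_total))
  labels <- condition_labels(run, what)
  rates <- mean_delay_rates(run$raster, run$raster_trials$delay, labels)
  S <- depth_of_selectivity(rates)
  list(S = S[pop], rates = rates[pop, , drop = FALSE],
       preferred = preferred_condition(rates[pop, , drop = FALSE]),
       population = pop, condition_set = what)
}
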