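#' One-step eligibility trace update
#'
#' Traces decay by the per-step factor (forward Euler `1 - 1/tau_e` by
#' default) and accumulate STDP events: a synapse is potentiated by one unit
#' when its presynaptic neuron was active at the previous step and its
#' postsynaptic neuron is active now, and depressed by `f` for the reverse
#' pairing.  The STDP window is one time step wide, the timescale of causal
#' interactions in the network.
#'
#' `e` is indexed postsynaptic-by-presynaptic (rows = post).  For recurrent
#' synapses pre and post range over the same population and the pre arguments
#' can be omitted.
#'
#' @param e Trace matrix (post x pre) or vector.
#' @param x_post_prev,x_post_now Postsynaptic activity at t-1 and t.
#' @param x_pre_prev,x_pre_now Presynaptic activity; default to the
#'   postsynaptic vectors (recurrent case).
#' @param f LTD asymmetry factor.
#' @param tau_e Trace time constant in steps.
#' @param method Decay discretization, see [trace_decay_factor()].
#' @param mask Optional logical matrix restricting events to plastic synapses.
#' @return Updated trace matrix.
#' @export
update_eligibility <- function(e, x_post_prev, x_post_now,
                               x_pre_prev = x_post_prev,
                               x_pre_now = x_post_now,
                               f, tau_e, method = c("euler", "exp"),
                               mask = NULL) {
  d <- trace_decay_factor(tau_e, match.arg(method))
  e <- as.matrix(e)
  if (nrow(e) != length(x_post_now) || ncol(e) != length(x_pre_now) ||
      length(x_post_prev) != length(x_post_now) ||
      length(x_pre_prev) != length(x_pre_now))
    stop("trace and activity dimensions do not match")
  ev <- outer(as.numeric(x_post_now), as.numeric(x_pre_prev)) -
    f * outer(as.numeric(x_post_prev), as.numeric(x_pre_now))
  if (!is.null(mask)) ev <- ev * mask
  e * d + ev
}

#' Commit eligibility traces to the weights at reward time
#'
#' Each plastic weight gains `eta * r * e`; weights are then rectified at
#' zero so Dale's law is preserved.  Synaptic scaling
#' ([scale_weights()]) is applied immediately afterwards by the training
#' loop.
#'
#' @param w Weight matrix (post x pre), non-negative.
#' @param e Eligibility traces, same shape.
#' @param r Reward, +1 (correct) or -1 (error).
#' @param eta Learning rate.
#' @return Updated, rectified weight matrix.
#' @export
apply_reward <- function(w, e, r, eta) {
  if (!(length(r) == 1L && r %in% c(-1, 1)))
    stop("reward r must be +1 or -1")
  if (!identical(dim(w), dim(as.matrix(e))) && length(w) != length(e))
    stop("weight and trace dimensions do not match")
  pmax(w + (eta * r) * e, 0)
}

#' Synaptic scaling: sum-to-one normalization of incoming weights
#'
#' Divides each neuron's incoming plastic weight vector (one row) by its sum.
#' A row summing to zero cannot be normalized and is left unchanged with a
#' warning.
#'
#' @param w Weight matrix (post x pre) or a single incoming-weight vector.
#' @return Matrix (or vector) with rows summing to one where possible.
#' @export
scale_weights <- function(w) {
  if (is.null(dim(w))) {
    s <- sum(w)
    if (s == 0) {
      warning("all-zero incoming weight vector left unnormalized")
      return(w)
    }
    return(w / s)
  }
  .row_normalize(w, warn = TRUE)
}

#' Homeostatic threshold adaptation of excitatory and decision units
#'
#' Intrinsic plasticity moves each threshold so the unit's long-run mean rate
#' approaches the target `x0`: a spike raises the threshold by
#' `lambda * (1 - x0)`, silence lowers it by `lambda * x0`.
#'
#' @param theta Threshold (vector or scalar).
#' @param x Binary output of the unit(s) this step.
#' @param x0 Target mean rate.
#' @param lambda Adaptation rate.
#' @return Updated threshold(s).
#' @export
adapt_threshold_exc <- function(theta, x, x0, lambda) {
  theta + lambda * (x - x0)
}

#' Homeostatic regulation of inhibitory thresholds
#'
#' Inhibitory excitability tracks the pooled activity of the excitatory
#' population: excess excitation lowers inhibitory thresholds (recruiting
#' more inhibition), a quiet circuit raises them.  The same update applies to
#' every inhibitory unit.
#'
#' @param theta Inhibitory threshold(s).
#' @param mean_x_exc Population mean of excitatory activity this step.
#' @param x0 Target excitatory rate.
#' @param lambda Adaptation rate.
#' @return Updated threshold(s).
#' @export
adapt_threshold_inh <- function(theta, mean_x_exc, x0, lambda) {
  theta - lambda * (mean_x_exc - x0)
}
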