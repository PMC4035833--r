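#' Network parameters
#'
#' Fixed structural and dynamical parameters of the recurrent circuit and its
#' winner-take-all decision layer.  Defaults are the values used throughout
#' the delayed-response experiments; the overlapping-context task raises
#' `x0_recurrent` to 0.05.
#'
#' @param n_total Number of recurrent units (excitatory + inhibitory).
#' @param frac_exc Fraction of excitatory units.
#' @param n_in Size of the excitatory subpopulation driven by one input
#'   channel (stimulus or context cue).
#' @param p_ee,p_ei,p_ie,p_ii Connection probabilities, target population
#'   first: `p_ei` is the probability that an excitatory neuron receives a
#'   synapse from a given inhibitory neuron.
#' @param noise_low,noise_high Bounds of the uniform background current drawn
#'   independently per neuron and time step.
#' @param n_decision Number of decision (action) units.
#' @param x0_recurrent Target mean rate of excitatory recurrent units.
#' @param x0_decision Target rate of decision units.
#' @param theta_init Initial threshold of excitatory and decision units.
#'   Intrinsic plasticity moves these to their operating point within the
#'   first training block, so the long-run behaviour does not depend on the
#'   value.
#' @param theta_init_inh Initial threshold of inhibitory units.  Unlike the
#'   excitatory thresholds this value matters: the population-level
#'   homeostasis of inhibitory excitability drifts too slowly to recruit a
#'   silent inhibitory population, so the threshold must start inside the
#'   dynamic range of the pooled excitatory drive.  The default (0.2) leaves
#'   inhibition silent during normal sparse activity and recruits it during
#'   activity surges.
#' @return An object of class `wm_network_params`.
#' @export
network_params <- function(n_total = 250L, frac_exc = 0.8, n_in = 5L,
                           p_ee = 0.1, p_ei = 0.25, p_ie = 0.4, p_ii = 0,
                           noise_low = 0, noise_high = 0.1,
                           n_decision = 4L,
                           x0_recurrent = 0.03, x0_decision = 0.25,
                           theta_init = 0.5, theta_init_inh = 0.2) {
  p <- list(n_total = as.integer(n_total), frac_exc = frac_exc,
            n_in = as.integer(n_in),
            p_ee = p_ee, p_ei = p_ei, p_ie = p_ie, p_ii = p_ii,
            noise_low = noise_low, noise_high = noise_high,
            n_decision = as.integer(n_decision),
            x0_recurrent = x0_recurrent, x0_decision = x0_decision,
            theta_init = theta_init, theta_init_inh = theta_init_inh)
  probs <- c(p_ee = p_ee, p_ei = p_ei, p_ie = p_ie, p_ii = p_ii)
  if (any(probs < 0 | probs > 1))
    stop("connection probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (!(frac_exc > 0 && frac_exc < 1))
    stop("frac_exc must lie strictly between 0 and 1")
  if (noise_low > noise_high)
    stop("noise_low must not exceed noise_high")
  if (p$n_total < 2L || p$n_in < 1L || p$n_decision < 1L)
    stop("n_total, n_in and n_decision must be positive")
  if (!(x0_recurrent > 0 && x0_recurrent < 1) ||
      !(x0_decision > 0 && x0_decision < 1))
    stop("target rates x0 must lie strictly between 0 and 1")
  structure(p, class = "wm_network_params")
}

#' Plasticity parameters
#'
#' Rates and time constants of reward-modulated STDP, synaptic scaling and
#' homeostatic threshold regulation.  Decision-layer synapses and thresholds
#' learn ten times faster than recurrent ones so the readout can exploit the
#' representation while it forms; the LTD asymmetry factor `f` is reduced to
#' 0.01 at decision synapses to limit interference from motor activity during
#' the delay.
#'
#' @param tau_e Eligibility-trace decay time constant, in time steps.
#' @param f_recurrent,f_decision LTD asymmetry factor for recurrent and
#'   decision synapses.
#' @param eta_recurrent,eta_decision Learning rates at reward time.
#' @param lambda_exc_recurrent,lambda_exc_decision Threshold adaptation rates
#'   of excitatory recurrent and decision units.
#' @param lambda_inh Adaptation rate of inhibitory thresholds.
#' @param trace_decay Discretization of the trace decay over one step:
#'   `"euler"` uses the forward-Euler factor `1 - 1/tau_e`; `"exp"` uses
#'   `exp(-1/tau_e)`.
#' @return An object of class `wm_plasticity_params`.
#' @export
plasticity_params <- function(tau_e = 2.5, f_recurrent = 1, f_decision = 0.01,
                              eta_recurrent = 1e-5, eta_decision = 1e-4,
                              lambda_exc_recurrent = 1e-4,
                              lambda_exc_decision = 1e-3,
                              lambda_inh = 1e-5,
                              trace_decay = c("euler", "exp")) {
  trace_decay <- match.arg(trace_decay)
  if (tau_e <= 1)
    stop("tau_e must exceed 1 (the Euler decay factor 1 - 1/tau_e must be positive)")
  rates <- c(f_recurrent, f_decision, eta_recurrent, eta_decision,
             lambda_exc_recurrent, lambda_exc_decision, lambda_inh)
  if (any(rates < 0)) stop("plasticity rates must be non-negative")
  structure(list(tau_e = tau_e,
                 f_recurrent = f_recurrent, f_decision = f_decision,
                 eta_recurrent = eta_recurrent, eta_decision = eta_decision,
                 lambda_exc_recurrent = lambda_exc_recurrent,
                 lambda_exc_decision = lambda_exc_decision,
                 lambda_inh = lambda_inh,
                 trace_decay = trace_decay),
            class = "wm_plasticity_params")
}

#' One-step eligibility decay factor
#'
#' @param tau_e Trace time constant in steps.
#' @param method `"euler"` for `1 - 1/tau_e`, `"exp"` for `exp(-1/tau_e)`.
#' @return The multiplicative per-step decay factor.
#' @export
trace_decay_factor <- function(tau_e, method = c("euler", "exp")) {
  method <- match.arg(method)
  if (method == "euler") {
    if (tau_e <= 1) stop("tau_e must exceed 1 for the Euler discretization")
    1 - 1 / tau_e
  } else {
    exp(-1 / tau_e)
  }
}
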