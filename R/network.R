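#' Initialize a recurrent working-memory network
#'
#' Samples the sparse random connectivity, draws weights uniformly on
#' \[0, 1\], normalizes incoming weights to sum one per neuron (excitatory and
#' inhibitory afferents separately, and once per decision unit), assigns the
#' input channels to disjoint leading blocks of the excitatory population,
#' and sets all thresholds to their initial value.
#'
#' Weights are stored as non-negative magnitudes; inhibitory afferents enter
#' the input current with a minus sign (Dale's law with rectification).
#' Self-connections are excluded.  The decision layer receives input from
#' every excitatory unit.
#'
#' @param params A [network_params()] object.
#' @param n_inputs Number of input channels (stimuli plus any context cues).
#' @param seed Optional integer seed set before sampling.
#' @return An object of class `wm_network`: a list with the weight matrices
#'   (`w_rec`, row = postsynaptic), the connectivity mask `conn`, decision
#'   weights `w_dec`, thresholds (`theta_exc`, `theta_inh`, `theta_dec`),
#'   current activities (`x`, `x_dec`), and `input_assignment` mapping each
#'   channel to its excitatory units.
#' @export
initialize_network <- function(params, n_inputs, seed = NULL) {
  stopifnot(inherits(params, "wm_network_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_total
  n_exc <- as.integer(round(params$frac_exc * n))
  n_inh <- n - n_exc
  n_inputs <- as.integer(n_inputs)
  if (n_inputs < 1L) stop("n_inputs must be at least 1")
  if (n_inputs * params$n_in > n_exc)
    stop("cannot assign ", n_inputs, " input channels of ", params$n_in,
         " units each to ", n_exc, " excitatory neurons")

  # connection probability per ordered (post, pre) pair, by population
  pmat <- matrix(0, n, n)
  e <- seq_len(n_exc); i <- (n_exc + 1L):n
  pmat[e, e] <- params$p_ee
  pmat[e, i] <- params$p_ei
  pmat[i, e] <- params$p_ie
  pmat[i, i] <- params$p_ii
  diag(pmat) <- 0

  conn <- matrix(runif(n * n) < pmat, n, n)
  w <- matrix(runif(n * n), n, n)
  w[!conn] <- 0
  w[, e] <- .row_normalize(w[, e, drop = FALSE], warn = FALSE)
  w[, i] <- .row_normalize(w[, i, drop = FALSE], warn = FALSE)

  m <- params$n_decision
  w_dec <- matrix(runif(m * n_exc), m, n_exc)
  w_dec <- .row_normalize(w_dec, warn = FALSE)

  assignment <- lapply(seq_len(n_inputs), function(k)
    ((k - 1L) * params$n_in + 1L):(k * params$n_in))
  names(assignment) <- paste0("channel", seq_len(n_inputs))

  structure(list(params = params,
                 n_total = n, n_exc = n_exc, n_inh = n_inh,
                 n_inputs = n_inputs,
                 w_rec = w, conn = conn, w_dec = w_dec,
                 theta_exc = rep(params$theta_init, n_exc),
                 theta_inh = rep(params$theta_init_inh, n_inh),
                 theta_dec = rep(params$theta_init, m),
                 x = integer(n), x_dec = integer(m),
                 input_assignment = assignment),
            class = "wm_network")
}

#' @export
print.wm_network <- function(x, ...) {
  cat("<wm_network> ", x$n_exc, " excitatory + ", x$n_inh, " inhibitory units, ",
      x$params$n_decision, " decision units, ", x$n_inputs, " input channels\n",
      sep = "")
  cat("  recurrent connections: ", sum(x$conn),
      sprintf(" (density %.3f)", mean(x$conn)), "\n", sep = "")
  cat("  mean thresholds: exc ", signif(mean(x$theta_exc), 3),
      ", inh ", signif(mean(x$theta_inh), 3),
      ", dec ", signif(mean(x$theta_dec), 3), "\n", sep = "")
  invisible(x)
}

# normalize each row to sum one; all-zero rows are left unchanged
.row_normalize <- function(w, warn = TRUE) {
  s <- rowSums(w)
  zero <- s == 0
  if (warn && any(zero))
    warning(sum(zero), " row(s) with all-zero incoming weights left unnormalized")
  s[zero] <- 1
  w / s
}

#' Input currents to the recurrent units
#'
#' Each neuron receives the sum of its excitatory afferent weights gated by
#' presynaptic activity, minus the corresponding inhibitory sum, plus an
#' independent uniform background noise term.
#'
#' @param net A `wm_network`.
#' @param x Presynaptic activity vector (defaults to the network's current
#'   state, i.e. the activity of the previous time step).
#' @param noise Optional noise vector; if `NULL`, drawn uniformly on
#'   `[noise_low, noise_high]` per neuron.
#' @return Numeric vector of per-neuron currents.
#' @export
compute_currents <- function(net, x = net$x, noise = NULL) {
  stopifnot(inherits(net, "wm_network"), length(x) == net$n_total)
  if (is.null(noise))
    noise <- runif(net$n_total, net$params$noise_low, net$params$noise_high)
  sgn <- rep(c(1, -1), c(net$n_exc, net$n_inh))
  as.vector(net$w_rec %*% (sgn * x)) + noise
}

#' Advance the recurrent layer by one step
#'
#' Excitatory drive is computed from the stored activity of the previous
#' step.  The inhibitory population is updated first from that drive and its
#' fresh state gates the excitatory update within the same step, so
#' inhibition tracks activity surges without a one-step lag (the
#' fast-inhibition convention of self-organising recurrent network models);
#' inhibitory-to-inhibitory interactions, when present, stay lagged.  The
#' inclusive threshold rule `x_i = I_i >= theta_i` is applied, then every
#' unit of each forced input channel is set active for this step regardless
#' of its current.
#'
#' @param net A `wm_network`.
#' @param forced_channels Integer indices of input channels forced this step
#'   (empty during delay steps).
#' @param noise Optional noise vector (length `n_total`).
#' @return The network with updated activity `x`.
#' @export
step_recurrent <- function(net, forced_channels = integer(0), noise = NULL) {
  if (length(forced_channels) &&
      (any(forced_channels < 1L) || any(forced_channels > net$n_inputs)))
    stop("unknown input channel: ",
         paste(setdiff(forced_channels, seq_len(net$n_inputs)), collapse = ", "))
  n <- net$n_total; n_exc <- net$n_exc
  if (is.null(noise))
    noise <- runif(n, net$params$noise_low, net$params$noise_high)
  exc_act <- which(net$x[seq_len(n_exc)] == 1)
  inh_act <- n_exc + which(net$x[(n_exc + 1L):n] == 1)
  cur <- noise
  for (j in exc_act) cur <- cur + net$w_rec[, j]
  inh_idx <- (n_exc + 1L):n
  for (j in inh_act) cur[inh_idx] <- cur[inh_idx] - net$w_rec[inh_idx, j]
  xn <- integer(n)
  xn[inh_idx] <- as.integer(cur[inh_idx] >= net$theta_inh)
  for (j in inh_idx[xn[inh_idx] == 1L])
    cur[seq_len(n_exc)] <- cur[seq_len(n_exc)] - net$w_rec[seq_len(n_exc), j]
  xn[seq_len(n_exc)] <- as.integer(cur[seq_len(n_exc)] >= net$theta_exc)
  for (ch in forced_channels) xn[net$input_assignment[[ch]]] <- 1L
  net$x <- xn
  net
}

#' Winner-take-all decision step
#'
#' Decision units are updated synchronously like every other neuron: their
#' currents are computed from the stored excitatory activity (the previous
#' step's state in the trial loop) plus per-unit noise, and exactly one
#' decision unit (the argmax) becomes active.  Exact ties are resolved in
#' favour of the lowest index.  The decision layer runs every time step, but
#' only the step at which the Go cue appears determines reward.  Reading the
#' previous step's activity makes the winner a function of exactly the
#' presynaptic vector that the eligibility trace pairs it with, so
#' reward-gated changes act on the synapses that caused the decision.
#'
#' @param net A `wm_network`; `x` holds the presynaptic activity to read.
#' @param allowed Optional subset of decision-unit indices the competition is
#'   restricted to (used when a context cue gates the decision layer).
#' @param noise Optional noise vector of length `n_decision`.
#' @return The network, with `x_dec` one-hot and the winning index stored in
#'   attribute `"winner"`.
#' @export
step_decision <- function(net, allowed = NULL, noise = NULL) {
  m <- net$params$n_decision
  if (is.null(noise))
    noise <- runif(m, net$params$noise_low, net$params$noise_high)
  cur <- as.vector(net$w_dec %*% net$x[seq_len(net$n_exc)]) + noise
  if (is.null(allowed)) allowed <- seq_len(m)
  winner <- allowed[which.max(cur[allowed])]
  xd <- integer(m); xd[winner] <- 1L
  net$x_dec <- xd
  attr(net, "winner") <- winner
  net
}
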