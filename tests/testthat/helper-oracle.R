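# independent brute-force oracle: literal per-synapse recursion of the trace
# dynamics and the reward commit, written without matrix shortcuts so it can
# arbitrate the vectorized implementation
oracle_episode <- function(activity, f, tau_e, r, eta, w0) {
  n <- ncol(activity)
  e <- matrix(0, n, n)
  for (t in 2:nrow(activity)) {
    e_new <- matrix(0, n, n)
    for (post in 1:n) for (pre in 1:n) {
      decayed <- e[post, pre] * (1 - 1 / tau_e)
      pot <- if (activity[t, post] == 1 && activity[t - 1, pre] == 1) 1 else 0
      dep <- if (activity[t - 1, post] == 1 && activity[t, pre] == 1) f else 0
      e_new[post, pre] <- decayed + pot - dep
    }
    e <- e_new
  }
  w <- w0
  for (post in 1:n) for (pre in 1:n) {
    w[post, pre] <- max(w0[post, pre] + eta * r * e[post, pre], 0)
  }
  list(e = e, w = w)
}
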