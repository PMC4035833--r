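# small deterministic fixtures used across test files

# a tiny network with hand-set weights and zero noise, for exact arithmetic
tiny_net <- function(noise = c(0, 0)) {
  p <- network_params(n_total = 5L, frac_exc = 0.8, n_in = 1L,
                      noise_low = noise[1], noise_high = noise[2],
                      n_decision = 4L)
  net <- initialize_network(p, n_inputs = 2L, seed = 1L)
  net$w_rec <- matrix(0, 5, 5)
  net$conn <- matrix(TRUE, 5, 5); diag(net$conn) <- FALSE
  net$theta_exc <- rep(0.5, 4)
  net$theta_inh <- 0.5
  net$x <- integer(5)
  net
}

# memoized trained runs shared by the acceptance tests
.run_cache <- new.env(parent = emptyenv())
cached <- function(key, maker) {
  if (is.null(.run_cache[[key]])) assign(key, maker(), envir = .run_cache)
  get(key, envir = .run_cache)
}

acc_run <- function(family, seed, schedule = 1:5, trials_per_block = 20000L,
                    delay_mode = "variable", recurrent_mode = "rstdp") {
  key <- paste(family, seed, paste(schedule, collapse = ""), trials_per_block,
               delay_mode, recurrent_mode, sep = "_")
  cached(key, function()
    run_experiment(run_config(family, delay_mode = delay_mode,
                              schedule = schedule,
                              trials_per_block = trials_per_block,
                              recurrent_mode = recurrent_mode, seed = seed)))
}
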