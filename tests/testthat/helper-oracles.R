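# Independent oracles used across tests.

# O(n^2) brute-force event finder: for every start spike, extend while the
# next interval is under the threshold; keep maximal runs with >= min_spikes.
brute_force_events <- function(times, thr = 0.5, min_spikes = 2L) {
  n <- length(times)
  out <- NULL
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && (times[j + 1L] - times[j]) < thr) j <- j + 1L
    if (j - i + 1L >= min_spikes)
      out <- rbind(out, c(times[i], times[j], j - i + 1L))
    i <- j + 1L
  }
  if (is.null(out))
    return(data.frame(start_s = numeric(), stop_s = numeric(),
                      n_spikes = integer()))
  data.frame(start_s = out[, 1], stop_s = out[, 2],
             n_spikes = as.integer(out[, 3]))
}

# exhaustive signed-rank null: enumerate all 2^n sign assignments of the
# ranked absolute differences and compute the two-sided exact p
exhaustive_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.vector(signs %*% r)
  p_lo <- mean(v_null <= v_obs)
  p_hi <- mean(v_null >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

random_spike_train <- function(n, span = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sort(runif(n, 0, span))
}

quick_spectrum <- function(f0, depth = 0.8, rate = 40, dur = 60, seed = 1) {
  tr <- simulate_oscillatory_train(rate, f0, depth, dur, seed = seed)
  analyze_spectrum(bin_spike_train(tr))
}

log_grid_step <- function() {
  g <- spectral_params()$log_grid
  (log(g$f_max) - log(g$f_min)) / (g$n_points - 1)
}
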