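# small shared fixtures, built in code

# compact config: 2 subjects/arm, one factorial pass (40 trials each)
small_config <- function(seed = 1, blink_rate = 0, ...) {
  sim_config(n_subjects_per_arm = 2, repetitions = 1,
             blink_rate = blink_rate, seed = seed, ...)
}

# dense grid-search oracle for the power-law SSE fit
grid_search_power <- function(attc, jttc,
                              alphas = seq(0.5, 3, by = 0.005),
                              betas = seq(0.1, 1.5, by = 0.005)) {
  best <- c(alpha = NA, beta = NA, sse = Inf)
  for (b in betas) {
    xb <- attc^b
    sse <- vapply(alphas, function(a) sum((jttc - a * xb)^2), 0)
    i <- which.min(sse)
    if (sse[i] < best["sse"])
      best <- c(alpha = alphas[i], beta = b, sse = sse[i])
  }
  best
}

# trajectories as scores on a known orthonormal basis (+ optional noise)
make_ensemble <- function(n, score_sds, noise_sd = 0, grid_size = 101,
                          seed = 1) {
  ef <- default_eigenfunctions(grid_size)
  set.seed(seed)
  S <- sapply(seq_along(score_sds), function(j) rnorm(n, 0, score_sds[j]))
  X <- sweep(S %*% t(ef$phi[, seq_along(score_sds), drop = FALSE]),
             2, ef$mean, "+")
  if (noise_sd > 0) X <- X + matrix(rnorm(n * grid_size, 0, noise_sd),
                                    n, grid_size)
  list(X = X, scores = S, basis = ef)
}

# per-subject sequences data.frame from a transition matrix
make_sequences <- function(P, n_subjects, len, seed = 1, arm = "G") {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_subjects), function(s)
    data.frame(subject_id = sprintf("%s_%02d", arm, s), arm = arm,
               trial = seq_len(len),
               profile = simulate_markov_chain(P, len))))
}
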