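# shared fixtures: all synthetic, built in code at test time

# discrete two-state Markov chain in E* space (open/closed) + Gaussian noise
two_state_series <- function(n_frames, k12 = 1.4, k21 = 5.3, dt = 0.04,
                             means = c(0.4, 0.6), sd = 0.05, seed = 1) {
  set.seed(seed)
  A <- matrix(c(exp(-k12 * dt), 1 - exp(-k12 * dt),
                1 - exp(-k21 * dt), exp(-k21 * dt)), 2, 2, byrow = TRUE)
  s <- integer(n_frames)
  s[1] <- 1L
  for (t in 2:n_frames) s[t] <- sample(1:2, 1, prob = A[s[t - 1], ])
  list(x = means[s] + rnorm(n_frames, 0, sd), states = s)
}

# exhaustive max-product decoding: the independent oracle for Viterbi
brute_viterbi <- function(logB, logA, logpi) {
  K <- ncol(logB); T_ <- nrow(logB)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  best <- -Inf; arg <- NULL
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, ]
    s <- logpi[p[1]] + logB[1, p[1]]
    if (T_ > 1)
      for (t in 2:T_) s <- s + logA[p[t - 1], p[t]] + logB[t, p[t]]
    if (s > best) { best <- s; arg <- p }
  }
  unname(arg)
}

# dual-labelled, no-bleach photophysics for clean recovery checks
phys_dual <- function(...) {
  photophysics_model(
    label_fractions = c(dual = 1, donor_only = 0, acceptor_only = 0,
                        unlabelled = 0),
    acceptor_bleach_rate = 0, donor_bleach_rate = 0, ...)
}

# small all-dual experiment helper
sim_dual <- function(scheme, n_molecules, duration, seed, phys = phys_dual()) {
  simulate_experiment(scheme, phys, n_molecules, duration,
                      contaminant_fraction = 0, no_binding_fraction = 0,
                      seed = seed)
}

# combined standard error: fit SE plus the uncertainty printed for the
# generative (measured) rate
combined_se <- function(se_fit, se_reported) sqrt(se_fit^2 + se_reported^2)
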