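test_that("absorbing schemes and validation behave", {
  sch0 <- kinetic_scheme(binding_rate = 0, unbinding_rate_pre = 0,
                         unbinding_rate_post = 0, k_close = 0, k_open = 0,
                         dntp_wait_rate = 0,
                         incorporation_rates = c(A = 0, C = 0, G = 0, T = 0),
                         n_max = 0, t_add = Inf)
  p <- simulate_state_path(sch0, 50, seed = 1)
  expect_equal(nrow(p), 1L)
  expect_equal(p$state, "unbound")
  expect_equal(c(p$t_start, p$t_end), c(0, 50))

  expect_error(kinetic_scheme(k_close = -1), "rates")
  expect_error(kinetic_scheme(k_close = NaN), "rates")
  expect_error(kinetic_scheme(n_max = 20), "exceeds")
  expect_error(simulate_state_path(kinetic_scheme(), 0, 1), "duration")
})

test_that("Gillespie dwell times have the exponential means", {
  # symmetric two-state interconversion at 1 s^-1: mean dwell 1 s each
  sch <- kinetic_scheme(binding_rate = 1000, unbinding_rate_pre = 0,
                        k_close = 1, k_open = 1, n_max = 0, t_add = Inf)
  p <- simulate_state_path(sch, 1e4, seed = 42)
  dur <- p$t_end - p$t_start
  open_d <- dur[p$state == "open"]
  closed_d <- dur[p$state == "closed"]
  expect_gt(length(open_d), 1000)
  # within 3 standard errors of 1/rate (and within the 5% design band)
  expect_lt(abs(mean(open_d) - 1), 3 * sd(open_d) / sqrt(length(open_d)))
  expect_lt(abs(mean(closed_d) - 1), 3 * sd(closed_d) / sqrt(length(closed_d)))
  expect_lt(abs(mean(open_d) - 1), 0.05)
})

test_that("fast dNTP binding drives closed-state occupancy toward 1", {
  sch <- kinetic_scheme(binding_rate = 1000, unbinding_rate_pre = 0,
                        dntp_wait_rate = 500,
                        incorporation_rates = c(A = 2, C = 2, G = 2, T = 2),
                        n_max = 5, t_add = 0, unbinding_rate_post = 0)
  occ <- vapply(1:30, function(s) {
    p <- simulate_state_path(sch, 30, seed = s)
    dur <- p$t_end - p$t_start
    ext_end <- attr(p, "incorporation_times")[attr(p, "n_incorporated")]
    inext <- p$t_end <= ext_end + 1e-9
    sum(dur[inext & p$state == "closed"]) / sum(dur[inext])
  }, numeric(1))
  expect_gt(mean(occ), 0.95) # expected 500/(500+2) per cycle
})

test_that("rendering is an occupancy-weighted noiseless identity", {
  phys <- phys_dual(noise_sd = 0)
  # entirely unbound: DD is exactly the background after the red window
  sch0 <- kinetic_scheme(binding_rate = 0, n_max = 0, t_add = Inf)
  p0 <- simulate_state_path(sch0, 20, seed = 1)
  tr0 <- render_trace(p0, phys, seed = 1)
  after <- tr0$time >= phys$red_laser_window
  expect_true(all(tr0$DD == phys$background_DD))
  expect_true(all(tr0$DA[after] == phys$background_DA))
  expect_true(all(tr0$DA[!after] > phys$background_DA)) # red-laser excess

  # pure closed segment: E* from rendered channels equals E_closed exactly
  p <- data.frame(state = c("unbound", "open", "closed", "unbound"),
                  t_start = c(0, 4, 8, 16), t_end = c(4, 8, 16, 20))
  attr(p, "t_add") <- Inf; attr(p, "duration") <- 20
  class(p) <- c("state_path", "data.frame")
  tr <- render_trace(p, phys, seed = 2)
  mid_closed <- tr$time >= 10 & tr$time < 15
  expect_true(all(abs(tr$E_star[mid_closed] - phys$E_closed) < 1e-9))
  mid_open <- tr$time >= 5 & tr$time < 7.8
  expect_true(all(abs(tr$E_star[mid_open] - phys$E_open) < 1e-9))

  # a switch mid-frame gives E* strictly between the two state values
  p2 <- data.frame(state = c("open", "closed"),
                   t_start = c(0, 1.02), t_end = c(1.02, 2))
  attr(p2, "t_add") <- Inf; attr(p2, "duration") <- 2
  class(p2) <- c("state_path", "data.frame")
  phys0 <- phys_dual(noise_sd = 0, red_laser_window = 0)
  tr2 <- render_trace(p2, phys0, seed = 3)
  # frame 25 covers [1.00, 1.04): half open, half closed
  expect_gt(tr2$E_star[26], phys0$E_open)
  expect_lt(tr2$E_star[26], phys0$E_closed)
})

test_that("simulate_experiment honours population structure and seeds", {
  sch <- kinetic_scheme(n_max = 0, t_add = Inf)
  phys <- photophysics_model()
  # all contaminants: bound essentially throughout
  exc <- simulate_experiment(sch, phys, 8, 40, contaminant_fraction = 1,
                             no_binding_fraction = 0, seed = 5)
  frac_bound <- vapply(exc$paths, function(p) {
    dur <- p$t_end - p$t_start
    sum(dur[p$state != "unbound"]) / sum(dur)
  }, numeric(1))
  expect_true(all(frac_bound > 0.9))

  # empty set, no error
  ex0 <- simulate_experiment(sch, phys, 0, 40, seed = 1)
  expect_length(ex0$traces, 0)

  # identical seed twice: bit-identical traces
  a <- simulate_experiment(sch, phys, 6, 30, seed = 7)
  b <- simulate_experiment(sch, phys, 6, 30, seed = 7)
  expect_identical(a$traces, b$traces)
  c2 <- simulate_experiment(sch, phys, 6, 30, seed = 8)
  expect_false(identical(a$traces, c2$traces))
})

test_that("dark-molecule fraction matches the labelling mixture", {
  # molecules whose binding events are all dark (acceptor-only/unlabelled)
  # should appear at the acceptor_only + unlabelled rate
  sch <- kinetic_scheme(n_max = 0, t_add = Inf, binding_rate = 0.2)
  phys <- photophysics_model()
  ex <- simulate_experiment(sch, phys, 200, 80, contaminant_fraction = 0,
                            no_binding_fraction = 0, seed = 9)
  p_dark <- sum(phys$label_fractions[c("acceptor_only", "unlabelled")])
  species <- unlist(lapply(ex$traces, function(tr) {
    et <- attr(tr, "events_truth"); if (is.null(et)) character(0) else et$species
  }))
  phat <- mean(species %in% c("acceptor_only", "unlabelled"))
  n <- length(species)
  expect_gt(n, 300)
  expect_lt(abs(phat - p_dark), 3 * sqrt(p_dark * (1 - p_dark) / n))
})

test_that("sums of exponential dwells have gamma moments and law", {
  x1 <- sample_extension_dwells(1, 2, reps = 1e5, seed = 1)
  expect_lt(abs(mean(x1) - 0.5), 3 * sd(x1) / sqrt(length(x1)))

  x5 <- sample_extension_dwells(5, 3.2, reps = 1e4, seed = 2)
  se_m <- sd(x5) / sqrt(length(x5))
  expect_lt(abs(mean(x5) - 5 / 3.2), 3 * se_m)
  expect_lt(abs(var(x5) - 5 / 3.2^2), 4 * 5 / 3.2^2 / sqrt(length(x5)) * 3)

  mixed <- c(3.4, 2, 1, 1.5, 3.4)
  xm <- sample_extension_dwells(5, mixed, reps = 2e4, seed = 3)
  expect_lt(abs(mean(xm) - sum(1 / mixed)), 3 * sd(xm) / sqrt(length(xm)))

  # identical-rates law: Kolmogorov-Smirnov against the gamma CDF
  ks <- suppressWarnings(ks.test(x5, pgamma, shape = 5, rate = 3.2))
  expect_gt(ks$p.value, 0.01)

  expect_error(sample_extension_dwells(2, c(1, 0), reps = 10, seed = 1),
               "rates")
  expect_error(sample_extension_dwells(2, c(1, 2, 3), reps = 10, seed = 1),
               "length")
})
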