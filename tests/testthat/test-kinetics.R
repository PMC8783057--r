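test_that("exponential MLE has its closed forms and guards", {
  set.seed(1)
  d <- rexp(500, 2.5)
  fit <- fit_exponential_rate(d, n_boot = 50, seed = 1)
  expect_equal(fit$rate, 1 / mean(d)) # uncensored, t_min = 0: exactly 1/mean
  expect_equal(fit$method, "mle_exponential")
  expect_gt(fit$stderr, 0)

  # censoring contributes exposure: censored-heavy data still unbiased
  set.seed(2)
  tau <- rexp(4000, 2.5)
  cens_at <- rexp(4000, 1.5)
  obs <- pmin(tau, cens_at)
  dfc <- data.frame(duration = obs, right_censored = cens_at < tau)
  fc <- fit_exponential_rate(dfc, n_boot = 50, seed = 2)
  expect_lt(abs(fc$rate - 2.5), 3 * fc$stderr)

  # drop-censored policy with everything censored: informative error
  allc <- data.frame(duration = rexp(50, 1), right_censored = TRUE)
  expect_error(fit_exponential_rate(allc, policy = "drop_censored"),
               "uncensored")
  expect_error(fit_exponential_rate(rexp(5, 1)), "too few")
})

test_that("frame-quantised dwells at 3.4/s are recovered via the discrete MLE", {
  dt <- 0.04
  set.seed(3)
  tau <- rexp(1e4, 3.4)
  m <- round(tau / dt) # camera rounding model
  d <- data.frame(duration = m[m >= 1] * dt, right_censored = FALSE)
  fit <- fit_exponential_rate(d, frame_dt = dt, n_boot = 200, seed = 3)
  expect_equal(fit$t_min, 2 * dt)
  expect_true(fit$discrete)
  expect_lt(abs(fit$rate - 3.4), 3 * fit$stderr)
})

test_that("first closed dwell implements the begin-closed filter", {
  dt <- 0.04
  dw <- data.frame(molecule_id = "m", event_id = 1L,
                   state_label = c("closed", "open"),
                   duration = c(1.5, 3), left_censored = c(TRUE, FALSE),
                   right_censored = c(FALSE, TRUE), start_time = c(0, 1.5))
  fc <- first_closed_dwell(dw, dt)
  expect_equal(fc$duration, 1.5)
  expect_false(fc$right_censored)

  # long leading open dwell fails the filter
  dw2 <- dw; dw2$state_label <- c("open", "closed"); dw2$duration <- c(2, 1.5)
  expect_null(first_closed_dwell(dw2, dt))

  # one-frame leading open dwell is tolerated
  dw3 <- data.frame(molecule_id = "m", event_id = 1L,
                    state_label = c("open", "closed"),
                    duration = c(dt, 1.5), left_censored = c(TRUE, FALSE),
                    right_censored = c(FALSE, TRUE),
                    start_time = c(0, dt))
  fc3 <- first_closed_dwell(dw3, dt, start_tolerance = 1)
  expect_equal(fc3$duration, 1.5)
  expect_true(fc3$right_censored) # censored flag propagates

  # return-to-open filter keeps only events with a later open dwell
  dws <- rbind(cbind(dw, K_selected = 2),
               cbind(data.frame(molecule_id = "m", event_id = 2L,
                                state_label = "closed", duration = 2,
                                left_censored = TRUE, right_censored = TRUE,
                                start_time = 0), K_selected = 2))
  pt_all <- polymerisation_times(dws, dt)
  expect_equal(nrow(pt_all), 2L)
  pt_open <- polymerisation_times(dws, dt, return_to_open_only = TRUE)
  expect_equal(nrow(pt_open), 1L)
  expect_equal(pt_open$event_id, 1L)
})

test_that("polymerisation-time histograms report mean and empty marker", {
  h <- polymerisation_time_histogram(c(1, 2, 3))
  expect_equal(h$mean, 2)
  expect_equal(h$n, 3L)
  expect_false(h$empty)
  expect_equal(diff(h$breaks[1:2]), 0.25)

  h0 <- polymerisation_time_histogram(numeric(0))
  expect_true(h0$empty)
  expect_true(is.na(h0$mean))

  # synthetic 5-nt extension dwells at identical 3.2/s rates: gamma mean
  x <- sample_extension_dwells(5, 3.2, reps = 2000, seed = 4)
  h5 <- polymerisation_time_histogram(x)
  expect_lt(abs(h5$mean - 5 / 3.2), 3 * sd(x) / sqrt(length(x)))
})

test_that("hypoexponential density integrates to one and collapses to gamma", {
  # equal rates: exact gamma
  tq <- seq(0.01, 5, by = 0.01)
  expect_equal(dhypoexp(tq, rep(3.2, 5)), dgamma(tq, 5, 3.2))
  expect_equal(phypoexp(tq, rep(3.2, 5)), pgamma(tq, 5, 3.2))

  # distinct rates: quadrature of the convolution density is 1 within 1e-6
  for (rates in list(c(3.4, 2, 1, 1.5), c(5, 0.8), c(3.4, 3.4, 2, 1, 1.5))) {
    gr <- polfret:::hypoexp_grid(rates)
    integral <- sum(gr$f) * gr$dt - (gr$f[1] + gr$f[length(gr$f)]) * gr$dt / 2
    expect_lt(abs(integral - 1), 1e-6)
    # mean of the density matches sum(1/rates)
    mu <- sum(gr$t * gr$f) * gr$dt
    expect_lt(abs(mu - sum(1 / rates)), 1e-4)
  }

  # near-equal rates stay numerically stable (classical partial fractions
  # would cancel catastrophically here)
  d1 <- dhypoexp(tq, c(2, 2 + 1e-7, 3))
  d2 <- dhypoexp(tq, c(2, 2, 3))
  expect_lt(max(abs(d1 - d2)), 1e-3)

  expect_error(dhypoexp(1, c(1, -1)), "rates")
})

test_that("extension-model fits recover rates and goodness of fit", {
  x <- sample_extension_dwells(5, 3.2, reps = 1e4, seed = 5)

  free <- fit_extension_model(x, 5, "free_identical")
  expect_lt(abs(free$rates[["rate"]] - 3.2) / 3.2, 0.02)

  fixed <- fit_extension_model(x, 5, "fixed_identical", rate = 3.2)
  expect_gt(fixed$ks_p, 0.01) # true model passes KS at alpha = 0.01
  # a visibly wrong fixed rate fails the same test
  wrong <- fit_extension_model(x, 5, "fixed_identical", rate = 6)
  expect_lt(wrong$ks_p, 0.01)

  expect_error(fit_extension_model(x[1:10], 5, "free_identical"), ">= 30")
  expect_error(fit_extension_model(x, 5, "per_base_type"),
               "template_sequence")
})

test_that("per-base-type hypoexponential MLE maximises the likelihood and
           recovers the identifiable structure", {
  # incorporated bases TAGC (templating ATCG): rates 3.4, 2, 1.5, 1.
  # Interior rates of a hypoexponential are weakly identified at n = 1e4
  # (the likelihood is symmetric in the rate multiset and nearly flat when
  # two rates approach each other), so the checks target what the data
  # determine: the attained likelihood, the slowest rate (which shapes the
  # tail), the distribution itself, and its mean.
  rates_by_base <- c(T = 3.4, A = 2, G = 1.5, C = 1)
  inc <- c("T", "A", "G", "C")
  x <- sample_extension_dwells(4, unname(rates_by_base[inc]), reps = 1e4,
                               seed = 6)
  fit <- fit_extension_model(x, 4, "per_base_type",
                             template_sequence = "ATCG", seed = 7)
  expect_setequal(names(fit$rates), c("A", "C", "G", "T"))

  # the optimiser reaches at least the likelihood of the generative rates
  nll_truth <- -sum(log(dhypoexp(x, unname(rates_by_base[inc]))))
  expect_lte(-fit$loglik, nll_truth + 0.01)

  # slowest rate recovered within 15%; fitted distribution matches the
  # sample (KS) and its mean matches sum(1/rates)
  expect_lt(abs(min(fit$rates) - 1) / 1, 0.15)
  expect_gt(fit$ks_p, 0.01)
  expect_lt(abs(sum(1 / fit$rates) - sum(1 / rates_by_base)) /
              sum(1 / rates_by_base), 0.02)
})

test_that("post-synchronised decay flags flat ensembles; guards hold", {
  dt <- 0.04
  # constant-E* events: no decay, k unidentifiable
  traces <- list()
  for (i in 1:25) {
    tot <- rep(200, 200); tot[51:150] <- 800
    traces[[sprintf("m%02d", i)]] <-
      time_trace(DD = tot * 0.54, DA = tot * 0.46, frame_dt = dt,
                 molecule_id = sprintf("m%02d", i))
  }
  traces <- structure(traces, class = "trace_set", frame_dt = dt)
  ev <- detect_events_set(traces)
  ps <- postsync_mean_fret(ev, traces, begins_closed_only = FALSE,
                           n_boot = 0)
  expect_true(ps$unidentifiable)

  expect_error(postsync_mean_fret(ev, traces, window = 0.01), "window")
  expect_error(postsync_mean_fret(ev[0, ], traces,
                                  begins_closed_only = FALSE), "events")
})

test_that("polymerisation rates and the Arrhenius energy match print forms", {
  expect_equal(polymerisation_rate(5, 1.9), 2.6)
  expect_equal(polymerisation_rate(10, 2.2), 4.5)
  expect_equal(polymerisation_rate(7, 7), 1.0)
  expect_error(polymerisation_rate(5, 0), "mean_dwell")

  expect_lt(abs(arrhenius_delta_e(29, 5.3, 298) - 1.0), 0.05)
  expect_equal(arrhenius_delta_e(2, 2), 0)
  expect_lt(abs(arrhenius_delta_e(exp(1) * 3, 3, 298) - 0.593), 1e-3)
  expect_error(arrhenius_delta_e(-1, 2), "rates")
})
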