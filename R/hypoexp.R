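# Hypoexponential (sum of independent exponentials) density/CDF.
#
# Equal rates collapse exactly to gamma(n, rate). With distinct rates the
# sum is a convolution of Erlang components, one per distinct rate, which
# is evaluated by trapezoid-corrected FFT convolution on a fine grid; this
# is stable for arbitrarily close rate pairs, where the classical
# partial-fraction formula suffers catastrophic cancellation.

hypoexp_components <- function(rates, rel_tol = 1e-9) {
  r <- sort(as.numeric(rates))
  grp <- cumsum(c(TRUE, diff(r) > rel_tol * r[-length(r)]))
  ks <- vapply(split(r, grp), mean, numeric(1))
  ms <- vapply(split(r, grp), length, integer(1))
  list(rate = unname(ks), shape = unname(ms))
}

hypoexp_grid <- function(rates, n_grid = 2^16, t_max = NULL) {
  cp <- hypoexp_components(rates)
  mu <- sum(cp$shape / cp$rate)
  sdv <- sqrt(sum(cp$shape / cp$rate^2))
  if (is.null(t_max)) t_max <- mu + 20 * sdv
  dt <- t_max / n_grid
  tg <- (0:(n_grid - 1)) * dt
  comp <- lapply(seq_along(cp$rate), function(j)
    dgamma(tg, shape = cp$shape[j], rate = cp$rate[j]))
  # halving endpoint samples makes the FFT convolution a trapezoid rule
  f <- comp[[1]]
  f[1] <- f[1] / 2
  if (length(comp) > 1) {
    for (j in 2:length(comp)) {
      g <- comp[[j]]
      g[1] <- g[1] / 2
      n <- length(f)
      ff <- stats::fft(c(f, rep(0, n)))
      fg <- stats::fft(c(g, rep(0, n)))
      f <- Re(stats::fft(ff * fg, inverse = TRUE))[seq_len(n)] / (2 * n) * dt
    }
  } else {
    f[1] <- f[1] * 2 # single gamma component: undo the edge halving
  }
  f <- pmax(f, 0)
  list(t = tg, f = f, dt = dt, t_max = t_max, components = cp)
}

#' Hypoexponential density
#'
#' Density of the sum of independent exponential variables with the given
#' `rates` (one rate per summand; repeats allowed). When all rates are
#' equal this is exactly the gamma density `dgamma(x, n, rate)`; otherwise
#' the Erlang-component convolution is evaluated numerically on a fine
#' grid and interpolated.
#'
#' @param x non-negative quantiles.
#' @param rates per-second rates of the summed exponentials.
#' @param n_grid grid resolution for the numerical convolution.
#' @return Density values at `x`.
#' @export
dhypoexp <- function(x, rates, n_grid = 2^16) {
  if (any(rates <= 0) || any(!is.finite(rates))) stop("rates must be > 0")
  cp <- hypoexp_components(rates)
  if (length(cp$rate) == 1L)
    return(dgamma(x, shape = cp$shape, rate = cp$rate))
  gr <- hypoexp_grid(rates, n_grid = n_grid)
  out <- approx(gr$t, gr$f, xout = x, yleft = 0, rule = 2)$y
  out[x < 0] <- 0
  out[x > gr$t_max] <- 0
  out
}

#' Hypoexponential distribution function
#'
#' @inheritParams dhypoexp
#' @param q non-negative quantiles.
#' @return `P(X <= q)`.
#' @export
phypoexp <- function(q, rates, n_grid = 2^16) {
  if (any(rates <= 0) || any(!is.finite(rates))) stop("rates must be > 0")
  cp <- hypoexp_components(rates)
  if (length(cp$rate) == 1L)
    return(pgamma(q, shape = cp$shape, rate = cp$rate))
  gr <- hypoexp_grid(rates, n_grid = n_grid)
  cf <- (cumsum(gr$f) - gr$f / 2 - gr$f[1] / 2) * gr$dt # trapezoid cumulative
  cf <- pmin(pmax(cf, 0), 1)
  out <- approx(gr$t, cf, xout = q, yleft = 0, yright = 1)$y
  out[q <= 0] <- 0
  out
}
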