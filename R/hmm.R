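#' Default priors for the variational-Bayes FRET HMM
#'
#' Conjugate priors: Normal-Gamma on each state's emission (mean, precision),
#' Dirichlet on the initial distribution and on each transition-matrix row.
#' Emission means are weakly anchored at E* = 0.2 / 0.45 / 0.65
#' (bleached-or-donor-only, fingers-open, fingers-closed) with a small
#' pseudo-count (`beta0`) so the data dominate; the precision prior is broad
#' around an E* noise SD of ~0.07. Transition rows get concentration 1 plus
#' a mild self-transition bonus, reflecting frame times well below typical
#' dwell times.
#'
#' @param K number of states (1-3).
#' @param mean_anchors anchor E* means used for `K = 3` (subsets used for
#'   smaller K).
#' @param beta0 prior pseudo-count on each emission mean.
#' @param a0,b0 Gamma prior shape/rate on each emission precision.
#' @param alpha_pi Dirichlet concentration for the initial distribution.
#' @param alpha_A off-diagonal Dirichlet concentration for transition rows.
#' @param self_bonus extra concentration added to the diagonal.
#' @return list of prior hyperparameters.
#' @export
hmm_priors <- function(K, mean_anchors = c(0.2, 0.45, 0.65), beta0 = 0.25,
                       a0 = 2, b0 = 0.01, alpha_pi = 1, alpha_A = 1,
                       self_bonus = 2) {
  stopifnot(K >= 1, K <= length(mean_anchors))
  m0 <- switch(K, mean_anchors[2], mean_anchors[2:3], mean_anchors)
  list(K = K, m0 = m0, beta0 = beta0, a0 = a0, b0 = b0,
       alpha_pi = rep(alpha_pi, K),
       alpha_A = matrix(alpha_A, K, K) + diag(self_bonus, K))
}

kl_dirichlet <- function(w, w0) {
  lgamma(sum(w)) - sum(lgamma(w)) - lgamma(sum(w0)) + sum(lgamma(w0)) +
    sum((w - w0) * (digamma(w) - digamma(sum(w))))
}

kl_normalgamma <- function(m, beta, a, b, m0, beta0, a0, b0) {
  kl_g <- (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
    a0 * (log(b) - log(b0)) + a * (b0 - b) / b
  kl_n <- 0.5 * (log(beta / beta0) + beta0 / beta - 1 +
                   beta0 * (a / b) * (m - m0)^2)
  kl_g + kl_n
}

state_label_from_mean <- function(m) {
  ifelse(m < 0.3, "donor_only",
         ifelse(m < 0.53, "open",
                ifelse(m < 0.8, "closed", "high_unassigned")))
}

#' Fit a Gaussian-emission hidden Markov model to an E* series
#'
#' Variational-Bayes fit of a `K`-state HMM with Gaussian emissions in E*
#' space, conjugate priors ([hmm_priors()]), and the variational lower
#' bound (log evidence approximation) as the model score. Undefined E*
#' frames (`NA`) are excluded before fitting. Several restarts with
#' jittered emission means are run and the best bound kept. The bound is
#' non-decreasing across iterations within each restart. A BIC score
#' computed at the posterior-mean parameters is also reported so evidence-
#' based selection can be cross-checked.
#'
#' @param E_series numeric vector of E* values (may contain `NA`).
#' @param K number of states (1-3).
#' @param priors list from [hmm_priors()]; default priors if `NULL`.
#' @param seed integer seed (restart jitter).
#' @param n_restarts restarts with jittered initial means (default 5).
#' @param max_iter maximum VB iterations per restart.
#' @param tol absolute ELBO convergence tolerance.
#' @return An object of class `fret_hmm`: fields `K`, `means`,
#'   `variances` (posterior-mean noise variances), `transition_matrix`
#'   (row-stochastic, per frame), `initial_probs`, `evidence` (ELBO),
#'   `bic`, `elbo_trace`, `state_labels`, `n_frames_fit`, `converged`.
#'   States are sorted by ascending mean.
#' @export
fit_hmm <- function(E_series, K, priors = NULL, seed = 1, n_restarts = 5,
                    max_iter = 200, tol = 1e-6) {
  x <- as.numeric(E_series)
  x <- x[is.finite(x)]
  T_ <- length(x)
  if (T_ < K + 2) stop("series too short for K = ", K, " (", T_, " frames)")
  pr <- priors %||% hmm_priors(K)
  stopifnot(pr$K == K)
  set.seed(seed)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    # initial q: prior hyperparameters, means at spread quantiles + jitter
    qs <- if (K == 1) 0.5 else seq(0.15, 0.85, length.out = K)
    m <- as.numeric(quantile(x, qs, names = FALSE)) +
      if (r == 1) 0 else rnorm(K, 0, 0.05)
    beta <- rep(pr$beta0 + 1, K)
    a <- rep(pr$a0 + 1, K)
    b <- a / 200 # initial precision guess ~ (0.07)^-2
    w_pi <- pr$alpha_pi + 1 / K
    W <- pr$alpha_A + T_ / (K * K)

    elbo <- -Inf; trace <- numeric(0); converged <- FALSE
    for (it in seq_len(max_iter)) {
      # E-step with expected-log parameters
      Elog_lam <- digamma(a) - log(b)
      logB <- matrix(0, T_, K)
      for (k in seq_len(K))
        logB[, k] <- 0.5 * Elog_lam[k] - 0.5 * log(2 * pi) -
          0.5 * ((a[k] / b[k]) * (x - m[k])^2 + 1 / beta[k])
      logA <- digamma(W) - digamma(rowSums(W))
      logpi <- digamma(w_pi) - digamma(sum(w_pi))
      fb <- fb_hmm(logB, logA, logpi)

      kl <- kl_dirichlet(w_pi, pr$alpha_pi)
      for (k in seq_len(K)) {
        kl <- kl + kl_dirichlet(W[k, ], pr$alpha_A[k, ]) +
          kl_normalgamma(m[k], beta[k], a[k], b[k],
                         pr$m0[k], pr$beta0, pr$a0, pr$b0)
      }
      new_elbo <- fb$loglik - kl
      trace <- c(trace, new_elbo)
      if (is.finite(elbo) && abs(new_elbo - elbo) < tol) {
        elbo <- new_elbo
        converged <- TRUE
        break
      }
      elbo <- new_elbo

      # M-step
      g <- fb$gamma
      Nk <- colSums(g)
      xbar <- ifelse(Nk > 1e-12, colSums(g * x) / pmax(Nk, 1e-12), pr$m0)
      Sk <- vapply(seq_len(K), function(k) {
        if (Nk[k] > 1e-12) sum(g[, k] * (x - xbar[k])^2) / Nk[k] else 0
      }, numeric(1))
      beta <- pr$beta0 + Nk
      m <- (pr$beta0 * pr$m0 + Nk * xbar) / beta
      a <- pr$a0 + Nk / 2
      b <- pr$b0 + 0.5 * (Nk * Sk +
                            pr$beta0 * Nk * (xbar - pr$m0)^2 / beta)
      w_pi <- pr$alpha_pi + g[1, ]
      W <- pr$alpha_A + fb$xi_sum
    }

    if (is.null(best) || elbo > best$evidence) {
      best <- list(m = m, beta = beta, a = a, b = b, w_pi = w_pi, W = W,
                   evidence = elbo, elbo_trace = trace,
                   converged = converged)
    }
  }

  # posterior-mean parameters, states sorted by ascending mean
  ord <- order(best$m)
  means <- best$m[ord]
  vars <- (best$b / best$a)[ord]
  A <- (best$W / rowSums(best$W))[ord, ord, drop = FALSE]
  ip <- (best$w_pi / sum(best$w_pi))[ord]

  # BIC at posterior-mean parameters (cross-check for model selection)
  logB <- vapply(seq_len(K), function(k)
    dnorm(x, means[k], sqrt(vars[k]), log = TRUE), numeric(T_))
  logB <- matrix(logB, T_, K)
  ll <- fb_hmm(logB, log(A), log(ip))$loglik
  p <- (K - 1) + K * (K - 1) + 2 * K
  bic <- -2 * ll + p * log(T_)

  structure(list(K = K, means = means, variances = vars,
                 transition_matrix = A, initial_probs = ip,
                 evidence = best$evidence, bic = bic, loglik = ll,
                 elbo_trace = best$elbo_trace,
                 state_labels = state_label_from_mean(means),
                 n_frames_fit = T_, converged = best$converged,
                 priors = pr, seed = seed),
            class = "fret_hmm")
}

#' @export
print.fret_hmm <- function(x, ...) {
  cat(sprintf("fret_hmm: K = %d, %d frames, evidence %.2f (BIC %.2f)%s\n",
              x$K, x$n_frames_fit, x$evidence, x$bic,
              if (x$converged) "" else " [not converged]"))
  cat("  states:", paste(sprintf("%s (E*=%.3f, sd=%.3f)", x$state_labels,
                                 x$means, sqrt(x$variances)),
                         collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.fret_hmm <- function(object, ...) {
  list(means = object$means, variances = object$variances,
       transition_matrix = object$transition_matrix,
       initial_probs = object$initial_probs)
}

#' @export
logLik.fret_hmm <- function(object, ...) {
  structure(object$loglik, df = (object$K - 1) + object$K * (object$K - 1) +
              2 * object$K, class = "logLik")
}

#' Select the best HMM by maximum evidence
#'
#' Returns the model with the largest variational evidence (ties broken
#' toward smaller `K`); with `criterion = "bic"` the smallest BIC wins
#' (the robustness cross-check).
#'
#' @param models list of [fit_hmm()] objects.
#' @param criterion "evidence" (default) or "bic".
#' @return The selected `fret_hmm`.
#' @export
select_model <- function(models, criterion = c("evidence", "bic")) {
  if (length(models) == 0L) stop("no models to select from")
  criterion <- match.arg(criterion)
  Ks <- vapply(models, `[[`, numeric(1), "K")
  score <- switch(criterion,
                  evidence = vapply(models, `[[`, numeric(1), "evidence"),
                  bic = -vapply(models, `[[`, numeric(1), "bic"))
  ord <- order(-score, Ks)
  models[[ord[1]]]
}

#' Decode the most probable state sequence
#'
#' Viterbi decoding under the posterior-mean parameters of a fitted
#' [fit_hmm()] model. Undefined E* frames (`NA`) carry no emission
#' information (flat emission) and are absorbed into the surrounding path.
#'
#' @param model a `fret_hmm`.
#' @param E_series numeric E* vector (may contain `NA`).
#' @return Character vector of state labels per frame (factor levels from
#'   the model's `state_labels`), with integer state indices in attribute
#'   `state_index`.
#' @export
decode_states <- function(model, E_series) {
  x <- as.numeric(E_series)
  T_ <- length(x)
  K <- model$K
  logB <- matrix(0, T_, K)
  ok <- is.finite(x)
  for (k in seq_len(K))
    logB[ok, k] <- dnorm(x[ok], model$means[k], sqrt(model$variances[k]),
                         log = TRUE)
  path <- viterbi_hmm(logB, log(model$transition_matrix),
                      log(model$initial_probs)) + 1L
  out <- model$state_labels[path]
  attr(out, "state_index") <- path
  out
}

#' Convert a decoded state path into dwells
#'
#' Run-length encodes the decoded labels; each maximal constant-label run
#' becomes one dwell of `run length * frame_dt` seconds. The first and last
#' dwells of an event are censored at the event boundaries (the underlying
#' state extends beyond the observation window).
#'
#' @param decoded character vector from [decode_states()].
#' @param frame_dt frame time in seconds.
#' @param start_time_s time of the first decoded frame (event start).
#' @param molecule_id,event_id identifiers copied into the output.
#' @return data.frame with columns `molecule_id`, `event_id`,
#'   `state_label`, `duration`, `left_censored`, `right_censored`,
#'   `start_time`.
#' @export
extract_dwells <- function(decoded, frame_dt, start_time_s = 0,
                           molecule_id = "mol", event_id = 1L) {
  if (length(decoded) == 0L) stop("empty decoded path")
  r <- rle(as.character(decoded))
  n <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(molecule_id = molecule_id, event_id = event_id,
             state_label = r$values,
             duration = r$lengths * frame_dt,
             left_censored = seq_len(n) == 1L,
             right_censored = seq_len(n) == n,
             start_time = start_time_s + (starts - 1L) * frame_dt,
             stringsAsFactors = FALSE)
}

#' Segment binding events with per-event HMMs
#'
#' For every binding event, fits HMMs with 1 to `max_states` states to the
#' first `fit_window` seconds of the event's E* series, selects the model
#' by maximum evidence, Viterbi-decodes the fitted window, and extracts
#' dwells. Each event is fitted independently.
#'
#' @param traces a `trace_set` (list of [time_trace()], named by
#'   molecule id).
#' @param events a `binding_events` data.frame.
#' @param max_states maximum state count tried (default 3).
#' @param fit_window seconds of each event fitted (default 5; `Inf` for
#'   the full event).
#' @param seed master seed; per-event seeds fan out from it.
#' @param criterion model-selection criterion (see [select_model()]).
#' @param ... further arguments to [fit_hmm()].
#' @return list with `dwells` (data.frame as in [extract_dwells()] plus a
#'   `K_selected` column merged per event) and `models` (list of selected
#'   `fret_hmm`, one per segmentable event, named `<molecule>:<event>`).
#' @export
segment_events <- function(traces, events, max_states = 3, fit_window = 5,
                           seed = 1, criterion = "evidence", ...) {
  dwells <- list()
  models <- list()
  dt <- attr(traces[[1]], "frame_dt")
  win_frames <- if (is.finite(fit_window)) max(3L, round(fit_window / dt)) else Inf
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    tr <- traces[[ev$molecule_id]]
    if (is.null(tr)) next
    idx <- (ev$start_frame + 1L):min(ev$end_frame, nrow(tr))
    if (is.finite(win_frames) && length(idx) > win_frames)
      idx <- idx[seq_len(win_frames)]
    x <- tr$E_star[idx]
    if (sum(is.finite(x)) < max_states + 2) next
    cand <- list()
    for (K in seq_len(max_states)) {
      fit <- tryCatch(
        fit_hmm(x, K, seed = fan_seed(seed, i * 10L + K), ...),
        error = function(e) NULL)
      if (!is.null(fit)) cand[[length(cand) + 1L]] <- fit
    }
    if (!length(cand)) next
    mod <- select_model(cand, criterion = criterion)
    dec <- decode_states(mod, x)
    dw <- extract_dwells(dec, dt, start_time_s = ev$start_s,
                         molecule_id = ev$molecule_id,
                         event_id = ev$event_id)
    dw$K_selected <- mod$K
    # a window truncated before the event end right-censors the last dwell
    dw$right_censored[nrow(dw)] <- TRUE
    dwells[[length(dwells) + 1L]] <- dw
    models[[paste0(ev$molecule_id, ":", ev$event_id)]] <- mod
  }
  dwells <- if (length(dwells)) do.call(rbind, dwells) else
    data.frame(molecule_id = character(0), event_id = integer(0),
               state_label = character(0), duration = numeric(0),
               left_censored = logical(0), right_censored = logical(0),
               start_time = numeric(0), K_selected = integer(0))
  rownames(dwells) <- NULL
  attr(dwells, "frame_dt") <- dt
  list(dwells = dwells, models = models)
}
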