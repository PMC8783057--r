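#' Simulate a ground-truth state path for one DNA molecule
#'
#' Exact stochastic (Gillespie) simulation of KF binding/unbinding and
#' fingers dynamics on a single immobilised DNA molecule. Before `t_add`
#' (nucleotide addition) only binary-complex dynamics occur: bound KF
#' interconverts open <-> closed at `k_close`/`k_open` and dissociates at
#' `unbinding_rate_pre`. From `t_add` onwards each bound episode runs the
#' nucleotide-addition cycle — a fingers-open dNTP wait
#' (`dntp_wait_rate`) followed by a fingers-closed incorporation dwell at
#' the per-base rate — until `n_max` bases are incorporated, after which
#' the complex shows binary dynamics but dissociates at
#' `unbinding_rate_post`. Rate switches at `t_add` are handled by
#' truncating the current exponential dwell at `t_add` and redrawing
#' (valid by memorylessness).
#'
#' @param scheme a [kinetic_scheme()].
#' @param duration total simulated time in seconds.
#' @param seed integer seed.
#' @param initial_state state at t = 0 ("unbound", "open" or "closed").
#' @return A `state_path`: data.frame with columns `state`, `t_start`,
#'   `t_end` (contiguous, non-overlapping), with attributes
#'   `n_incorporated`, `incorporation_times`, `t_add`, `duration`.
#' @export
#' @examples
#' sch <- kinetic_scheme(n_max = 0, t_add = Inf)
#' p <- simulate_state_path(sch, 100, seed = 1)
#' head(p)
simulate_state_path <- function(scheme, duration, seed,
                                initial_state = c("unbound", "open", "closed")) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  initial_state <- match.arg(initial_state)
  set.seed(seed)

  rate_pos <- incorporation_rate_by_position(scheme)
  if (any(!is.finite(rate_pos))) stop("non-finite incorporation rate")
  # dissociation after extension stalls: fast only for blunt/short overhangs
  leftover <- nchar(scheme$template_sequence) - scheme$n_max
  u_post <- if (leftover <= (scheme$overhang_cutoff %||% 4))
    scheme$unbinding_rate_post else scheme$unbinding_rate_pre

  t <- 0
  state <- initial_state
  n_inc <- 0L
  inc_times <- numeric(0)
  st <- character(0); t0 <- numeric(0); t1 <- numeric(0)

  push <- function(s, a, b) {
    n <- length(st)
    if (n && st[n] == s && abs(t1[n] - a) < 1e-12) {
      t1[n] <<- b # merge contiguous same-state segments
    } else {
      st[n + 1L] <<- s; t0[n + 1L] <<- a; t1[n + 1L] <<- b
    }
  }

  repeat {
    post_add <- t >= scheme$t_add
    extending <- post_add && n_inc < scheme$n_max
    if (state == "unbound") {
      rates <- c(bind = scheme$binding_rate)
      dests <- "open"
    } else if (extending) {
      if (state == "open") {
        rates <- c(close = scheme$dntp_wait_rate,
                   unbind = scheme$unbinding_rate_pre)
        dests <- c("closed", "unbound")
      } else {
        rates <- c(incorporate = rate_pos[n_inc + 1L],
                   unbind = scheme$unbinding_rate_pre)
        dests <- c("open", "unbound")
      }
    } else {
      u <- if (post_add && n_inc >= scheme$n_max) u_post
        else scheme$unbinding_rate_pre
      if (state == "open") {
        rates <- c(close = scheme$k_close, unbind = u)
        dests <- c("closed", "unbound")
      } else {
        rates <- c(open = scheme$k_open, unbind = u)
        dests <- c("open", "unbound")
      }
    }
    r <- sum(rates)
    dwell <- if (r > 0) rexp(1, r) else Inf
    t_next <- t + dwell
    if (!post_add && t_next > scheme$t_add && scheme$t_add < duration) {
      # regime change: truncate at t_add, redraw under post-addition rates
      push(state, t, scheme$t_add)
      t <- scheme$t_add
      next
    }
    if (t_next >= duration) {
      push(state, t, duration)
      break
    }
    push(state, t, t_next)
    what <- if (length(rates) == 1L) 1L else
      sample.int(length(rates), 1L, prob = rates)
    if (names(rates)[what] == "incorporate") {
      n_inc <- n_inc + 1L
      inc_times <- c(inc_times, t_next)
    }
    state <- dests[what]
    t <- t_next
  }

  out <- data.frame(state = st, t_start = t0, t_end = t1,
                    stringsAsFactors = FALSE)
  attr(out, "n_incorporated") <- n_inc
  attr(out, "incorporation_times") <- inc_times
  attr(out, "t_add") <- scheme$t_add
  attr(out, "duration") <- duration
  class(out) <- c("state_path", "data.frame")
  out
}

# mean of a piecewise-constant function over consecutive frames.
# breaks: sorted breakpoints (length m+1 spanning [0, duration]);
# values: m interval values; edges: frame edges (length n_frames+1).
frame_average <- function(breaks, values, edges) {
  cum <- c(0, cumsum(values * diff(breaks)))
  idx <- findInterval(edges, breaks, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(values))
  at <- cum[idx] + values[idx] * (edges - breaks[idx])
  diff(at) / diff(edges)
}

#' Render a state path as a camera-frame fluorescence trace
#'
#' Converts a ground-truth [simulate_state_path()] trajectory into DD/DA
#' intensity time series at the camera frame rate. Each bound episode is a
#' fresh KF molecule whose labelling species is drawn from
#' `phys$label_fractions` (or forced via `force_species`); acceptor
#' photobleaching converts a dual-labelled complex to donor-only emission
#' mid-event and donor bleaching extinguishes emission. Frames straddling a
#' state switch take the occupancy-weighted mean intensity (the camera
#' integrates photons within the exposure). Constant channel backgrounds,
#' the initial red-laser DA excess, and Gaussian camera noise are added;
#' noisy values are *not* clipped at zero (offset-subtracted cameras go
#' negative). `E_star` is computed from the background-subtracted channels
#' and is `NA` where DD + DA <= 0.
#'
#' @param path a `state_path`.
#' @param phys a [photophysics_model()].
#' @param duration trace length in seconds (default: the path's duration).
#' @param seed integer seed (species draws, bleach times, camera noise).
#' @param molecule_id identifier stored in the trace.
#' @param force_species `NULL` (draw from `label_fractions`) or one of
#'   "dual", "donor_only", "acceptor_only", "unlabelled" applied to every
#'   binding event.
#' @return A `time_trace`: data.frame with columns `frame` (0-based),
#'   `time` (frame start, s), `DD`, `DA`, `E_star`; attributes `frame_dt`,
#'   `t_add`, `background_DD`, `background_DA`, `red_laser_window`,
#'   `events_truth` (per bound episode: start, end, species, bleach times).
#' @export
render_trace <- function(path, phys, duration = attr(path, "duration"),
                         seed = 1, molecule_id = "mol", force_species = NULL) {
  stopifnot(inherits(path, "state_path"), inherits(phys, "photophysics_model"))
  if (is.null(duration) || max(path$t_end) < duration - 1e-9)
    stop("path must cover [0, duration]")
  set.seed(seed)
  dt <- phys$frame_dt
  n_frames <- max(1L, floor(duration / dt + 1e-9))
  edges <- (0:n_frames) * dt

  bound <- path$state != "unbound"
  ep_id <- cumsum(bound & !c(FALSE, bound[-length(bound)]))
  ep_id[!bound] <- 0L

  # per-time emission levels (AU per frame-time unit)
  bk <- 0; vDD <- NULL; vDA <- NULL; brk <- NULL
  add_piece <- function(a, b, dd, da) {
    brk <<- c(brk, a); vDD <<- c(vDD, dd); vDA <<- c(vDA, da)
  }
  truth <- list()
  cur <- 0
  for (e in unique(ep_id[ep_id > 0L])) {
    seg <- path[ep_id == e, , drop = FALSE]
    a <- seg$t_start[1]; b <- seg$t_end[nrow(seg)]
    if (a >= duration) break
    species <- force_species %||%
      sample(names(phys$label_fractions), 1L, prob = phys$label_fractions)
    tb_a <- if (species == "dual" && phys$acceptor_bleach_rate > 0)
      a + rexp(1, phys$acceptor_bleach_rate) else Inf
    tb_d <- if (species %in% c("dual", "donor_only") && phys$donor_bleach_rate > 0)
      a + rexp(1, phys$donor_bleach_rate) else Inf
    truth[[length(truth) + 1L]] <-
      data.frame(episode = e, t_start = a, t_end = b, species = species,
                 t_bleach_acceptor = tb_a, t_bleach_donor = tb_d)
    if (cur < a) add_piece(cur, a, 0, 0)
    # split segments at bleach times
    cuts <- sort(unique(c(seg$t_start, seg$t_end,
                          tb_a[tb_a > a & tb_a < b], tb_d[tb_d > a & tb_d < b])))
    for (j in seq_len(length(cuts) - 1L)) {
      s0 <- cuts[j]; s1 <- min(cuts[j + 1L], duration)
      if (s0 >= duration) break
      mid <- (s0 + s1) / 2
      stt <- seg$state[findInterval(mid, seg$t_start)]
      if (species %in% c("acceptor_only", "unlabelled") || mid > tb_d) {
        dd <- 0; da <- 0
      } else if (species == "donor_only" || mid > tb_a) {
        dd <- phys$I_total * (1 - phys$E_donor_only)
        da <- phys$I_total * phys$E_donor_only
      } else {
        E <- if (stt == "closed") phys$E_closed else phys$E_open
        dd <- phys$I_total * (1 - E)
        da <- phys$I_total * E
      }
      add_piece(s0, s1, dd, da)
    }
    cur <- min(b, duration)
  }
  if (cur < duration) add_piece(cur, duration, 0, 0)
  brk <- c(brk, duration)

  DD <- frame_average(brk, vDD, edges)
  # red-laser DA excess: constant source on [0, red_laser_window]
  red <- if (phys$red_laser_window > 0 && phys$red_excess_DA != 0) {
    rw <- min(phys$red_laser_window, duration)
    frame_average(c(0, rw, duration), c(phys$red_excess_DA, 0), edges)
  } else 0
  DA <- frame_average(brk, vDA, edges) + red

  DD <- DD + phys$background_DD
  DA <- DA + phys$background_DA
  if (phys$noise_sd > 0) {
    DD <- DD + rnorm(n_frames, 0, phys$noise_sd)
    DA <- DA + rnorm(n_frames, 0, phys$noise_sd)
  }

  time_trace(DD = DD, DA = DA, frame_dt = dt, molecule_id = molecule_id,
             t_add = attr(path, "t_add"),
             background_DD = phys$background_DD,
             background_DA = phys$background_DA,
             red_laser_window = phys$red_laser_window,
             events_truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

#' Construct a per-molecule DD/DA/E* time trace
#'
#' Canonical container for one molecule's intensity time series on a
#' uniform frame grid. `E_star` is the apparent FRET efficiency
#' DA/(DA + DD) computed on background-subtracted channels (see
#' [compute_fret()]); it is `NA` where the background-subtracted total is
#' non-positive.
#'
#' @param DD,DA numeric vectors of equal length (AU per frame).
#' @param frame_dt frame time in seconds.
#' @param molecule_id identifier.
#' @param t_add nucleotide-addition time (s), `NA`/`Inf` if none.
#' @param background_DD,background_DA constant backgrounds subtracted
#'   before computing `E_star` (0 for externally extracted traces).
#' @param red_laser_window seconds of initial red-laser illumination
#'   (frames in this window are excluded from event detection).
#' @param events_truth optional ground-truth annotation (internal).
#' @return A `time_trace` data.frame.
#' @export
time_trace <- function(DD, DA, frame_dt, molecule_id = "mol", t_add = NA,
                       background_DD = 0, background_DA = 0,
                       red_laser_window = 0, events_truth = NULL) {
  stopifnot(length(DD) == length(DA), frame_dt > 0)
  n <- length(DD)
  out <- data.frame(frame = seq_len(n) - 1L,
                    time = (seq_len(n) - 1L) * frame_dt,
                    DD = as.numeric(DD), DA = as.numeric(DA))
  out$E_star <- compute_fret(out$DD - background_DD, out$DA - background_DA)
  attr(out, "frame_dt") <- frame_dt
  attr(out, "molecule_id") <- molecule_id
  attr(out, "t_add") <- t_add
  attr(out, "background_DD") <- background_DD
  attr(out, "background_DA") <- background_DA
  attr(out, "red_laser_window") <- red_laser_window
  if (!is.null(events_truth)) attr(out, "events_truth") <- events_truth
  class(out) <- c("time_trace", "data.frame")
  out
}

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf("time_trace '%s': %d frames @ %.0f ms (%.1f s), t_add = %s\n",
              attr(x, "molecule_id"), nrow(x), 1000 * attr(x, "frame_dt"),
              nrow(x) * attr(x, "frame_dt"), format(attr(x, "t_add"))))
  print.data.frame(head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Simulate a full TIRF field-of-view experiment
#'
#' Generates `n_molecules` traces plus ground truth. Each molecule is one
#' of three kinds: a fraction `no_binding_fraction` of DNAs shows no KF
#' binding (background only); a fraction `contaminant_fraction` are
#' "persistent binders" — surface-adsorbed complexes bound essentially
#' throughout the acquisition with nucleotide-independent open/closed
#' dynamics; the remainder follow `scheme`. Kind assignment and all
#' per-molecule simulation/rendering seeds fan out deterministically from
#' `seed`, so identical seeds give bit-identical output.
#'
#' @param scheme a [kinetic_scheme()].
#' @param phys a [photophysics_model()].
#' @param n_molecules number of DNA molecules (0 gives an empty set).
#' @param duration acquisition length in seconds.
#' @param contaminant_fraction probability a molecule is a persistent
#'   binder (default 0.13, matching the observed ~19% of the displayed
#'   stack after ~32% low-binding removal).
#' @param no_binding_fraction probability a molecule shows no binding
#'   (default 0.32).
#' @param seed master integer seed.
#' @return A list with elements `traces` (a `trace_set`: list of
#'   `time_trace`), `paths` (list of `state_path` ground truth) and
#'   `molecules` (data.frame: molecule_id, kind).
#' @export
simulate_experiment <- function(scheme, phys, n_molecules, duration,
                                contaminant_fraction = 0.13,
                                no_binding_fraction = 0.32,
                                seed = 1) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(phys, "photophysics_model"))
  if (contaminant_fraction < 0 || contaminant_fraction > 1 ||
      no_binding_fraction < 0 || no_binding_fraction > 1 ||
      contaminant_fraction + no_binding_fraction > 1)
    stop("fractions must lie in [0, 1] and sum to <= 1")
  if (n_molecules == 0)
    return(list(traces = structure(list(), class = "trace_set"),
                paths = list(), molecules = data.frame()))

  set.seed(fan_seed(seed, 0))
  kind <- sample(c("contaminant", "no_binding", "scheme"), n_molecules,
                 replace = TRUE,
                 prob = c(contaminant_fraction, no_binding_fraction,
                          1 - contaminant_fraction - no_binding_fraction))

  contam_scheme <- kinetic_scheme(
    binding_rate = scheme$binding_rate,
    unbinding_rate_pre = 0.005, unbinding_rate_post = 0.005,
    k_close = scheme$k_close, k_open = scheme$k_open,
    dntp_wait_rate = scheme$dntp_wait_rate,
    incorporation_rates = scheme$incorporation_rates,
    n_max = 0, template_sequence = scheme$template_sequence,
    t_add = Inf)

  traces <- vector("list", n_molecules)
  paths <- vector("list", n_molecules)
  ids <- sprintf("mol%04d", seq_len(n_molecules))
  for (i in seq_len(n_molecules)) {
    ps <- fan_seed(seed, 2L * i - 1L)
    rs <- fan_seed(seed, 2L * i)
    path <- switch(kind[i],
      no_binding = {
        p <- data.frame(state = "unbound", t_start = 0, t_end = duration)
        attr(p, "n_incorporated") <- 0L
        attr(p, "incorporation_times") <- numeric(0)
        attr(p, "t_add") <- scheme$t_add
        attr(p, "duration") <- duration
        class(p) <- c("state_path", "data.frame")
        p
      },
      contaminant = simulate_state_path(contam_scheme, duration, ps,
                                        initial_state = "open"),
      scheme = simulate_state_path(scheme, duration, ps))
    attr(path, "t_add") <- scheme$t_add # contaminants share the experiment clock
    tr <- render_trace(path, phys, duration, seed = rs, molecule_id = ids[i],
                       force_species = if (kind[i] == "contaminant") "dual")
    traces[[i]] <- tr
    paths[[i]] <- path
  }
  names(traces) <- ids
  names(paths) <- ids
  traces <- structure(traces, class = "trace_set",
                      frame_dt = phys$frame_dt, t_add = scheme$t_add)
  list(traces = traces, paths = paths,
       molecules = data.frame(molecule_id = ids, kind = kind,
                              stringsAsFactors = FALSE))
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %d molecules @ %.0f ms/frame, t_add = %s\n",
              length(x), 1000 * (attr(x, "frame_dt") %||% NA),
              format(attr(x, "t_add"))))
  invisible(x)
}

#' Sample sums of exponential incorporation dwells
#'
#' Draws `reps` polymerisation times, each the sum of `n_bases`
#' independent exponential random variables (one per incorporated base).
#' With identical rates the sum is gamma(`n_bases`, rate); with distinct
#' rates it is hypoexponential.
#'
#' @param n_bases number of bases per polymerisation.
#' @param rates per-second rates, length 1 (recycled) or `n_bases`.
#' @param reps number of samples.
#' @param seed integer seed.
#' @return Numeric vector of `reps` times in seconds.
#' @export
#' @examples
#' x <- sample_extension_dwells(5, 3.2, reps = 1000, seed = 1)
#' mean(x) # ~ 5 / 3.2
sample_extension_dwells <- function(n_bases, rates, reps, seed) {
  if (reps < 1) stop("reps must be >= 1")
  if (n_bases < 1) stop("n_bases must be >= 1")
  if (!length(rates) %in% c(1L, n_bases))
    stop("rates must have length 1 or n_bases")
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all rates must be finite and > 0")
  set.seed(seed)
  rates <- rep_len(rates, n_bases)
  m <- matrix(rexp(n_bases * reps, rate = rates), nrow = n_bases)
  colSums(m)
}
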