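#' Adaptive intensity threshold for binding-event detection
#'
#' To absorb illumination differences across the field of view, the
#' detection threshold is set per molecule from the median of total
#' intensity (DD + DA) samples falling inside an AU window (default
#' 400–3000 AU), scaled by `factor`. The window selects bound-level
#' samples; `factor` (default 0.5) places the threshold halfway between
#' background and the median bound intensity. If no samples fall in the
#' window the threshold falls back to the global median + 3 MAD.
#'
#' @param trace a [time_trace()].
#' @param window numeric length-2, AU window `(lo, hi)` (default
#'   `c(400, 3000)`).
#' @param factor multiplier applied to the in-window median.
#' @return Threshold in AU, with attribute `fallback` (logical).
#' @export
adaptive_threshold <- function(trace, window = c(400, 3000), factor = 0.5) {
  if (nrow(trace) == 0L) stop("trace is empty")
  if (window[1] >= window[2]) stop("window_lo must be < window_hi")
  tot <- trace$DD + trace$DA
  inw <- tot[tot >= window[1] & tot <= window[2]]
  if (length(inw)) {
    structure(factor * median(inw), fallback = FALSE)
  } else {
    structure(median(tot) + 3 * mad(tot), fallback = TRUE)
  }
}

#' Detect KF-binding events by intensity thresholding
#'
#' Finds maximal runs of frames whose total intensity (DD + DA) exceeds
#' `threshold`. Short dips of up to `bridge_gap` frames inside a run are
#' bridged (single-frame camera-noise dips). Runs shorter than
#' `min_duration` are discarded (0.5 s default — shorter events are
#' predominantly non-specific surface sticking). Frames within the initial
#' red-laser window are excluded from detection. Events touching the trace
#' boundaries (or the red-window edge) are flagged censored.
#'
#' @param trace a [time_trace()].
#' @param threshold AU threshold; default from [adaptive_threshold()].
#' @param min_duration minimum event duration in seconds (default 0.5).
#' @param bridge_gap maximum number of consecutive below-threshold frames
#'   bridged inside an event (default 1).
#' @param closed_edge E* boundary used for `begins_closed` and mean-E*
#'   species assignment (default 0.53).
#' @return data.frame of class `binding_events` with columns
#'   `molecule_id`, `event_id`, `start_frame`, `end_frame` (half-open
#'   `[start, end)`, 0-based), `start_s`, `end_s`, `duration_s`,
#'   `left_censored`, `right_censored`, `mean_E`, `begins_closed`,
#'   `species_guess`; attribute `threshold`.
#' @export
detect_events <- function(trace, threshold = adaptive_threshold(trace),
                          min_duration = 0.5, bridge_gap = 1,
                          closed_edge = 0.53) {
  stopifnot(is.finite(threshold))
  dt <- attr(trace, "frame_dt")
  rw <- attr(trace, "red_laser_window") %||% 0
  excluded <- trace$time < rw
  above <- (trace$DD + trace$DA) > threshold & !excluded

  empty <- data.frame(molecule_id = character(0), event_id = integer(0),
                      start_frame = integer(0), end_frame = integer(0),
                      start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), left_censored = logical(0),
                      right_censored = logical(0), mean_E = numeric(0),
                      begins_closed = logical(0),
                      species_guess = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("binding_events", "data.frame")
  attr(empty, "threshold") <- as.numeric(threshold)
  if (!any(above)) return(empty)

  # bridge interior gaps of <= bridge_gap frames
  r <- rle(above)
  if (bridge_gap > 0 && length(r$values) > 2) {
    interior <- seq_along(r$values)[-c(1, length(r$values))]
    fill <- interior[!r$values[interior] & r$lengths[interior] <= bridge_gap]
    r$values[fill] <- TRUE
    r <- rle(inverse.rle(r))
  }

  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  s <- starts[on]; e <- ends[on] + 1L # half-open, 1-based frame index
  dur <- (e - s) * dt
  keep <- dur >= min_duration - 1e-9
  s <- s[keep]; e <- e[keep]; dur <- dur[keep]
  if (!length(s)) return(empty)

  first_idx <- length(which(excluded)) + 1L # first detectable frame
  mean_E <- vapply(seq_along(s), function(i)
    mean(trace$E_star[s[i]:(e[i] - 1L)], na.rm = TRUE), numeric(1))
  first_E <- trace$E_star[s]
  out <- data.frame(
    molecule_id = attr(trace, "molecule_id") %||% "mol",
    event_id = seq_along(s),
    start_frame = s - 1L, end_frame = e - 1L,
    start_s = (s - 1L) * dt, end_s = (e - 1L) * dt,
    duration_s = dur,
    left_censored = s <= first_idx,
    right_censored = e - 1L >= nrow(trace),
    mean_E = mean_E,
    begins_closed = !is.na(first_E) & first_E >= closed_edge,
    species_guess = ifelse(is.na(mean_E), "unknown",
                           ifelse(mean_E < 0.3, "donor_only",
                                  ifelse(mean_E <= 1, "dual", "unknown"))),
    stringsAsFactors = FALSE)
  class(out) <- c("binding_events", "data.frame")
  attr(out, "threshold") <- as.numeric(threshold)
  attr(out, "frame_dt") <- dt
  out
}

#' Remove events whose emission centroid is far from the DNA spot
#'
#' Movie-mode filter: events whose emission centroid lies further than
#' `max_dist` pixels from the initially localised DNA position are removed
#' (non-specific surface binding near, but not at, the DNA). For
#' trace-table input without positions the event list is returned
#' unchanged.
#'
#' @param events a `binding_events` data.frame.
#' @param spot_positions data.frame with `molecule_id`, `x`, `y` (DNA
#'   spots), or `NULL`.
#' @param event_positions data.frame with `molecule_id`, `event_id`, `x`,
#'   `y` (per-event emission centroids), or `NULL`.
#' @param max_dist maximum allowed distance in pixels (default 0.5).
#' @return Filtered `binding_events`.
#' @export
proximity_filter <- function(events, spot_positions = NULL,
                             event_positions = NULL, max_dist = 0.5) {
  if (is.null(spot_positions) || is.null(event_positions) || !nrow(events))
    return(events)
  key <- paste(events$molecule_id, events$event_id)
  ekey <- paste(event_positions$molecule_id, event_positions$event_id)
  mi <- match(key, ekey)
  si <- match(events$molecule_id, spot_positions$molecule_id)
  d <- sqrt((event_positions$x[mi] - spot_positions$x[si])^2 +
            (event_positions$y[mi] - spot_positions$y[si])^2)
  keep <- is.na(d) | d <= max_dist
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split events at the nucleotide-addition time
#'
#' Events straddling `t_add` are cut at the nearest frame boundary; both
#' halves are flagged censored at the cut. Returns the events occurring
#' before and after addition separately.
#'
#' @param events a `binding_events` data.frame.
#' @param t_add nucleotide-addition time in seconds (must be defined).
#' @param frame_dt frame time in seconds (default from events attribute).
#' @return list with elements `pre` and `post` (both `binding_events`).
#' @export
split_by_addition <- function(events, t_add,
                              frame_dt = attr(events, "frame_dt")) {
  if (is.null(t_add) || is.na(t_add)) stop("t_add must be defined")
  if (is.null(frame_dt)) stop("frame_dt unknown; pass it explicitly")
  if (!is.finite(t_add) || t_add < 0) stop("t_add outside trace")
  cut_frame <- round(t_add / frame_dt)
  pre <- events[events$end_frame <= cut_frame, , drop = FALSE]
  post <- events[events$start_frame >= cut_frame, , drop = FALSE]
  strad <- events[events$start_frame < cut_frame &
                  events$end_frame > cut_frame, , drop = FALSE]
  if (nrow(strad)) {
    a <- strad; b <- strad
    a$end_frame <- cut_frame; a$end_s <- cut_frame * frame_dt
    a$duration_s <- a$end_s - a$start_s
    a$right_censored <- TRUE
    b$start_frame <- cut_frame; b$start_s <- cut_frame * frame_dt
    b$duration_s <- b$end_s - b$start_s
    b$left_censored <- TRUE
    pre <- rbind(pre, a)
    post <- rbind(post, b)
  }
  ord <- function(x) {
    x <- x[order(x$molecule_id, x$start_frame), , drop = FALSE]
    rownames(x) <- NULL
    class(x) <- c("binding_events", "data.frame")
    attr(x, "frame_dt") <- frame_dt
    x
  }
  list(pre = ord(pre), post = ord(post))
}

#' Detect events across a whole trace set
#'
#' Applies [adaptive_threshold()] + [detect_events()] to every trace and
#' binds the results.
#'
#' @param traces a `trace_set` (list of [time_trace()]).
#' @param ... passed to [detect_events()].
#' @return A `binding_events` data.frame for all molecules.
#' @export
detect_events_set <- function(traces, ...) {
  out <- lapply(traces, function(tr) detect_events(tr, ...))
  out <- do.call(rbind, out)
  if (is.null(out)) return(detect_events(traces[[1]]))
  rownames(out) <- NULL
  class(out) <- c("binding_events", "data.frame")
  attr(out, "frame_dt") <- attr(traces[[1]], "frame_dt")
  out
}
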