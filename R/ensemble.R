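# FRET classification bins. Half-open [lo, hi); the top bin is closed at 1;
# out-of-range E* is clamped to the nearest bin. Codes: 0 unbound,
# 1 donor_only [0, 0.3), 2 open [0.3, 0.53), 3 closed [0.53, 0.8),
# 4 high_unassigned [0.8, 1].
frame_class_levels <- c("unbound", "donor_only", "open", "closed",
                        "high_unassigned")

#' FRET classification bin edges
#'
#' @return Named numeric vector of the E* bin edges used throughout the
#'   package (donor-only / open / closed / high).
#' @export
fret_bins <- function() c(donor_only = 0, open = 0.3, closed = 0.53,
                          high_unassigned = 0.8, top = 1)

classify_E <- function(E) {
  # clamp, then bin; boundaries belong to the upper bin
  E <- pmin(pmax(E, 0), 1)
  idx <- findInterval(E, c(0.3, 0.53, 0.8)) + 2L # 2..5
  idx
}

#' Classify every frame of a trace
#'
#' Frames outside detected binding events are `unbound` regardless of E*;
#' frames within events are binned by E* into donor-only
#' (E* < 0.3), fingers-open (0.3 <= E* < 0.53), fingers-closed
#' (0.53 <= E* < 0.8) and unassigned high FRET (E* >= 0.8). Bound frames
#' with undefined E* are coded donor-only (no acceptor signal).
#'
#' @param trace a [time_trace()].
#' @param events `binding_events` for this molecule.
#' @return Factor vector (one level per frame) with levels
#'   `unbound`, `donor_only`, `open`, `closed`, `high_unassigned`.
#' @export
classify_frames <- function(trace, events) {
  n <- nrow(trace)
  code <- rep(1L, n) # unbound
  mid <- attr(trace, "molecule_id") %||% "mol"
  ev <- events[events$molecule_id == mid, , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    idx <- (ev$start_frame[i] + 1L):min(ev$end_frame[i], n)
    E <- trace$E_star[idx]
    ci <- ifelse(is.na(E), 2L, classify_E(E))
    code[idx] <- ci
  }
  factor(frame_class_levels[code], levels = frame_class_levels)
}

#' Fraction of a time window covered by binding events
#'
#' @param trace a [time_trace()].
#' @param events `binding_events` for this molecule.
#' @param window length-2 numeric `(t0, t1)` in seconds.
#' @return Fraction in `[0, 1]` of frames in the window that fall inside
#'   an event.
#' @export
binding_extent <- function(trace, events, window) {
  dt <- attr(trace, "frame_dt")
  f0 <- max(0L, floor(window[1] / dt))
  f1 <- min(nrow(trace), ceiling(window[2] / dt))
  if (f1 <= f0) stop("empty window")
  frames <- f0:(f1 - 1L) # 0-based frame indices in window
  covered <- rep(FALSE, length(frames))
  for (i in seq_len(nrow(events))) {
    covered <- covered |
      (frames >= events$start_frame[i] & frames < events$end_frame[i])
  }
  mean(covered)
}

#' Group-classification rules for the ensemble heat map
#'
#' @param persistence_cutoff binding extent over the final `tail_window`
#'   at/above which a molecule is a persistent binder (group a).
#' @param tail_window seconds at the end of the acquisition inspected for
#'   persistence (default 20).
#' @param bright_window seconds after nucleotide addition inspected for
#'   closed-state events (bright/dark split of group b).
#' @return list of thresholds.
#' @export
group_rules <- function(persistence_cutoff = 0.5, tail_window = 20,
                        bright_window = 10) {
  list(persistence_cutoff = persistence_cutoff, tail_window = tail_window,
       bright_window = bright_window)
}

#' Classify molecules into heat-map groups
#'
#' Group a ("persistent binders"): molecules still bound for at least
#' `persistence_cutoff` of the final `tail_window` seconds — no clear
#' decrease in binding after nucleotide addition. The remaining molecules
#' polymerised and are split by whether a fingers-closed frame occurs
#' within `bright_window` seconds after `t_add`: `b_bright` (visible,
#' dual-labelled polymerisation) or `b_dark` (extension by unlabelled or
#' acceptor-only KF).
#'
#' @param traces a `trace_set`.
#' @param events_by_mol named list of `binding_events` per molecule.
#' @param t_add nucleotide-addition time (s); must be defined.
#' @param rules a [group_rules()] list.
#' @return Named character vector: molecule -> "a_persistent", "b_bright"
#'   or "b_dark".
#' @export
classify_groups <- function(traces, events_by_mol, t_add,
                            rules = group_rules()) {
  if (is.null(t_add) || !is.finite(t_add)) stop("t_add must be defined")
  out <- character(length(traces))
  names(out) <- names(traces)
  for (id in names(traces)) {
    tr <- traces[[id]]
    ev <- events_by_mol[[id]]
    if (is.null(ev)) ev <- detect_events(tr)
    t_end <- nrow(tr) * attr(tr, "frame_dt")
    tail_ext <- binding_extent(tr, ev,
                               c(max(0, t_end - rules$tail_window), t_end))
    if (tail_ext >= rules$persistence_cutoff) {
      out[id] <- "a_persistent"
      next
    }
    cls <- classify_frames(tr, ev)
    in_win <- tr$time >= t_add & tr$time < t_add + rules$bright_window
    out[id] <- if (any(cls[in_win] == "closed")) "b_bright" else "b_dark"
  }
  out
}

#' Build the sorted colour-coded ensemble matrix
#'
#' Reproduces the two-pass sorted single-molecule heat map: every
#' molecule's trace is reduced to a per-frame class code
#' ([classify_frames()]); molecules whose binding extent before `t_add`
#' falls below `low_binding_cutoff` are labelled `c_low_binding` and
#' removed from the displayed stack; the remainder are sorted by their
#' binding extent *after* `t_add` (least binding at the bottom by
#' default) and classified into groups a/b ([classify_groups()]).
#'
#' @param traces a `trace_set`.
#' @param events `binding_events` for all molecules.
#' @param t_add nucleotide-addition time (s).
#' @param low_binding_cutoff minimum pre-addition binding extent (default
#'   0.05).
#' @param rules [group_rules()] for the a/b split.
#' @param decreasing sort direction for post-addition extent.
#' @return An `ensemble_matrix`: list with `matrix` (displayed molecules x
#'   frames, integer codes 0-4), `sort_order` (displayed molecule ids,
#'   bottom to top), `group_labels` (all molecules ->
#'   a_persistent/b_bright/b_dark/c_low_binding), `extents` (pre/post per
#'   molecule), `t_add`, `frame_dt`.
#' @export
build_heatmap <- function(traces, events, t_add, low_binding_cutoff = 0.05,
                          rules = group_rules(), decreasing = FALSE) {
  stopifnot(length(traces) >= 1)
  dt <- attr(traces[[1]], "frame_dt")
  n_frames <- nrow(traces[[1]])
  t_end <- n_frames * dt
  if (!is.finite(t_add) || t_add <= 0 || t_add >= t_end)
    stop("t_add must lie within the acquisition")
  ids <- names(traces)
  ev_by <- split(events, factor(events$molecule_id, levels = ids))

  pre <- post <- setNames(numeric(length(ids)), ids)
  for (id in ids) {
    pre[id] <- binding_extent(traces[[id]], ev_by[[id]], c(0, t_add))
    post[id] <- binding_extent(traces[[id]], ev_by[[id]], c(t_add, t_end))
  }
  groups <- setNames(rep("c_low_binding", length(ids)), ids)
  shown <- ids[pre >= low_binding_cutoff]
  if (length(shown)) {
    gb <- classify_groups(traces[shown], ev_by[shown], t_add, rules)
    groups[names(gb)] <- gb
  }
  # deterministic ordering: extent, then id as tie-break
  ord <- shown[order(post[shown], shown, decreasing = decreasing)]
  mat <- matrix(0L, length(ord), n_frames,
                dimnames = list(ord, NULL))
  for (i in seq_along(ord)) {
    cls <- classify_frames(traces[[ord[i]]], ev_by[[ord[i]]])
    mat[i, ] <- as.integer(cls) - 1L # codes 0..4
  }
  structure(list(matrix = mat, sort_order = ord, group_labels = groups,
                 extents = data.frame(molecule_id = ids, pre = unname(pre),
                                      post = unname(post)),
                 t_add = t_add, frame_dt = dt),
            class = "ensemble_matrix")
}

#' @export
print.ensemble_matrix <- function(x, ...) {
  tb <- table(x$group_labels)
  cat(sprintf("ensemble_matrix: %d molecules displayed (of %d), t_add = %.1f s\n",
              nrow(x$matrix), length(x$group_labels), x$t_add))
  cat("  groups:", paste(sprintf("%s %d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

heatmap_palette <- c(unbound = "#FFFFFF", donor_only = "#2166AC",
                     open = "#1B7837", closed = "#B2182B",
                     high_unassigned = "#000000")

#' Render the ensemble heat map
#'
#' Draws the colour-coded molecule-by-frame raster (white unbound, blue
#' donor-only, green fingers-open, red fingers-closed, black unassigned
#' high FRET) with the nucleotide-addition time marked. The colour matrix
#' is returned invisibly and is bit-stable for identical input.
#'
#' @param x an `ensemble_matrix`.
#' @param draw draw to the active graphics device? (set `FALSE` to only
#'   return the colour matrix).
#' @param ... ignored.
#' @return (Invisibly) the character matrix of hex colours, molecules x
#'   frames.
#' @export
render_heatmap <- function(x, draw = TRUE, ...) {
  stopifnot(inherits(x, "ensemble_matrix"))
  if (nrow(x$matrix) == 0L) stop("empty ensemble matrix")
  cols <- matrix(unname(heatmap_palette)[x$matrix + 1L], nrow(x$matrix),
                 dimnames = dimnames(x$matrix))
  if (draw) {
    nf <- ncol(x$matrix); nm <- nrow(x$matrix)
    graphics::image(x = (seq_len(nf) - 0.5) * x$frame_dt,
                    y = seq_len(nm), z = t(x$matrix),
                    col = unname(heatmap_palette), zlim = c(0, 4),
                    xlab = "time (s)", ylab = "DNA molecule",
                    useRaster = TRUE)
    graphics::abline(v = x$t_add, lty = 2)
  }
  invisible(cols)
}

#' @export
plot.ensemble_matrix <- function(x, ...) render_heatmap(x, draw = TRUE, ...)

#' Post-synchronised time-series FRET histogram
#'
#' Aligns binding events at their start and accumulates (time-since-start,
#' E*) counts over all frames while bound, the ensemble view of the
#' conformational time course during polymerisation. With
#' `begins_closed_only = TRUE` only events whose first frame is in the
#' closed class are used (removing persistent binders with no
#' nucleotide-specific activity); the complement can be inspected by
#' passing `complement = TRUE`.
#'
#' @param events `binding_events`.
#' @param traces a `trace_set`.
#' @param begins_closed_only filter to events beginning fingers-closed.
#' @param complement with `begins_closed_only`, keep the complement
#'   instead.
#' @param t_bins time bin edges in seconds (default 0 to 6 s in frames).
#' @param E_bins E* bin edges (default 30 bins over \[0, 1\]).
#' @return list of class `postsync_hist`: `counts` (time x E*), `t_bins`,
#'   `E_bins`, `n_events`, `empty`.
#' @export
postsync_fret_histogram <- function(events, traces, begins_closed_only = TRUE,
                                    complement = FALSE,
                                    t_bins = NULL, E_bins = seq(0, 1, by = 1 / 30)) {
  dt <- attr(traces[[1]], "frame_dt")
  if (is.null(t_bins)) t_bins <- seq(0, 6, by = dt)
  if (begins_closed_only) {
    keep <- if (complement) !events$begins_closed else events$begins_closed
    events <- events[keep, , drop = FALSE]
  }
  counts <- matrix(0L, length(t_bins) - 1L, length(E_bins) - 1L)
  if (nrow(events) == 0L)
    return(structure(list(counts = counts, t_bins = t_bins, E_bins = E_bins,
                          n_events = 0L, empty = TRUE),
                     class = "postsync_hist"))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    tr <- traces[[ev$molecule_id]]
    idx <- (ev$start_frame + 1L):min(ev$end_frame, nrow(tr))
    trel <- (seq_along(idx) - 1L) * dt
    E <- tr$E_star[idx]
    ok <- is.finite(E) & trel < max(t_bins)
    E <- pmin(pmax(E[ok], 0), 1 - 1e-12)
    trel <- trel[ok]
    ti <- findInterval(trel, t_bins, rightmost.closed = TRUE)
    Ei <- findInterval(E, E_bins, rightmost.closed = TRUE)
    for (j in seq_along(ti)) counts[ti[j], Ei[j]] <- counts[ti[j], Ei[j]] + 1L
  }
  structure(list(counts = counts, t_bins = t_bins, E_bins = E_bins,
                 n_events = nrow(events), empty = FALSE),
            class = "postsync_hist")
}

#' @export
print.postsync_hist <- function(x, ...) {
  if (x$empty) cat("postsync_hist: empty (no qualifying events)\n")
  else cat(sprintf("postsync_hist: %d events, %d time x %d E* bins, %d frames\n",
                   x$n_events, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}
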