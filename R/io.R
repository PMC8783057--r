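#' Write / read a trace set as CSV
#'
#' Long-format table with columns `molecule_id`, `frame`, `time_s`, `DD`,
#' `DA`. Grid metadata (`frame_dt`, `t_add`, backgrounds, red-laser
#' window) is stored in a JSON sidecar `<file>.meta.json` and restored on
#' read; external tables without a sidecar default to zero background and
#' the frame step inferred from the time column.
#'
#' @param traces a `trace_set`.
#' @param file CSV path.
#' @return `write_traces`: the file path, invisibly. `read_traces`: a
#'   `trace_set`.
#' @export
write_traces <- function(traces, file) {
  rows <- lapply(traces, function(tr)
    data.frame(molecule_id = attr(tr, "molecule_id"), frame = tr$frame,
               time_s = tr$time, DD = tr$DD, DA = tr$DA))
  write.csv(do.call(rbind, rows), file, row.names = FALSE)
  tr1 <- traces[[1]]
  meta <- list(frame_dt = attr(tr1, "frame_dt"),
               t_add = attr(tr1, "t_add"),
               background_DD = attr(tr1, "background_DD"),
               background_DA = attr(tr1, "background_DA"),
               red_laser_window = attr(tr1, "red_laser_window"))
  jsonlite::write_json(meta, paste0(file, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(file)
}

#' @rdname write_traces
#' @export
read_traces <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  metafile <- paste0(file, ".meta.json")
  meta <- if (file.exists(metafile))
    jsonlite::read_json(metafile, simplifyVector = TRUE) else list()
  ids <- unique(df$molecule_id)
  dt <- meta$frame_dt %||% stats::median(diff(sort(unique(df$time_s))))
  t_add <- meta$t_add %||% NA
  if (is.character(t_add)) t_add <- as.numeric(t_add) # "Inf" round-trips as string
  traces <- lapply(ids, function(id) {
    d <- df[df$molecule_id == id, , drop = FALSE]
    d <- d[order(d$frame), , drop = FALSE]
    time_trace(DD = d$DD, DA = d$DA, frame_dt = dt, molecule_id = id,
               t_add = t_add,
               background_DD = meta$background_DD %||% 0,
               background_DA = meta$background_DA %||% 0,
               red_laser_window = meta$red_laser_window %||% 0)
  })
  names(traces) <- ids
  structure(traces, class = "trace_set", frame_dt = dt, t_add = t_add)
}

#' Write / read ground-truth state paths as JSON
#'
#' @param paths list of `state_path` objects.
#' @param file JSON path.
#' @return `write_state_paths`: the path, invisibly; `read_state_paths`:
#'   the list of `state_path` objects.
#' @export
write_state_paths <- function(paths, file) {
  enc <- lapply(paths, function(p)
    list(segments = as.data.frame(p),
         n_incorporated = attr(p, "n_incorporated"),
         incorporation_times = attr(p, "incorporation_times"),
         t_add = attr(p, "t_add"),
         duration = attr(p, "duration")))
  jsonlite::write_json(enc, file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' @rdname write_state_paths
#' @export
read_state_paths <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  lapply(raw, function(x) {
    p <- as.data.frame(x$segments)
    attr(p, "n_incorporated") <- x$n_incorporated
    attr(p, "incorporation_times") <- x$incorporation_times %||% numeric(0)
    attr(p, "t_add") <- if (is.character(x$t_add)) as.numeric(x$t_add) else x$t_add
    attr(p, "duration") <- x$duration
    class(p) <- c("state_path", "data.frame")
    p
  })
}

#' Write events / dwells tables
#'
#' Plain CSV writers for the `binding_events` and dwell tables.
#'
#' @param x the table.
#' @param file CSV path.
#' @return The path, invisibly.
#' @export
write_events <- function(x, file) {
  write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

#' Write a spot set as CSV (columns x, y)
#'
#' @param spots a `spot_set`.
#' @param file CSV path.
#' @return The path, invisibly.
#' @export
write_spots <- function(spots, file) {
  write.csv(as.data.frame(spots), file, row.names = FALSE)
  invisible(file)
}
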