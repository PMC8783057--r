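#' Apparent FRET efficiency
#'
#' Computes E* = DA / (DA + DD), the uncorrected (apparent) FRET
#' efficiency, elementwise. Where DA + DD <= 0 the ratio is undefined and
#' `NA` is returned — an undefined marker, not an error. The raw ratio is
#' reported without clamping to \[0, 1\]; downstream classification handles
#' out-of-range values. E* is invariant to rescaling both channels by any
#' positive constant.
#'
#' @param DD,DA numeric vectors (recycled to common length), AU.
#' @return Numeric vector of E* values with `NA` where undefined.
#' @export
#' @examples
#' compute_fret(300, 300) # 0.5
#' compute_fret(0, 0)     # NA
compute_fret <- function(DD, DA) {
  n <- max(length(DD), length(DA))
  DD <- rep_len(as.numeric(DD), n)
  DA <- rep_len(as.numeric(DA), n)
  tot <- DD + DA
  out <- DA / tot
  out[!is.finite(tot) | tot <= 0] <- NA_real_
  out
}

# pixel convention: 0-based, pixel centre at integer coordinates.
# image arrays are indexed [row (y), column (x), frame].

#' Localise fluorescent spots in an image stack
#'
#' Detects DNA positions from the initial red-laser localisation frames:
#' the detection frames are averaged, local maxima above
#' `background + threshold_sd * MAD` are found, and each is refined to
#' sub-pixel precision by intensity-weighted centroid in a small window.
#' Spots closer than `min_separation` are merged, keeping the brighter one.
#'
#' @param stack numeric array `[ny, nx, n_frames]` (or a matrix for a
#'   single frame).
#' @param detection_frames integer frame indices (1-based) to average.
#' @param min_separation minimum spot separation in pixels.
#' @param threshold_sd detection threshold in robust SDs above background.
#' @param window half-width (px) of the centroid-refinement window.
#' @return A `spot_set`: data.frame with columns `x`, `y` (0-based pixel
#'   coordinates, sub-pixel) and `brightness`.
#' @export
localise_spots <- function(stack, detection_frames = NULL,
                           min_separation = 3, threshold_sd = 5,
                           window = 2) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  stopifnot(length(dim(stack)) == 3L)
  nf <- dim(stack)[3]
  if (is.null(detection_frames)) detection_frames <- seq_len(nf)
  if (length(detection_frames) == 0L) stop("empty detection frame range")
  if (any(detection_frames < 1L | detection_frames > nf))
    stop("detection frames outside stack")
  img <- apply(stack[, , detection_frames, drop = FALSE], c(1, 2), mean)
  ny <- nrow(img); nx <- ncol(img)
  bg <- median(img)
  sdv <- mad(img)
  if (sdv == 0) sdv <- sd(img)
  thr <- bg + threshold_sd * max(sdv, .Machine$double.eps)

  # 3x3 local maxima above threshold (borders excluded)
  peaks <- NULL
  for (i in 2:(ny - 1)) {
    for (j in 2:(nx - 1)) {
      v <- img[i, j]
      if (v > thr && v == max(img[(i - 1):(i + 1), (j - 1):(j + 1)]))
        peaks <- rbind(peaks, c(i, j, v))
    }
  }
  if (is.null(peaks))
    return(structure(data.frame(x = numeric(0), y = numeric(0),
                                brightness = numeric(0)),
                     class = c("spot_set", "data.frame")))

  # centroid refinement on background-subtracted intensities
  refine <- function(i, j) {
    ii <- max(1, i - window):min(ny, i + window)
    jj <- max(1, j - window):min(nx, j + window)
    w <- pmax(img[ii, jj, drop = FALSE] - bg, 0)
    if (sum(w) == 0) return(c(j - 1, i - 1))
    # 0-based: x along columns, y along rows
    x <- sum(outer(rep(1, length(ii)), jj - 1) * w) / sum(w)
    y <- sum(outer(ii - 1, rep(1, length(jj))) * w) / sum(w)
    c(x, y)
  }
  cent <- t(apply(peaks, 1, function(p) refine(p[1], p[2])))
  spots <- data.frame(x = cent[, 1], y = cent[, 2], brightness = peaks[, 3])
  spots <- spots[order(-spots$brightness), , drop = FALSE]

  # merge close spots toward the brighter
  keep <- rep(TRUE, nrow(spots))
  for (i in seq_len(nrow(spots))) {
    if (!keep[i]) next
    if (i < nrow(spots)) {
      d <- sqrt((spots$x[-(1:i)] - spots$x[i])^2 +
                (spots$y[-(1:i)] - spots$y[i])^2)
      keep[-(1:i)][d < min_separation] <- FALSE
    }
  }
  spots <- spots[keep, , drop = FALSE]
  rownames(spots) <- NULL
  structure(spots, class = c("spot_set", "data.frame"))
}

# squared distance of every pixel centre to a 0-based position
pixel_dist2 <- function(ny, nx, position) {
  xs <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  ys <- matrix(rep(0:(ny - 1), nx), ny, nx)
  (xs - position[1])^2 + (ys - position[2])^2
}

#' Extract a fluorescence time trace by aperture photometry
#'
#' Sums pixel intensities within a circular aperture around a spot,
#' subtracting a local background estimated as the per-frame median of an
#' annulus, for each channel stack.
#'
#' @param stack_DD,stack_DA numeric arrays `[ny, nx, n_frames]`.
#' @param position `c(x, y)` spot centre, 0-based pixels.
#' @param aperture_radius aperture radius in pixels (default 3).
#' @param annulus inner/outer radii (px) of the background annulus.
#' @param frame_dt frame time in seconds.
#' @param molecule_id identifier.
#' @param t_add nucleotide-addition time (s) or `NA`.
#' @param red_laser_window seconds of initial red illumination.
#' @return A [time_trace()] (backgrounds already subtracted, so its
#'   background attributes are 0).
#' @export
extract_trace <- function(stack_DD, stack_DA, position, aperture_radius = 3,
                          annulus = c(5, 7), frame_dt = 0.04,
                          molecule_id = "mol", t_add = NA,
                          red_laser_window = 0) {
  stopifnot(identical(dim(stack_DD), dim(stack_DA)),
            length(dim(stack_DD)) == 3L)
  ny <- dim(stack_DD)[1]; nx <- dim(stack_DD)[2]
  if (position[1] - aperture_radius < 0 || position[2] - aperture_radius < 0 ||
      position[1] + aperture_radius > nx - 1 ||
      position[2] + aperture_radius > ny - 1)
    stop("aperture outside image bounds")
  d2 <- pixel_dist2(ny, nx, position)
  ap <- d2 <= aperture_radius^2
  an <- d2 >= annulus[1]^2 & d2 <= annulus[2]^2
  n_ap <- sum(ap)
  photom <- function(stack) {
    m <- matrix(stack, ny * nx, dim(stack)[3])
    sig <- colSums(m[ap, , drop = FALSE])
    bg <- apply(m[an, , drop = FALSE], 2, median)
    sig - n_ap * bg
  }
  time_trace(DD = photom(stack_DD), DA = photom(stack_DA),
             frame_dt = frame_dt, molecule_id = molecule_id, t_add = t_add,
             red_laser_window = red_laser_window)
}

#' Render a synthetic TIRF movie from time traces
#'
#' Places each molecule's per-frame intensity as a 2D Gaussian spot
#' (sigma ~ 1 px, integrated intensity equal to the trace value) on a
#' constant background, producing one image stack per channel. Exercises
#' the localisation/photometry path end to end; optionally writes
#' multi-page TIFF via the `tiff` package.
#'
#' @param traces a `trace_set` (or list of `time_trace`); the *rendered
#'   signal* is `DD`/`DA` minus the trace's stored background attributes,
#'   which are re-added as a flat camera background.
#' @param positions data.frame/matrix with columns `x`, `y` (0-based px),
#'   one row per trace.
#' @param dim image `c(ny, nx)` in pixels.
#' @param sigma Gaussian PSF sigma in pixels.
#' @param background flat background added to every pixel (per channel).
#' @param file_DD,file_DA optional TIFF output paths.
#' @return list with arrays `DD` and `DA` of size `[ny, nx, n_frames]`.
#' @export
render_movie <- function(traces, positions, dim = c(32, 32), sigma = 1,
                         background = 10, file_DD = NULL, file_DA = NULL) {
  stopifnot(length(traces) == nrow(positions))
  ny <- dim[1]; nx <- dim[2]
  n_frames <- nrow(traces[[1]])
  DD <- array(background, c(ny, nx, n_frames))
  DA <- array(background, c(ny, nx, n_frames))
  for (k in seq_along(traces)) {
    tr <- traces[[k]]
    pos <- as.numeric(positions[k, c("x", "y")])
    d2 <- pixel_dist2(ny, nx, pos)
    psf <- exp(-d2 / (2 * sigma^2))
    psf <- psf / sum(psf) # integrated intensity == trace value
    sDD <- tr$DD - (attr(tr, "background_DD") %||% 0)
    sDA <- tr$DA - (attr(tr, "background_DA") %||% 0)
    DD <- DD + outer(psf, sDD)
    DA <- DA + outer(psf, sDA)
  }
  if (!is.null(file_DD) || !is.null(file_DA)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("TIFF output requires the 'tiff' package")
    wr <- function(arr, f) {
      sc <- max(arr)
      tiff::writeTIFF(lapply(seq_len(n_frames), function(i) arr[, , i] / sc), f)
    }
    if (!is.null(file_DD)) wr(DD, file_DD)
    if (!is.null(file_DA)) wr(DA, file_DA)
  }
  list(DD = DD, DA = DA)
}
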