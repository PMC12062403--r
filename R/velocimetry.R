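#' Construct a keypoint track series
#'
#' Container for a single keypoint track from markerless pose estimation:
#' frame index, pixel (or metric) coordinates, and per-frame confidence.
#'
#' @param frame Integer frame indices, strictly increasing.
#' @param x,y Keypoint coordinates (pixels unless `scale = 1`).
#' @param conf Confidence/likelihood in `[0, 1]` (recycled).
#' @param fps Frame rate, Hz (> 0).
#' @param scale Metres per pixel.
#' @param BL Body length, m (for BL-normalised speeds).
#' @return An object of class `track_series` (data.frame with columns
#'   `frame`, `t`, `x`, `y`, `conf`; attributes `fps`, `scale`, `BL`).
#' @export
track_series <- function(frame, x, y, conf = 1, fps = 60,
                         scale = 0.057 / 200, BL = 0.057) {
  if (fps <= 0) stop("'fps' must be positive")
  if (any(diff(frame) <= 0)) stop("format error: frames must be strictly increasing")
  conf <- rep_len(conf, length(frame))
  if (any(conf < 0 | conf > 1))
    stop("format error: confidences must lie in [0, 1]")
  d <- data.frame(frame = as.integer(frame), t = frame / fps,
                  x = x, y = y, conf = conf)
  attr(d, "fps") <- fps; attr(d, "scale") <- scale; attr(d, "BL") <- BL
  class(d) <- c("track_series", "data.frame")
  d
}

#' Read a keypoint track table
#'
#' Two dialects are supported: `"plain"` — a CSV with columns
#' `frame, x, y, conf` — and `"dlc"` — the pose-estimation export layout
#' with three header rows (scorer, bodyparts, coords) and `x/y/likelihood`
#' column triplets per body part.
#'
#' @param path CSV file path.
#' @param dialect `"plain"` or `"dlc"`.
#' @param bodypart For `"dlc"`, which body part to extract (default the
#'   first).
#' @param fps,scale,BL Metadata passed to [track_series()].
#' @return A `track_series`.
#' @export
load_tracks <- function(path, dialect = c("plain", "dlc"), bodypart = NULL,
                        fps = 60, scale = 0.057 / 200, BL = 0.057) {
  dialect <- match.arg(dialect)
  if (dialect == "plain") {
    d <- utils::read.csv(path)
    need <- c("frame", "x", "y")
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop(sprintf("format error: missing columns: %s",
                   paste(miss, collapse = ", ")))
    if (is.null(d$conf)) d$conf <- 1
    return(track_series(d$frame, d$x, d$y, d$conf, fps, scale, BL))
  }
  hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                         colClasses = "character")
  body <- utils::read.csv(path, header = FALSE, skip = 3)
  parts <- as.character(unlist(hdr[2, -1]))
  coords <- as.character(unlist(hdr[3, -1]))
  if (is.null(bodypart)) bodypart <- parts[1]
  sel <- which(parts == bodypart)
  if (!length(sel))
    stop(sprintf("format error: body part '%s' not found", bodypart))
  cx <- sel[coords[sel] == "x"][1] + 1L
  cy <- sel[coords[sel] == "y"][1] + 1L
  cl <- sel[coords[sel] == "likelihood"][1] + 1L
  if (any(is.na(c(cx, cy, cl))))
    stop("format error: missing x/y/likelihood columns for body part")
  track_series(body[[1]], body[[cx]], body[[cy]], body[[cl]],
               fps, scale, BL)
}

#' Write a track series as a plain CSV
#' @param track A `track_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(track, path) {
  utils::write.csv(track[, c("frame", "x", "y", "conf")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Estimate swimming speed from a keypoint track
#'
#' Drops samples below the confidence threshold, fills the gaps by linear
#' interpolation, smooths the positions with a local least-squares quadratic
#' (Savitzky-Golay) filter, differentiates centrally, and converts to body
#' lengths per second. The plateau speed `u_e` is the mean of the top decile
#' of smoothed speeds.
#'
#' @param track A `track_series`.
#' @param half_width Smoothing half-width in frames (window `2*half_width +
#'   1`).
#' @param conf_threshold Minimum confidence to accept a sample.
#' @return List with `series` (data.frame `t`, `u` in BL/s, interior frames
#'   only) and `u_e` (plateau speed, BL/s).
#' @export
estimate_speed <- function(track, half_width = 5, conf_threshold = 0.9) {
  fps <- attr(track, "fps"); scale <- attr(track, "scale")
  BL <- attr(track, "BL")
  ok <- track$conf >= conf_threshold
  if (sum(ok) < 5)
    stop("insufficient data: fewer than 5 samples pass the confidence threshold")
  fr <- track$frame
  grid <- seq(min(fr[ok]), max(fr[ok]))
  xs <- stats::approx(fr[ok], track$x[ok], xout = grid)$y
  ys <- stats::approx(fr[ok], track$y[ok], xout = grid)$y
  n <- 2 * half_width + 1
  if (length(grid) > n) {
    xs <- signal::sgolayfilt(xs, p = 2, n = n)
    ys <- signal::sgolayfilt(ys, p = 2, n = n)
  }
  m <- length(grid)
  du <- (xs[3:m] - xs[1:(m - 2)]) / 2
  dv <- (ys[3:m] - ys[1:(m - 2)]) / 2
  sp <- sqrt(du^2 + dv^2) * fps * scale / BL
  tt <- grid[2:(m - 1)] / fps
  u_e <- mean(sort(sp, decreasing = TRUE)[
    seq_len(max(1, floor(0.1 * length(sp))))])
  list(series = data.frame(t = tt, u = sp), u_e = u_e)
}

#' Fin-beat frequency from a fin-tip track
#'
#' Counts zero crossings of the mean-subtracted lateral excursion and divides
#' by twice the window length; a periodogram peak is available as an
#' alternative estimator. At 60 fps the crossing quantum is
#' `1 / (2 * duration)` Hz.
#'
#' @param track A `track_series` of a fin-tip keypoint.
#' @param axis Which coordinate oscillates, `"y"` (default) or `"x"`.
#' @param method `"zero_crossing"` or `"periodogram"`.
#' @return Frequency, Hz, with the crossing quantum as attribute
#'   `"quantum"`.
#' @export
fin_frequency <- function(track, axis = c("y", "x"),
                          method = c("zero_crossing", "periodogram")) {
  axis <- match.arg(axis); method <- match.arg(method)
  fps <- attr(track, "fps")
  s <- track[[axis]] - mean(track[[axis]])
  dur <- (track$frame[nrow(track)] - track$frame[1]) / fps
  sgn <- sign(s); sgn[sgn == 0] <- 1
  ncross <- sum(diff(sgn) != 0)
  if (ncross < 6)
    stop("insufficient data: fewer than 3 oscillation periods in the window")
  if (method == "zero_crossing") {
    f <- ncross / (2 * dur)
  } else {
    pg <- stats::spec.pgram(stats::ts(s, frequency = fps), plot = FALSE,
                            detrend = TRUE, taper = 0)
    f <- pg$freq[which.max(pg$spec)]
  }
  structure(f, quantum = 1 / (2 * dur))
}

#' Frequency-speed relation across observations
#'
#' Ordinary least-squares line and Pearson correlation of swimming speed
#' against fin-beat frequency, the relation used to classify slow vs fast
#' swimming.
#'
#' @param f Fin-beat frequencies, Hz (>= 3 values).
#' @param u_e Swimming speeds, BL/s.
#' @return List with `slope`, `intercept`, `r`, `slope_se` and the `lm`
#'   fit.
#' @export
correlate_f_u <- function(f, u_e) {
  if (length(f) < 3) stop("need at least 3 (f, u_e) pairs")
  if (stats::var(f) == 0)
    stop("undefined fit: zero variance in 'f'")
  fit <- stats::lm(u_e ~ f)
  co <- suppressWarnings(summary(fit))$coefficients  # exact fits are fine
  list(slope = unname(co["f", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r = stats::cor(f, u_e),
       slope_se = unname(co["f", "Std. Error"]),
       fit = fit)
}
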