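#' Zero-phase Butterworth low-pass filter
#'
#' Designs a digital Butterworth low-pass filter and applies it forward and
#' backward (zero phase lag, DC gain exactly one, squared magnitude
#' response). The series is extended by odd reflection at both ends before
#' filtering so that start-up transients decay inside the padding.
#'
#' @param x numeric vector or matrix (columns filtered independently).
#' @param fs sampling frequency, Hz.
#' @param fc cut-off frequency, Hz (default 6).
#' @param order filter order (default 4; the forward-backward pass doubles
#'   the effective order).
#' @return Filtered series with the same shape as `x`.
#' @export
butterworth_lowpass <- function(x, fs, fc = 6, order = 4) {
  if (fs <= 2 * fc) stop("sampling rate must exceed twice the cut-off frequency")
  if (is.matrix(x)) {
    y <- apply(x, 2L, butterworth_lowpass, fs = fs, fc = fc, order = order)
    dimnames(y) <- dimnames(x)
    return(y)
  }
  n <- length(x)
  if (n <= 3 * order) stop("series too short to filter (need > 3 * order samples)")
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  ## demean (restored afterwards) so the DC component is untouched exactly
  mu <- mean(x)
  xc <- x - mu
  npad <- min(n - 1L, ceiling(6 * fs / fc))
  head_pad <- 2 * xc[1L] - xc[seq(npad + 1L, 2L)]
  tail_pad <- 2 * xc[n] - xc[seq(n - 1L, n - npad)]
  xp <- c(head_pad, xc, tail_pad)
  yp <- signal::filtfilt(bf, xp)
  yp[seq(npad + 1L, npad + n)] + mu
}

#' Low-pass filter the quaternion components of a session
#'
#' Component-wise zero-phase Butterworth filtering of each sensor's
#' quaternion series followed by renormalization to unit quaternions (the
#' default pipeline ordering: filter the orientation signals, then run
#' inverse kinematics).
#'
#' @param session an `orientation_session`.
#' @inheritParams butterworth_lowpass
#' @return The filtered session.
#' @export
filter_session <- function(session, fc = 6, order = 4) {
  for (s in names(session$quats)) {
    Q <- session$quats[[s]]
    sign_flip <- sign(Q[, 1L]); sign_flip[sign_flip == 0] <- 1
    Q <- Q * sign_flip  # hemisphere-align before component filtering
    Qf <- butterworth_lowpass(Q, fs = session$rate, fc = fc, order = order)
    Qf <- Qf / sqrt(rowSums(Qf^2))
    session$quats[[s]] <- Qf
  }
  session
}

#' Pull segmentation configuration
#'
#' Pull detection is threshold-based on a designated activity signal (the
#' right shoulder-flexion angular velocity, positive during the pulling
#' reach): a segment opens when the signal exceeds `enter_frac` of the
#' session's `ref_quantile` reference level, closes when it falls below
#' `exit_frac` (hysteresis), is then extended outward to where the signal
#' drops below `refine_frac` of the reference, and is kept only if longer
#' than `min_duration`.
#'
#' @param signal_coord coordinate whose velocity is the activity signal.
#' @param enter_frac,exit_frac hysteresis thresholds (fractions of the
#'   reference level).
#' @param refine_frac boundary-refinement threshold.
#' @param min_duration minimum pull duration, s.
#' @param ref_quantile quantile of the activity signal used as reference.
#' @return A list of segmentation settings.
#' @export
segmentation_config <- function(signal_coord = "shoulder_flexion_r",
                                enter_frac = 0.8, exit_frac = 0.2,
                                refine_frac = 0.01, min_duration = 0.3,
                                ref_quantile = 0.95) {
  list(signal_coord = signal_coord, enter_frac = enter_frac,
       exit_frac = exit_frac, refine_frac = refine_frac,
       min_duration = min_duration, ref_quantile = ref_quantile)
}

#' Segment the pulls of a trajectory
#'
#' @param traj a (filtered) `joint_trajectory`, e.g. the inverse-kinematics
#'   output of a session.
#' @param config a [segmentation_config()].
#' @return A `pull_set`: list with `pulls` (list of `joint_trajectory`
#'   slices), `spans` (start/end times) and the source id.
#' @export
segment_pulls <- function(traj, config = segmentation_config()) {
  empty <- structure(list(pulls = list(), spans = matrix(numeric(0), 0L, 2L),
                          source = attr(traj, "source")), class = "pull_set")
  if (is.null(traj) || nrow(traj$q) == 0L) return(empty)
  sig <- if (!is.null(traj$qdot)) traj$qdot[, config$signal_coord] else {
    c(0, diff(traj$q[, config$signal_coord])) / c(1, diff(traj$time))
  }
  ref <- stats::quantile(sig, config$ref_quantile, names = FALSE)
  if (!is.finite(ref) || ref <= 0) return(empty)
  hi <- config$enter_frac * ref
  lo <- config$exit_frac * ref
  tiny <- config$refine_frac * ref

  n <- length(sig)
  open <- FALSE
  starts <- ends <- integer(0)
  for (i in seq_len(n)) {
    if (!open && sig[i] >= hi) {
      open <- TRUE
      starts <- c(starts, i)
    } else if (open && sig[i] < lo) {
      open <- FALSE
      ends <- c(ends, i)
    }
  }
  if (open) ends <- c(ends, n)
  if (!length(starts)) return(empty)

  spans <- matrix(NA_real_, 0L, 2L)
  pulls <- list()
  for (k in seq_along(starts)) {
    a <- starts[k]; b <- ends[k]
    while (a > 1L && sig[a - 1L] > tiny) a <- a - 1L
    while (b < n && sig[b + 1L] > tiny) b <- b + 1L
    if (traj$time[b] - traj$time[a] < config$min_duration) next
    if (nrow(spans) && a <= spans[nrow(spans), 2L]) next  # overlap guard
    idx <- a:b
    pulls[[length(pulls) + 1L]] <- joint_trajectory(
      traj$time[idx], traj$q[idx, , drop = FALSE],
      if (!is.null(traj$qdot)) traj$qdot[idx, , drop = FALSE],
      if (!is.null(traj$qddot)) traj$qddot[idx, , drop = FALSE])
    spans <- rbind(spans, c(a, b))
  }
  spans_t <- cbind(start = traj$time[spans[, 1L]], end = traj$time[spans[, 2L]])
  structure(list(pulls = pulls, spans = spans_t,
                 source = attr(traj, "source")), class = "pull_set")
}

#' @export
print.pull_set <- function(x, ...) {
  cat("Pull set:", length(x$pulls), "pulls\n")
  invisible(x)
}

#' Resample a pull onto a uniform normalized-time grid
#'
#' Linear interpolation onto `n_points` uniformly spaced samples of
#' normalized time in `[0, 1]`; endpoints are preserved exactly. The output
#' keeps the pull's real duration on a uniform time base.
#'
#' @param pull a `joint_trajectory` with at least 2 frames.
#' @param n_points number of output samples (>= 2).
#' @return A `joint_trajectory` with `n_points` frames.
#' @export
resample_linear <- function(pull, n_points = 101) {
  stopifnot(nrow(pull$q) >= 2L, n_points >= 2L)
  t0 <- pull$time[1L]
  dur <- pull$time[length(pull$time)] - t0
  tout <- t0 + dur * seq(0, 1, length.out = n_points)
  interp <- function(M) {
    if (is.null(M)) return(NULL)
    out <- apply(M, 2L, function(col)
      stats::approx(pull$time, col, xout = tout, rule = 2)$y)
    colnames(out) <- colnames(M)
    out
  }
  joint_trajectory(tout - t0, interp(pull$q), interp(pull$qdot),
                   interp(pull$qddot))
}

#' Average the pulls of a set into one representative pull
#'
#' Each pull is resampled to `n_points` normalized-time samples and the
#' pointwise mean per coordinate is taken; the representative pull spans the
#' mean pull duration and its velocities/accelerations are recomputed by
#' central differences.
#'
#' @param pulls a `pull_set` or list of `joint_trajectory` pulls (>= 1).
#' @param n_points normalized-time grid length (default 101, the
#'   conventional 0-100% cycle representation).
#' @return A `joint_trajectory`.
#' @export
average_pulls <- function(pulls, n_points = 101) {
  plist <- if (inherits(pulls, "pull_set")) pulls$pulls else pulls
  if (!length(plist)) stop("cannot average an empty pull set")
  res <- lapply(plist, resample_linear, n_points = n_points)
  qbar <- Reduce(`+`, lapply(res, `[[`, "q")) / length(res)
  dur <- mean(vapply(res, function(p) max(p$time), 0))
  time <- seq(0, dur, length.out = n_points)
  traj <- joint_trajectory(time, qbar)
  traj$qdot <- central_diff(qbar, time)
  traj$qddot <- central_diff(traj$qdot, time)
  traj
}

## Central differences along rows (one-sided at the ends).
central_diff <- function(M, time) {
  n <- nrow(M)
  D <- matrix(0, n, ncol(M), dimnames = dimnames(M))
  if (n < 2L) return(D)
  D[1L, ] <- (M[2L, ] - M[1L, ]) / (time[2L] - time[1L])
  D[n, ] <- (M[n, ] - M[n - 1L, ]) / (time[n] - time[n - 1L])
  if (n > 2L) {
    i <- 2:(n - 1L)
    D[i, ] <- (M[i + 1L, , drop = FALSE] - M[i - 1L, , drop = FALSE]) /
      (time[i + 1L] - time[i - 1L])
  }
  D
}
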