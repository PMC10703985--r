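#' Joint trajectory container
#'
#' @param time strictly increasing time vector, s.
#' @param q matrix of generalized coordinates (frames x coordinates), rad.
#' @param qdot,qddot optional velocity/acceleration matrices.
#' @return A `joint_trajectory` object.
#' @export
joint_trajectory <- function(time, q, qdot = NULL, qddot = NULL) {
  q <- as.matrix(q)
  if (length(time) != nrow(q)) stop("time and q have inconsistent lengths")
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  structure(list(time = as.numeric(time), q = q, qdot = qdot, qddot = qddot,
                 coord_names = colnames(q)),
            class = "joint_trajectory")
}

#' @export
print.joint_trajectory <- function(x, ...) {
  cat("Joint trajectory:", nrow(x$q), "frames,", ncol(x$q), "coordinates,",
      signif(diff(range(x$time)), 4), "s\n")
  invisible(x)
}

minjerk_s <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
minjerk_sd <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4
minjerk_sdd <- function(tau) 60 * tau - 180 * tau^2 + 120 * tau^3

#' Pulling-motion profile
#'
#' Describes one sagittal-dominant pull as per-coordinate start/end angles
#' joined by a minimum-jerk shape. The default profile flexes the back from
#' 20 to 40 degrees, raises both shoulders from 30 to 64 degrees (the
#' reported maximum arm elevation during harvesting) and extends the elbows
#' from 90 to 40 degrees over 1.2 s; all other coordinates stay at zero.
#' These kinematic values are fixture choices for the synthetic generator.
#'
#' @param duration pull duration, s (> 0).
#' @param start_deg,end_deg named vectors of start/end angles in degrees for
#'   a subset of coordinates (unnamed coordinates stay at 0).
#' @param cap_deg peak arm-elevation cap in degrees (default 64).
#' @param model optional `msk_model`; when given, angles are validated
#'   against the coordinate ranges.
#' @return A `pull_profile` object.
#' @export
pull_profile <- function(duration = 1.2,
                         start_deg = c(back_flexion = 20,
                                       shoulder_flexion_r = 30,
                                       shoulder_flexion_l = 30,
                                       elbow_flexion_r = 90,
                                       elbow_flexion_l = 90),
                         end_deg = c(back_flexion = 40,
                                     shoulder_flexion_r = 64,
                                     shoulder_flexion_l = 64,
                                     elbow_flexion_r = 40,
                                     elbow_flexion_l = 40),
                         cap_deg = 64, model = NULL) {
  if (duration <= 0) stop("pull duration must be positive")
  elev <- grep("^shoulder_flexion", unique(c(names(start_deg), names(end_deg))),
               value = TRUE)
  for (cn in elev) {
    if (max(start_deg[cn], end_deg[cn], na.rm = TRUE) > cap_deg + 1e-9) {
      stop("arm elevation exceeds the ", cap_deg, " degree cap")
    }
  }
  if (!is.null(model)) {
    for (cn in names(start_deg)) {
      rng <- model$coordinates[[cn]]$range * 180 / pi
      if (start_deg[cn] < rng[1L] || start_deg[cn] > rng[2L] ||
          end_deg[cn] < rng[1L] || end_deg[cn] > rng[2L]) {
        stop("profile angle for '", cn, "' outside the coordinate range")
      }
    }
  }
  structure(list(duration = duration, start_deg = start_deg,
                 end_deg = end_deg, cap_deg = cap_deg, shape = "min_jerk"),
            class = "pull_profile")
}

profile_angles <- function(profile, coord_names) {
  deg <- pi / 180
  q0 <- q1 <- stats::setNames(numeric(length(coord_names)), coord_names)
  q0[names(profile$start_deg)] <- profile$start_deg * deg
  q1[names(profile$end_deg)] <- profile$end_deg * deg
  list(q0 = q0, q1 = q1)
}

#' Generate a single minimum-jerk pull
#'
#' Interpolates every coordinate from its start to its end angle with a
#' minimum-jerk shape (zero velocity and acceleration at both ends) and
#' returns the trajectory with analytic first and second derivatives.
#'
#' @param profile a [pull_profile()].
#' @param rate sampling rate, Hz.
#' @param model an `msk_model` supplying the coordinate set (default model
#'   if omitted).
#' @param duration optional duration override, s.
#' @return A `joint_trajectory`.
#' @export
generate_pull <- function(profile, rate = 100, model = build_default_model(),
                          duration = NULL) {
  d <- duration %||% profile$duration
  cn <- model$coordinate_names
  ang <- profile_angles(profile, cn)
  for (nm in cn) {
    rng <- model$coordinates[[nm]]$range
    if (ang$q0[nm] < rng[1L] - 1e-9 || ang$q0[nm] > rng[2L] + 1e-9 ||
        ang$q1[nm] < rng[1L] - 1e-9 || ang$q1[nm] > rng[2L] + 1e-9) {
      stop("profile angle for '", nm, "' outside the coordinate range")
    }
  }
  time <- seq(0, d, by = 1 / rate)
  tau <- time / d
  dq <- ang$q1 - ang$q0
  s <- minjerk_s(tau)
  q <- outer(s, dq) + matrix(ang$q0, length(tau), length(cn), byrow = TRUE)
  qdot <- outer(minjerk_sd(tau) / d, dq)
  qddot <- outer(minjerk_sdd(tau) / d^2, dq)
  colnames(q) <- colnames(qdot) <- colnames(qddot) <- cn
  joint_trajectory(time, q, qdot, qddot)
}

#' Compose sensor orientations from a joint trajectory
#'
#' Forward kinematics: composes the joint rotations along the segment chain
#' and reads off the world orientation of each sensor's segment as a unit
#' quaternion (scalar first). At `q = 0` every sensor is at its calibration
#' orientation (identity).
#'
#' @param model an `msk_model`.
#' @param traj a `joint_trajectory` whose coordinates match the model.
#' @return An `orientation_session` with the trajectory stored as ground
#'   truth.
#' @export
forward_orientations <- function(model, traj) {
  sensors <- model$sensors
  nt <- nrow(traj$q)
  quats <- lapply(sensors, function(s) matrix(0, nt, 4L))
  for (i in seq_len(nt)) {
    fk <- fk_orientations(model, traj$q[i, ])
    for (j in seq_along(sensors)) {
      quats[[j]][i, ] <- rotmat_to_quat(fk[[sensors[[j]]]])
    }
  }
  names(quats) <- names(sensors)
  rate <- 1 / stats::median(diff(traj$time))
  orientation_session(traj$time, quats, rate = rate, ground_truth = traj)
}

## World rotation matrix of every segment at configuration q.
fk_orientations <- function(model, q) {
  q <- check_q(model, q, enforce_range = FALSE)
  lk <- model$links$links
  R <- vector("list", length(lk))
  out <- list()
  for (i in seq_along(lk)) {
    l <- lk[[i]]
    Rp <- if (l$parent == 0L) diag(3) else R[[l$parent]]
    R[[i]] <- if (is.null(l$axis)) Rp else
      Rp %*% axis_angle_rotmat(l$axis, q[[l$coord]])
    if (!is.na(l$segment)) out[[l$segment]] <- R[[i]]
  }
  out
}

#' Orientation session container
#'
#' Per-sensor unit-quaternion time series for the six body-worn sensors.
#'
#' @param time time vector, s.
#' @param quats named list of frames x 4 quaternion matrices (w, x, y, z).
#' @param rate sampling rate, Hz.
#' @param ground_truth optional `joint_trajectory`.
#' @param seed optional integer used to generate the session.
#' @param pull_spans optional matrix of ground-truth pull intervals.
#' @return An `orientation_session`.
#' @export
orientation_session <- function(time, quats, rate, ground_truth = NULL,
                                seed = NULL, pull_spans = NULL) {
  lens <- vapply(quats, nrow, 0L)
  if (length(unique(lens)) != 1L || lens[1L] != length(time)) {
    stop("all sensors must have the same number of frames as 'time'")
  }
  if (rate <= 0) stop("sampling rate must be positive")
  structure(list(time = as.numeric(time), quats = quats,
                 sensors = names(quats), rate = rate,
                 ground_truth = ground_truth, seed = seed,
                 pull_spans = pull_spans),
            class = "orientation_session")
}

#' @export
print.orientation_session <- function(x, ...) {
  cat("Orientation session:", length(x$time), "frames at", x$rate, "Hz,",
      length(x$quats), "sensors\n")
  if (!is.null(x$pull_spans)) cat("  ground-truth pulls:", nrow(x$pull_spans), "\n")
  invisible(x)
}

#' Add isotropic orientation noise to a session
#'
#' Right-multiplies each quaternion by a random small rotation whose axis is
#' uniform on the sphere and whose angle is `|N(0, sigma_deg)|`, then
#' renormalizes. Reproducible under the seed.
#'
#' @param session an `orientation_session`.
#' @param sigma_deg noise magnitude, degrees (>= 0).
#' @param seed integer seed.
#' @return A perturbed copy of the session.
#' @export
add_orientation_noise <- function(session, sigma_deg, seed = 1L) {
  stopifnot(sigma_deg >= 0)
  if (sigma_deg == 0) return(session)
  deg <- pi / 180
  with_seed(seed, {
    for (s in names(session$quats)) {
      Q <- session$quats[[s]]
      n <- nrow(Q)
      ax <- matrix(stats::rnorm(3 * n), n, 3L)
      ax <- ax / sqrt(rowSums(ax^2))
      ang <- abs(stats::rnorm(n, 0, sigma_deg * deg))
      h <- ang / 2
      dn <- cbind(cos(h), sin(h) * ax)
      W <- Q[, 1L]; X <- Q[, 2L]; Y <- Q[, 3L]; Z <- Q[, 4L]
      w <- dn[, 1L]; x <- dn[, 2L]; y <- dn[, 3L]; z <- dn[, 4L]
      Qn <- cbind(W * w - X * x - Y * y - Z * z,
                  W * x + X * w + Y * z - Z * y,
                  W * y - X * z + Y * w + Z * x,
                  W * z + X * y - Y * x + Z * w)
      Qn <- Qn / sqrt(rowSums(Qn^2))
      session$quats[[s]] <- Qn
    }
    session$seed <- seed
    session
  })
}

#' Generate a synthetic multi-pull orientation session
#'
#' Emulates a harvesting trial: `n_pulls` minimum-jerk pulls whose durations
#' are jittered by `(1 + U(-jitter, +jitter))`, each followed by a slower
#' return stroke to the starting posture and a rest pause, with isotropic
#' orientation noise added at the end. The exact joint-angle ground truth
#' and the pull (out-stroke) intervals are retained.
#'
#' @param model an `msk_model`.
#' @param profile a [pull_profile()].
#' @param n_pulls number of pulls (>= 1).
#' @param duration_jitter fractional duration jitter in `[0, 1)`.
#' @param sigma_deg orientation noise, degrees.
#' @param seed integer seed driving jitter and noise.
#' @param rate sampling rate, Hz (default 100; the field recordings used
#'   1000 Hz, available via this argument).
#' @param pause rest pause between pulls, s.
#' @param return_fraction duration of the return stroke relative to the
#'   pull duration.
#' @return An `orientation_session` with `ground_truth` and `pull_spans`.
#' @export
generate_session <- function(model, profile = pull_profile(), n_pulls = 5,
                             duration_jitter = 0.1, sigma_deg = 0.5,
                             seed = 1L, rate = 100, pause = 0.5,
                             return_fraction = 0.7) {
  if (n_pulls < 1) stop("n_pulls must be >= 1")
  if (duration_jitter >= 1 || duration_jitter < 0) {
    stop("duration_jitter must be in [0, 1)")
  }
  cn <- model$coordinate_names
  ang <- profile_angles(profile, cn)
  dt <- 1 / rate
  durations <- with_seed(seed, {
    profile$duration *
      (1 + stats::runif(n_pulls, -duration_jitter, duration_jitter))
  })

  blocks <- list()
  spans <- matrix(NA_real_, n_pulls, 2L,
                  dimnames = list(NULL, c("start", "end")))
  t0 <- 0
  hold <- function(qv, dur) {
    nf <- max(1L, round(dur / dt))
    list(q = matrix(qv, nf, length(cn), byrow = TRUE),
         qdot = matrix(0, nf, length(cn)),
         qddot = matrix(0, nf, length(cn)))
  }
  stroke <- function(qa, qb, dur) {
    nf <- max(2L, round(dur / dt))
    tau <- seq_len(nf) / nf  # excludes tau = 0 (previous block ends there)
    dq <- qb - qa
    list(q = outer(minjerk_s(tau), dq) +
           matrix(qa, nf, length(cn), byrow = TRUE),
         qdot = outer(minjerk_sd(tau) / dur, dq),
         qddot = outer(minjerk_sdd(tau) / dur^2, dq))
  }
  blocks[[1L]] <- hold(ang$q0, pause)
  t0 <- nrow(blocks[[1L]]$q) * dt
  for (i in seq_len(n_pulls)) {
    out <- stroke(ang$q0, ang$q1, durations[i])
    spans[i, ] <- c(t0, t0 + nrow(out$q) * dt)
    blocks[[length(blocks) + 1L]] <- out
    t0 <- t0 + nrow(out$q) * dt
    back <- stroke(ang$q1, ang$q0, return_fraction * durations[i])
    blocks[[length(blocks) + 1L]] <- back
    t0 <- t0 + nrow(back$q) * dt
    rest <- hold(ang$q0, pause)
    blocks[[length(blocks) + 1L]] <- rest
    t0 <- t0 + nrow(rest$q) * dt
  }
  q <- do.call(rbind, lapply(blocks, `[[`, "q"))
  qdot <- do.call(rbind, lapply(blocks, `[[`, "qdot"))
  qddot <- do.call(rbind, lapply(blocks, `[[`, "qddot"))
  colnames(q) <- colnames(qdot) <- colnames(qddot) <- cn
  time <- seq(0, by = dt, length.out = nrow(q))
  traj <- joint_trajectory(time, q, qdot, qddot)
  session <- forward_orientations(model, traj)
  session$pull_spans <- spans
  session$seed <- seed
  add_orientation_noise(session, sigma_deg, seed = seed + 1L)
}
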