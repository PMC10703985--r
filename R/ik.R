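#' Geodesic orientation error between two rotations
#'
#' Returns the angle (rad, in `[0, pi]`) of the relative rotation between a
#' measured and a model orientation. Inputs may be unit quaternions
#' (scalar-first, checked to 1e-6) or 3x3 rotation matrices.
#'
#' @param R_measured,R_model rotations.
#' @return Angle in radians.
#' @export
orientation_error <- function(R_measured, R_model) {
  qa <- as_quat(R_measured)
  qb <- as_quat(R_model)
  quat_angle(quat_mul(quat_conj(qa), qb))
}

as_quat <- function(r) {
  if (is.matrix(r) && all(dim(r) == c(3L, 3L))) return(rotmat_to_quat(r))
  r <- as.numeric(r)
  if (length(r) != 4L) stop("rotation must be a unit quaternion or 3x3 matrix")
  if (abs(quat_norm(r) - 1) > 1e-6) stop("quaternion is not unit-norm")
  r
}

#' Inverse-kinematics weights
#'
#' @param weights named non-negative per-sensor weights (at least one > 0).
#' @param sensors sensor names (defaults for unnamed input).
#' @return A named weight vector.
#' @export
ik_weights <- function(weights = NULL, sensors = NULL) {
  if (is.null(weights)) {
    if (is.null(sensors)) stop("either weights or sensors must be given")
    weights <- stats::setNames(rep(1, length(sensors)), sensors)
  }
  if (any(weights < 0) || all(weights == 0)) {
    stop("weights must be non-negative with at least one positive entry")
  }
  weights
}

## Weighted residual vector: per sensor, sqrt(w) times the rotation vector
## of the relative rotation between model and measured orientation.
ik_residual <- function(model, q, measured, weights) {
  fk <- fk_orientations(model, q)
  res <- numeric(0)
  for (s in names(measured)) {
    w <- weights[[s]]
    if (is.null(w) || w == 0) next
    qm <- rotmat_to_quat(fk[[model$sensors[[s]]]])
    rel <- quat_mul(quat_conj(qm), measured[[s]])
    res <- c(res, sqrt(w) * quat_to_rotvec(rel))
  }
  res
}

#' Solve one inverse-kinematics frame
#'
#' Finds a local minimizer of the weighted sum of squared geodesic
#' orientation errors between measured and model sensor orientations, using
#' damped Gauss-Newton with numeric Jacobians. Coordinates are clipped to
#' their ranges; the objective at the solution never exceeds the objective
#' at `q_init`. Non-convergence after `max_iter` iterations returns the
#' best-so-far result flagged as unconverged.
#'
#' @param model an `msk_model`.
#' @param measured named list of per-sensor unit quaternions.
#' @param weights per-sensor weights (default 1 for all sensors).
#' @param q_init starting coordinate vector (rad), within ranges.
#' @param max_iter maximum Gauss-Newton iterations.
#' @param tol step-norm convergence tolerance, rad.
#' @return List with `q`, `objective`, `converged`, `iterations`.
#' @export
ik_solve_frame <- function(model, measured, weights = NULL, q_init = NULL,
                           max_iter = 60L, tol = 1e-9) {
  weights <- ik_weights(weights, names(model$sensors))
  cn <- model$coordinate_names
  lower <- vapply(model$coordinates, function(cc) cc$range[1L], 0)
  upper <- vapply(model$coordinates, function(cc) cc$range[2L], 0)
  q <- if (is.null(q_init)) stats::setNames(numeric(length(cn)), cn) else
    check_q(model, q_init)
  q <- pmin(pmax(q, lower), upper)

  obj <- function(qq) sum(ik_residual(model, qq, measured, weights)^2)
  f <- obj(q)
  lambda <- 1e-3
  converged <- FALSE
  it <- 0L
  h <- 1e-6
  while (it < max_iter) {
    it <- it + 1L
    r <- ik_residual(model, q, measured, weights)
    J <- matrix(0, length(r), length(cn))
    for (j in seq_along(cn)) {
      qp <- q; qp[j] <- q[j] + h
      qm <- q; qm[j] <- q[j] - h
      J[, j] <- (ik_residual(model, qp, measured, weights) -
                   ik_residual(model, qm, measured, weights)) / (2 * h)
    }
    g <- -crossprod(J, r)
    JtJ <- crossprod(J)
    accepted <- FALSE
    for (try in 1:10) {
      delta <- tryCatch(
        solve(JtJ + lambda * diag(length(cn)), g),
        error = function(e) NULL)
      if (!is.null(delta)) {
        q_new <- pmin(pmax(q + as.numeric(delta), lower), upper)
        f_new <- obj(q_new)
        if (f_new <= f) {
          step <- sqrt(sum((q_new - q)^2))
          q <- q_new; f <- f_new
          lambda <- max(lambda / 3, 1e-10)
          accepted <- TRUE
          if (step < tol || f < 1e-20) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted) { converged <- TRUE }  # no descent direction left
    if (converged) break
  }
  list(q = q, objective = f, converged = converged || it < max_iter,
       iterations = it)
}

#' Solve inverse kinematics over a whole session
#'
#' Frame-sequential solve, warm-started from the previous frame (or
#' independently from `q_init` when `warm_start = FALSE`). Velocities and
#' accelerations are obtained by central finite differences of the solved
#' coordinates after zero-phase low-pass filtering.
#'
#' @param model an `msk_model`.
#' @param session an `orientation_session`.
#' @param weights per-sensor weights.
#' @param warm_start warm-start each frame from the previous solution.
#' @param fc cut-off frequency for the coordinate low-pass filter, Hz
#'   (`NA` to skip filtering).
#' @param q_init initial coordinate vector for the first frame.
#' @return A `joint_trajectory` with a `quality` attribute (per-frame
#'   objective and convergence flags).
#' @export
ik_solve_trajectory <- function(model, session, weights = NULL,
                                warm_start = TRUE, fc = 6, q_init = NULL) {
  if (!length(session$time)) stop("session is empty")
  weights <- ik_weights(weights, names(model$sensors))
  cn <- model$coordinate_names
  nt <- length(session$time)
  qmat <- matrix(0, nt, length(cn), dimnames = list(NULL, cn))
  objective <- numeric(nt)
  flags <- logical(nt)
  qprev <- q_init
  for (i in seq_len(nt)) {
    measured <- lapply(session$quats, function(Q) Q[i, ])
    sol <- ik_solve_frame(model, measured, weights,
                          q_init = if (warm_start) qprev else q_init)
    qmat[i, ] <- sol$q
    objective[i] <- sol$objective
    flags[i] <- !sol$converged
    if (warm_start) qprev <- sol$q
  }
  qs <- if (is.na(fc) || nt <= 12L) qmat else
    butterworth_lowpass(qmat, fs = session$rate, fc = fc)
  traj <- joint_trajectory(session$time, qs)
  traj$qdot <- central_diff(qs, session$time)
  traj$qddot <- central_diff(traj$qdot, session$time)
  attr(traj, "quality") <- list(objective = objective, flagged = flags)
  traj
}
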