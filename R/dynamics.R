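#' Inverse dynamics of a joint trajectory
#'
#' Computes the generalized forces `tau = M(q) qdd + C(q, qd) + G(q) -
#' J(q)^T F_ext` frame by frame with a recursive Newton-Euler traversal of
#' the segment tree. Gravity enters through the standard fictitious base
#' acceleration; external loads (world-frame forces at segment-frame
#' application points) are mapped through the moment balance of the
#' backward pass.
#'
#' @param model an `msk_model`.
#' @param traj a `joint_trajectory` with `qdot` and `qddot` (missing
#'   derivatives are obtained by central differences).
#' @param loads list of external loads (see [hand_load_default()]); `NULL`
#'   for none.
#' @return A `generalized_forces` object: list with `time` and `tau`
#'   (frames x coordinates, N m).
#' @export
inverse_dynamics <- function(model, traj, loads = NULL) {
  qdot <- traj$qdot %||% central_diff(traj$q, traj$time)
  qddot <- traj$qddot %||% central_diff(qdot, traj$time)
  nt <- nrow(traj$q)
  tau <- matrix(0, nt, length(model$coordinates),
                dimnames = list(NULL, model$coordinate_names))
  for (i in seq_len(nt)) {
    tau[i, ] <- rnea(model, traj$q[i, ], qdot[i, ], qddot[i, ], loads = loads)
  }
  structure(list(time = traj$time, tau = tau), class = "generalized_forces")
}

#' @export
print.generalized_forces <- function(x, ...) {
  cat("Generalized forces:", nrow(x$tau), "frames,", ncol(x$tau),
      "coordinates\n")
  invisible(x)
}

## Recursive Newton-Euler in world coordinates over the virtual-link chain.
## Returns the generalized-force vector for one state.
rnea <- function(model, q, qd, qdd, loads = NULL, gravity = model$gravity) {
  q <- check_q(model, q, enforce_range = FALSE)
  if (is.null(names(qd))) names(qd) <- model$coordinate_names
  if (is.null(names(qdd))) names(qdd) <- model$coordinate_names
  lk <- model$links$links
  nl <- length(lk)
  R <- vector("list", nl)
  p <- vector("list", nl)      # link origin
  w <- vector("list", nl)      # angular velocity
  al <- vector("list", nl)     # angular acceleration
  ao <- vector("list", nl)     # linear acceleration of link origin
  s_ax <- vector("list", nl)   # world joint axis

  load_by_seg <- list()
  if (!is.null(loads)) {
    for (ld in loads) {
      load_by_seg[[ld$segment]] <- c(load_by_seg[[ld$segment]], list(ld))
    }
  }

  a_base <- -gravity
  for (i in seq_len(nl)) {
    l <- lk[[i]]
    if (l$parent == 0L) {
      Rp <- diag(3); pp <- c(0, 0, 0); wp <- c(0, 0, 0)
      alp <- c(0, 0, 0); aop <- a_base
    } else {
      Rp <- R[[l$parent]]; pp <- p[[l$parent]]; wp <- w[[l$parent]]
      alp <- al[[l$parent]]; aop <- ao[[l$parent]]
    }
    d <- as.numeric(Rp %*% l$offset)
    p[[i]] <- pp + d
    ao_i <- aop + cross3(alp, d) + cross3(wp, cross3(wp, d))
    if (is.null(l$axis)) {
      R[[i]] <- Rp; w[[i]] <- wp; al[[i]] <- alp
    } else {
      cn <- model$coordinate_names[l$coord]
      R[[i]] <- Rp %*% axis_angle_rotmat(l$axis, q[[cn]])
      s <- as.numeric(Rp %*% l$axis)
      s_ax[[i]] <- s
      w[[i]] <- wp + s * qd[[cn]]
      al[[i]] <- alp + s * qdd[[cn]] + cross3(wp, s) * qd[[cn]]
    }
    ao[[i]] <- ao_i
  }

  f <- vector("list", nl)   # joint force transmitted from parent
  n <- vector("list", nl)   # joint moment about link origin
  for (i in seq_len(nl)) { f[[i]] <- c(0, 0, 0); n[[i]] <- c(0, 0, 0) }

  tau <- stats::setNames(numeric(length(model$coordinates)),
                         model$coordinate_names)
  for (i in rev(seq_len(nl))) {
    l <- lk[[i]]
    if (l$mass > 0) {
      cw <- as.numeric(R[[i]] %*% l$com)
      a_c <- ao[[i]] + cross3(al[[i]], cw) + cross3(w[[i]], cross3(w[[i]], cw))
      Iw <- R[[i]] %*% l$inertia %*% t(R[[i]])
      Fi <- l$mass * a_c
      Ni <- as.numeric(Iw %*% al[[i]]) + cross3(w[[i]], as.numeric(Iw %*% w[[i]]))
      f[[i]] <- f[[i]] + Fi
      n[[i]] <- n[[i]] + Ni + cross3(cw, Fi)
    }
    if (!is.na(l$segment) && !is.null(load_by_seg[[l$segment]])) {
      for (ld in load_by_seg[[l$segment]]) {
        pa <- as.numeric(R[[i]] %*% ld$application_point)
        f[[i]] <- f[[i]] - ld$force
        n[[i]] <- n[[i]] - cross3(pa, ld$force)
      }
    }
    if (!is.null(s_ax[[i]])) {
      tau[model$coordinate_names[l$coord]] <- sum(s_ax[[i]] * n[[i]])
    }
    if (l$parent > 0L) {
      j <- l$parent
      f[[j]] <- f[[j]] + f[[i]]
      n[[j]] <- n[[j]] + n[[i]] + cross3(p[[i]] - p[[j]], f[[i]])
    }
  }
  tau
}

#' Forward dynamics (verification oracle)
#'
#' Solves `M(q) qdd = tau + J^T F_ext - C - G` with the mass matrix
#' assembled column-by-column from inverse dynamics at unit accelerations
#' and the bias term taken from inverse dynamics at zero acceleration, so
#' the inverse/forward pair is consistent by construction.
#'
#' @param model an `msk_model`.
#' @param q,qdot state vectors (rad, rad/s).
#' @param tau applied generalized forces (N m).
#' @param loads external loads.
#' @return Generalized accelerations `qddot` (rad/s^2).
#' @export
forward_dynamics <- function(model, q, qdot, tau, loads = NULL) {
  n <- length(model$coordinates)
  M <- mass_matrix(model, q)
  bias <- rnea(model, q, qdot, numeric(n), loads = loads)
  if (is.null(names(tau))) names(tau) <- model$coordinate_names
  qdd <- solve(M, tau[model$coordinate_names] - bias)
  stats::setNames(as.numeric(qdd), model$coordinate_names)
}

#' Joint-space mass matrix
#'
#' @param model an `msk_model`.
#' @param q coordinate vector.
#' @return Symmetric positive-definite n x n matrix.
#' @export
mass_matrix <- function(model, q) {
  n <- length(model$coordinates)
  zero_g <- c(0, 0, 0)
  M <- matrix(0, n, n,
              dimnames = list(model$coordinate_names, model$coordinate_names))
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    M[, j] <- rnea(model, q, numeric(n), e, loads = NULL, gravity = zero_g)
  }
  (M + t(M)) / 2
}

#' Total mechanical energy of a state
#'
#' Kinetic plus gravitational potential energy; used to verify energy
#' conservation of unforced forward-dynamics rollouts.
#'
#' @param model an `msk_model`.
#' @param q,qdot state vectors.
#' @return Energy in joules.
#' @export
mechanical_energy <- function(model, q, qdot) {
  M <- mass_matrix(model, q)
  ke <- 0.5 * sum(qdot * as.numeric(M %*% qdot))
  q <- check_q(model, q, enforce_range = FALSE)
  lk <- model$links$links
  R <- vector("list", length(lk)); p <- vector("list", length(lk))
  pe <- 0
  for (i in seq_along(lk)) {
    l <- lk[[i]]
    Rp <- if (l$parent == 0L) diag(3) else R[[l$parent]]
    pp <- if (l$parent == 0L) c(0, 0, 0) else p[[l$parent]]
    p[[i]] <- pp + as.numeric(Rp %*% l$offset)
    R[[i]] <- if (is.null(l$axis)) Rp else
      Rp %*% axis_angle_rotmat(l$axis, q[[model$coordinate_names[l$coord]]])
    if (l$mass > 0) {
      cw <- p[[i]] + as.numeric(R[[i]] %*% l$com)
      pe <- pe - l$mass * sum(model$gravity * cw)
    }
  }
  ke + pe
}
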