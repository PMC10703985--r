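## Core quadratic program of the muscle-redundancy resolution.
##
## minimize  sum(a^2) + sum_j∈R ((tau_j - (K a)_j) / F_j)^2
## subject   (K a)_j = tau_j  for coordinates without a reserve actuator,
##           0 <= a <= 1
##
## kappa: coords x muscles matrix of moment per unit activation (F0 * f * r).
## reserve_fopt: named optimal forces for reserve-equipped coordinates.
## Solved with an active-set QP, then the detected active set is re-solved
## exactly (KKT system) to tighten the solution to ~1e-12.
so_qp <- function(kappa, tau, reserve_fopt = NULL) {
  m <- ncol(kappa)
  coords <- rownames(kappa)
  if (is.null(coords)) coords <- paste0("c", seq_len(nrow(kappa)))
  rownames(kappa) <- coords
  tau <- tau[coords]
  resv <- intersect(coords, names(reserve_fopt))
  eqc <- setdiff(coords, resv)

  W <- if (length(resv)) diag(1 / reserve_fopt[resv]^2,
                              nrow = length(resv)) else NULL
  BR <- kappa[resv, , drop = FALSE]
  BE <- kappa[eqc, , drop = FALSE]
  C <- 2 * (diag(m) + if (length(resv)) crossprod(BR, W %*% BR) else 0)
  C <- (C + t(C)) / 2
  d <- if (length(resv)) as.numeric(-2 * crossprod(BR, W %*% tau[resv])) else
    numeric(m)

  sol <- tryCatch(
    pracma::quadprog(C, d,
                     Aeq = if (length(eqc)) BE else NULL,
                     beq = if (length(eqc)) as.numeric(tau[eqc]) else NULL,
                     lb = rep(0, m), ub = rep(1, m)),
    error = function(e) NULL)
  if (is.null(sol) || sol$eflag != 1) {
    stop("static optimization infeasible: no activation/reserve combination ",
         "balances the required moments")
  }
  a <- pmin(pmax(sol$xmin, 0), 1)

  ## exact re-solve on the detected active set
  tol_act <- 1e-7
  free <- which(a > tol_act & a < 1 - tol_act)
  act <- setdiff(seq_len(m), free)
  if (length(free)) {
    aA <- a; aA[free] <- 0
    rhs1 <- -(d[free] + as.numeric(C[free, act, drop = FALSE] %*% a[act]))
    if (length(eqc)) {
      K11 <- C[free, free, drop = FALSE]
      K12 <- t(BE[, free, drop = FALSE])
      Kmat <- rbind(cbind(K11, K12),
                    cbind(BE[, free, drop = FALSE],
                          matrix(0, length(eqc), length(eqc))))
      rhs <- c(rhs1, as.numeric(tau[eqc]) -
                 as.numeric(BE[, act, drop = FALSE] %*% a[act]))
      ref <- tryCatch(solve(Kmat, rhs), error = function(e) NULL)
      if (!is.null(ref)) {
        a_try <- a; a_try[free] <- ref[seq_along(free)]
        if (all(a_try >= -1e-9 & a_try <= 1 + 1e-9)) a <- pmin(pmax(a_try, 0), 1)
      }
    } else {
      ref <- tryCatch(solve(C[free, free, drop = FALSE], rhs1),
                      error = function(e) NULL)
      if (!is.null(ref)) {
        a_try <- a; a_try[free] <- ref
        if (all(a_try >= -1e-9 & a_try <= 1 + 1e-9)) a <- pmin(pmax(a_try, 0), 1)
      }
    }
  }

  resid <- as.numeric(tau - kappa %*% a)
  names(resid) <- coords
  reserves <- stats::setNames(numeric(length(resv)), resv)
  reserves[resv] <- resid[resv]
  objective <- sum(a^2) +
    if (length(resv)) sum((reserves / reserve_fopt[resv])^2) else 0
  list(activations = a, reserves = reserves, objective = objective,
       residual = resid, equality_residual =
         if (length(eqc)) max(abs(resid[eqc])) else 0)
}

## Per-frame muscle data at state (q, qdot): path lengths, velocities,
## Hill scale factors and the kappa matrix.
so_frame_data <- function(model, q, qdot) {
  cn <- model$coordinate_names
  fnames <- names(model$fascicles)
  kappa <- matrix(0, length(cn), length(fnames), dimnames = list(cn, fnames))
  lens <- vels <- scales <- stats::setNames(numeric(length(fnames)), fnames)
  for (fn in fnames) {
    f <- model$fascicles[[fn]]
    L <- muscle_length(model, fn, q, enforce_range = FALSE)
    v <- 0
    for (cc in setdiff(names(f$path), "const")) {
      r <- moment_arm(model, fn, q, cc, enforce_range = FALSE)
      kappa[cc, fn] <- f$F0 * r
      v <- v - r * qdot[[cc]]
    }
    sc <- hill_force_scale(f, L, v)
    kappa[, fn] <- kappa[, fn] * sc
    lens[fn] <- L; vels[fn] <- v; scales[fn] <- sc
  }
  list(kappa = kappa, lengths = lens, velocities = vels, scales = scales)
}

#' Solve one static-optimization frame
#'
#' Resolves the net joint moments into muscle activations, reserve torques
#' and the (state-determined) exotendon contribution by minimizing the sum
#' of squared activations plus squared normalized reserve torques, subject
#' to moment balance at every coordinate and activation bounds `[0, 1]`.
#' The exotendon tension is evaluated first from the kinematic state and
#' moved to the left-hand side as a fixed moment contribution.
#'
#' @param model an `msk_model` (optionally carrying one exotendon).
#' @param tau named vector of required generalized forces, N m.
#' @param q coordinate vector, rad.
#' @param qdot coordinate velocities, rad/s (default zero).
#' @param exo_Ldot exotendon path lengthening rate override, m/s; by
#'   default computed analytically from `qdot` along the shared host path.
#' @return A `frame_solution`: activations, muscle forces (N), reserve
#'   torques (N m), exotendon tension and per-coordinate moments, objective,
#'   moment-balance residual and a saturation flag.
#' @export
so_solve_frame <- function(model, tau, q, qdot = NULL, exo_Ldot = NULL) {
  cn <- model$coordinate_names
  if (is.null(qdot)) qdot <- stats::setNames(numeric(length(cn)), cn)
  if (is.null(names(qdot))) names(qdot) <- cn
  q <- check_q(model, q, enforce_range = FALSE)
  if (is.null(names(tau))) names(tau) <- cn
  dat <- so_frame_data(model, q, qdot)

  exo_T <- 0
  exo_mom <- stats::setNames(numeric(length(cn)), cn)
  if (length(model$exotendons)) {
    exo <- model$exotendons[[1L]]
    host <- exo$host_fascicle
    L <- dat$lengths[[host]]
    Ldot <- exo_Ldot %||% dat$velocities[[host]]
    exo_T <- exotendon_tension(exo, L, Ldot)
    for (cc in setdiff(names(model$fascicles[[host]]$path), "const")) {
      exo_mom[cc] <- exo_T * moment_arm(model, host, q, cc,
                                        enforce_range = FALSE)
    }
  }
  tau_eff <- tau[cn] - exo_mom

  qp <- so_qp(dat$kappa, tau_eff, model$reserves)
  forces <- qp$activations *
    vapply(model$fascicles, `[[`, 0, "F0")[colnames(dat$kappa)] * dat$scales
  structure(list(
    activations = stats::setNames(qp$activations, colnames(dat$kappa)),
    muscle_forces = stats::setNames(forces, colnames(dat$kappa)),
    reserve_torques = qp$reserves,
    exotendon_tension = exo_T,
    exotendon_moments = exo_mom,
    objective = qp$objective,
    balance_residual = qp$equality_residual,
    saturated = any(qp$activations >= 1 - 1e-9),
    status = "optimal"
  ), class = "frame_solution")
}

#' Solve static optimization over a run
#'
#' Applies [so_solve_frame()] to every frame of a trajectory with its
#' generalized forces. The exotendon path-length rate is taken from finite
#' differences of the host-path length along the trajectory.
#'
#' @param model an `msk_model`.
#' @param traj a `joint_trajectory` (the representative pull).
#' @param gen_forces a `generalized_forces` object aligned with `traj`.
#' @return A `run_result`: per-frame activation/force/reserve matrices, the
#'   exotendon tension series, the inputs, and a device descriptor.
#' @export
so_solve_run <- function(model, traj, gen_forces) {
  nt <- nrow(traj$q)
  if (nrow(gen_forces$tau) != nt) stop("trajectory and forces are misaligned")
  qdot <- traj$qdot %||% central_diff(traj$q, traj$time)

  exo_Ldot <- rep(0, nt)
  if (length(model$exotendons)) {
    host <- model$exotendons[[1L]]$host_fascicle
    Lser <- vapply(seq_len(nt), function(i)
      muscle_length(model, host, traj$q[i, ], enforce_range = FALSE), 0)
    exo_Ldot <- as.numeric(central_diff(matrix(Lser), traj$time))
  }

  frames <- vector("list", nt)
  for (i in seq_len(nt)) {
    frames[[i]] <- tryCatch(
      so_solve_frame(model, gen_forces$tau[i, ], traj$q[i, ], qdot[i, ],
                     exo_Ldot = exo_Ldot[i]),
      error = function(e) stop("static optimization failed at frame ", i,
                               ": ", conditionMessage(e)))
  }
  device <- if (length(model$exotendons)) {
    e <- model$exotendons[[1L]]
    list(host = e$host_fascicle, stiffness = e$stiffness,
         rule = e$resting_rule, resting_length = e$resting_length)
  } else "unassisted"
  structure(list(
    time = traj$time,
    activations = do.call(rbind, lapply(frames, `[[`, "activations")),
    muscle_forces = do.call(rbind, lapply(frames, `[[`, "muscle_forces")),
    reserve_torques = do.call(rbind, lapply(frames, `[[`, "reserve_torques")),
    exotendon_tension = vapply(frames, `[[`, 0, "exotendon_tension"),
    exotendon_moments = do.call(rbind, lapply(frames, `[[`, "exotendon_moments")),
    objective = vapply(frames, `[[`, 0, "objective"),
    balance_residual = vapply(frames, `[[`, 0, "balance_residual"),
    trajectory = traj,
    gen_forces = gen_forces,
    device = device,
    model = model
  ), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  dev <- if (identical(x$device, "unassisted")) "unassisted" else
    paste0(x$device$host, " (K = ", x$device$stiffness, " N/m, ",
           x$device$rule, ")")
  cat("Static-optimization run:", nrow(x$activations), "frames,", dev, "\n")
  invisible(x)
}

#' Brute-force oracle for small static-optimization instances
#'
#' Independent verification route for instances with at most 3 muscles and
#' 2 coordinates: a zooming grid search over activations (final resolution
#' 1e-3) on the penalized objective, followed by a bounded quasi-Newton
#' polish. Coordinates without a reserve are enforced with a large
#' quadratic penalty.
#'
#' @param kappa coords x muscles matrix of moment per unit activation.
#' @param tau named required-moment vector.
#' @param reserve_fopt named reserve optimal forces (`NULL` for none).
#' @return List with `activations` and `objective` (comparable with the QP
#'   objective of [so_solve_frame()]).
#' @export
so_brute_force <- function(kappa, tau, reserve_fopt = NULL) {
  m <- ncol(kappa)
  stopifnot(m <= 3L, nrow(kappa) <= 2L)
  coords <- rownames(kappa)
  if (is.null(coords)) {
    coords <- paste0("c", seq_len(nrow(kappa)))
    rownames(kappa) <- coords
  }
  tau <- tau[coords]
  resv <- intersect(coords, names(reserve_fopt))
  eqc <- setdiff(coords, resv)
  pen_obj_at <- function(a, big) {
    r <- as.numeric(tau - kappa %*% a)
    names(r) <- coords
    sum(a^2) +
      (if (length(resv)) sum((r[resv] / reserve_fopt[resv])^2) else 0) +
      (if (length(eqc)) big * sum(r[eqc]^2) else 0)
  }
  centre <- rep(0.5, m); half <- 0.5
  best <- centre; fbest <- pen_obj_at(centre, 1e6)
  for (pass in 1:4) {
    grids <- lapply(seq_len(m), function(j) {
      g <- seq(centre[j] - half, centre[j] + half, length.out = 11L)
      pmin(pmax(g, 0), 1)
    })
    pts <- as.matrix(expand.grid(grids))
    vals <- apply(pts, 1L, pen_obj_at, big = 1e6)
    k <- which.min(vals)
    if (vals[k] < fbest) { fbest <- vals[k]; best <- as.numeric(pts[k, ]) }
    centre <- best
    half <- half / 5
  }
  ## penalty continuation keeps the bounded quasi-Newton polish conditioned
  for (big in c(1e2, 1e4, 1e6, 1e8, 1e10)) {
    ref <- stats::optim(best, pen_obj_at, big = big, method = "L-BFGS-B",
                        lower = rep(0, m), upper = rep(1, m),
                        control = list(factr = 1, maxit = 500))
    best <- ref$par
  }
  r <- as.numeric(tau - kappa %*% best); names(r) <- coords
  objective <- sum(best^2) +
    if (length(resv)) sum((r[resv] / reserve_fopt[resv])^2) else 0
  list(activations = best, objective = objective)
}
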