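## Delimited-text serialization. Numbers are written with 17 significant
## digits so that IEEE doubles round-trip exactly.

fmt_num <- function(x) sprintf("%.17g", x)

write_delim_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write or read a joint trajectory as delimited text
#'
#' One row per frame: time (s) followed by one column per coordinate in
#' degrees.
#'
#' @param traj a `joint_trajectory`.
#' @param path file path.
#' @return `read_trajectory` returns a `joint_trajectory` (radians).
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = traj$time, traj$q * 180 / pi, check.names = FALSE)
  write_delim_exact(df, path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  q <- as.matrix(df[, -1L, drop = FALSE]) * pi / 180
  traj <- joint_trajectory(df$time, q)
  traj$qdot <- central_diff(q, df$time)
  traj$qddot <- central_diff(traj$qdot, df$time)
  traj
}

#' Write or read an orientation session as delimited text
#'
#' One row per frame: time then `w,x,y,z` per sensor in the fixed sensor
#' order, with a header naming the sensors.
#'
#' @param session an `orientation_session`.
#' @param path file path.
#' @return `read_session` returns an `orientation_session` (without ground
#'   truth).
#' @export
write_session <- function(session, path) {
  cols <- list(time = session$time)
  for (s in session$sensors) {
    Q <- session$quats[[s]]
    for (k in 1:4) {
      cols[[paste0(s, "_", c("w", "x", "y", "z")[k])]] <- Q[, k]
    }
  }
  write_delim_exact(as.data.frame(cols, check.names = FALSE), path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  comp_cols <- setdiff(names(df), "time")
  sensors <- unique(sub("_[wxyz]$", "", comp_cols))
  quats <- lapply(sensors, function(s) {
    M <- as.matrix(df[, paste0(s, "_", c("w", "x", "y", "z"))])
    dimnames(M) <- NULL
    M
  })
  names(quats) <- sensors
  rate <- 1 / stats::median(diff(df$time))
  orientation_session(df$time, quats, rate = rate)
}

#' Write or read a static-optimization run
#'
#' The per-frame table (time, activations, muscle forces, reserve torques,
#' exotendon tension and moments) goes to `<path>.tsv` and the run manifest
#' (device descriptor, seed) to `<path>.json`.
#'
#' @param run a `run_result`.
#' @param path file path prefix (no extension).
#' @param model the `msk_model` the run was produced with (required to
#'   rebuild the `run_result` on read).
#' @return `read_run_result` returns a `run_result`.
#' @export
write_run_result <- function(run, path) {
  df <- data.frame(
    time = run$time,
    stats::setNames(as.data.frame(run$activations),
                    paste0("act_", colnames(run$activations))),
    stats::setNames(as.data.frame(run$muscle_forces),
                    paste0("force_", colnames(run$muscle_forces))),
    stats::setNames(as.data.frame(run$reserve_torques),
                    paste0("reserve_", colnames(run$reserve_torques))),
    exo_tension = run$exotendon_tension,
    stats::setNames(as.data.frame(run$exotendon_moments),
                    paste0("exomom_", colnames(run$exotendon_moments))),
    stats::setNames(as.data.frame(run$gen_forces$tau),
                    paste0("tau_", colnames(run$gen_forces$tau))),
    check.names = FALSE)
  write_delim_exact(df, paste0(path, ".tsv"))
  manifest <- list(device = run$device,
                   n_frames = length(run$time),
                   objective_total = sum(run$objective))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_run_result
#' @export
read_run_result <- function(path, model) {
  df <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t",
                          check.names = FALSE)
  manifest <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pick <- function(prefix) {
    cols <- grep(paste0("^", prefix, "_"), names(df), value = TRUE)
    M <- as.matrix(df[, cols, drop = FALSE])
    colnames(M) <- sub(paste0("^", prefix, "_"), "", cols)
    M
  }
  q <- matrix(0, nrow(df), length(model$coordinates),
              dimnames = list(NULL, model$coordinate_names))
  tau_m <- pick("tau")
  traj <- joint_trajectory(df$time, q)
  structure(list(
    time = df$time,
    activations = pick("act"),
    muscle_forces = pick("force"),
    reserve_torques = pick("reserve"),
    exotendon_tension = df$exo_tension,
    exotendon_moments = pick("exomom"),
    objective = rep(NA_real_, nrow(df)),
    balance_residual = rep(NA_real_, nrow(df)),
    trajectory = traj,
    gen_forces = structure(list(time = df$time, tau = tau_m),
                           class = "generalized_forces"),
    device = if (is.character(manifest$device)) manifest$device else
      manifest$device,
    model = model
  ), class = "run_result")
}
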