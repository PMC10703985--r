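#' Run the kinematic front end of a synthetic harvesting trial
#'
#' Generates a seeded multi-pull orientation session, low-pass filters the
#' orientation signals, solves inverse kinematics, segments and averages the
#' pulls into one representative pull, and computes its net joint moments
#' under the external hand loads. The result feeds [run_unassisted()],
#' [run_assisted()] and [run_sweep()], which share this kinematic state (the
#' assistive device does not change the upper-extremity kinematics).
#'
#' @param seed integer seed for the session.
#' @param model an `msk_model`.
#' @param profile a [pull_profile()].
#' @param n_pulls number of pulls.
#' @param sigma_deg orientation noise, degrees.
#' @param rate sampling rate, Hz.
#' @param n_points normalized-time grid of the representative pull.
#' @param loads external loads (default [hand_load_default()]).
#' @param fc low-pass cut-off, Hz.
#' @return A `harvest_scenario` list.
#' @export
harvest_scenario <- function(seed = 1L, model = build_default_model(),
                             profile = pull_profile(), n_pulls = 5,
                             sigma_deg = 0.5, rate = 100, n_points = 101,
                             loads = hand_load_default(), fc = 6) {
  session <- generate_session(model, profile, n_pulls = n_pulls,
                              sigma_deg = sigma_deg, seed = seed, rate = rate)
  filtered <- filter_session(session, fc = fc)
  traj <- ik_solve_trajectory(model, filtered, fc = fc)
  pulls <- segment_pulls(traj)
  if (!length(pulls$pulls)) stop("no pulls detected in the session")
  rep_pull <- average_pulls(pulls, n_points)
  tau <- inverse_dynamics(model, rep_pull, loads)
  structure(list(model = model, session = session, trajectory = traj,
                 pulls = pulls, representative_pull = rep_pull,
                 gen_forces = tau, loads = loads, seed = seed),
            class = "harvest_scenario")
}

#' @export
print.harvest_scenario <- function(x, ...) {
  cat("Harvest scenario (seed", x$seed, "):", length(x$pulls$pulls),
      "pulls detected,", nrow(x$representative_pull$q),
      "frames in the representative pull\n")
  invisible(x)
}

#' Solve the unassisted condition of a scenario
#'
#' @param scenario a [harvest_scenario()].
#' @return A `run_result`.
#' @export
run_unassisted <- function(scenario) {
  so_solve_run(scenario$model, scenario$representative_pull,
               scenario$gen_forces)
}

#' Solve an assisted condition of a scenario
#'
#' Attaches one exotendon to the host fascicle and re-solves the static
#' optimization on the same kinematics and net joint moments.
#'
#' @param scenario a [harvest_scenario()].
#' @param host host fascicle name.
#' @param stiffness exotendon stiffness, N/m.
#' @param rule resting-length rule.
#' @return A `run_result`.
#' @export
run_assisted <- function(scenario, host, stiffness = 10000, rule = "LR2") {
  m <- attach_exotendon(scenario$model, host, stiffness, rule)
  so_solve_run(m, scenario$representative_pull, scenario$gen_forces)
}

#' Sweep assistive-device placements, resting-length rules and stiffnesses
#'
#' Runs the unassisted condition once and every `(host, rule, stiffness)`
#' cell of the grid, then tabulates the percent reductions in peak summed
#' activation and force of the measured muscle groups.
#'
#' @param scenario a [harvest_scenario()].
#' @param hosts host fascicles (default: the seven published devices).
#' @param rules resting-length rules (default `LR1`, `LR2`).
#' @param stiffnesses stiffness grid, N/m (default 1 kN/m and 10 kN/m).
#' @return A `sweep_result`: the unassisted run, the per-cell runs and a
#'   long-format `cells` data frame.
#' @export
run_sweep <- function(scenario, hosts = device_order,
                      rules = c("LR1", "LR2"),
                      stiffnesses = c(1000, 10000)) {
  unassisted <- run_unassisted(scenario)
  pm0 <- peak_metrics(unassisted)
  runs <- list()
  cells <- list()
  for (host in hosts) {
    for (rule in rules) {
      for (K in stiffnesses) {
        key <- paste(host, rule, K, sep = "|")
        run <- run_assisted(scenario, host, stiffness = K, rule = rule)
        runs[[key]] <- run
        pm1 <- peak_metrics(run)
        for (mu in table_muscles) {
          cells[[length(cells) + 1L]] <- data.frame(
            device = host, rule = rule, stiffness = K, muscle = mu,
            activation_reduction = reduction_percent(
              pm0$activation_peak[[mu]], pm1$activation_peak[[mu]]),
            force_reduction = reduction_percent(
              pm0$force_peak[[mu]], pm1$force_peak[[mu]]))
        }
      }
    }
  }
  structure(list(unassisted = unassisted, runs = runs,
                 cells = do.call(rbind, cells),
                 baseline = list(activation = pm0$activation_peak,
                                 force = pm0$force_peak),
                 hosts = hosts, rules = rules, stiffnesses = stiffnesses),
            class = "sweep_result")
}

#' Sweep table in the published layout
#'
#' Reshapes the sweep cells into the published table layouts: measured
#' muscle blocks x device rows, with one column pair per resting-length
#' rule (at fixed stiffness) or per stiffness (at fixed rule).
#'
#' @param sweep a `sweep_result`.
#' @param by `"rule"` (resting-length table, at `at = 10000` N/m) or
#'   `"stiffness"` (stiffness table, at `at = "LR2"`).
#' @param at the fixed level of the other factor.
#' @param metric `"activation_reduction"` or `"force_reduction"`.
#' @return A data frame, devices as rows and sweep levels as columns.
#' @export
sweep_table <- function(sweep, by = c("rule", "stiffness"), at = NULL,
                        metric = "activation_reduction") {
  by <- match.arg(by)
  cells <- sweep$cells
  if (by == "rule") {
    at <- at %||% max(sweep$stiffnesses)
    cells <- cells[cells$stiffness == at, ]
    levels <- sweep$rules
    key <- "rule"
  } else {
    at <- at %||% "LR2"
    cells <- cells[cells$rule == at, ]
    levels <- sweep$stiffnesses
    key <- "stiffness"
  }
  out <- list()
  for (mu in unique(cells$muscle)) {
    for (dev in unique(cells$device)) {
      row <- list(muscle = mu, device = dev)
      for (lv in levels) {
        v <- cells[cells$muscle == mu & cells$device == dev &
                     cells[[key]] == lv, metric]
        row[[paste0(key, "_", lv)]] <- v
      }
      out[[length(out) + 1L]] <- as.data.frame(row)
    }
  }
  do.call(rbind, out)
}

#' Reserve-actuator audit of a run
#'
#' Peak absolute reserve torque at a coordinate as a percentage of the peak
#' absolute net joint moment at that coordinate — the standard check that
#' the modelled muscles, not the reserves, produce the motion.
#'
#' @param run a `run_result`.
#' @param coord coordinate name (default the back flexion-extension
#'   coordinate, the worst case reported for harvesting).
#' @return Percentage (>= 0).
#' @export
reserve_audit <- function(run, coord = "back_flexion") {
  peak_res <- max(abs(run$reserve_torques[, coord]))
  peak_tau <- max(abs(run$gen_forces$tau[, coord]))
  if (peak_tau == 0) stop("net joint moment is identically zero at ", coord)
  100 * peak_res / peak_tau
}
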