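## Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, expr, envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

test_model <- function() memo("model", build_default_model())

## Single hanging pendulum: one massive rod on the fixed base.
pendulum_config <- function(mass = 2, l_com = 0.5) {
  list(
    subject_mass = 10, gravity = c(0, 0, -9.81),
    segments = list(
      list(name = "pelvis", parent = NA, mass = 1, com = c(0, 0, 0),
           joint_offset = c(0, 0, 0), inertia_diag = c(0.01, 0.01, 0.01)),
      list(name = "rod", parent = "pelvis", mass = mass,
           com = c(0, 0, -l_com), joint_offset = c(0, 0, 0),
           inertia_diag = c(0.02, 0.02, 0.001))),
    coordinates = list(
      list(name = "swing", segment = "rod", axis = c(0, 1, 0),
           range = c(-pi, pi))),
    fascicles = list(
      list(name = "fm", group = "flexors", F0 = 100,
           optimal_fiber_length = 0.1, tendon_slack_length = 0.1,
           path = list(const = 0.2, swing = c(0.05, 0)))),
    reserves = list(optimal_force = 30),
    sensors = c(s1 = "rod"))
}

pendulum_model <- function(...) memo("pendulum", build_model(pendulum_config(...)))

## Planar two-link chain used for energy-conservation rollouts.
two_link_model <- function() memo("two_link", build_model(list(
  subject_mass = 5, gravity = c(0, 0, -9.81),
  segments = list(
    list(name = "pelvis", parent = NA, mass = 1, com = c(0, 0, 0),
         joint_offset = c(0, 0, 0), inertia_diag = c(0.01, 0.01, 0.01)),
    list(name = "link1", parent = "pelvis", mass = 1.5, com = c(0, 0, -0.3),
         joint_offset = c(0, 0, 0), inertia_diag = c(0.02, 0.02, 0.002)),
    list(name = "link2", parent = "link1", mass = 0.8, com = c(0, 0, -0.2),
         joint_offset = c(0, 0, -0.6), inertia_diag = c(0.01, 0.01, 0.001))),
  coordinates = list(
    list(name = "q1", segment = "link1", axis = c(0, 1, 0), range = c(-pi, pi)),
    list(name = "q2", segment = "link2", axis = c(0, 1, 0), range = c(-pi, pi))),
  fascicles = list(
    list(name = "fm", group = "g", F0 = 100, optimal_fiber_length = 0.1,
         tendon_slack_length = 0.1, path = list(const = 0.2, q1 = c(0.05, 0)))),
  reserves = list(optimal_force = 30),
  sensors = c(s1 = "link2"))))

random_q <- function(model, margin = 0.3) {
  vapply(model$coordinates, function(cc) {
    lo <- cc$range[1L]; hi <- cc$range[2L]
    stats::runif(1, lo + margin * (hi - lo), hi - margin * (hi - lo))
  }, 0)
}

## Reference central-difference operator (interior rows only).
central_diff_ref <- function(M, time) {
  n <- nrow(M)
  D <- M * 0
  i <- 2:(n - 1L)
  D[i, ] <- (M[i + 1L, , drop = FALSE] - M[i - 1L, , drop = FALSE]) /
    (time[i + 1L] - time[i - 1L])
  D
}

## Expensive end-to-end fixtures shared by the acceptance tests.
acceptance_scenario <- function() memo("scenario42",
  harvest_scenario(seed = 42, n_pulls = 5, sigma_deg = 0.5))

acceptance_sweep <- function() memo("sweep42", run_sweep(acceptance_scenario()))
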