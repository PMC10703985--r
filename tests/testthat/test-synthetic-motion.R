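test_that("minimum-jerk pulls interpolate with analytic derivatives", {
  m <- test_model()
  p <- pull_profile()
  traj <- generate_pull(p, rate = 100, model = m)
  ## midpoint displacement fraction is exactly 1/2
  i_mid <- which.min(abs(traj$time - p$duration / 2))
  bf <- traj$q[, "back_flexion"]
  expect_equal((bf[i_mid] - bf[1L]) / (bf[length(bf)] - bf[1L]), 0.5,
               tolerance = 1e-9)
  ## boundary conditions: zero velocity at both ends
  expect_equal(traj$qdot[1L, ], traj$qdot[1L, ] * 0, tolerance = 1e-12)
  expect_equal(traj$qdot[nrow(traj$q), ], traj$qdot[1L, ] * 0,
               tolerance = 1e-12)
  ## analytic derivatives agree with finite differences in the interior
  n <- nrow(traj$q)
  fd <- central_diff_ref(traj$q, traj$time)
  expect_lt(max(abs(fd[3:(n - 2), ] - traj$qdot[3:(n - 2), ])), 1e-3)
  ## elevation cap respected
  expect_lte(max(traj$q[, "shoulder_flexion_r"]) * 180 / pi, 64 + 1e-9)
  ## constant profile collapses to a constant trajectory
  pc <- pull_profile(start_deg = c(back_flexion = 10),
                     end_deg = c(back_flexion = 10))
  tc <- generate_pull(pc, rate = 100, model = m)
  expect_equal(max(abs(sweep(tc$q, 2L, tc$q[1L, ]))), 0)
  expect_equal(max(abs(tc$qdot)), 0)
})

test_that("profiles exceeding the elevation cap or coordinate ranges error", {
  expect_error(pull_profile(end_deg = c(shoulder_flexion_r = 80)), "cap")
  m <- test_model()
  p <- pull_profile(start_deg = c(back_flexion = -60),
                    end_deg = c(back_flexion = 0))
  expect_error(generate_pull(p, model = m), "outside the coordinate range")
})

test_that("forward orientations compose the kinematic chain correctly", {
  m <- test_model()
  n <- 3L
  q <- matrix(0, n, 11L, dimnames = list(NULL, m$coordinate_names))
  traj <- joint_trajectory(seq_len(n) / 100, q)
  ses <- forward_orientations(m, traj)
  ## all-zero configuration: every sensor at calibration identity
  for (s in names(ses$quats)) {
    expect_equal(ses$quats[[s]][1L, ], c(1, 0, 0, 0), tolerance = 1e-12)
  }
  ## pure back flexion: sternum and upper arms rotate together, lumbar fixed
  q2 <- q; q2[, "back_flexion"] <- 0.4
  ses2 <- forward_orientations(m, joint_trajectory(seq_len(n) / 100, q2))
  ang <- function(qq) 2 * atan2(sqrt(sum(qq[2:4]^2)), abs(qq[1L]))
  expect_equal(ang(ses2$quats$sternum[1L, ]), 0.4, tolerance = 1e-10)
  expect_equal(ang(ses2$quats$upper_arm_r[1L, ]), 0.4, tolerance = 1e-10)
  expect_equal(ang(ses2$quats$upper_arm_l[1L, ]), 0.4, tolerance = 1e-10)
  expect_equal(ang(ses2$quats$lumbar[1L, ]), 0, tolerance = 1e-12)
})

test_that("orientation noise is seeded, unit-norm and half-normal in angle", {
  m <- test_model()
  p <- pull_profile()
  ses <- forward_orientations(m, generate_pull(p, rate = 100, model = m))
  ## sigma 0 returns the identical session
  expect_identical(add_orientation_noise(ses, 0, seed = 3), ses)
  n1 <- add_orientation_noise(ses, 1, seed = 11)
  n2 <- add_orientation_noise(ses, 1, seed = 11)
  n3 <- add_orientation_noise(ses, 1, seed = 12)
  expect_identical(n1$quats, n2$quats)
  expect_false(identical(n1$quats, n3$quats))
  norms <- sqrt(rowSums(n1$quats$sternum^2))
  expect_lt(max(abs(norms - 1)), 1e-9)
  ## mean perturbation angle ~ sigma * sqrt(2/pi) over many samples
  sigma <- 1 * pi / 180
  angles <- unlist(lapply(names(ses$quats), function(s) {
    A <- ses$quats[[s]]; B <- n1$quats[[s]]
    vapply(seq_len(nrow(A)), function(i)
      orientation_error(A[i, ], B[i, ]), 0)
  }))
  expect_gt(length(angles), 500)
  expect_equal(mean(angles), sigma * sqrt(2 / pi), tolerance = 0.05)
})

test_that("multi-pull sessions are reproducible with jittered durations", {
  m <- test_model()
  s1 <- generate_session(m, pull_profile(), n_pulls = 3, duration_jitter = 0.2,
                         sigma_deg = 0.3, seed = 5, rate = 50)
  s2 <- generate_session(m, pull_profile(), n_pulls = 3, duration_jitter = 0.2,
                         sigma_deg = 0.3, seed = 5, rate = 50)
  expect_identical(s1$quats, s2$quats)
  expect_equal(nrow(s1$pull_spans), 3L)
  durs <- s1$pull_spans[, "end"] - s1$pull_spans[, "start"]
  expect_gt(length(unique(round(durs, 6))), 1L)  # distinct jittered durations
  expect_error(generate_session(m, pull_profile(), duration_jitter = 1), "jitter")
  expect_error(generate_session(m, pull_profile(), n_pulls = 0), "n_pulls")
  ## ground-truth quaternions all unit-norm
  for (s in names(s1$quats)) {
    expect_lt(max(abs(sqrt(rowSums(s1$quats[[s]]^2)) - 1)), 1e-9)
  }
})
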