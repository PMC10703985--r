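test_that("default model covers the reported segments, coordinates and devices", {
  m <- test_model()
  expect_s3_class(m, "msk_model")
  expect_gte(length(m$segments), 8L)
  expect_setequal(
    c("pelvis", "torso", "head", "upperarm_r", "upperarm_l",
      "forearm_r", "forearm_l", "hand_r", "hand_l"),
    names(m$segments))
  ## back FE/LB/rotation, shoulder FE/AA/rotation x2, elbow FE x2
  expect_length(m$coordinates, 11L)
  expect_true(all(c("back_flexion", "back_bending", "back_rotation",
                    "shoulder_flexion_r", "shoulder_adduction_r",
                    "shoulder_rotation_r", "elbow_flexion_r",
                    "elbow_flexion_l") %in% m$coordinate_names))
  ## the seven published host fascicles are present
  hosts <- c("rectus_abdominis", "longissimus_L1", "longissimus_R11",
             "longissimus_T9", "iliocostalis_R10", "iliocostalis_R11",
             "iliocostalis_R12")
  expect_true(all(hosts %in% names(m$fascicles)))
  expect_gte(length(m$fascicles), 14L)
  groups <- unique(vapply(m$fascicles, `[[`, "", "group"))
  expect_true(all(c("longissimus", "iliocostalis", "latissimus_dorsi",
                    "quadratus_lumborum", "external_obliques",
                    "internal_obliques", "psoas_major", "rectus_abdominis",
                    "multifidus", "triceps", "biceps") %in% groups))
  ## pinned rectus abdominis fiber/tendon lengths
  ra <- m$fascicles$rectus_abdominis
  expect_equal(ra$optimal_fiber_length, 0.30)
  expect_equal(ra$tendon_slack_length, 0.08)
  expect_equal(m$subject_mass, 56.83)
})

test_that("configuration overrides and errors behave as specified", {
  m <- build_default_model(subject_mass = 56.83)
  expect_equal(m$subject_mass, 56.83)
  ## segment masses scale with subject mass
  m2 <- build_default_model(subject_mass = 2 * 56.83)
  expect_equal(m2$segments$torso$mass, 2 * m$segments$torso$mass)
  expect_error(build_default_model(bogus_key = 1), "bogus_key")
  cfg <- default_model_config()
  cfg$segments[[3L]]$parent <- "no_such_segment"
  expect_error(build_model(cfg), "unknown parent")
  cfg2 <- default_model_config()
  cfg2$coordinates[[1L]]$axis <- c(1, 1, 0)
  expect_error(build_model(cfg2), "unit norm")
})

test_that("muscle_length evaluates path polynomials and guards its domain", {
  m <- pendulum_model()
  q0 <- c(swing = 0)
  expect_equal(muscle_length(m, "fm", q0), 0.2)
  expect_equal(muscle_length(m, "fm", c(swing = 1)), 0.25)
  expect_error(muscle_length(m, "nope", q0), "unknown fascicle")
  expect_error(muscle_length(m, "fm", c(swing = 10)), "outside its range")
})

test_that("moment arm is the negative path derivative (finite-difference oracle)", {
  m <- test_model()
  set.seed(7)
  h <- 1e-5
  for (rep in 1:100) {
    q <- random_q(m)
    fn <- sample(names(m$fascicles), 1L)
    spanned <- setdiff(names(m$fascicles[[fn]]$path), "const")
    cc <- sample(spanned, 1L)
    qp <- q; qp[cc] <- q[cc] + h
    qm <- q; qm[cc] <- q[cc] - h
    fd <- -(muscle_length(m, fn, qp, enforce_range = FALSE) -
              muscle_length(m, fn, qm, enforce_range = FALSE)) / (2 * h)
    expect_equal(moment_arm(m, fn, q, cc), fd, tolerance = 1e-8)
  }
  ## linear path: constant arm; unspanned coordinate: zero
  pm <- pendulum_model()
  expect_equal(moment_arm(pm, "fm", c(swing = 0.3), "swing"), -0.05)
  expect_equal(moment_arm(m, "rectus_abdominis", random_q(m), "elbow_flexion_r"), 0)
})

test_that("hill force scale matches its stated curve shapes", {
  f <- test_model()$fascicles$rectus_abdominis  # Lo = 0.30, Ls = 0.08
  expect_equal(hill_force_scale(f, 0.08 + 0.30, 0), 1.0)
  expect_equal(hill_force_scale(f, 0.38, -10 * 0.30), 0)
  ## fl at normalized length 0.4
  expect_equal(hill_force_scale(f, 0.08 + 0.4 * 0.30, 0),
               exp(-0.36 / 0.45), tolerance = 1e-12)
  ## bounded, unity at optimum, non-increasing away from optimum
  lt <- seq(0.2, 1.8, by = 0.05)
  vals <- vapply(lt, function(x) hill_force_scale(f, 0.08 + x * 0.30, 0), 0)
  expect_true(all(vals >= 0 & vals <= 1.8))
  expect_true(all(diff(vals[lt <= 1]) >= 0))
  expect_true(all(diff(vals[lt >= 1]) <= 0))
  ## eccentric plateau below 1.8
  expect_lte(hill_force_scale(f, 0.38, 100), 1.8)
})

test_that("resting-length rules reproduce the published device lengths", {
  m <- test_model()
  ra <- m$fascicles$rectus_abdominis
  expect_equal(resting_length(ra, "LR1"), 0.20)
  expect_equal(resting_length(ra, "LR2"), 0.30)
  ## published resting lengths back-solved for all seven devices
  published <- list(
    rectus_abdominis = c(0.20, 0.30), iliocostalis_R10 = c(0.16, 0.16),
    iliocostalis_R11 = c(0.12, 0.14), iliocostalis_R12 = c(0.09, 0.10),
    longissimus_L1 = c(0.14, 0.09), longissimus_R11 = c(0.21, 0.12),
    longissimus_T9 = c(0.28, 0.14))
  for (nm in names(published)) {
    f <- m$fascicles[[nm]]
    expect_equal(resting_length(f, "LR1"), published[[nm]][1L], tolerance = 1e-12)
    expect_equal(resting_length(f, "LR2"), published[[nm]][2L], tolerance = 1e-12)
  }
  ## rules coincide exactly when Ls = 0.6 Lo
  f <- list(optimal_fiber_length = 0.25, tendon_slack_length = 0.15)
  expect_identical(resting_length(f, "LR1"), resting_length(f, "LR2"))
  expect_error(resting_length(ra, "explicit"), "requires")
})

test_that("exotendon tension follows the spring law with a zero floor", {
  exo <- list(stiffness = 10000, resting_length = 0.3, dissipation = 0.01)
  expect_equal(exotendon_tension(exo, 0.25), 0)
  expect_equal(exotendon_tension(exo, 0.3), 0)
  expect_equal(exotendon_tension(exo, 0.31, 0), 100)
  expect_equal(exotendon_tension(exo, 0.31, 1), 101)
  expect_equal(exotendon_tension(exo, 0.31, -200), 0)  # clamped, cannot push
  ## monotone in stiffness and stretch at fixed non-negative rate
  Ks <- seq(0, 2e4, by = 5e3)
  tK <- vapply(Ks, function(K)
    exotendon_tension(list(stiffness = K, resting_length = 0.3,
                           dissipation = 0.01), 0.32, 0.5), 0)
  expect_true(all(diff(tK) >= 0))
  Ls <- seq(0.3, 0.4, by = 0.02)
  tL <- vapply(Ls, function(L) exotendon_tension(exo, L, 0.5), 0)
  expect_true(all(diff(tL) >= 0))
})

test_that("attach_exotendon shares the host path and rejects misuse", {
  m <- test_model()
  m2 <- attach_exotendon(m, "longissimus_T9", 10000, "LR2")
  expect_equal(m2$exotendons[[1L]]$resting_length, 0.14)
  expect_error(attach_exotendon(m, "not_a_muscle", 1e4), "unknown fascicle")
  expect_error(attach_exotendon(m2, "longissimus_L1", 1e4),
               "one assistive device")
  ## zero stiffness device leaves the frame solution unchanged
  q <- stats::setNames(numeric(11), m$coordinate_names)
  q["back_flexion"] <- 0.5
  tau <- stats::setNames(numeric(11), m$coordinate_names)
  tau["back_flexion"] <- -80
  base <- so_solve_frame(m, tau, q)
  m0 <- attach_exotendon(m, "longissimus_T9", 0, "LR2")
  zero <- so_solve_frame(m0, tau, q)
  expect_equal(zero$activations, base$activations, tolerance = 1e-9)
  expect_equal(zero$exotendon_tension, 0)
})
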