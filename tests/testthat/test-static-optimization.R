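## Small hand-built instances: kappa is the coords x muscles matrix of
## moment per unit activation (F0 * f * r).

test_that("analytic toy instances solve exactly", {
  ## one muscle, one coordinate, no reserve: unique feasible scaling
  kappa <- matrix(50, 1, 1, dimnames = list("c1", "m1"))  # 1000 N * 0.05 m
  sol <- exotendon:::so_qp(kappa, c(c1 = 25))
  expect_equal(unname(sol$activations), 0.5, tolerance = 1e-9)
  expect_lt(sol$equality_residual, 1e-6)
  ## two identical muscles share the load equally
  kappa2 <- matrix(c(50, 50), 1, 2, dimnames = list("c1", c("m1", "m2")))
  sol2 <- exotendon:::so_qp(kappa2, c(c1 = 25))
  expect_equal(unname(sol2$activations), c(0.25, 0.25), tolerance = 1e-9)
  ## a fixed exotendon moment of 12.5 N m halves the single-muscle activation
  sol3 <- exotendon:::so_qp(kappa, c(c1 = 25 - 12.5))
  expect_equal(unname(sol3$activations), 0.25, tolerance = 1e-9)
  oracle3 <- so_brute_force(kappa, c(c1 = 12.5))
  expect_equal(sol3$objective, oracle3$objective, tolerance = 1e-3)
})

test_that("QP agrees with the brute-force oracle on random small instances", {
  set.seed(20)
  worst <- 0
  for (i in 1:50) {
    nm <- sample(1:3, 1L)
    nc <- sample(1:2, 1L)
    kappa <- matrix(stats::runif(nc * nm, -60, 60), nc, nm,
                    dimnames = list(paste0("c", 1:nc), paste0("m", 1:nm)))
    has_reserve <- stats::runif(1) < 0.7
    fopt <- if (has_reserve)
      stats::setNames(rep(30, nc), paste0("c", 1:nc)) else NULL
    tau <- stats::setNames(stats::runif(nc, -20, 20), paste0("c", 1:nc))
    if (is.null(fopt)) {
      ## keep the equality-constrained instance feasible inside the box
      a_ref <- stats::runif(nm, 0.1, 0.9)
      tau <- stats::setNames(as.numeric(kappa %*% a_ref), paste0("c", 1:nc))
    }
    qp <- exotendon:::so_qp(kappa, tau, fopt)
    bf <- so_brute_force(kappa, tau, fopt)
    worst <- max(worst, abs(qp$objective - bf$objective))
    expect_lte(qp$objective, bf$objective + 1e-3)
  }
  expect_lt(worst, 1e-3)
})

test_that("reserves rescue infeasible instances and match the oracle", {
  kappa <- matrix(10, 1, 1, dimnames = list("c1", "m1"))
  ## tau = 50 needs a > 5: infeasible without a reserve
  expect_error(exotendon:::so_qp(kappa, c(c1 = 50)), "infeasible")
  fopt <- c(c1 = 30)
  qp <- exotendon:::so_qp(kappa, c(c1 = 50), fopt)
  bf <- so_brute_force(kappa, c(c1 = 50), fopt)
  expect_equal(qp$objective, bf$objective, tolerance = 1e-3)
  expect_equal(unname(qp$reserves),
               50 - 10 * unname(qp$activations), tolerance = 1e-2)
})

test_that("frame solutions balance moments and respect bounds", {
  m <- test_model()
  set.seed(22)
  for (i in 1:20) {
    q <- random_q(m)
    tau <- stats::setNames(stats::rnorm(11, sd = 40), m$coordinate_names)
    fs <- so_solve_frame(m, tau, q, qdot = stats::rnorm(11, sd = 0.5))
    expect_true(all(fs$activations >= 0 & fs$activations <= 1))
    expect_lt(fs$balance_residual, 1e-6)
  }
  ## explicit balance check including reserves at one frame
  q <- random_q(m)
  tau <- stats::setNames(stats::rnorm(11, sd = 40), m$coordinate_names)
  fs <- so_solve_frame(m, tau, q)
  dat <- exotendon:::so_frame_data(
    m, exotendon:::check_q(m, q, FALSE),
    stats::setNames(numeric(11), m$coordinate_names))
  recon <- as.numeric(dat$kappa %*% fs$activations) + fs$reserve_torques +
    fs$exotendon_moments
  expect_equal(unname(recon), unname(tau[m$coordinate_names]),
               tolerance = 1e-6)
})

test_that("an agonist-side exotendon unloads and an antagonist-side one loads", {
  ## flexor + extensor pair on one coordinate with a reserve
  kappa <- matrix(c(60, -55), 1, 2, dimnames = list("c1", c("flex", "ext")))
  fopt <- c(c1 = 30)
  base <- exotendon:::so_qp(kappa, c(c1 = 30), fopt)
  ## extensor-side fixed moment (-12 N m) while flexion is demanded:
  ## flexor must work strictly harder
  loaded <- exotendon:::so_qp(kappa, c(c1 = 30 - (-12)), fopt)
  expect_gt(loaded$activations[1L], base$activations[1L])
  ## agonist-side assistance reduces the flexor activation
  helped <- exotendon:::so_qp(kappa, c(c1 = 30 - 12), fopt)
  expect_lt(helped$activations[1L], base$activations[1L])
})

test_that("activation reduction grows with stiffness until unloading", {
  ## single-coordinate toy mirroring the stiffness sweep
  m <- pendulum_model()
  q <- c(swing = 0.8)  # path 0.2 + 0.05*0.8 = 0.24, resting LR2 = 0.1
  tau <- c(swing = -2.0)  # extensor demand on the fm muscle (arm -0.05)
  acts <- vapply(c(0, 500, 1000, 2000, 4000), function(K) {
    mk <- attach_exotendon(m, "fm", K, "LR2")
    so_solve_frame(mk, tau, q)$activations[["fm"]]
  }, 0)
  expect_true(all(diff(acts) <= 1e-9))
  ## reserve torques shrink toward zero as muscles get stronger
  res <- vapply(c(1, 4, 16, 64), function(scale) {
    cfg <- pendulum_config()
    cfg$fascicles[[1L]]$F0 <- 100 * scale
    ms <- build_model(cfg)
    abs(so_solve_frame(ms, tau, q)$reserve_torques[["swing"]])
  }, 0)
  expect_true(all(diff(res) < 0))
})

test_that("runs are frame-wise consistent and K = 0 equals unassisted", {
  m <- test_model()
  traj <- generate_pull(pull_profile(), rate = 25, model = m)
  gf <- inverse_dynamics(m, traj, loads = hand_load_default())
  run0 <- so_solve_run(m, traj, gf)
  expect_equal(nrow(run0$activations), nrow(traj$q))
  expect_lt(max(run0$balance_residual), 1e-6)
  runK0 <- so_solve_run(attach_exotendon(m, "longissimus_T9", 0, "LR2"),
                        traj, gf)
  expect_equal(runK0$activations, run0$activations, tolerance = 1e-9)
  expect_true(all(runK0$exotendon_tension == 0))
  ## constant trajectory gives identical frame solutions
  nq <- matrix(0.3, 20, 11, dimnames = list(NULL, m$coordinate_names))
  nq[, setdiff(m$coordinate_names, "back_flexion")] <- 0
  ctraj <- joint_trajectory(seq_len(20) / 10, nq,
                            qdot = nq * 0, qddot = nq * 0)
  cgf <- inverse_dynamics(m, ctraj)
  crun <- so_solve_run(m, ctraj, cgf)
  expect_equal(crun$activations[1L, ], crun$activations[20L, ],
               tolerance = 1e-9)
})
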