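test_that("fascicle aggregation sums within groups and conserves totals", {
  series <- cbind(l1 = c(0.2, 0.1), l2 = c(0.15, 0.2), l3 = c(0.1, 0.0),
                  solo = c(0.5, 0.4))
  grouping <- c(l1 = "longissimus", l2 = "longissimus", l3 = "longissimus",
                solo = "biceps")
  agg <- aggregate_fascicles(series, grouping)
  expect_equal(unname(agg[1L, "longissimus"]), 0.45)
  expect_equal(agg[, "biceps"], series[, "solo"])  # single-fascicle identity
  expect_equal(rowSums(agg), rowSums(series))      # partition conservation
  expect_error(aggregate_fascicles(series, grouping[-1L]), "not mapped")
})

test_that("reduction percentages follow the published sign convention", {
  ## latissimus dorsi worked example from the reported peak activations
  expect_equal(reduction_percent(53.02, 28.72), 45.83, tolerance = 0.005)
  expect_equal(reduction_percent(7, 7), 0)
  expect_equal(reduction_percent(10, 20), -100)
  expect_error(reduction_percent(0, 1), "positive")
  ## identity: reducing x by p percent reports exactly p
  for (p in c(-50, 0, 12.5, 99)) {
    expect_equal(reduction_percent(8, 8 * (1 - p / 100)), p)
  }
})

test_that("peak metrics normalize to mass and subject maxima", {
  m <- test_model()
  nt <- 5L
  run <- structure(list(
    time = seq_len(nt) / 10,
    activations = matrix(0.4, nt, length(m$fascicles),
                         dimnames = list(NULL, names(m$fascicles))),
    muscle_forces = matrix(10, nt, length(m$fascicles),
                           dimnames = list(NULL, names(m$fascicles))),
    reserve_torques = matrix(1, nt, 11,
                             dimnames = list(NULL, m$coordinate_names)),
    gen_forces = structure(list(
      time = seq_len(nt) / 10,
      tau = matrix(c(rep(0, nt * 10), c(-10, -221.6, -50, 0, 10)), nt, 11,
                   dimnames = list(NULL, rev(m$coordinate_names)))),
      class = "generalized_forces"),
    model = m), class = "run_result")
  pm <- peak_metrics(run, subject_mass = 56.83)
  expect_equal(pm$moment_peak[["back_flexion"]], 221.6)
  expect_equal(pm$moment_peak_norm[["back_flexion"]], 221.6 / 56.83,
               tolerance = 1e-12)  # 3.90 N m/kg
  ## constant activation 0.4 against a subject max of 0.8 -> 50%
  smax <- list(
    activation = stats::setNames(rep(0.8, length(pm$activation_peak)),
                                 names(pm$activation_peak)),
    force = stats::setNames(rep(100, length(pm$force_peak)),
                            names(pm$force_peak)))
  ## single-fascicle groups peak at 0.4; multi-fascicle groups sum higher
  pm2 <- peak_metrics(run, subject_mass = 56.83, subject_max = smax)
  expect_equal(pm2$activation_peak_pct[["biceps"]],
               100 * (0.4 * 2) / 0.8)
  smax$activation[1L] <- 0
  expect_error(peak_metrics(run, subject_max = smax), "non-zero")
})

test_that("one-way ANOVA matches stats::aov and its invariances", {
  set.seed(30)
  groups <- list(a = rnorm(6, 0), b = rnorm(6, 1), c = rnorm(6, 3))
  an <- one_way_anova(groups)
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(names(groups), each = 6)))
  ref <- summary(stats::aov(y ~ g, data = df))[[1L]]
  expect_equal(an$F, ref[["F value"]][1L], tolerance = 1e-10)
  expect_equal(an$p, ref[["Pr(>F)"]][1L], tolerance = 1e-10)
  ## hand-computed three-group decomposition
  g3 <- list(c(1, 2, 3), c(2, 3, 4), c(6, 7, 8))
  an3 <- one_way_anova(g3)
  ms_b <- (3 * (2 - 4)^2 + 3 * (3 - 4)^2 + 3 * (7 - 4)^2) / 2
  ms_w <- (2 + 2 + 2) / 6
  expect_equal(an3$F, ms_b / ms_w, tolerance = 1e-12)
  ## identical groups: F = 0, p = 1
  eq <- one_way_anova(list(c(1, 1), c(1, 1)))
  expect_equal(eq$F, 0); expect_equal(eq$p, 1)
  ## invariance to shifts; F = t^2 for two groups
  sh <- lapply(groups, `+`, 100)
  expect_equal(one_way_anova(sh)$F, an$F, tolerance = 1e-9)
  sc <- lapply(groups, `*`, 3.7)
  expect_equal(one_way_anova(sc)$F, an$F, tolerance = 1e-9)
  two <- groups[1:2]
  tt <- stats::t.test(two[[1L]], two[[2L]], var.equal = TRUE)
  expect_equal(one_way_anova(two)$F, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("Tukey-Kramer reduces to the t test for two balanced groups", {
  set.seed(31)
  g <- list(a = rnorm(8, 0), b = rnorm(8, 1.2))
  tk <- tukey_kramer(g, alpha = 0.05)
  tt <- stats::t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(tk$q[1L], sqrt(2) * abs(unname(tt$statistic)), tolerance = 1e-10)
  expect_equal(tk$significant[1L], tt$p.value < 0.05)
  expect_equal(tk$p[1L], tt$p.value, tolerance = 1e-6)
  ## identical groups: nothing significant; well-separated groups: flagged
  expect_false(any(tukey_kramer(list(c(1, 2), c(1, 2), c(1, 2)))$significant))
  far <- list(a = rnorm(6, 0), b = rnorm(6, 100))
  expect_true(all(tukey_kramer(far)$significant))
})

test_that("Tukey-Kramer agrees with TukeyHSD and is conservative", {
  set.seed(32)
  ## agreement with the reference implementation on unbalanced data
  groups <- list(a = rnorm(5, 0), b = rnorm(7, 0.8), c = rnorm(6, 2))
  tk <- tukey_kramer(groups)
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(names(groups), times = c(5, 7, 6))))
  ref <- stats::TukeyHSD(stats::aov(y ~ g, data = df))$g
  expect_equal(sort(tk$p), sort(unname(ref[, "p adj"])), tolerance = 1e-6)
  ## flags are a subset of unadjusted pairwise-t flags on balanced nulls
  violations <- 0L
  for (i in 1:100) {
    g <- list(rnorm(5), rnorm(5), rnorm(5), rnorm(5))
    tk <- tukey_kramer(g, alpha = 0.1)
    tflags <- apply(utils::combn(4, 2), 2L, function(pr) {
      stats::t.test(g[[pr[1L]]], g[[pr[2L]]], var.equal = TRUE)$p.value < 0.1
    })
    violations <- violations + sum(tk$significant & !tflags)
  }
  expect_equal(violations, 0L)
})

test_that("reports compare a run against itself as all-zero reductions", {
  m <- test_model()
  traj <- generate_pull(pull_profile(), rate = 25, model = m)
  gf <- inverse_dynamics(m, traj, loads = hand_load_default())
  run <- so_solve_run(m, traj, gf)
  rep1 <- build_report(run, list(self = run))
  expect_true(all(abs(rep1$reductions$activation_reduction) < 1e-9))
  expect_true(all(abs(rep1$reductions$force_reduction) < 1e-9))
  ## serialization round trip leaves the report identical
  tmp <- file.path(tempdir(), "run_rt")
  write_run_result(run, tmp)
  run2 <- read_run_result(tmp, m)
  expect_identical(run$activations, run2$activations)
  expect_identical(run$muscle_forces, run2$muscle_forces)
  rep2 <- build_report(run2, list(self = run2))
  expect_identical(rep1$reductions, rep2$reductions)
})

test_that("sweep selection prefers the dominating cell with LR2/high-K ties", {
  cells <- expand.grid(rule = c("LR1", "LR2"), stiffness = c(1000, 10000),
                       muscle = c("longissimus", "iliocostalis"),
                       stringsAsFactors = FALSE)
  cells$device <- "d1"
  cells$activation_reduction <- ifelse(cells$rule == "LR2" &
                                         cells$stiffness == 10000, 40, 10)
  cells$force_reduction <- cells$activation_reduction
  sw <- structure(list(cells = cells), class = "sweep_result")
  sel <- sweep_select(sw)
  expect_equal(sel$rule, "LR2")
  expect_equal(sel$stiffness, 10000)
  ## exact ties resolve toward LR2 and the larger stiffness
  cells$activation_reduction <- 5
  cells$force_reduction <- 5
  sel2 <- sweep_select(structure(list(cells = cells), class = "sweep_result"))
  expect_equal(sel2$rule, "LR2")
  expect_equal(sel2$stiffness, 10000)
  ## incomplete grids are rejected
  expect_error(
    sweep_select(structure(list(cells = cells[cells$rule == "LR1" |
                                                cells$stiffness == 1000, ]),
                           class = "sweep_result")),
    "incomplete")
})
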