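#' Aggregate fascicle series into muscle-group series
#'
#' Individual fascicle activations (or forces) are aggregated by summation
#' to obtain the overall muscle activation per group at each frame.
#'
#' @param series frames x fascicles matrix.
#' @param grouping named character vector mapping every fascicle to exactly
#'   one group.
#' @return frames x groups matrix.
#' @export
aggregate_fascicles <- function(series, grouping) {
  fn <- colnames(series)
  missing <- setdiff(fn, names(grouping))
  if (length(missing)) {
    stop("fascicle '", missing[1L], "' is not mapped to a group")
  }
  groups <- unique(grouping[fn])
  out <- sapply(groups, function(g) {
    cols <- fn[grouping[fn] == g]
    rowSums(series[, cols, drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L,
                                       dimnames = list(NULL, groups))
  out
}

model_grouping <- function(model) {
  vapply(model$fascicles, `[[`, "", "group")
}

#' Peak outcome metrics of a run
#'
#' Peaks over frames of the absolute net joint moments (raw and normalized
#' to body mass, N m/kg), of per-fascicle and per-group (summed) muscle
#' activation (raw fraction and, when a subject maximum is supplied,
#' percent of that maximum) and of per-group muscle force (N and N/kg).
#'
#' @param run a `run_result`.
#' @param subject_mass body mass, kg.
#' @param subject_max optional list with elements `activation` and `force`:
#'   named per-group maxima used for percent normalization (the
#'   cross-condition maximum of the subject); zero maxima are an error.
#' @return A `peak_metrics` list.
#' @export
peak_metrics <- function(run, subject_mass = run$model$subject_mass,
                         subject_max = NULL) {
  if (!nrow(run$activations)) stop("run is empty")
  grouping <- model_grouping(run$model)
  peak_abs <- function(M) apply(abs(M), 2L, max)

  moment_peak <- peak_abs(run$gen_forces$tau)
  act_group <- aggregate_fascicles(run$activations, grouping)
  force_group <- aggregate_fascicles(run$muscle_forces, grouping)

  out <- list(
    moment_peak = moment_peak,
    moment_peak_norm = moment_peak / subject_mass,
    activation_peak_fascicle = peak_abs(run$activations),
    activation_peak = peak_abs(act_group),
    force_peak = peak_abs(force_group),
    force_peak_norm = peak_abs(force_group) / subject_mass,
    reserve_peak = peak_abs(run$reserve_torques)
  )
  if (!is.null(subject_max)) {
    amax <- subject_max$activation[names(out$activation_peak)]
    fmax <- subject_max$force[names(out$force_peak)]
    if (any(amax == 0, na.rm = TRUE) || any(fmax == 0, na.rm = TRUE)) {
      stop("subject maxima must be non-zero for percent normalization")
    }
    ## NA maxima (muscles silent in every condition) yield NA percentages
    out$activation_peak_pct <- 100 * out$activation_peak / amax
    out$force_peak_pct <- 100 * out$force_peak / fmax
  }
  structure(out, class = "peak_metrics")
}

#' Reduction percentage of an assisted relative to an unassisted peak
#'
#' `100 * (unassisted - assisted) / unassisted`; positive values indicate a
#' decrease under assistance and negative values an increase.
#'
#' @param unassisted_peak unassisted peak (> 0).
#' @param assisted_peak assisted peak.
#' @return Reduction in percent.
#' @export
reduction_percent <- function(unassisted_peak, assisted_peak) {
  if (any(unassisted_peak <= 0)) {
    stop("reduction_percent requires a positive unassisted peak")
  }
  100 * (unassisted_peak - assisted_peak) / unassisted_peak
}

#' One-way analysis of variance
#'
#' Classical between/within sum-of-squares decomposition; the p-value comes
#' from the F distribution. With zero within-group variance and equal means
#' the statistic is defined as 0 (p = 1).
#'
#' @param groups list of >= 2 numeric samples, each with >= 2 values.
#' @return List with `F`, `p`, degrees of freedom and mean squares.
#' @export
one_way_anova <- function(groups) {
  k <- length(groups)
  if (k < 2L || any(vapply(groups, length, 0L) < 2L)) {
    stop("one_way_anova needs >= 2 groups with >= 2 samples each")
  }
  n <- vapply(groups, length, 0L)
  N <- sum(n)
  means <- vapply(groups, mean, 0)
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1L
  df2 <- N - k
  ms_between <- ss_between / df1
  ms_within <- ss_within / df2
  if (ss_within == 0 && ss_between == 0) {
    return(list(F = 0, p = 1, df1 = df1, df2 = df2,
                ms_between = 0, ms_within = 0))
  }
  Fstat <- ms_between / ms_within
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, ms_between = ms_between, ms_within = ms_within)
}

#' Tukey-Kramer multiple comparisons
#'
#' Pairwise studentized-range statistics
#' `q_ij = |m_i - m_j| / sqrt((MSE / 2) (1/n_i + 1/n_j))` compared against
#' the studentized-range quantile at the family-wise level `alpha`.
#'
#' @param groups list of numeric samples (named or indexed).
#' @param alpha significance level (default 0.05).
#' @return Data frame with one row per pair: group labels, mean difference,
#'   `q`, adjusted p-value and the significance flag. Exact ties with zero
#'   residual variance are flagged (`tie = TRUE`, p undefined).
#' @export
tukey_kramer <- function(groups, alpha = 0.05) {
  k <- length(groups)
  an <- one_way_anova(groups)
  labels <- names(groups) %||% paste0("g", seq_len(k))
  n <- vapply(groups, length, 0L)
  means <- vapply(groups, mean, 0)
  mse <- an$ms_within
  df2 <- an$df2
  pairs <- utils::combn(k, 2L)
  out <- data.frame(
    group1 = labels[pairs[1L, ]], group2 = labels[pairs[2L, ]],
    diff = means[pairs[2L, ]] - means[pairs[1L, ]],
    q = NA_real_, p = NA_real_, significant = FALSE, tie = FALSE,
    row.names = NULL)
  for (idx in seq_len(ncol(pairs))) {
    i <- pairs[1L, idx]; j <- pairs[2L, idx]
    se <- sqrt((mse / 2) * (1 / n[i] + 1 / n[j]))
    if (se == 0) {
      out$tie[idx] <- TRUE
      out$significant[idx] <- means[i] != means[j]
      next
    }
    qij <- abs(means[i] - means[j]) / se
    out$q[idx] <- qij
    out$p[idx] <- stats::ptukey(qij, k, df2, lower.tail = FALSE)
    out$significant[idx] <- qij > stats::qtukey(1 - alpha, k, df2)
  }
  attr(out, "alpha") <- alpha
  attr(out, "critical_q") <- stats::qtukey(1 - alpha, k, df2)
  out
}

## Measured muscle groups and the device ordering of the published
## reduction tables.
table_muscles <- c("longissimus", "iliocostalis", "rectus_abdominis")
device_order <- c("rectus_abdominis", "iliocostalis_R10", "iliocostalis_R11",
                  "iliocostalis_R12", "longissimus_T9", "longissimus_L1",
                  "longissimus_R11")

#' Reduction table between an unassisted and a set of assisted runs
#'
#' For each assistive device and each measured muscle group, the percent
#' reduction in peak summed activation and peak summed force.
#'
#' @param unassisted a `run_result`.
#' @param assisted named list of `run_result`s (one per device).
#' @param muscles muscle groups to report (default: the longissimus,
#'   iliocostalis and rectus abdominis rows of the published tables).
#' @return Data frame with columns `device`, `muscle`,
#'   `activation_reduction`, `force_reduction` (percent).
#' @export
reduction_table <- function(unassisted, assisted, muscles = table_muscles) {
  pm0 <- peak_metrics(unassisted)
  rows <- list()
  for (dev in names(assisted)) {
    pm1 <- peak_metrics(assisted[[dev]])
    for (mu in muscles) {
      rows[[length(rows) + 1L]] <- data.frame(
        device = dev, muscle = mu,
        activation_reduction =
          reduction_percent(pm0$activation_peak[[mu]],
                            pm1$activation_peak[[mu]]),
        force_reduction =
          reduction_percent(pm0$force_peak[[mu]], pm1$force_peak[[mu]]))
    }
  }
  do.call(rbind, rows)
}

#' Select the best resting-length rule and stiffness from a sweep
#'
#' Over the complete `{LR1, LR2} x {K1, K2}` grid, selects the cell whose
#' mean reduction (activation and force pooled) across the target muscles
#' and devices is maximal. Ties are broken toward rule LR2 and the higher
#' stiffness (the conventions adopted in the published selection).
#'
#' Only muscles with a significant unassisted baseline take part in the
#' pooling (assisted-motion changes are evaluated for the muscles that
#' demonstrated significant activity during unassisted motion); muscles
#' whose unassisted peak activation is below `min_baseline_frac` of the
#' largest group peak are excluded from the cell means.
#'
#' @param sweep a `sweep_result` from [run_sweep()].
#' @param min_baseline_frac baseline-significance threshold (fraction of
#'   the largest unassisted group activation peak).
#' @return List with `rule`, `stiffness` and the per-cell mean reductions.
#' @export
sweep_select <- function(sweep, min_baseline_frac = 0.05) {
  cells <- sweep$cells
  if (!is.null(sweep$baseline)) {
    base <- sweep$baseline$activation
    keep <- names(base)[base >= min_baseline_frac * max(base)]
    kept <- cells$muscle %in% keep
    if (any(kept)) cells <- cells[kept, ]
  }
  rules <- unique(cells$rule)
  stiffs <- unique(cells$stiffness)
  grid <- expand.grid(rule = rules, stiffness = stiffs,
                      stringsAsFactors = FALSE)
  if (nrow(grid) != length(unique(paste(cells$rule, cells$stiffness)))) {
    stop("incomplete sweep grid")
  }
  means <- vapply(seq_len(nrow(grid)), function(i) {
    sub <- cells[cells$rule == grid$rule[i] &
                   cells$stiffness == grid$stiffness[i], ]
    if (!nrow(sub)) stop("incomplete sweep grid")
    mean(c(sub$activation_reduction, sub$force_reduction))
  }, 0)
  grid$mean_reduction <- means
  ## deterministic tie-break: prefer LR2, then larger K
  ord <- order(-grid$mean_reduction,
               grid$rule != "LR2",
               -grid$stiffness)
  best <- grid[ord[1L], ]
  list(rule = best$rule, stiffness = best$stiffness, table = grid)
}

#' Assemble the assisted-vs-unassisted comparison report
#'
#' Collects peak metrics (with per-subject cross-condition maxima used for
#' percent normalization), reduction tables in the published device
#' ordering, optional sweep tables, and — when replicate runs are supplied —
#' one-way ANOVA with Tukey-Kramer pairwise comparisons per metric family.
#'
#' @param unassisted a `run_result` or list of replicate `run_result`s.
#' @param assisted named list (by device) of `run_result`s or of replicate
#'   lists shaped like `unassisted`.
#' @param sweep optional `sweep_result`.
#' @param alpha significance level for the statistics.
#' @return A `comparison_report`.
#' @export
build_report <- function(unassisted, assisted, sweep = NULL, alpha = 0.05) {
  as_rep_list <- function(x) if (inherits(x, "run_result")) list(x) else x
  un <- as_rep_list(unassisted)
  as_l <- lapply(assisted, as_rep_list)
  n_rep <- length(un)
  if (any(vapply(as_l, length, 0L) != n_rep)) {
    stop("assisted and unassisted conditions have mismatched replicates")
  }
  model0 <- un[[1L]]$model
  cn0 <- colnames(un[[1L]]$activations)
  for (runs in c(as_l, list(un))) {
    for (r in runs) {
      if (!identical(colnames(r$activations), cn0)) {
        stop("runs come from inconsistent models/scenarios")
      }
    }
  }

  ## subject maxima: cross-condition maxima per replicate index
  grouping <- model_grouping(model0)
  all_conditions <- c(list(unassisted = un), as_l)
  subject_max <- lapply(seq_len(n_rep), function(i) {
    acts <- lapply(all_conditions, function(runs)
      apply(abs(aggregate_fascicles(runs[[i]]$activations, grouping)), 2L, max))
    fors <- lapply(all_conditions, function(runs)
      apply(abs(aggregate_fascicles(runs[[i]]$muscle_forces, grouping)), 2L, max))
    amax <- do.call(pmax, acts)
    fmax <- do.call(pmax, fors)
    amax[amax == 0] <- NA_real_  # groups silent across every condition
    fmax[fmax == 0] <- NA_real_
    list(activation = amax, force = fmax)
  })

  metrics <- lapply(names(all_conditions), function(cond) {
    lapply(seq_len(n_rep), function(i)
      peak_metrics(all_conditions[[cond]][[i]],
                   subject_max = subject_max[[i]]))
  })
  names(metrics) <- names(all_conditions)

  devs <- intersect(device_order, names(assisted))
  devs <- c(devs, setdiff(names(assisted), devs))
  ## reductions of replicate-averaged peaks, devices in the published order
  mean_peak <- function(cond, field, sub) {
    mean(vapply(metrics[[cond]], function(pm) pm[[field]][[sub]], 0))
  }
  rows <- list()
  for (dev in devs) {
    for (mu in table_muscles) {
      rows[[length(rows) + 1L]] <- data.frame(
        device = dev, muscle = mu,
        activation_reduction = reduction_percent(
          mean_peak("unassisted", "activation_peak", mu),
          mean_peak(dev, "activation_peak", mu)),
        force_reduction = reduction_percent(
          mean_peak("unassisted", "force_peak", mu),
          mean_peak(dev, "force_peak", mu)))
    }
  }
  reductions <- do.call(rbind, rows)

  stats_out <- NULL
  if (n_rep >= 2L) {
    metric_family <- function(field, sub) {
      sapply(names(all_conditions), function(cond) {
        vapply(metrics[[cond]], function(pm) pm[[field]][[sub]], 0)
      })
    }
    families <- list()
    for (co in colnames(un[[1L]]$gen_forces$tau)) {
      families[[paste0("moment_", co)]] <- metric_family("moment_peak_norm", co)
    }
    for (mu in table_muscles) {
      families[[paste0("activation_", mu)]] <- metric_family("activation_peak", mu)
      families[[paste0("force_", mu)]] <- metric_family("force_peak_norm", mu)
    }
    stats_out <- lapply(families, function(M) {
      gr <- lapply(seq_len(ncol(M)), function(j) M[, j])
      names(gr) <- colnames(M)
      an <- one_way_anova(gr)
      tk <- if (is.finite(an$p) && an$p < alpha) tukey_kramer(gr, alpha) else NULL
      list(F = an$F, p = an$p, tukey = tk)
    })
  }

  structure(list(
    metrics = metrics,
    reductions = reductions,
    sweep = sweep,
    statistics = stats_out,
    devices = devs,
    alpha = alpha
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 2, ...) {
  cat("Assisted-vs-unassisted comparison report\n")
  cat("Devices:", paste(x$devices, collapse = ", "), "\n\n")
  r <- x$reductions
  r$activation_reduction <- round(r$activation_reduction, digits)
  r$force_reduction <- round(r$force_reduction, digits)
  print(r, row.names = FALSE)
  if (!is.null(x$statistics)) {
    cat("\nOne-way ANOVA across conditions (alpha =", x$alpha, "):\n")
    for (nm in names(x$statistics)) {
      s <- x$statistics[[nm]]
      cat(sprintf("  %-28s F = %8.3f  p = %.4g%s\n", nm, s$F, s$p,
                  if (!is.null(s$tukey)) "  (Tukey-Kramer run)" else ""))
    }
  }
  invisible(x)
}
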