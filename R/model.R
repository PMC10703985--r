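#' Default configuration of the reduced harvesting model
#'
#' Returns the configuration list from which [build_default_model()] builds
#' the reduced upper-body harvester model: nine rigid segments (pelvis base,
#' torso, head, paired upper arms, forearms and hands), eleven generalized
#' coordinates (3-DOF lumbosacral joint, two 3-DOF shoulders, two 1-DOF
#' elbows), eighteen Hill-type muscle fascicles covering the ten muscle
#' groups reported for harvesting, reserve actuators (optimal force 30 N m)
#' on every coordinate, and the two-handed external harvesting load.
#'
#' Segment masses are anthropometric fractions of the subject mass
#' (default 56.83 kg, the mean harvester weight). Muscle paths are
#' polynomials (degree <= 2) of the spanned coordinates; moment arms are the
#' negative path-length derivatives (tendon-excursion convention). The seven
#' exotendon host fascicles (rectus abdominis, longissimus L1/R11/T9,
#' iliocostalis R10/R11/R12) carry optimal fiber lengths and tendon slack
#' lengths chosen so that the two published device resting-length rules
#' evaluate to the published resting lengths.
#'
#' @return A nested list with elements `subject_mass`, `gravity`, `segments`,
#'   `coordinates`, `fascicles`, `reserves`, `sensors`, `external_loads`.
#' @export
default_model_config <- function() {
  deg <- pi / 180
  seg <- function(name, parent, mass_frac, com, joint_offset, inertia_diag) {
    list(name = name, parent = parent, mass_frac = mass_frac, com = com,
         joint_offset = joint_offset, inertia_diag = inertia_diag)
  }
  coord <- function(name, segment, axis, range_deg) {
    list(name = name, segment = segment, axis = axis, range = range_deg * deg)
  }
  fasc <- function(name, group, F0, Lo, Ls, path) {
    list(name = name, group = group, F0 = F0,
         optimal_fiber_length = Lo, tendon_slack_length = Ls, path = path)
  }

  list(
    subject_mass = 56.83,
    gravity = c(0, 0, -9.81),
    segments = list(
      seg("pelvis",     NA,        0.142, c(0, 0, 0.05),   c(0, 0, 0),
          c(0.08, 0.08, 0.06)),
      seg("torso",      "pelvis",  0.355, c(0, 0, 0.22),   c(0, 0, 0.10),
          c(1.00, 0.90, 0.40)),
      seg("head",       "torso",   0.081, c(0, 0, 0.10),   c(0, 0, 0.45),
          c(0.030, 0.030, 0.020)),
      seg("upperarm_r", "torso",   0.028, c(0, 0, -0.13),  c(0, -0.20, 0.42),
          c(0.012, 0.012, 0.002)),
      seg("upperarm_l", "torso",   0.028, c(0, 0, -0.13),  c(0,  0.20, 0.42),
          c(0.012, 0.012, 0.002)),
      seg("forearm_r",  "upperarm_r", 0.016, c(0, 0, -0.11), c(0, 0, -0.28),
          c(0.006, 0.006, 0.001)),
      seg("forearm_l",  "upperarm_l", 0.016, c(0, 0, -0.11), c(0, 0, -0.28),
          c(0.006, 0.006, 0.001)),
      seg("hand_r",     "forearm_r", 0.006, c(0, 0, -0.08), c(0, 0, -0.25),
          c(0.001, 0.001, 0.0005)),
      seg("hand_l",     "forearm_l", 0.006, c(0, 0, -0.08), c(0, 0, -0.25),
          c(0.001, 0.001, 0.0005))
    ),
    ## Sign conventions: flexion, lateral bending to the right, adduction and
    ## rotation to the right are positive. World frame: X forward, Y left,
    ## Z up; all joint frames coincide with the world frame at q = 0.
    coordinates = list(
      coord("back_flexion",       "torso", c(0, 1, 0),  c(-25, 90)),
      coord("back_bending",       "torso", c(1, 0, 0),  c(-35, 35)),
      coord("back_rotation",      "torso", c(0, 0, -1), c(-45, 45)),
      coord("shoulder_flexion_r", "upperarm_r", c(0, -1, 0), c(-60, 150)),
      coord("shoulder_adduction_r", "upperarm_r", c(-1, 0, 0), c(-120, 60)),
      coord("shoulder_rotation_r", "upperarm_r", c(0, 0, -1), c(-90, 90)),
      coord("shoulder_flexion_l", "upperarm_l", c(0, -1, 0), c(-60, 150)),
      coord("shoulder_adduction_l", "upperarm_l", c(1, 0, 0), c(-120, 60)),
      coord("shoulder_rotation_l", "upperarm_l", c(0, 0, 1), c(-90, 90)),
      coord("elbow_flexion_r",    "forearm_r", c(0, -1, 0), c(-5, 150)),
      coord("elbow_flexion_l",    "forearm_l", c(0, -1, 0), c(-5, 150))
    ),
    ## Paths: list(const = L(0) [m], <coordinate> = c(c1, c2)) so that
    ## L(q) = const + sum_j (c1_j q_j + c2_j q_j^2). By construction
    ## const = tendon_slack_length + optimal_fiber_length (fiber at optimal
    ## length in the neutral upright pose).
    fascicles = list(
      fasc("longissimus_L1",  "longissimus",  1400, 0.09, 0.104,
           list(const = 0.194, back_flexion = c(0.050, -0.004))),
      fasc("longissimus_R11", "longissimus",  1400, 0.12, 0.162,
           list(const = 0.282, back_flexion = c(0.055, -0.004))),
      fasc("longissimus_T9",  "longissimus",  1400, 0.14, 0.224,
           list(const = 0.364, back_flexion = c(0.060, -0.004))),
      fasc("iliocostalis_R10", "iliocostalis", 1300, 0.16, 0.096,
           list(const = 0.256, back_flexion = c(0.052, -0.003))),
      fasc("iliocostalis_R11", "iliocostalis", 1300, 0.14, 0.064,
           list(const = 0.204, back_flexion = c(0.054, -0.003))),
      fasc("iliocostalis_R12", "iliocostalis", 1300, 0.10, 0.050,
           list(const = 0.150, back_flexion = c(0.056, -0.003))),
      fasc("multifidus", "multifidus", 900, 0.05, 0.030,
           list(const = 0.080, back_flexion = c(0.035, 0),
                back_rotation = c(0.015, 0))),
      fasc("quadratus_lumborum", "quadratus_lumborum", 700, 0.08, 0.050,
           list(const = 0.130, back_flexion = c(0.030, 0),
                back_bending = c(0.035, 0))),
      fasc("rectus_abdominis", "rectus_abdominis", 1100, 0.30, 0.080,
           list(const = 0.380, back_flexion = c(-0.080, 0.005))),
      fasc("external_oblique", "external_obliques", 900, 0.12, 0.040,
           list(const = 0.160, back_flexion = c(-0.045, 0),
                back_rotation = c(-0.040, 0))),
      fasc("internal_oblique", "internal_obliques", 900, 0.10, 0.040,
           list(const = 0.140, back_flexion = c(-0.040, 0),
                back_rotation = c(0.035, 0))),
      fasc("psoas_major", "psoas_major", 1000, 0.10, 0.090,
           list(const = 0.190, back_flexion = c(-0.050, 0),
                back_bending = c(-0.020, 0))),
      fasc("latissimus_dorsi_r", "latissimus_dorsi", 1200, 0.30, 0.120,
           list(const = 0.420, back_flexion = c(0.025, 0),
                shoulder_flexion_r = c(0.045, -0.003),
                shoulder_adduction_r = c(-0.025, 0))),
      fasc("latissimus_dorsi_l", "latissimus_dorsi", 1200, 0.30, 0.120,
           list(const = 0.420, back_flexion = c(0.025, 0),
                shoulder_flexion_l = c(0.045, -0.003),
                shoulder_adduction_l = c(-0.025, 0))),
      fasc("biceps_r", "biceps", 600, 0.12, 0.250,
           list(const = 0.370, elbow_flexion_r = c(-0.032, 0.002),
                shoulder_flexion_r = c(-0.010, 0))),
      fasc("biceps_l", "biceps", 600, 0.12, 0.250,
           list(const = 0.370, elbow_flexion_l = c(-0.032, 0.002),
                shoulder_flexion_l = c(-0.010, 0))),
      fasc("triceps_r", "triceps", 800, 0.13, 0.200,
           list(const = 0.330, elbow_flexion_r = c(0.025, -0.002),
                shoulder_flexion_r = c(0.008, 0))),
      fasc("triceps_l", "triceps", 800, 0.13, 0.200,
           list(const = 0.330, elbow_flexion_l = c(0.025, -0.002),
                shoulder_flexion_l = c(0.008, 0)))
    ),
    reserves = list(optimal_force = 30),  # one reserve per coordinate
    sensors = c(sternum = "torso", lumbar = "pelvis",
                upper_arm_r = "upperarm_r", upper_arm_l = "upperarm_l",
                wrist_r = "forearm_r", wrist_l = "forearm_l"),
    external_loads = NULL  # filled with hand_load_default() at build time
  )
}

#' Build the default reduced harvester model
#'
#' Assembles a validated `msk_model` object from a configuration list (see
#' [default_model_config()]). Named arguments in `...` override top-level
#' scalar configuration entries (currently `subject_mass` and `gravity`);
#' unknown override keys raise a configuration error naming the key.
#'
#' @param config configuration list, by default [default_model_config()].
#' @param ... scalar overrides, e.g. `subject_mass = 60`.
#' @return An object of class `msk_model`.
#' @examples
#' m <- build_default_model()
#' length(m$fascicles)
#' m2 <- build_default_model(subject_mass = 60)
#' @export
build_default_model <- function(config = default_model_config(), ...) {
  overrides <- list(...)
  allowed <- c("subject_mass", "gravity")
  for (key in names(overrides)) {
    if (!key %in% allowed) {
      stop("unknown configuration key: '", key, "'")
    }
    config[[key]] <- overrides[[key]]
  }
  build_model(config)
}

#' Build a musculoskeletal model from a configuration list
#'
#' Validates the segment tree, coordinates, fascicles and reserves and
#' returns an `msk_model`. The segment graph must be a tree rooted at a
#' single fixed base segment (the pelvis); all masses must be positive and
#' inertias symmetric positive-definite; coordinate axes must be unit
#' vectors with non-degenerate ranges.
#'
#' @param config a configuration list with elements `segments`,
#'   `coordinates`, `fascicles`, `reserves`, `sensors`, `subject_mass`,
#'   `gravity` and optionally `external_loads`.
#' @return An object of class `msk_model`.
#' @export
build_model <- function(config) {
  stopifnot(is.list(config))
  subject_mass <- config$subject_mass
  if (!is.numeric(subject_mass) || subject_mass <= 0) {
    stop("configuration error: 'subject_mass' must be a positive number")
  }
  gravity <- config$gravity %||% c(0, 0, -9.81)

  seg_names <- vapply(config$segments, `[[`, "", "name")
  if (anyDuplicated(seg_names)) stop("configuration error: duplicate segment names")
  parents <- vapply(config$segments, function(s)
    if (is.null(s$parent) || is.na(s$parent)) NA_character_ else s$parent, "")
  roots <- which(is.na(parents))
  if (length(roots) != 1L) {
    stop("configuration error: segment graph must have exactly one base segment")
  }
  bad <- which(!is.na(parents) & !(parents %in% seg_names))
  if (length(bad)) {
    stop("configuration error: segment '", seg_names[bad[1L]],
         "' has unknown parent '", parents[bad[1L]], "'")
  }

  segments <- lapply(config$segments, function(s) {
    mass <- if (!is.null(s[["mass"]])) s[["mass"]] else
      s[["mass_frac"]] * subject_mass
    if (mass <= 0) stop("configuration error: segment '", s$name,
                        "' has non-positive mass")
    inertia <- if (!is.null(s[["inertia"]])) {
      matrix(as.numeric(unlist(s[["inertia"]])), 3L, 3L)
    } else diag(as.numeric(s[["inertia_diag"]]), 3L)
    if (max(abs(inertia - t(inertia))) > 1e-12 ||
        any(eigen(inertia, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
      stop("configuration error: segment '", s$name,
           "' inertia must be symmetric positive-definite")
    }
    list(name = s$name, parent = if (is.na(parents[match(s$name, seg_names)]))
      NA_character_ else s$parent,
      mass = mass, com = as.numeric(s$com),
      joint_offset = as.numeric(s$joint_offset), inertia = inertia)
  })
  names(segments) <- seg_names

  ## topological order (parents before children); also detects cycles
  order <- character(0)
  remaining <- seg_names
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nm) {
      p <- segments[[nm]]$parent
      is.na(p) || p %in% order
    }, TRUE)]
    if (!length(ready)) stop("configuration error: segment graph contains a cycle")
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }

  coords <- lapply(config$coordinates, function(cc) {
    ax <- as.numeric(cc$axis)
    if (abs(sqrt(sum(ax^2)) - 1) > 1e-9) {
      stop("configuration error: coordinate '", cc$name,
           "' axis must have unit norm")
    }
    rng <- as.numeric(cc$range)
    if (!(rng[1L] < rng[2L])) {
      stop("configuration error: coordinate '", cc$name,
           "' range lower bound must be below upper bound")
    }
    if (!cc$segment %in% seg_names) {
      stop("configuration error: coordinate '", cc$name,
           "' references unknown segment '", cc$segment, "'")
    }
    list(name = cc$name, segment = cc$segment, axis = ax, range = rng)
  })
  coord_names <- vapply(coords, `[[`, "", "name")
  if (anyDuplicated(coord_names)) stop("configuration error: duplicate coordinate names")
  names(coords) <- coord_names

  fascicles <- lapply(config$fascicles, function(f) {
    if (f$F0 <= 0) stop("configuration error: fascicle '", f$name, "' needs F0 > 0")
    if (f$optimal_fiber_length <= 0)
      stop("configuration error: fascicle '", f$name,
           "' needs optimal_fiber_length > 0")
    if (f$tendon_slack_length < 0)
      stop("configuration error: fascicle '", f$name,
           "' needs tendon_slack_length >= 0")
    spanned <- setdiff(names(f$path), "const")
    if (!all(spanned %in% coord_names)) {
      stop("configuration error: fascicle '", f$name,
           "' spans unknown coordinate '",
           setdiff(spanned, coord_names)[1L], "'")
    }
    f$path <- c(list(const = as.numeric(f$path$const)),
                lapply(f$path[spanned],
                       function(v) c(as.numeric(v), 0)[1:2]))
    f
  })
  fasc_names <- vapply(fascicles, `[[`, "", "name")
  if (anyDuplicated(fasc_names)) stop("configuration error: duplicate fascicle names")
  names(fascicles) <- fasc_names

  reserves <- config$reserves %||% list(optimal_force = 30)
  if (is.null(reserves$coordinates)) reserves$coordinates <- coord_names
  if (any(reserves$optimal_force <= 0)) {
    stop("configuration error: reserve optimal_force must be positive")
  }
  res_fopt <- rep_len(reserves$optimal_force, length(reserves$coordinates))
  names(res_fopt) <- reserves$coordinates

  model <- structure(list(
    subject_mass = subject_mass,
    gravity = as.numeric(gravity),
    segments = segments,
    segment_order = order,
    coordinates = coords,
    coordinate_names = coord_names,
    fascicles = fascicles,
    reserves = res_fopt,
    exotendons = list(),
    external_loads = config$external_loads,
    sensors = config$sensors
  ), class = "msk_model")
  model$links <- build_links(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.msk_model <- function(x, ...) {
  cat("Reduced musculoskeletal model\n")
  cat("  segments:   ", length(x$segments), "\n")
  cat("  coordinates:", length(x$coordinates), "\n")
  cat("  fascicles:  ", length(x$fascicles), "(",
      length(unique(vapply(x$fascicles, `[[`, "", "group"))), "groups )\n")
  cat("  reserves:   ", length(x$reserves), "x", x$reserves[1L], "N m\n")
  if (length(x$exotendons)) {
    e <- x$exotendons[[1L]]
    cat("  exotendon:  host", e$host_fascicle, " K =", e$stiffness,
        "N/m  L0 =", signif(e$resting_length, 4), "m\n")
  } else cat("  exotendon:   none (unassisted)\n")
  invisible(x)
}

## Internal articulated-chain representation: every generalized coordinate
## becomes a massless virtual link with one revolute axis; each segment's
## mass rides on its last link. Used by the kinematics and dynamics passes.
build_links <- function(model) {
  links <- list()
  seg_link <- integer(0)
  coord_of_segment <- split(
    seq_along(model$coordinates),
    vapply(model$coordinates, `[[`, "", "segment")
  )
  for (nm in model$segment_order) {
    s <- model$segments[[nm]]
    parent_link <- if (is.na(s$parent)) 0L else seg_link[[s$parent]]
    ci <- coord_of_segment[[nm]]
    if (is.null(ci)) ci <- integer(0)
    if (length(ci) == 0L) {
      links[[length(links) + 1L]] <- list(
        parent = parent_link, offset = s$joint_offset, axis = NULL,
        coord = NA_integer_, mass = s$mass, com = s$com, inertia = s$inertia,
        segment = nm)
    } else {
      for (k in seq_along(ci)) {
        last <- k == length(ci)
        links[[length(links) + 1L]] <- list(
          parent = if (k == 1L) parent_link else length(links),
          offset = if (k == 1L) s$joint_offset else c(0, 0, 0),
          axis = model$coordinates[[ci[k]]]$axis,
          coord = ci[k],
          mass = if (last) s$mass else 0,
          com = if (last) s$com else c(0, 0, 0),
          inertia = if (last) s$inertia else matrix(0, 3L, 3L),
          segment = if (last) nm else NA_character_)
      }
    }
    seg_link[[nm]] <- length(links)
  }
  list(links = links, segment_link = seg_link)
}

check_q <- function(model, q, enforce_range = TRUE) {
  n <- length(model$coordinates)
  if (is.null(names(q))) {
    if (length(q) != n) stop("coordinate vector has length ", length(q),
                             ", expected ", n)
    names(q) <- model$coordinate_names
  } else {
    q <- q[model$coordinate_names]
    if (anyNA(q)) stop("coordinate vector is missing coordinates")
  }
  if (enforce_range) {
    for (i in seq_len(n)) {
      rng <- model$coordinates[[i]]$range
      if (q[i] < rng[1L] - 1e-9 || q[i] > rng[2L] + 1e-9) {
        stop("coordinate '", model$coordinate_names[i],
             "' value ", signif(q[i], 4), " outside its range [",
             signif(rng[1L], 4), ", ", signif(rng[2L], 4), "]")
      }
    }
  }
  q
}

#' Musculotendon path length of a fascicle
#'
#' Evaluates the fascicle's polynomial path length at a coordinate vector.
#'
#' @param model an `msk_model`.
#' @param fascicle fascicle name.
#' @param q named (or ordered) coordinate vector in radians.
#' @param enforce_range check that `q` is within the coordinate ranges.
#' @return Path length in metres (strictly positive).
#' @export
muscle_length <- function(model, fascicle, q, enforce_range = TRUE) {
  f <- model$fascicles[[fascicle]]
  if (is.null(f)) stop("unknown fascicle: '", fascicle, "'")
  q <- check_q(model, q, enforce_range)
  L <- f$path$const
  for (cn in setdiff(names(f$path), "const")) {
    cf <- f$path[[cn]]
    L <- L + cf[1L] * q[[cn]] + cf[2L] * q[[cn]]^2
  }
  if (L <= 0) stop("fascicle '", fascicle, "' has non-positive path length at q")
  unname(L)
}

#' Moment arm of a fascicle about a coordinate
#'
#' Tendon-excursion convention: the moment arm is the negative partial
#' derivative of path length with respect to the coordinate, so a positive
#' moment arm means tension produces a positive generalized force.
#'
#' @inheritParams muscle_length
#' @param coord coordinate name.
#' @return Moment arm in metres; 0 if the fascicle does not span `coord`.
#' @export
moment_arm <- function(model, fascicle, q, coord, enforce_range = TRUE) {
  f <- model$fascicles[[fascicle]]
  if (is.null(f)) stop("unknown fascicle: '", fascicle, "'")
  q <- check_q(model, q, enforce_range)
  cf <- f$path[[coord]]
  if (is.null(cf)) return(0)
  unname(-(cf[1L] + 2 * cf[2L] * q[[coord]]))
}

#' Hill force-length-velocity scale factor
#'
#' Dimensionless available-force multiplier of a Hill-type fascicle with a
#' rigid tendon: a Gaussian active force-length curve (width 0.45 on
#' normalized fiber length) times a Hill force-velocity factor normalized to
#' 1 at zero velocity, 0 at maximal shortening (`v = -v_max` with
#' `v_max = 10` optimal fiber lengths per second) and saturating at 1.8 for
#' fast lengthening.
#'
#' @param fascicle a fascicle list (element of `model$fascicles`).
#' @param l musculotendon path length, m.
#' @param v path lengthening rate, m/s (negative = shortening).
#' @return A value in `[0, 1.8]`.
#' @export
hill_force_scale <- function(fascicle, l, v = 0) {
  stopifnot(l > 0)
  Lo <- fascicle$optimal_fiber_length
  lt <- (l - fascicle$tendon_slack_length) / Lo
  fl <- exp(-(lt - 1)^2 / 0.45)
  vmax <- 10 * Lo
  fv <- if (v <= 0) {
    if (v <= -vmax) 0 else (vmax + v) / (vmax - 4 * v)
  } else {
    (1.8 * v + 0.16 * vmax) / (v + 0.16 * vmax)
  }
  max(0, min(1.8, fl * fv))
}

#' Exotendon resting length rules
#'
#' Rule `LR1` sets the resting length to 40% of the host's optimal fiber
#' length plus its tendon slack length (the tendon transmits force from its
#' slack length while the fiber produces active force from 40% of its
#' optimal length); rule `LR2` sets it to the optimal fiber length (where
#' passive fiber force begins).
#'
#' @param fascicle a fascicle list.
#' @param rule `"LR1"`, `"LR2"`, or `"explicit"` with `length` given.
#' @param length explicit resting length (m), only for `rule = "explicit"`.
#' @return Resting length in metres.
#' @export
resting_length <- function(fascicle, rule = c("LR2", "LR1", "explicit"),
                           length = NULL) {
  rule <- match.arg(rule)
  switch(rule,
    LR1 = 0.4 * fascicle$optimal_fiber_length + fascicle$tendon_slack_length,
    LR2 = fascicle$optimal_fiber_length,
    explicit = {
      if (is.null(length) || !is.numeric(length) || length <= 0) {
        stop("configuration error: explicit resting-length rule requires a ",
             "positive 'length'")
      }
      length
    })
}

#' Tension of a passive elastic exotendon
#'
#' `T = K * s * (1 + D * Ldot)` with stretch `s = max(0, L - L0)`; the
#' result is floored at zero (an elastic band cannot push, so a large
#' negative shortening rate cannot produce negative tension).
#'
#' @param exo an exotendon list with `stiffness` (N/m), `resting_length` (m)
#'   and `dissipation` (s/m).
#' @param L path length, m (> 0).
#' @param Ldot path lengthening rate, m/s.
#' @return Tension in newtons (>= 0; 0 whenever `L <= resting_length`).
#' @export
exotendon_tension <- function(exo, L, Ldot = 0) {
  stopifnot(L > 0)
  s <- L - exo$resting_length
  if (s <= 0) return(0)
  max(0, exo$stiffness * s * (1 + exo$dissipation * Ldot))
}

#' Attach a parallel elastic exotendon to a host fascicle
#'
#' The exotendon shares the host fascicle's path exactly (it acts in
#' parallel), hence has identical length and moment arms. Only one device is
#' investigated at a time; attaching a second exotendon is an error.
#'
#' @param model an `msk_model`.
#' @param host host fascicle name.
#' @param stiffness spring stiffness K, N/m (>= 0).
#' @param rule resting-length rule, see [resting_length()].
#' @param length explicit resting length for `rule = "explicit"`.
#' @param dissipation dissipation factor D, s/m (default 0.01).
#' @return A copy of the model with the exotendon attached.
#' @export
attach_exotendon <- function(model, host, stiffness,
                             rule = c("LR2", "LR1", "explicit"),
                             length = NULL, dissipation = 0.01) {
  rule <- match.arg(rule)
  f <- model$fascicles[[host]]
  if (is.null(f)) stop("unknown fascicle: '", host, "'")
  if (length(model$exotendons) > 0L) {
    stop("only one assistive device may be attached per simulation")
  }
  if (stiffness < 0) stop("exotendon stiffness must be >= 0")
  if (dissipation < 0) stop("exotendon dissipation must be >= 0")
  model$exotendons <- list(list(
    host_fascicle = host,
    stiffness = stiffness,
    resting_length = resting_length(f, rule, length),
    dissipation = dissipation,
    resting_rule = rule
  ))
  model
}

#' Default external harvesting hand loads
#'
#' The 328 N harvesting force is split equally between the two hands
#' (164 N each), directed along the pull direction (default: a unit vector
#' 60 degrees below horizontal, pointing backward in the sagittal plane),
#' applied at the hand-segment origin.
#'
#' @param total total harvesting force magnitude, N.
#' @param direction world-frame direction (normalized internally).
#' @param two_handed split between both hands (default) or apply the whole
#'   load to the right hand.
#' @return A list of external-load records with `segment`, `force` (N,
#'   world frame) and `application_point` (m, segment frame).
#' @export
hand_load_default <- function(total = 328,
                              direction = c(-cos(60 * pi / 180), 0,
                                            -sin(60 * pi / 180)),
                              two_handed = TRUE) {
  dir <- direction / sqrt(sum(direction^2))
  if (two_handed) {
    per_hand <- total / 2
    list(
      list(segment = "hand_r", force = per_hand * dir,
           application_point = c(0, 0, 0)),
      list(segment = "hand_l", force = per_hand * dir,
           application_point = c(0, 0, 0))
    )
  } else {
    list(list(segment = "hand_r", force = total * dir,
              application_point = c(0, 0, 0)))
  }
}

#' Read or write a model configuration as YAML
#'
#' The structured-text model definition mirrors the configuration list of
#' [build_model()]: top-level keys `segments`, `coordinates`, `fascicles`,
#' `reserves`, `sensors`, `gravity`, `subject_mass` (lengths in m, forces in
#' N, stiffness in N/m, angles in radians).
#'
#' @param config a configuration list.
#' @param path file path.
#' @return `read_model_config` returns a configuration list.
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  yaml::read_yaml(path)
}
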