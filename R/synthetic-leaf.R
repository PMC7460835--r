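# Synthetic marker-tracked leaves -------------------------------------------
#
# The generator emulates the time-lapse point-tracking data the kinematics
# stage consumes: 17 markers (p1..p17) on the leaf mid-line, sampled at 1/6 Hz
# over 60 min, with each leaf segment contracting towards a saturating
# plateau and isotropic Gaussian tracking noise added per coordinate.

MARKER_NAMES <- paste0("p", 1:17)
PAINTED_IDX <- c(1L, 5L, 9L, 13L, 17L)
SEGMENT_NAMES <- c("apex", "incision", "base")

#' Configure a synthetic marker-tracked leaf
#'
#' Defines the geometry and contraction dynamics of one simulated leaf. The
#' mid-line is either a straight line (leaf held vertically, apex up) or a
#' circular arc of given radius (recurved leaf). Five painted markers sit at
#' the positions used in ring-incision experiments: the apex (`p1`), 2 mm
#' above (`p5`) and below (`p9`) the incision (which lies at one third of the
#' leaf length from the apex), the base (`p17`), and halfway between `p9` and
#' `p17` (`p13`). The remaining twelve virtual markers are equally spaced
#' along the mid-line between consecutive painted markers.
#'
#' Each segment's arc length follows a saturating exponential,
#' \eqn{L_i(t) = L_i(0) (1 + \epsilon_{\infty,i} (1 - e^{-t/\tau}))},
#' the simplest hydraulic-relaxation surrogate for the observed
#' contraction-to-plateau time courses.
#'
#' @param shape `"straight"` or `"recurved"` mid-line.
#' @param leaf_length_mm total mid-line length at `t0` in mm (must exceed
#'   6 mm so the incision markers fit). Defaults to 45.5 mm for straight and
#'   27.4 mm for recurved leaves, the reported mean leaf lengths of the two
#'   study species.
#' @param curvature_radius_mm radius of the circular-arc mid-line in mm
#'   (recurved only; `Inf` degenerates to a straight mid-line).
#' @param plateaus named numeric vector of plateau contractions
#'   \eqn{\epsilon_\infty} for segments `apex`, `incision`, `base`
#'   (dimensionless; negative = contraction; must lie in (-1, 1)).
#' @param tau_min saturation time constant in minutes.
#' @param noise_sd_mm sd of the isotropic Gaussian tracking noise added
#'   independently per coordinate per frame, in mm.
#' @param frame_interval_s sampling interval in seconds (default 6 s,
#'   i.e. 1/6 Hz).
#' @param duration_min recording duration in minutes (default 60).
#' @param seed integer RNG seed; identical configs and seeds give
#'   bit-identical output.
#' @return a `leaf_sim_config` list.
#' @seealso [simulate_leaf()]
#' @export
leaf_sim_config <- function(shape = c("straight", "recurved"),
                            leaf_length_mm = NULL,
                            curvature_radius_mm = 50,
                            plateaus = c(apex = -0.03, incision = -0.10,
                                         base = -0.04),
                            tau_min = 10,
                            noise_sd_mm = 0.02,
                            frame_interval_s = 6,
                            duration_min = 60,
                            seed = 1L) {
  shape <- match.arg(shape)
  if (is.null(leaf_length_mm)) {
    leaf_length_mm <- if (shape == "straight") 45.5 else 27.4
  }
  assert_scalar_finite(leaf_length_mm, "leaf_length_mm", positive = TRUE)
  if (leaf_length_mm <= 6) {
    stop("`leaf_length_mm` must exceed 6 mm so that the incision markers ",
         "(2 mm either side of the incision at one third leaf length) fit",
         call. = FALSE)
  }
  if (shape == "recurved") {
    if (!is.numeric(curvature_radius_mm) || length(curvature_radius_mm) != 1L ||
        is.na(curvature_radius_mm) || curvature_radius_mm <= 0) {
      stop("`curvature_radius_mm` must be a positive number (or Inf)",
           call. = FALSE)
    }
  }
  if (is.null(names(plateaus)) || !setequal(names(plateaus), SEGMENT_NAMES)) {
    stop("`plateaus` must be named with exactly: ",
         paste(SEGMENT_NAMES, collapse = ", "), call. = FALSE)
  }
  plateaus <- plateaus[SEGMENT_NAMES]
  if (any(!is.finite(plateaus))) {
    stop("plateau contractions must be finite", call. = FALSE)
  }
  if (any(plateaus <= -1)) {
    stop("plateau contraction <= -1 would collapse a segment to zero length",
         call. = FALSE)
  }
  if (any(abs(plateaus) >= 1)) {
    stop("|plateau| must be < 1", call. = FALSE)
  }
  assert_scalar_finite(tau_min, "tau_min", positive = TRUE)
  assert_scalar_finite(noise_sd_mm, "noise_sd_mm", nonneg = TRUE)
  assert_scalar_finite(frame_interval_s, "frame_interval_s", positive = TRUE)
  assert_scalar_finite(duration_min, "duration_min", positive = TRUE)
  if (duration_min * 60 / frame_interval_s < 1) {
    stop("duration and frame interval must yield at least 2 frames",
         call. = FALSE)
  }
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  structure(
    list(shape = shape,
         leaf_length_mm = leaf_length_mm,
         curvature_radius_mm = curvature_radius_mm,
         plateaus = plateaus,
         tau_min = tau_min,
         noise_sd_mm = noise_sd_mm,
         frame_interval_s = frame_interval_s,
         duration_min = duration_min,
         seed = seed),
    class = "leaf_sim_config")
}

#' Closed-form contraction time course of the generator
#'
#' \eqn{\epsilon(t) = \epsilon_\infty (1 - e^{-t/\tau})}. Serves as the
#' independent oracle when the kinematics stage is run on noiseless synthetic
#' leaves.
#'
#' @param eps_inf plateau contraction (dimensionless).
#' @param t_min time since wounding in minutes.
#' @param tau_min saturation time constant in minutes.
#' @return contraction at `t_min` (dimensionless).
#' @export
contraction_closed_form <- function(eps_inf, t_min, tau_min) {
  eps_inf * (1 - exp(-t_min / tau_min))
}

# arc-length positions of the 17 markers measured from the apex (p1)
marker_positions_from_apex <- function(leaf_length_mm) {
  L <- leaf_length_mm
  painted <- c(0, L / 3 - 2, L / 3 + 2, ((L / 3 + 2) + L) / 2, L)
  s <- stats::approx(PAINTED_IDX, painted, xout = 1:17)$y
  names(s) <- MARKER_NAMES
  s
}

# segment lengths at t0 implied by the marker layout
initial_segment_lengths <- function(leaf_length_mm) {
  s <- marker_positions_from_apex(leaf_length_mm)
  c(apex = unname(s["p5"] - s["p1"]),
    incision = unname(s["p9"] - s["p5"]),
    base = unname(s["p17"] - s["p9"]))
}

#' Simulate one marker-tracked leaf
#'
#' Places 17 markers on the mid-line, contracts each segment's arc length
#' towards its plateau with the configured saturating time course (the leaf
#' base `p17` stays fixed at the origin; markers move by arc-length
#' proportionality within their segment), maps arc positions to XY
#' (x to the right, y upward, origin at `p17` at `t0`), and adds Gaussian
#' tracking noise per coordinate per frame.
#'
#' @param cfg a [leaf_sim_config()].
#' @return a `marker_track` data frame with columns
#'   `frame`, `time_s`, `marker`, `x_mm`, `y_mm` and the config stored in
#'   attribute `"config"`.
#' @examples
#' trk <- simulate_leaf(leaf_sim_config(noise_sd_mm = 0, seed = 7))
#' head(trk)
#' @export
simulate_leaf <- function(cfg) {
  stopifnot(inherits(cfg, "leaf_sim_config"))
  t_s <- seq(0, cfg$duration_min * 60, by = cfg$frame_interval_s)
  t_min <- t_s / 60
  n_frames <- length(t_s)
  L <- cfg$leaf_length_mm

  s_apex0 <- marker_positions_from_apex(L)
  sb0 <- L - s_apex0                      # arc position from the base (p17)
  L0 <- initial_segment_lengths(L)

  # segment lengths over time (frames x 3), closed form
  growth <- vapply(SEGMENT_NAMES, function(seg) {
    L0[[seg]] * (1 + contraction_closed_form(cfg$plateaus[[seg]], t_min,
                                             cfg$tau_min))
  }, numeric(n_frames))
  if (n_frames == 1L) growth <- matrix(growth, nrow = 1L,
                                       dimnames = list(NULL, SEGMENT_NAMES))
  Lb <- growth[, "base"]; Li <- growth[, "incision"]; La <- growth[, "apex"]

  # classify each marker by its segment at t0 and its within-segment fraction
  seg_of <- ifelse(sb0 <= L0[["base"]] + 1e-12, "base",
                   ifelse(sb0 <= L0[["base"]] + L0[["incision"]] + 1e-12,
                          "incision", "apex"))
  frac <- numeric(17)
  for (k in seq_len(17)) {
    frac[k] <- switch(seg_of[k],
      base = sb0[k] / L0[["base"]],
      incision = (sb0[k] - L0[["base"]]) / L0[["incision"]],
      apex = (sb0[k] - L0[["base"]] - L0[["incision"]]) / L0[["apex"]])
  }

  # arc position from base for every marker and frame (frames x 17)
  sb_t <- matrix(NA_real_, n_frames, 17)
  for (k in seq_len(17)) {
    sb_t[, k] <- switch(seg_of[k],
      base = frac[k] * Lb,
      incision = Lb + frac[k] * Li,
      apex = Lb + Li + frac[k] * La)
  }

  if (cfg$shape == "straight" || is.infinite(cfg$curvature_radius_mm)) {
    x <- matrix(0, n_frames, 17)
    y <- sb_t
  } else {
    R <- cfg$curvature_radius_mm
    phi <- sb_t / R
    x <- R - R * cos(phi)                 # apex curves towards +x
    y <- R * sin(phi)
  }

  if (cfg$noise_sd_mm > 0) {
    noise <- local_seed(cfg$seed, {
      stats::rnorm(2L * n_frames * 17L, mean = 0, sd = cfg$noise_sd_mm)
    })
    x <- x + matrix(noise[seq_len(n_frames * 17L)], n_frames, 17)
    y <- y + matrix(noise[n_frames * 17L + seq_len(n_frames * 17L)],
                    n_frames, 17)
  }

  out <- data.frame(
    frame = rep(seq_len(n_frames), times = 17L),
    time_s = rep(t_s, times = 17L),
    marker = factor(rep(MARKER_NAMES, each = n_frames),
                    levels = MARKER_NAMES),
    x_mm = as.vector(x),
    y_mm = as.vector(y))
  out <- out[order(out$frame, as.integer(out$marker)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  class(out) <- c("marker_track", "data.frame")
  out
}

# Cohorts ---------------------------------------------------------------------

#' Default group plateau means for the 2x2 species x humidity design
#'
#' Plateau contraction means per (species, humidity, segment). The ordering of
#' effects follows the reported pattern: the incision region of the straight
#' species contracts most, both species contract more at low relative
#' humidity, and the recurved species shows weaker, more uniform
#' contractions. Magnitudes are generator assumptions (the raw per-leaf
#' plateaus are not tabulated in the published record).
#'
#' @return data frame with columns `species`, `rh`, `segment`, `eps_inf`.
#' @export
default_plateau_means <- function() {
  g <- expand.grid(segment = SEGMENT_NAMES,
                   rh = c("low", "high"),
                   species = c("D_cooperi", "D_ecklonis"),
                   stringsAsFactors = FALSE)
  vals <- c(
    # D_cooperi low: apex, incision, base
    -0.030, -0.100, -0.040,
    # D_cooperi high
    -0.020, -0.060, -0.025,
    # D_ecklonis low
    -0.025, -0.050, -0.030,
    # D_ecklonis high
    -0.015, -0.030, -0.020)
  g$eps_inf <- vals
  g[, c("species", "rh", "segment", "eps_inf")]
}

#' Default leaf geometry per species
#'
#' Straight 45.5 mm leaves for the terete species, recurved 27.4 mm leaves
#' (circular-arc mid-line, radius 50 mm) for the triquetrous one; lengths are
#' the reported species means.
#'
#' @return data frame with columns `species`, `shape`, `leaf_length_mm`,
#'   `curvature_radius_mm`.
#' @export
default_species_geometry <- function() {
  data.frame(
    species = c("D_cooperi", "D_ecklonis"),
    shape = c("straight", "recurved"),
    leaf_length_mm = c(45.5, 27.4),
    curvature_radius_mm = c(Inf, 50),
    stringsAsFactors = FALSE)
}

#' Configure a simulated cohort for the two-factor design
#'
#' Crossed species x relative-humidity design with `n_leaves_per_group`
#' leaves per cell. Each leaf draws its segment plateaus from
#' Normal(group mean, `between_leaf_sd`), truncated (by redrawing) to
#' (-1, 0], and receives its own tracking-noise seed derived from the cohort
#' seed by a fixed splitting rule.
#'
#' @param n_leaves_per_group leaves per (species, rh) cell (>= 2).
#' @param plateau_means data frame as [default_plateau_means()].
#' @param species_geometry data frame as [default_species_geometry()].
#' @param between_leaf_sd sd of the per-leaf plateau draws (dimensionless).
#' @param noise_sd_mm tracking noise sd in mm.
#' @param tau_min saturation time constant in minutes.
#' @param frame_interval_s sampling interval in seconds.
#' @param duration_min recording duration in minutes.
#' @param seed cohort seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_leaves_per_group = 10L,
                          plateau_means = default_plateau_means(),
                          species_geometry = default_species_geometry(),
                          between_leaf_sd = 0.01,
                          noise_sd_mm = 0.02,
                          tau_min = 10,
                          frame_interval_s = 6,
                          duration_min = 60,
                          seed = 1L) {
  n_leaves_per_group <- as.integer(n_leaves_per_group)
  if (is.na(n_leaves_per_group) || n_leaves_per_group < 2L) {
    stop("`n_leaves_per_group` must be an integer >= 2", call. = FALSE)
  }
  needed <- c("species", "rh", "segment", "eps_inf")
  stopifnot(is.data.frame(plateau_means), all(needed %in% names(plateau_means)))
  species <- unique(plateau_means$species)
  rh <- unique(plateau_means$rh)
  if (length(species) < 1L || length(rh) < 2L) {
    stop("the design needs at least two humidity levels", call. = FALSE)
  }
  cells <- expand.grid(species = species, rh = rh, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    sub <- plateau_means[plateau_means$species == cells$species[i] &
                           plateau_means$rh == cells$rh[i], ]
    if (!setequal(sub$segment, SEGMENT_NAMES)) {
      stop("plateau_means must cover all segments for every ",
           "(species, rh) combination", call. = FALSE)
    }
  }
  stopifnot(all(species %in% species_geometry$species))
  assert_scalar_finite(between_leaf_sd, "between_leaf_sd", nonneg = TRUE)
  assert_scalar_finite(noise_sd_mm, "noise_sd_mm", nonneg = TRUE)
  structure(
    list(n_leaves_per_group = n_leaves_per_group,
         plateau_means = plateau_means,
         species_geometry = species_geometry,
         between_leaf_sd = between_leaf_sd,
         noise_sd_mm = noise_sd_mm,
         tau_min = tau_min,
         frame_interval_s = frame_interval_s,
         duration_min = duration_min,
         seed = as.integer(seed)),
    class = "cohort_config")
}

# truncated-normal draw on (-1, 0] by redrawing (vector of length n)
draw_truncated_plateau <- function(n, mean, sd) {
  if (sd == 0) return(rep(pmin(0, pmax(mean, -1 + 1e-9)), n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:1000) {
      z <- stats::rnorm(1L, mean, sd)
      if (z > -1 && z <= 0) { out[i] <- z; break }
      if (try == 1000) stop("could not draw a plateau in (-1, 0]; check ",
                            "group means / between_leaf_sd", call. = FALSE)
    }
  }
  out
}

#' Simulate a labelled cohort of leaves
#'
#' @param cfg a [cohort_config()].
#' @return object of class `leaf_cohort`: a list with `leaves` (one record
#'   per leaf holding `leaf_id`, `species`, `rh`, the drawn `plateaus` and
#'   the `track`) and the `config`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_leaves_per_group = 2,
#'                                      frame_interval_s = 120, seed = 3))
#' length(coh$leaves)
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  cells <- expand.grid(species = unique(cfg$plateau_means$species),
                       rh = unique(cfg$plateau_means$rh),
                       stringsAsFactors = FALSE)
  leaves <- list()
  idx <- 0L
  for (ci in seq_len(nrow(cells))) {
    sp <- cells$species[ci]; hum <- cells$rh[ci]
    geom <- cfg$species_geometry[cfg$species_geometry$species == sp, ]
    means <- cfg$plateau_means[cfg$plateau_means$species == sp &
                                 cfg$plateau_means$rh == hum, ]
    mu <- stats::setNames(means$eps_inf, means$segment)[SEGMENT_NAMES]
    # group-level seed for the plateau draws keeps them independent of the
    # per-leaf tracking-noise streams
    plat <- local_seed(derive_seed(cfg$seed, 100000L + ci), {
      vapply(SEGMENT_NAMES, function(seg) {
        draw_truncated_plateau(cfg$n_leaves_per_group, mu[[seg]],
                               cfg$between_leaf_sd)
      }, numeric(cfg$n_leaves_per_group))
    })
    if (cfg$n_leaves_per_group == 1L) {
      plat <- matrix(plat, nrow = 1L, dimnames = list(NULL, SEGMENT_NAMES))
    }
    for (li in seq_len(cfg$n_leaves_per_group)) {
      idx <- idx + 1L
      leaf_cfg <- leaf_sim_config(
        shape = geom$shape,
        leaf_length_mm = geom$leaf_length_mm,
        curvature_radius_mm = geom$curvature_radius_mm,
        plateaus = stats::setNames(plat[li, SEGMENT_NAMES], SEGMENT_NAMES),
        tau_min = cfg$tau_min,
        noise_sd_mm = cfg$noise_sd_mm,
        frame_interval_s = cfg$frame_interval_s,
        duration_min = cfg$duration_min,
        seed = derive_seed(cfg$seed, idx))
      leaves[[idx]] <- list(
        leaf_id = sprintf("%s_%s_%02d", sp, hum, li),
        species = sp, rh = hum,
        plateaus = leaf_cfg$plateaus,
        track = simulate_leaf(leaf_cfg))
    }
  }
  structure(list(leaves = leaves, config = cfg), class = "leaf_cohort")
}

# Tensile traces --------------------------------------------------------------

#' Simulate a tensile stress-strain trace
#'
#' Linear loading of slope `E_target` up to a yield point at
#' `yield_fraction * sigma_max`, followed by a concave (cubic Hermite) rise
#' to `sigma_max` at the failure strain, where the trace ends. Gaussian noise
#' is added to stress only.
#'
#' @param E_target elastic modulus of the linear region, MPa.
#' @param sigma_max tensile strength (maximum stress), MPa.
#' @param noise_sd sd of the stress noise, MPa.
#' @param seed RNG seed.
#' @param n_points number of sampled points.
#' @param yield_fraction stress fraction at which the linear region ends.
#' @return data frame with columns `strain` (dimensionless, non-decreasing)
#'   and `stress_mpa`.
#' @export
simulate_stress_strain <- function(E_target, sigma_max, noise_sd = 0,
                                   seed = 1L, n_points = 200L,
                                   yield_fraction = 0.6) {
  assert_scalar_finite(E_target, "E_target", positive = TRUE)
  assert_scalar_finite(sigma_max, "sigma_max", positive = TRUE)
  assert_scalar_finite(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot(n_points >= 10L, yield_fraction > 0, yield_fraction < 1)
  sig_y <- yield_fraction * sigma_max
  e_y <- sig_y / E_target
  e_f <- 2 * e_y
  strain <- seq(0, e_f, length.out = n_points)
  stress <- ifelse(strain <= e_y, E_target * strain, NA_real_)
  post <- which(strain > e_y)
  u <- (strain[post] - e_y) / (e_f - e_y)
  # cubic Hermite: value sig_y -> sigma_max, slope E_target -> 0
  h00 <- 2 * u^3 - 3 * u^2 + 1
  h10 <- u^3 - 2 * u^2 + u
  h01 <- -2 * u^3 + 3 * u^2
  stress[post] <- h00 * sig_y + h10 * (e_f - e_y) * E_target +
    h01 * sigma_max
  if (noise_sd > 0) {
    stress <- stress + local_seed(seed, stats::rnorm(n_points, 0, noise_sd))
  }
  data.frame(strain = strain, stress_mpa = stress)
}

# IO --------------------------------------------------------------------------

#' Write / read a marker track as CSV
#'
#' Schema: `frame,time_s,marker,x_mm,y_mm`, markers `p1`..`p17`, coordinate
#' frame x to the right, y upward, origin at `p17` at `t0`.
#'
#' @param track a `marker_track` data frame.
#' @param path file path.
#' @return `write_marker_track()` returns `path` invisibly;
#'   `read_marker_track()` returns a `marker_track` data frame.
#' @export
write_marker_track <- function(track, path) {
  stopifnot(is.data.frame(track),
            all(c("frame", "time_s", "marker", "x_mm", "y_mm") %in%
                  names(track)))
  utils::write.csv(track[, c("frame", "time_s", "marker", "x_mm", "y_mm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_marker_track
#' @export
read_marker_track <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "marker", "x_mm", "y_mm")
  if (!all(need %in% names(out))) {
    stop("marker-track CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out$marker <- factor(out$marker, levels = unique(out$marker))
  class(out) <- c("marker_track", "data.frame")
  out
}
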