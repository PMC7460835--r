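# Tissue mechanics from tensile traces ----------------------------------------

#' Elastic modulus from a stress-strain trace
#'
#' Slope of the best linear region of the pre-peak trace, found by sliding a
#' window covering at least `window_fraction` of the pre-peak points and
#' maximizing R-squared; ties resolve to the earliest window, so the result
#' is deterministic.
#'
#' @param strain dimensionless strain, non-decreasing.
#' @param stress_mpa stress in MPa.
#' @param window_fraction minimum window width as a fraction of the
#'   pre-peak points (default 0.2).
#' @param min_points minimum window width in points.
#' @param r2_min reject the trace if no window reaches this R-squared.
#' @return the modulus in MPa (numeric scalar) with attributes `r2` and
#'   `window` (index range of the selected window).
#' @examples
#' tr <- simulate_stress_strain(2, 0.16)
#' elastic_modulus(tr$strain, tr$stress_mpa)
#' @export
elastic_modulus <- function(strain, stress_mpa, window_fraction = 0.2,
                            min_points = 5L, r2_min = 0.9) {
  stopifnot(is.numeric(strain), is.numeric(stress_mpa),
            length(strain) == length(stress_mpa))
  n <- length(strain)
  if (n < 5L) stop("need at least 5 points", call. = FALSE)
  if (any(diff(strain) < 0)) stop("strain must be non-decreasing",
                                  call. = FALSE)
  if (any(!is.finite(stress_mpa))) stop("stress must be finite",
                                        call. = FALSE)
  m <- which.max(stress_mpa)
  if (m < 5L) stop("too few pre-peak points", call. = FALSE)
  xs <- strain[1:m]; ys <- stress_mpa[1:m]
  w <- max(as.integer(min_points), ceiling(window_fraction * m))
  w <- min(w, m)
  starts <- seq_len(m - w + 1L)
  slope <- numeric(length(starts)); r2 <- numeric(length(starts))
  for (i in starts) {
    xi <- xs[i:(i + w - 1L)]; yi <- ys[i:(i + w - 1L)]
    sxx <- sum((xi - mean(xi))^2)
    syy <- sum((yi - mean(yi))^2)
    sxy <- sum((xi - mean(xi)) * (yi - mean(yi)))
    if (sxx == 0) { slope[i] <- NA_real_; r2[i] <- -Inf; next }
    slope[i] <- sxy / sxx
    r2[i] <- if (syy == 0) -Inf else (sxy^2) / (sxx * syy)
  }
  best <- which.max(r2)   # ties -> first
  if (!is.finite(r2[best]) || r2[best] < r2_min) {
    stop(sprintf(paste0("no linear region found: best window R^2 = %.3f ",
                        "(start %d, width %d, threshold %.2f)"),
                 max(r2[is.finite(r2)], -Inf), best, w, r2_min),
         call. = FALSE)
  }
  structure(slope[best], r2 = r2[best],
            window = c(start = best, end = best + w - 1L))
}

#' Tensile strength of a trace
#'
#' Maximum stress attained.
#'
#' @param stress_mpa stress values in MPa (non-empty).
#' @return maximum stress in MPa.
#' @export
tensile_strength <- function(stress_mpa) {
  if (length(stress_mpa) == 0L) stop("empty trace", call. = FALSE)
  max(stress_mpa)
}

#' Poisson's ratio from paired strain series
#'
#' \eqn{\nu} is minus the least-squares slope of lateral versus axial
#' strain, as obtained from image sequences captured during tensile tests.
#'
#' @param axial_strain strictly increasing axial strain.
#' @param lateral_strain lateral strain, same length.
#' @return Poisson's ratio (dimensionless).
#' @examples
#' ax <- seq(0, 0.1, length.out = 20)
#' poisson_ratio(ax, -0.35 * ax)  # 0.35
#' @export
poisson_ratio <- function(axial_strain, lateral_strain) {
  stopifnot(is.numeric(axial_strain), is.numeric(lateral_strain))
  if (length(axial_strain) != length(lateral_strain)) {
    stop("strain series must have equal length", call. = FALSE)
  }
  if (any(diff(axial_strain) <= 0)) {
    stop("axial strain must be strictly increasing", call. = FALSE)
  }
  xc <- axial_strain - mean(axial_strain)
  -sum(xc * (lateral_strain - mean(lateral_strain))) / sum(xc^2)
}

#' Turgor-based elastic modulus of parenchymatous tissue
#'
#' Linear-in-turgor micromechanical relation for a tissue of thin-walled,
#' turgid cells:
#' \deqn{E = c_w E_{cw} \frac{t_{cw}}{d_c} + c_P P}
#' The first term is the turgor-independent cell-wall contribution (membrane
#' stiffness of a thin-walled closed cell scales with the wall-thickness to
#' cell-diameter ratio), the second the turgor stiffening. The default
#' coefficients (`wall_coefficient = 4`, `turgor_coefficient = 3.4`) are
#' calibrated against published hydrenchyma and chlorenchyma moduli of the
#' two study species (see the methods vignette); both are exposed so the
#' relation can be re-calibrated. The tissue Poisson's ratio is part of the
#' published input set and is validated for admissibility, but over the
#' physiological range covered by the calibration data it does not enter the
#' relation.
#'
#' @param d_c_um median cell diameter, micrometres.
#' @param t_cw_um median cell-wall thickness, micrometres (much smaller
#'   than `d_c_um`).
#' @param turgor_mpa turgor pressure P, MPa (>= 0).
#' @param poisson tissue Poisson's ratio, in `[0, 0.5]`.
#' @param E_cw_mpa elastic modulus of the cell wall, MPa (default 5.00).
#' @param wall_coefficient,turgor_coefficient calibration coefficients.
#' @return tissue elastic modulus in MPa; monotone non-decreasing in
#'   `turgor_mpa`, reducing to the cell-wall term at zero turgor.
#' @examples
#' nilsson_parenchyma_modulus(92.00, 0.42, 0.04, 0.29)  # ~0.23 MPa
#' @export
nilsson_parenchyma_modulus <- function(d_c_um, t_cw_um, turgor_mpa, poisson,
                                       E_cw_mpa = 5.00,
                                       wall_coefficient = 4,
                                       turgor_coefficient = 3.4) {
  assert_scalar_finite(d_c_um, "d_c_um", positive = TRUE)
  assert_scalar_finite(t_cw_um, "t_cw_um", positive = TRUE)
  assert_scalar_finite(turgor_mpa, "turgor_mpa", nonneg = TRUE)
  assert_scalar_finite(poisson, "poisson")
  assert_scalar_finite(E_cw_mpa, "E_cw_mpa", positive = TRUE)
  if (poisson < 0 || poisson > 0.5) {
    stop("`poisson` must lie in [0, 0.5]", call. = FALSE)
  }
  if (t_cw_um >= d_c_um / 10) {
    stop("`t_cw_um` must be much smaller than `d_c_um`; check that both ",
         "are in micrometres", call. = FALSE)
  }
  if (d_c_um < 1) {
    stop("`d_c_um` below 1: cell diameters are expected in micrometres",
         call. = FALSE)
  }
  wall_coefficient * E_cw_mpa * t_cw_um / d_c_um +
    turgor_coefficient * turgor_mpa
}

#' Interspecific comparison table
#'
#' Builds the species-ratio column of a mechanical-property table:
#' `ratio = median_a / median_b`, rounded to `digits` decimals half away
#' from zero; significance stars are attached from a supplied p-value or
#' carried through from a `stars` column.
#'
#' @param medians data frame with columns `property`, `median_a`,
#'   `median_b`, and optionally `p` (numeric) or `stars` (character).
#' @param digits decimals for the ratio (default 2).
#' @return the input with an appended `ratio` column (and `stars` when
#'   derivable).
#' @examples
#' comparison_table(data.frame(property = "E_leaf",
#'                             median_a = 1.21, median_b = 0.72))
#' @export
comparison_table <- function(medians, digits = 2L) {
  stopifnot(is.data.frame(medians),
            all(c("property", "median_a", "median_b") %in% names(medians)))
  if (any(!is.finite(medians$median_a)) ||
      any(!is.finite(medians$median_b))) {
    stop("medians must be finite", call. = FALSE)
  }
  if (any(medians$median_b == 0)) {
    stop("zero denominator median", call. = FALSE)
  }
  out <- medians
  out$ratio <- round_half_away(out$median_a / out$median_b, digits)
  if (!"stars" %in% names(out) && "p" %in% names(out)) {
    out$stars <- significance_stars(out$p)
  }
  out
}
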