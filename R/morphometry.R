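# Cross-section morphometry ---------------------------------------------------
#
# The succulent leaf cross-section is modelled as five concentric tissue
# layers (epidermal bladder cells, epidermis, chlorenchyma, net of vascular
# bundles, hydrenchyma, central vascular strand, outside-in). For terete
# leaves, layers are measured as radii along the minor/major diameters; for
# triquetrous leaves along the three interior angle bisectors and one side
# bisector of the triangle.

#' Tissue layer thickness from consecutive radii
#'
#' The thickness of a layer is its outer radius (or outer intercept distance
#' along a measurement line) minus the radius of the adjacent inner tissue.
#'
#' @param outer_radius,inner_radius radii in micrometres
#'   (`outer >= inner >= 0`); vectorised.
#' @return thickness in micrometres.
#' @examples
#' tissue_thickness(1700, 1640)  # 60
#' @export
tissue_thickness <- function(outer_radius, inner_radius) {
  stopifnot(is.numeric(outer_radius), is.numeric(inner_radius),
            length(outer_radius) == length(inner_radius))
  if (any(!is.finite(outer_radius)) || any(!is.finite(inner_radius))) {
    stop("radii must be finite", call. = FALSE)
  }
  if (any(inner_radius < 0)) stop("radii must be >= 0", call. = FALSE)
  if (any(inner_radius > outer_radius)) {
    stop("inner radius exceeds outer radius", call. = FALSE)
  }
  outer_radius - inner_radius
}

#' Thicknesses of a full layer stack
#'
#' Given the outer radii of the layers ordered outside-in along one
#' measurement line, returns the per-layer thicknesses. The thicknesses plus
#' the innermost radius telescope back to the outermost radius.
#'
#' @param radii named numeric vector of outer radii (micrometres), strictly
#'   decreasing outside-in.
#' @return named numeric vector of layer thicknesses; the innermost layer's
#'   thickness is its full radius.
#' @examples
#' layer_thicknesses(c(epi = 1700, chl = 1640, hyd = 1100, cvs = 60))
#' @export
layer_thicknesses <- function(radii) {
  stopifnot(is.numeric(radii), length(radii) >= 2L)
  if (any(diff(radii) >= 0)) {
    stop("radii must be strictly decreasing outside-in", call. = FALSE)
  }
  if (any(radii <= 0)) stop("radii must be positive", call. = FALSE)
  inner <- c(radii[-1L], 0)
  th <- tissue_thickness(unname(radii), unname(inner))
  stats::setNames(th, names(radii))
}

#' Shrinkage of embedded relative to fresh tissue
#'
#' Percentage shrinkage \eqn{\gamma = 100 (fresh - embedded) / fresh}.
#' Histological embedding shrinks the parenchymatous tissues; applying the
#' correction factor \eqn{1 / (1 - \gamma/100)} to an embedded dimension
#' recovers the fresh one ([shrinkage_correction()]).
#'
#' @param fresh,embedded dimensions in mm (`fresh > 0`); vectorised.
#' @return shrinkage in percent.
#' @examples
#' shrinkage(5.4, 4.86)  # 10
#' @export
shrinkage <- function(fresh, embedded) {
  stopifnot(is.numeric(fresh), is.numeric(embedded))
  if (any(!is.finite(fresh)) || any(fresh <= 0)) {
    stop("fresh dimension must be positive", call. = FALSE)
  }
  100 * (fresh - embedded) / fresh
}

#' @rdname shrinkage
#' @param gamma shrinkage in percent (< 100).
#' @export
shrinkage_correction <- function(embedded, gamma) {
  if (any(gamma >= 100)) stop("gamma must be < 100", call. = FALSE)
  embedded / (1 - gamma / 100)
}

#' Aspect ratio of cell cross-section diameters
#'
#' Major over minor diameter; the axes are ordered internally so the result
#' is always >= 1 and order-invariant.
#'
#' @param d1,d2 cross-sectional diameters (same unit); vectorised.
#' @return dimensionless aspect ratio >= 1.
#' @examples
#' aspect_ratio(154, 100)  # 1.54
#' @export
aspect_ratio <- function(d1, d2) {
  stopifnot(is.numeric(d1), is.numeric(d2), length(d1) == length(d2))
  if (any(d1 <= 0) || any(d2 <= 0)) {
    stop("diameters must be positive", call. = FALSE)
  }
  pmax(d1, d2) / pmin(d1, d2)
}

# Triangle bisectors -----------------------------------------------------------

#' Measurement lines of a triquetrous cross-section
#'
#' For a triangle with vertices `V1`, `V2`, `V3`, returns the three interior
#' angle bisectors `r1`-`r3` (from each vertex to the opposite side; the foot
#' divides that side in the ratio of the adjacent side lengths) and the side
#' bisector `r4`: the segment from the midpoint of the designated side,
#' perpendicular to it, to the opposite triangle boundary.
#'
#' @param vertices 3x2 numeric matrix of vertex XY coordinates
#'   (micrometres), rows `V1`, `V2`, `V3`.
#' @param r4_side index (1-3) of the vertex *opposite* the side carrying
#'   `r4` (default 1, i.e. `r4` sits on side `V2V3`). Which side carries the
#'   side bisector depends on how the section was mounted, hence it is
#'   configurable.
#' @return data frame with columns `line`, `x0`, `y0`, `x1`, `y1`,
#'   `length`.
#' @examples
#' tri <- rbind(c(0, 0), c(4, 0), c(0, 3))  # right triangle, sides 3-4-5
#' bisector_lines(tri)
#' @export
bisector_lines <- function(vertices, r4_side = 1L) {
  V <- as.matrix(vertices)
  stopifnot(nrow(V) == 3L, ncol(V) == 2L, all(is.finite(V)))
  r4_side <- as.integer(r4_side)
  stopifnot(r4_side %in% 1:3)
  area2 <- abs((V[2, 1] - V[1, 1]) * (V[3, 2] - V[1, 2]) -
                 (V[3, 1] - V[1, 1]) * (V[2, 2] - V[1, 2]))
  if (area2 <= .Machine$double.eps * max(abs(V), 1)^2) {
    stop("collinear vertices: degenerate triangle", call. = FALSE)
  }
  dist2 <- function(p, q) sqrt(sum((p - q)^2))
  rows <- vector("list", 4L)
  for (i in 1:3) {
    j <- setdiff(1:3, i)[1L]; k <- setdiff(1:3, i)[2L]
    lj <- dist2(V[i, ], V[j, ])   # side i-j
    lk <- dist2(V[i, ], V[k, ])   # side i-k
    # foot on side j-k divides it in ratio |ij| : |ik| measured from j
    D <- V[j, ] + (lj / (lj + lk)) * (V[k, ] - V[j, ])
    rows[[i]] <- data.frame(line = paste0("r", i),
                            x0 = V[i, 1], y0 = V[i, 2],
                            x1 = D[1], y1 = D[2],
                            length = dist2(V[i, ], D))
  }
  # r4: perpendicular from the midpoint of the designated side to the
  # opposite boundary
  j <- setdiff(1:3, r4_side)[1L]; k <- setdiff(1:3, r4_side)[2L]
  M <- (V[j, ] + V[k, ]) / 2
  side <- V[k, ] - V[j, ]
  nrm <- c(-side[2L], side[1L]) / sqrt(sum(side^2))
  centroid <- colMeans(V)
  if (sum((centroid - M) * nrm) < 0) nrm <- -nrm   # point into the triangle
  # intersect ray M + t*nrm with the two other sides, keep nearest hit
  t_best <- Inf; P_best <- NULL
  for (edge in list(c(r4_side, j), c(r4_side, k))) {
    Pa <- V[edge[1L], ]; Pb <- V[edge[2L], ]
    d <- Pb - Pa
    den <- nrm[1L] * (-d[2L]) - nrm[2L] * (-d[1L])
    if (abs(den) < 1e-14) next
    rhs <- Pa - M
    t <- (rhs[1L] * (-d[2L]) - rhs[2L] * (-d[1L])) / den
    s <- (nrm[1L] * rhs[2L] - nrm[2L] * rhs[1L]) / den
    if (t > 1e-12 && s >= -1e-9 && s <= 1 + 1e-9 && t < t_best) {
      t_best <- t; P_best <- M + t * nrm
    }
  }
  if (is.null(P_best)) stop("side bisector does not meet the boundary",
                            call. = FALSE)
  rows[[4L]] <- data.frame(line = "r4", x0 = M[1L], y0 = M[2L],
                           x1 = P_best[1L], y1 = P_best[2L],
                           length = dist2(M, P_best))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Surface-area-to-volume ratios -------------------------------------------------

#' Surface-area-to-volume ratio of idealized leaf shapes
#'
#' Terete leaves are idealized as a cone (total surface = lateral + base
#' area), triquetrous leaves as an irregular tetrahedron built from four
#' vertex coordinates. All dimensions in mm, result in 1/mm.
#'
#' @param shape `"cone"` or `"tetrahedron"`.
#' @param radius,height cone base radius and height (mm).
#' @param vertices 4x3 matrix of tetrahedron vertex coordinates (mm).
#' @return surface-area-to-volume ratio in 1/mm.
#' @examples
#' sa_vol("cone", radius = 3, height = 4)  # 2
#' @export
sa_vol <- function(shape = c("cone", "tetrahedron"), radius = NULL,
                   height = NULL, vertices = NULL) {
  shape <- match.arg(shape)
  if (shape == "cone") {
    sa_vol_cone(radius, height)
  } else {
    sa_vol_tetrahedron(vertices)
  }
}

#' @rdname sa_vol
#' @export
sa_vol_cone <- function(radius, height) {
  assert_scalar_finite(radius, "radius", positive = TRUE)
  assert_scalar_finite(height, "height", positive = TRUE)
  slant <- sqrt(radius^2 + height^2)
  sa <- pi * radius * slant + pi * radius^2
  vol <- pi * radius^2 * height / 3
  sa / vol
}

#' @rdname sa_vol
#' @export
sa_vol_tetrahedron <- function(vertices) {
  V <- as.matrix(vertices)
  stopifnot(nrow(V) == 4L, ncol(V) == 3L, all(is.finite(V)))
  e1 <- V[2, ] - V[1, ]; e2 <- V[3, ] - V[1, ]; e3 <- V[4, ] - V[1, ]
  vol <- abs(det(rbind(e1, e2, e3))) / 6
  if (vol <= .Machine$double.eps * max(abs(V), 1)^3) {
    stop("degenerate tetrahedron (coplanar vertices)", call. = FALSE)
  }
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  faces <- utils::combn(4L, 3L)
  sa <- sum(apply(faces, 2L, function(f) {
    a <- V[f[2], ] - V[f[1], ]; b <- V[f[3], ] - V[f[1], ]
    sqrt(sum(cross3(a, b)^2)) / 2
  }))
  sa / vol
}

#' Unit converters
#'
#' Cross-section computations run in micrometres, whole-leaf quantities in
#' millimetres; conversions are explicit.
#'
#' @param x numeric vector.
#' @return converted numeric vector.
#' @export
um_to_mm <- function(x) x / 1000

#' @rdname um_to_mm
#' @export
mm_to_um <- function(x) x * 1000
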