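# Segment-wise contraction from marker trajectories --------------------------
#
# Absolute contraction of segment i at time t (dimensionless, negative =
# shortening):
#     eps_i(t) = (L_i(t) - L_i(t0)) / L_i(t0)
# Relative contraction weights the segment by its share of the whole leaf:
#     eps*_i(t) = eps_i(t) * L_i(t) / L_total(t)
# Segment length L is marker Y-spacing for straight leaves and the arc length
# of a polynomial mid-line fit between projected boundary markers for
# recurved leaves.

#' Default leaf segments
#'
#' Contiguous, non-overlapping segments along the marker order: apex
#' (`p1`->`p5`), incision (`p5`->`p9`) and base (`p9`->`p17`).
#'
#' @return data frame with columns `segment`, `from`, `to`.
#' @export
default_segments <- function() {
  data.frame(segment = c("apex", "incision", "base"),
             from = c("p1", "p5", "p9"),
             to = c("p5", "p9", "p17"),
             stringsAsFactors = FALSE)
}

# Mid-line fit ----------------------------------------------------------------

#' Fit a polynomial mid-line to a frame's marker cloud
#'
#' The point cloud is first rotated so that its principal axis becomes the
#' abscissa (this keeps strongly recurved leaves single-valued and avoids
#' vertical tangents), then a least-squares polynomial `y(x)` of the given
#' degree is fitted in the rotated frame.
#'
#' @param points two-column matrix or data frame of marker XY positions (mm).
#' @param degree polynomial degree (>= 1; needs at least `degree + 1`
#'   distinct abscissa values after rotation).
#' @return a `midline_fit` object: polynomial coefficients (ascending
#'   powers), degree, fit domain on the rotated abscissa, per-point
#'   residuals and their RMS, plus the rotation used.
#' @examples
#' pts <- cbind(x = seq(-1, 1, length.out = 9), y = seq(-1, 1,
#'   length.out = 9)^2)
#' fit_midline(pts, degree = 2)$coefficients
#' @export
fit_midline <- function(points, degree = 3L) {
  xy <- as.matrix(points)
  stopifnot(ncol(xy) == 2L)
  if (!all(is.finite(xy))) stop("marker coordinates must be finite",
                                call. = FALSE)
  degree <- as.integer(degree)
  if (degree < 1L) stop("`degree` must be >= 1", call. = FALSE)
  n <- nrow(xy)
  if (n < degree + 1L) {
    stop("need at least degree + 1 points", call. = FALSE)
  }
  ctr <- colMeans(xy)
  X <- sweep(xy, 2L, ctr)
  cv <- crossprod(X) / max(1, n - 1)
  ev <- eigen(cv, symmetric = TRUE)
  v1 <- ev$vectors[, 1L]
  # deterministic orientation of the principal axis
  if (v1[1L] < 0 || (v1[1L] == 0 && v1[2L] < 0)) v1 <- -v1
  Q <- cbind(v1, c(-v1[2L], v1[1L]))      # proper rotation, det = +1
  uv <- X %*% Q
  u <- uv[, 1L]; v <- uv[, 2L]
  M <- outer(u, 0:degree, `^`)
  qrM <- qr(M)
  if (qrM$rank < degree + 1L) {
    stop("rank-deficient mid-line fit: fewer than degree + 1 distinct ",
         "abscissa values after rotation", call. = FALSE)
  }
  beta <- qr.coef(qrM, v)
  res <- v - drop(M %*% beta)
  structure(
    list(coefficients = unname(beta),
         degree = degree,
         domain = range(u),
         residuals = res,
         residual_rms = sqrt(mean(res^2)),
         center = ctr,
         rotation = Q),
    class = "midline_fit")
}

# polynomial and derivative evaluation in the rotated frame
poly_eval <- function(coefs, x) {
  drop(outer(x, seq_along(coefs) - 1L, `^`) %*% coefs)
}

poly_deriv_coefs <- function(coefs) {
  d <- length(coefs) - 1L
  if (d == 0L) return(0)
  coefs[-1L] * seq_len(d)
}

#' Arc length along a fitted mid-line
#'
#' \eqn{\int_{x_a}^{x_b} \sqrt{1 + y'(x)^2}\,dx} by adaptive quadrature
#' (relative tolerance 1e-8) on the rotated abscissa. Swapping the bounds
#' gives the same (positive) length.
#'
#' @param fit a [fit_midline()] result.
#' @param x_a,x_b bounds on the rotated abscissa (mm); must lie within the
#'   fit domain up to a small tolerance (2.5% of the domain width).
#' @return arc length in mm.
#' @export
arc_length <- function(fit, x_a, x_b) {
  stopifnot(inherits(fit, "midline_fit"))
  assert_scalar_finite(x_a, "x_a"); assert_scalar_finite(x_b, "x_b")
  dom <- fit$domain
  tol <- 0.025 * diff(dom) + 1e-9
  if (min(x_a, x_b) < dom[1L] - tol || max(x_a, x_b) > dom[2L] + tol) {
    stop(sprintf("arc-length bounds [%.4g, %.4g] outside fit domain [%.4g, %.4g]",
                 min(x_a, x_b), max(x_a, x_b), dom[1L], dom[2L]),
         call. = FALSE)
  }
  if (x_a == x_b) return(0)
  dc <- poly_deriv_coefs(fit$coefficients)
  f <- function(x) sqrt(1 + poly_eval(dc, x)^2)
  val <- stats::integrate(f, min(x_a, x_b), max(x_a, x_b),
                          rel.tol = 1e-8, subdivisions = 500L)$value
  val
}

#' Project a point onto a fitted mid-line
#'
#' Nearest point on the fitted curve (rotated frame), searched over the fit
#' domain padded by 2.5% on each side.
#'
#' @param fit a [fit_midline()] result.
#' @param point length-2 numeric XY in the original coordinates (mm).
#' @return abscissa of the nearest curve point in the rotated frame.
#' @export
project_onto_midline <- function(fit, point) {
  stopifnot(inherits(fit, "midline_fit"), length(point) == 2L)
  uv <- drop((as.numeric(point) - fit$center) %*% fit$rotation)
  dom <- fit$domain
  pad <- 0.025 * diff(dom) + 1e-9
  obj <- function(x) (x - uv[1L])^2 + (poly_eval(fit$coefficients, x) -
                                         uv[2L])^2
  stats::optimize(obj, lower = dom[1L] - pad, upper = dom[2L] + pad,
                  tol = 1e-10)$minimum
}

# Segment lengths -------------------------------------------------------------

# reshape a long track into frames x markers matrices; errors name the
# offending frame and marker
track_matrices <- function(track, required_markers) {
  need <- c("frame", "time_s", "marker", "x_mm", "y_mm")
  stopifnot(is.data.frame(track), all(need %in% names(track)))
  frames <- sort(unique(track$frame))
  markers <- as.character(unique(track$marker))
  fr <- factor(track$frame, levels = frames)
  mk <- factor(as.character(track$marker), levels = markers)
  x <- tapply(track$x_mm, list(fr, mk), function(z) z[1L])
  y <- tapply(track$y_mm, list(fr, mk), function(z) z[1L])
  for (m in required_markers) {
    if (!m %in% markers) {
      stop(sprintf("marker %s missing from the track", m), call. = FALSE)
    }
    bad <- which(is.na(y[, m]) | is.na(x[, m]))
    if (length(bad)) {
      stop(sprintf("marker %s missing in frame %s", m,
                   frames[bad[1L]]), call. = FALSE)
    }
  }
  t_s <- as.numeric(tapply(track$time_s, fr, function(z) z[1L]))
  if (any(diff(t_s) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  list(frames = frames, time_s = t_s, markers = markers, x = x, y = y)
}

#' Per-frame segment lengths from a marker track
#'
#' `mode = "y_spacing"` (straight leaves): the segment length is the absolute
#' Y-spacing of its boundary markers. `mode = "arc"` (recurved leaves): per
#' frame, a polynomial mid-line is fitted to all markers, the boundary
#' markers are projected onto the curve, and the arc length between the
#' projections is integrated.
#'
#' @param track a `marker_track` data frame.
#' @param segdef segment definition, see [default_segments()].
#' @param mode `"arc"` or `"y_spacing"`.
#' @param degree polynomial degree for arc mode (default 3).
#' @return data frame with columns `segment`, `frame`, `time_s`, `L_mm`.
#' @export
segment_lengths <- function(track, segdef = default_segments(),
                            mode = c("arc", "y_spacing"), degree = 3L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(segdef),
            all(c("segment", "from", "to") %in% names(segdef)))
  boundary <- unique(c(segdef$from, segdef$to))
  tm <- track_matrices(track, required_markers = boundary)
  n_frames <- length(tm$frames)
  res <- vector("list", nrow(segdef))

  if (mode == "y_spacing") {
    for (i in seq_len(nrow(segdef))) {
      L <- abs(tm$y[, segdef$to[i]] - tm$y[, segdef$from[i]])
      res[[i]] <- data.frame(segment = segdef$segment[i],
                             frame = tm$frames, time_s = tm$time_s,
                             L_mm = unname(L))
    }
  } else {
    # all markers enter the fit; boundary markers must additionally be
    # present (checked above)
    all_mk <- tm$markers
    Lmat <- matrix(NA_real_, n_frames, nrow(segdef))
    for (f in seq_len(n_frames)) {
      xs <- tm$x[f, all_mk]; ys <- tm$y[f, all_mk]
      ok <- !is.na(xs) & !is.na(ys)
      fit <- fit_midline(cbind(xs[ok], ys[ok]), degree = degree)
      proj <- vapply(boundary, function(m) {
        project_onto_midline(fit, c(tm$x[f, m], tm$y[f, m]))
      }, numeric(1L))
      for (i in seq_len(nrow(segdef))) {
        Lmat[f, i] <- arc_length(fit, proj[[segdef$from[i]]],
                                 proj[[segdef$to[i]]])
      }
    }
    for (i in seq_len(nrow(segdef))) {
      res[[i]] <- data.frame(segment = segdef$segment[i],
                             frame = tm$frames, time_s = tm$time_s,
                             L_mm = Lmat[, i])
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Contraction -----------------------------------------------------------------

#' Absolute contraction of a segment-length series
#'
#' \eqn{\epsilon(t) = (L(t) - L(t_0)) / L(t_0)}; exactly zero at `t0`,
#' dimensionless, negative for shortening, and invariant under uniform
#' scaling of all lengths.
#'
#' @param L numeric vector of segment lengths over time (mm); the first
#'   element is \eqn{L(t_0)}.
#' @param L0 reference length; defaults to `L[1]`.
#' @return vector of contractions.
#' @examples
#' absolute_contraction(c(10, 9.5, 9))  # 0 -0.05 -0.10
#' @export
absolute_contraction <- function(L, L0 = L[1L]) {
  stopifnot(is.numeric(L), length(L) >= 1L)
  if (!is.finite(L0) || L0 <= 0) {
    stop("initial segment length must be positive", call. = FALSE)
  }
  (L - L0) / L0
}

#' Relative contraction (length-share weighted)
#'
#' \eqn{\epsilon^*(t) = \epsilon(t) \, L(t) / L_{total}(t)}. Its magnitude
#' never exceeds the absolute contraction, and summed over the segments it
#' equals the length-weighted mean segment contraction.
#'
#' @param eps absolute contraction \eqn{\epsilon(t)}.
#' @param L segment length at `t` (mm).
#' @param L_total whole-leaf length at `t` (mm), sum of all segment lengths.
#' @return vector of relative contractions.
#' @export
relative_contraction <- function(eps, L, L_total) {
  stopifnot(length(eps) == length(L), length(L) == length(L_total))
  if (any(!is.finite(L_total)) || any(L_total <= 0)) {
    stop("total leaf length must be positive", call. = FALSE)
  }
  if (any(L > L_total * (1 + 1e-9))) {
    stop("segment length exceeds total leaf length", call. = FALSE)
  }
  eps * L / L_total
}

#' Segment-wise contraction series for one leaf
#'
#' Runs [segment_lengths()] and derives absolute and relative contractions
#' per segment and frame.
#'
#' @inheritParams segment_lengths
#' @return a `contraction_series` data frame with columns `segment`, `frame`,
#'   `time_s`, `L_mm`, `eps_abs`, `eps_rel`.
#' @examples
#' trk <- simulate_leaf(leaf_sim_config(noise_sd_mm = 0,
#'                                      frame_interval_s = 600))
#' contraction(trk, mode = "y_spacing")
#' @export
contraction <- function(track, segdef = default_segments(),
                        mode = c("arc", "y_spacing"), degree = 3L) {
  mode <- match.arg(mode)
  len <- segment_lengths(track, segdef, mode = mode, degree = degree)
  segs <- segdef$segment
  sp <- split(len, factor(len$segment, levels = segs))
  L0 <- vapply(sp, function(d) d$L_mm[order(d$frame)][1L], numeric(1L))
  if (any(L0 <= 0)) stop("initial segment length must be positive",
                         call. = FALSE)
  len <- len[order(match(len$segment, segs), len$frame), , drop = FALSE]
  len$eps_abs <- unlist(lapply(segs, function(s) {
    d <- len[len$segment == s, ]
    absolute_contraction(d$L_mm)
  }), use.names = FALSE)
  tot <- stats::aggregate(L_mm ~ frame, data = len, FUN = sum)
  names(tot)[2L] <- "L_total"
  len <- merge(len, tot, by = "frame", sort = TRUE)
  len$eps_rel <- relative_contraction(len$eps_abs, len$L_mm, len$L_total)
  out <- len[order(match(len$segment, segs), len$frame),
             c("segment", "frame", "time_s", "L_mm", "eps_abs", "eps_rel")]
  rownames(out) <- NULL
  class(out) <- c("contraction_series", "data.frame")
  out
}

#' Endpoint contraction summary per segment
#'
#' Scalar per segment: the median contraction over the final
#' `window_frames` frames (robust against frame-level tracking noise).
#'
#' @param series a [contraction()] result.
#' @param window_frames number of final frames to summarise over (>= 1,
#'   <= number of frames).
#' @return data frame with columns `segment`, `eps_abs`, `eps_rel`.
#' @export
endpoint_summary <- function(series, window_frames = 5L) {
  stopifnot(is.data.frame(series),
            all(c("segment", "frame", "eps_abs", "eps_rel") %in%
                  names(series)))
  if (nrow(series) == 0L) stop("empty contraction series", call. = FALSE)
  window_frames <- as.integer(window_frames)
  n_frames <- length(unique(series$frame))
  if (window_frames < 1L || window_frames > n_frames) {
    stop("`window_frames` must be in [1, number of frames]", call. = FALSE)
  }
  segs <- unique(series$segment)
  out <- do.call(rbind, lapply(segs, function(s) {
    d <- series[series$segment == s, ]
    d <- d[order(d$frame), ]
    tail_idx <- seq(nrow(d) - window_frames + 1L, nrow(d))
    data.frame(segment = s,
               eps_abs = stats::median(d$eps_abs[tail_idx]),
               eps_rel = stats::median(d$eps_rel[tail_idx]))
  }))
  rownames(out) <- NULL
  out
}

#' Write a contraction series as tidy CSV
#'
#' Schema: `leaf_id,segment,time_s,L_mm,eps_abs,eps_rel`.
#'
#' @param series a [contraction()] result.
#' @param leaf_id identifier recorded in the `leaf_id` column.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_contraction_series <- function(series, leaf_id, path) {
  out <- cbind(leaf_id = leaf_id,
               series[, c("segment", "time_s", "L_mm", "eps_abs", "eps_rel")])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
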