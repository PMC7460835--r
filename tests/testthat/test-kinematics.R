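# Mid-line fitting, arc length and contraction

test_that("mid-line fit is exact on collinear and polynomial data", {
  # collinear, degree 1: zero residuals
  pts <- cbind(seq(0, 10, length.out = 9), 2 + 0 * seq_len(9))
  fit <- fit_midline(pts, degree = 1)
  expect_equal(fit$residuals, rep(0, 9), tolerance = 1e-12)

  # exact parabola, symmetric sample: principal axis is x, so the fitted
  # coefficients are (-mean(y), 0, 1) in the centred frame
  x <- seq(-1, 1, length.out = 11)
  fit2 <- fit_midline(cbind(x, x^2), degree = 2)
  expect_equal(fit2$coefficients, c(-mean(x^2), 0, 1), tolerance = 1e-9)
})

test_that("noisy parabola residual RMS stays near the noise level", {
  set.seed(31)
  x <- seq(-1, 1, length.out = 17)
  y <- x^2 + rnorm(17, sd = 0.05)
  fit <- fit_midline(cbind(x, y), degree = 2)
  expect_lt(fit$residual_rms, 2 * 0.05)
})

test_that("rank-deficient designs raise an explicit error", {
  pts <- rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 0), c(1, 0))
  expect_error(fit_midline(pts, degree = 2), "rank-deficient")
  expect_error(fit_midline(rbind(c(0, 0), c(1, 1)), degree = 3),
               "at least")
})

test_that("arc length matches closed forms and is symmetric", {
  # flat segment
  pts <- cbind(seq(0, 10, length.out = 11), rep(0, 11))
  fit <- fit_midline(pts, degree = 1)
  expect_equal(arc_length(fit, -5, 5), 10, tolerance = 1e-10)

  # parabola y = x^2 over [0, 1]: (2*sqrt(5) + asinh(2)) / 4
  x <- seq(-1, 1, length.out = 17)
  fitp <- fit_midline(cbind(x, x^2), degree = 2)
  closed <- (2 * sqrt(5) + asinh(2)) / 4
  expect_equal(arc_length(fitp, 0, 1), closed, tolerance = 1e-8)
  expect_equal(arc_length(fitp, 1, 0), arc_length(fitp, 0, 1))
  expect_equal(arc_length(fitp, 0.3, 0.3), 0)
  expect_error(arc_length(fitp, 0, 5), "outside fit domain")
})

test_that("arc length never falls below the chord", {
  set.seed(71)
  for (i in 1:50) {
    deg <- sample(1:4, 1)
    coefs <- rnorm(deg + 1)
    x <- sort(runif(17, -2, 2))
    y <- drop(outer(x, 0:deg, `^`) %*% coefs)
    fit <- fit_midline(cbind(x, y), degree = deg)
    a <- runif(1, fit$domain[1], fit$domain[2])
    b <- runif(1, fit$domain[1], fit$domain[2])
    chord <- sqrt((b - a)^2 +
                    (sum(fit$coefficients * b^(0:deg)) -
                       sum(fit$coefficients * a^(0:deg)))^2)
    expect_gte(arc_length(fit, a, b) + 1e-9, chord)
  }
})

test_that("y-spacing segment lengths are plain marker spacings", {
  y <- rbind(c(p1 = 40, p5 = 30, p9 = 20, p17 = 0),
             c(p1 = 39, p5 = 30, p9 = 20.5, p17 = 0))
  trk <- manual_straight_track(y)
  len <- segment_lengths(trk, mode = "y_spacing")
  expect_equal(len$L_mm[len$segment == "incision"], c(10, 9.5))
  expect_equal(len$L_mm[len$segment == "apex"], c(10, 9))
  expect_equal(len$L_mm[len$segment == "base"], c(20, 20.5))
})

test_that("arc mode equals y-spacing on a straight leaf", {
  cfg <- leaf_sim_config("straight", noise_sd_mm = 0,
                         frame_interval_s = 600)
  trk <- simulate_leaf(cfg)
  l_arc <- segment_lengths(trk, mode = "arc", degree = 1)
  l_y <- segment_lengths(trk, mode = "y_spacing")
  expect_equal(l_arc$L_mm, l_y$L_mm, tolerance = 1e-9)
})

test_that("missing markers are reported with frame and marker", {
  y <- rbind(c(p1 = 40, p5 = 30, p9 = 20, p17 = 0),
             c(p1 = 39, p5 = 30, p9 = 20.5, p17 = 0))
  trk <- manual_straight_track(y)
  trk <- trk[!(trk$frame == 2 & trk$marker == "p9"), ]
  expect_error(segment_lengths(trk, mode = "y_spacing"),
               "marker p9 missing in frame 2")
})

test_that("absolute contraction implements the defining identity", {
  expect_equal(absolute_contraction(c(10, 10)), c(0, 0))
  expect_equal(absolute_contraction(c(10, 9)), c(0, -0.10))
  expect_equal(absolute_contraction(c(10, 10.5)), c(0, 0.05))
  expect_error(absolute_contraction(c(0, 1)), "positive")
  # scale invariance
  L <- c(10, 9.7, 9.1)
  expect_equal(absolute_contraction(L * 3.7), absolute_contraction(L),
               tolerance = 1e-12)
})

test_that("relative contraction weights by length share", {
  expect_equal(relative_contraction(-0.10, 9, 30), -0.03)
  expect_equal(relative_contraction(-0.2, 25, 25), -0.2)  # single segment
  expect_equal(relative_contraction(0, 7, 30), 0)
  expect_error(relative_contraction(-0.1, 10, 0), "positive")
  expect_error(relative_contraction(-0.1, 40, 30), "exceeds")
  # |eps*| <= |eps|
  expect_lte(abs(relative_contraction(-0.1, 9, 30)), 0.1)
})

test_that("contraction series: eps(t0) is exactly zero, totals add up", {
  cfg <- leaf_sim_config("straight", noise_sd_mm = 0.05, seed = 17,
                         frame_interval_s = 300)
  cs <- contraction(simulate_leaf(cfg), mode = "y_spacing")
  expect_true(all(cs$eps_abs[cs$frame == 1] == 0))
  # sum of relative contractions = length-weighted mean contraction
  for (f in unique(cs$frame)) {
    d <- cs[cs$frame == f, ]
    expect_equal(sum(d$eps_rel), sum(d$eps_abs * d$L_mm) / sum(d$L_mm),
                 tolerance = 1e-12)
  }
})

test_that("contraction is invariant to uniform coordinate scaling", {
  cfg <- leaf_sim_config("recurved", noise_sd_mm = 0.02, seed = 13,
                         frame_interval_s = 600)
  trk <- simulate_leaf(cfg)
  scaled <- trk
  scaled$x_mm <- trk$x_mm * 2.5
  scaled$y_mm <- trk$y_mm * 2.5
  for (mode in c("arc", "y_spacing")) {
    # spacing mode is exactly scale-free; arc mode is limited only by the
    # quadrature tolerance
    tol <- if (mode == "arc") 1e-9 else 1e-12
    a <- contraction(trk, mode = mode)
    b <- contraction(scaled, mode = mode)
    expect_equal(b$eps_abs, a$eps_abs, tolerance = tol)
    expect_equal(b$eps_rel, a$eps_rel, tolerance = tol)
  }
})

test_that("fitted segment arcs dominate their marker chords", {
  cfg <- leaf_sim_config("recurved", noise_sd_mm = 0,
                         frame_interval_s = 600)
  trk <- simulate_leaf(cfg)
  cs <- contraction(trk, mode = "arc", degree = 3)
  segdef <- default_segments()
  for (i in seq_len(nrow(segdef))) {
    for (f in unique(cs$frame)) {
      d <- trk[trk$frame == f, ]
      p_from <- unlist(d[d$marker == segdef$from[i], c("x_mm", "y_mm")])
      p_to <- unlist(d[d$marker == segdef$to[i], c("x_mm", "y_mm")])
      chord <- sqrt(sum((p_from - p_to)^2))
      L <- cs$L_mm[cs$segment == segdef$segment[i] & cs$frame == f]
      expect_gte(L + 1e-6, chord)
    }
  }
})

test_that("endpoint summary behaves and wider windows stabilise estimates", {
  cs <- data.frame(segment = "apex", frame = 1:10, time_s = (0:9) * 6,
                   L_mm = 10, eps_abs = -0.05, eps_rel = -0.02)
  ep <- endpoint_summary(cs, window_frames = 4)
  expect_equal(ep$eps_abs, -0.05)
  expect_error(endpoint_summary(cs, window_frames = 11), "window_frames")
  expect_error(endpoint_summary(cs[0, ], window_frames = 1), "empty")

  # across seeds, a 5-frame window has lower variance than a single frame
  est <- function(w, s) {
    cfg <- leaf_sim_config("straight", noise_sd_mm = 0.1, seed = s,
                           frame_interval_s = 120)
    cs <- contraction(simulate_leaf(cfg), mode = "y_spacing")
    endpoint_summary(cs, window_frames = w)$eps_abs[2]
  }
  e1 <- vapply(1:30, function(s) est(1, s), numeric(1))
  e5 <- vapply(1:30, function(s) est(5, s), numeric(1))
  expect_lt(var(e5), var(e1))
})

test_that("contraction series CSV export is tidy", {
  cfg <- leaf_sim_config(frame_interval_s = 1200, seed = 2)
  cs <- contraction(simulate_leaf(cfg), mode = "y_spacing")
  path <- tempfile(fileext = ".csv")
  write_contraction_series(cs, "leaf01", path)
  back <- read.csv(path)
  expect_named(back, c("leaf_id", "segment", "time_s", "L_mm", "eps_abs",
                       "eps_rel"))
  expect_equal(nrow(back), nrow(cs))
})
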