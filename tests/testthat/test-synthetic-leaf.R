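# Synthetic marker-track generator

test_that("zero plateaus and zero noise give stationary markers", {
  cfg <- leaf_sim_config(plateaus = c(apex = 0, incision = 0, base = 0),
                         noise_sd_mm = 0, frame_interval_s = 120)
  trk <- simulate_leaf(cfg)
  ref <- trk[trk$frame == 1L, c("marker", "x_mm", "y_mm")]
  for (f in unique(trk$frame)) {
    cur <- trk[trk$frame == f, ]
    expect_equal(cur$x_mm, ref$x_mm, tolerance = 1e-12)
    expect_equal(cur$y_mm, ref$y_mm, tolerance = 1e-12)
  }
})

test_that("noiseless incision contraction follows the closed form", {
  # eps(60) = eps_inf * (1 - exp(-60/tau)); markers p5/p9 bound the incision
  cfg <- leaf_sim_config("straight",
                         plateaus = c(apex = 0, incision = -0.10, base = 0),
                         tau_min = 10, noise_sd_mm = 0)
  trk <- simulate_leaf(cfg)
  first <- trk[trk$frame == 1L, ]
  last <- trk[trk$frame == max(trk$frame), ]
  L0 <- abs(first$y_mm[first$marker == "p5"] -
              first$y_mm[first$marker == "p9"])
  L1 <- abs(last$y_mm[last$marker == "p5"] -
              last$y_mm[last$marker == "p9"])
  expect_equal((L1 - L0) / L0, -0.10 * (1 - exp(-6)), tolerance = 1e-10)
  expect_equal(-0.10 * (1 - exp(-6)), -0.09975212, tolerance = 1e-7)
})

test_that("recurved leaves have chord strictly shorter than arc", {
  cfg <- leaf_sim_config("recurved", curvature_radius_mm = 50,
                         noise_sd_mm = 0, frame_interval_s = 600)
  trk <- simulate_leaf(cfg)
  f1 <- trk[trk$frame == 1L, ]
  p1 <- unlist(f1[f1$marker == "p1", c("x_mm", "y_mm")])
  p17 <- unlist(f1[f1$marker == "p17", c("x_mm", "y_mm")])
  chord <- sqrt(sum((p1 - p17)^2))
  expect_lt(chord, cfg$leaf_length_mm)
  expect_gt(chord, 0)
})

test_that("identical configs and seeds are bit-identical; seeds matter", {
  cfg <- leaf_sim_config(noise_sd_mm = 0.05, seed = 11,
                         frame_interval_s = 300)
  expect_identical(simulate_leaf(cfg), simulate_leaf(cfg))
  cfg2 <- leaf_sim_config(noise_sd_mm = 0.05, seed = 12,
                          frame_interval_s = 300)
  expect_false(identical(simulate_leaf(cfg)$y_mm,
                         simulate_leaf(cfg2)$y_mm))
})

test_that("generator self-consistency: kinematics recovers the closed form", {
  cfg <- leaf_sim_config("straight", noise_sd_mm = 0, tau_min = 10,
                         frame_interval_s = 60)
  trk <- simulate_leaf(cfg)
  cs <- contraction(trk, mode = "y_spacing")
  for (seg in c("apex", "incision", "base")) {
    d <- cs[cs$segment == seg, ]
    expected <- contraction_closed_form(cfg$plateaus[[seg]],
                                        d$time_s / 60, cfg$tau_min)
    expect_equal(d$eps_abs, expected, tolerance = 1e-6)
  }
})

test_that("config validation rejects impossible settings", {
  expect_error(leaf_sim_config(plateaus = c(apex = -1.2, incision = 0,
                                            base = 0)),
               "collapse")
  expect_error(leaf_sim_config(plateaus = c(apex = NA, incision = 0,
                                            base = 0)),
               "finite")
  expect_error(leaf_sim_config(leaf_length_mm = 5), "6 mm")
  expect_error(leaf_sim_config(noise_sd_mm = -1), ">= 0")
  expect_error(leaf_sim_config(plateaus = c(a = 0, b = 0, c = 0)), "named")
})

test_that("cohort: zero variance gives identical noiseless group members", {
  cc <- cohort_config(n_leaves_per_group = 3, between_leaf_sd = 0,
                      noise_sd_mm = 0, frame_interval_s = 600, seed = 5)
  coh <- simulate_cohort(cc)
  meta <- data.frame(species = sapply(coh$leaves, `[[`, "species"),
                     rh = sapply(coh$leaves, `[[`, "rh"))
  grp <- paste(meta$species, meta$rh)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    ref <- coh$leaves[[idx[1]]]$track
    for (i in idx[-1]) {
      expect_equal(coh$leaves[[i]]$track$y_mm, ref$y_mm, tolerance = 1e-12)
    }
  }
  # all four factor combinations present, n per group as configured
  expect_equal(sort(unique(grp)),
               sort(c("D_cooperi low", "D_cooperi high",
                      "D_ecklonis low", "D_ecklonis high")))
  expect_true(all(table(grp) == 3))
})

test_that("cohort plateau draws are truncated to (-1, 0]", {
  pm <- default_plateau_means()
  pm$eps_inf <- -0.9
  cc <- cohort_config(n_leaves_per_group = 5, plateau_means = pm,
                      between_leaf_sd = 0.5, noise_sd_mm = 0,
                      frame_interval_s = 1200, seed = 99)
  coh <- simulate_cohort(cc)
  plats <- do.call(rbind, lapply(coh$leaves, `[[`, "plateaus"))
  expect_true(all(plats > -1))
  expect_true(all(plats <= 0))
})

test_that("cohort determinism and per-leaf seed splitting", {
  cc <- cohort_config(n_leaves_per_group = 2, frame_interval_s = 600,
                      seed = 7)
  a <- simulate_cohort(cc); b <- simulate_cohort(cc)
  expect_identical(lapply(a$leaves, `[[`, "track"),
                   lapply(b$leaves, `[[`, "track"))
  # different leaves of one group get different noise streams
  expect_false(identical(a$leaves[[1]]$track$y_mm,
                         a$leaves[[2]]$track$y_mm))
})

test_that("humidity effect raises SRH rejection above the null rate", {
  # straight species only (fast Y-spacing path); factor A = RH level
  reps <- 80
  run_cohort <- function(low_eps, seed) {
    pm <- default_plateau_means()
    pm <- pm[pm$species == "D_cooperi", ]
    pm$eps_inf <- -0.04
    pm$eps_inf[pm$rh == "low"] <- low_eps
    cc <- cohort_config(n_leaves_per_group = 5, plateau_means = pm,
                        between_leaf_sd = 0.01, noise_sd_mm = 0.02,
                        frame_interval_s = 300, seed = seed)
    ep <- cohort_contractions(simulate_cohort(cc))$endpoints
    srh <- scheirer_ray_hare(eps_abs ~ rh + segment, ep)
    srh$p_chisq[1] <= 0.05
  }
  null_rej <- mean(vapply(seq_len(reps), function(s) {
    run_cohort(-0.04, 1000 + s)
  }, logical(1)))
  alt_rej <- mean(vapply(seq_len(reps), function(s) {
    run_cohort(-0.08, 2000 + s)
  }, logical(1)))
  expect_gt(alt_rej, null_rej)
  expect_gt(alt_rej, 0.5)    # a doubled plateau at low RH is easy to detect
  expect_lt(null_rej, 0.2)
})

test_that("stress-strain generator hits its target properties", {
  tr <- simulate_stress_strain(2.0, 0.16, noise_sd = 0)
  expect_equal(unclass(elastic_modulus(tr$strain, tr$stress_mpa))[1], 2.0,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(tensile_strength(tr$stress_mpa), 0.16, tolerance = 1e-12)
  expect_equal(tr$stress_mpa[1], 0)
  expect_true(all(diff(tr$strain) >= 0))
  # noisy recovery: median extracted modulus within 5% of target
  E_hat <- vapply(1:50, function(s) {
    tn <- simulate_stress_strain(32.80, 8.80, noise_sd = 0.01, seed = s)
    as.numeric(elastic_modulus(tn$strain, tn$stress_mpa))
  }, numeric(1))
  expect_lt(abs(median(E_hat) - 32.80) / 32.80, 0.05)
  expect_error(simulate_stress_strain(-1, 1), "> 0")
})

test_that("marker-track CSV round-trips", {
  trk <- simulate_leaf(leaf_sim_config(frame_interval_s = 1200, seed = 3))
  path <- tempfile(fileext = ".csv")
  write_marker_track(trk, path)
  back <- read_marker_track(path)
  expect_equal(back$y_mm, trk$y_mm, tolerance = 1e-12)
  expect_equal(as.character(back$marker), as.character(trk$marker))
  expect_error(read_marker_track({
    p <- tempfile(); writeLines("a,b\n1,2", p); p
  }), "columns")
})
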