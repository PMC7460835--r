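#!/usr/bin/env Rscript
# Stage 2: segment-wise contraction kinematics.
#
# Reads the simulated marker tracks, computes per-segment absolute and
# relative contractions (Y-spacing for straight leaves, cubic mid-line
# arc-length analysis for recurved ones) and summarises each leaf by the
# median contraction over the last five frames.

suppressPackageStartupMessages(library(leafseal))

out <- "results/analysis"
tracks <- read.csv(file.path(out, "tracks.csv"))

series_all <- list(); ends_all <- list()
for (id in unique(tracks$leaf_id)) {
  d <- tracks[tracks$leaf_id == id, ]
  trk <- d[, c("frame", "time_s", "marker", "x_mm", "y_mm")]
  trk$marker <- factor(trk$marker, levels = unique(trk$marker))
  mode <- if (d$shape[1] == "recurved") "arc" else "y_spacing"
  cs <- contraction(trk, mode = mode, degree = 3)
  series_all[[id]] <- cbind(leaf_id = id, species = d$species[1],
                            rh = d$rh[1], as.data.frame(cs))
  ends_all[[id]] <- cbind(leaf_id = id, species = d$species[1],
                          rh = d$rh[1],
                          endpoint_summary(cs, window_frames = 5))
}
series <- do.call(rbind, series_all)
ends <- do.call(rbind, ends_all)
write.csv(series, file.path(out, "contraction.csv"), row.names = FALSE,
          quote = FALSE)
write.csv(ends, file.path(out, "endpoints.csv"), row.names = FALSE,
          quote = FALSE)

med <- aggregate(eps_abs ~ segment + species + rh, data = ends,
                 FUN = median)
cat("median endpoint contraction per segment x species x humidity:\n")
print(med, row.names = FALSE)

# compare against the configured plateaus (saturation at 60 min)
plat <- read.csv(file.path(out, "true_plateaus.csv"))
truth <- aggregate(cbind(apex, incision, base) ~ species + rh,
                   data = plat, FUN = median)
cat("\nmedian configured plateaus per group (for reference):\n")
print(truth, row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(series, aes(time_s / 60, eps_abs, group = leaf_id,
                          colour = species)) +
    geom_line(alpha = 0.35) +
    facet_grid(rh ~ segment) +
    labs(x = "time since incision (min)", y = "absolute contraction",
         colour = NULL) +
    theme_minimal()
  ggsave(file.path(out, "contraction_curves.pdf"), p, width = 9,
         height = 5)
  cat("\nwrote contraction_curves.pdf\n")
}
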