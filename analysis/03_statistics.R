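#!/usr/bin/env Rscript
# Stage 3: rank-based factorial statistics of the endpoint contractions.
#
# Per humidity level: Scheirer-Ray-Hare test of species and segment on the
# absolute endpoint contraction, then Bonferroni-adjusted pairwise Wilcoxon
# rank-sum tests over the species:segment groups.

suppressPackageStartupMessages(library(leafseal))

out <- "results/analysis"
ends <- read.csv(file.path(out, "endpoints.csv"))

srh_rows <- list(); ph_rows <- list()
for (h in unique(ends$rh)) {
  d <- ends[ends$rh == h, ]
  srh <- scheirer_ray_hare(eps_abs ~ species + segment, d)
  cat(sprintf("\n== %s RH ==\n", h))
  print(srh)
  srh_rows[[h]] <- cbind(rh = h, as.data.frame(srh),
                         stars = significance_stars(srh$p_chisq))
  grp <- interaction(d$species, d$segment, drop = TRUE, sep = ":")
  ph <- pairwise_wilcoxon(d$eps_abs, grp)
  sig <- ph[ph$p_adj <= 0.05, ]
  cat(sprintf("%d of %d pairwise comparisons significant after Bonferroni\n",
              nrow(sig), nrow(ph)))
  ph_rows[[h]] <- cbind(rh = h, ph)
}
write.csv(do.call(rbind, srh_rows), file.path(out, "srh.csv"),
          row.names = FALSE, quote = FALSE)
write.csv(do.call(rbind, ph_rows), file.path(out, "posthoc.csv"),
          row.names = FALSE, quote = FALSE)
cat("\nwrote srh.csv and posthoc.csv\n")
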