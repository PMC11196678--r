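#!/usr/bin/env Rscript
# Stage 6 — area-of-occupancy findings from the persisted species series.
#
# Group-mean trajectories under the no-dispersal and proportional-expansion
# hypotheses, and the distribution of per-species losses at 2100.

source(file.path("analysis", "_common.R"))

aoo <- read.csv(file.path(RUN_DIR, "aoo_series.csv"))
scen <- "SSP-like-3-7.0"

for (g in unique(aoo$group)) {
  sub <- aoo[aoo$group == g & aoo$scenario == scen, ]
  years <- sort(unique(sub$year))
  mk <- function(col) {
    m <- t(vapply(split(sub, sub$species_id), function(d)
      d[order(d$year), col], numeric(length(years))))
    colnames(m) <- years
    m
  }
  nd <- mean_aoo_trajectory(mk("aoo_km2"))
  pe <- mean_aoo_trajectory(mk("aoo_expansion_km2"))
  last <- function(tr) tr$pct[nrow(tr$pct), ]
  cat(sprintf("%s (%s): AOO change by 2100 %.1f%% +- %.1f (no dispersal), %.1f%% +- %.1f (proportional expansion)\n",
              g, scen, last(nd)$mean, last(nd)$se, last(pe)$mean, last(pe)$se))
  d <- per_species_loss_distribution(mk("aoo_km2"))
  cat(sprintf("  per-species changes: median %.1f%%, worst %.1f%%, skewness %.2f\n",
              median(d$pct_change), min(d$pct_change), d$skewness))
}
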