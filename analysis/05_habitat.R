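#!/usr/bin/env Rscript
# Stage 5 — habitat-extent findings from the persisted area tables.
#
# Percent change of thresholded suitable habitat relative to 2015, per
# probability threshold and scenario, and the shift in regional shares.

source(file.path("analysis", "_common.R"))

hab <- read.csv(file.path(RUN_DIR, "habitat_area.csv"))
for (g in unique(hab$group)) {
  for (scen in unique(hab$scenario)) {
    sub <- hab[hab$group == g & hab$scenario == scen, ]
    chg <- vapply(sort(unique(sub$threshold)), function(th) {
      a <- sub[sub$threshold == th, ]
      suppressWarnings(pct_change_area(a$area_km2[a$year == max(a$year)],
                                       a$area_km2[a$year == min(a$year)]))
    }, 0)
    cat(sprintf("%s / %s: habitat change by 2100 at p >= {0.6, 0.7, 0.8, 0.9}: %s\n",
                g, scen, paste(sprintf("%.1f%%", chg), collapse = ", ")))
  }
}

sh <- read.csv(file.path(RUN_DIR, "regional_shares.csv"))
legend <- read.csv(file.path(RUN_DIR, "region_legend.csv"))
polar <- legend$id[legend$band == "polar"]
for (g in unique(sh$group)) {
  s <- sh[sh$group == g & sh$scenario == "SSP-like-3-7.0", ]
  p0 <- sum(s$share_pct[s$year == min(s$year) & s$id %in% polar])
  pN <- sum(s$share_pct[s$year == max(s$year) & s$id %in% polar])
  cat(sprintf("%s: polar share of suitable habitat (p >= 0.6) %.1f%% -> %.1f%%\n",
              g, p0, pN))
}
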