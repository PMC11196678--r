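#!/usr/bin/env Rscript
# Stage 4 — diversity findings, recomputed from the persisted run tables.
#
# Reads the richness maps and trajectory tables written by stage 3 and
# restates the headline diversity numbers from those intermediates alone,
# demonstrating that every reported figure is reproducible from files.

source(file.path("analysis", "_common.R"))

scen <- "SSP-like-3-7.0"
safe <- gsub("[^A-Za-z0-9.-]", "_", scen)
traj <- read.csv(file.path(RUN_DIR, "diversity_trajectory.csv"))

for (g in c("brown_macroalgae", "seagrasses")) {
  r0 <- read_layer_csv(file.path(RUN_DIR, sprintf("richness_%s_%s_2015.csv", g, safe)))$values
  rN <- read_layer_csv(file.path(RUN_DIR, sprintf("richness_%s_%s_2100.csv", g, safe)))$values
  r0[is.na(r0)] <- 0; rN[is.na(rN)] <- 0
  change <- mean(log_pct_change(rN, r0), na.rm = TRUE)
  frac <- fraction_losing(r0, rN, 0.10)
  tr <- traj[traj$group == g & traj$scenario == scen, ]
  last <- tr[nrow(tr), ]
  cat(sprintf("%s (%s): mean local diversity change %.1f%% [95%% CI %.1f, %.1f]; %.1f%% of occupied localities lose >= 10%% of species\n",
              g, scen, change, last$ci_low, last$ci_high, 100 * frac))
}

lat <- read.csv(file.path(RUN_DIR, "latitudinal_profile.csv"))
lb <- lat[lat$group == "brown_macroalgae" & lat$scenario == scen & !is.na(lat$mean), ]
cat(sprintf("latitudinal profile (brown macroalgae): strongest loss %.1f%% at %.0f deg, strongest gain %.1f%% at %.0f deg\n",
            min(lb$mean), lb$lat[which.min(lb$mean)],
            max(lb$mean), lb$lat[which.max(lb$mean)]))
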