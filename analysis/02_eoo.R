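#!/usr/bin/env Rscript
# Stage 2 — extents of occurrence from the occurrence records.
#
# Applies the 10-record filter, fits each retained species' alpha hull with
# the iterative area/occurrence ratio rule, rasterizes the hulls at a tenth
# of the analysis resolution and clips them with the light-at-bottom mask.

source(file.path("analysis", "_common.R"))
ensure_results()

w <- analysis_world()
cfg <- w$cfg
records <- read_occurrences(file.path(RESULTS_DIR, "occurrences.csv"))

filt <- filter_min_records(records, cfg$eoo$min_records)
cat(sprintf("%d of %d species retained (>= %d records); dropped: %s\n",
            nrow(filt$retained), nrow(filt$retained) + nrow(filt$dropped),
            cfg$eoo$min_records,
            if (nrow(filt$dropped)) paste(filt$dropped$species_id, collapse = ", ")
            else "none"))

areas <- cell_area(cfg$grid)
rows <- lapply(filt$retained$species_id, function(id) {
  xy <- as.matrix(filt$records[filt$records$species_id == id,
                               c("longitude", "latitude")])
  hull <- fit_alpha(xy, alpha0 = cfg$eoo$alpha0, step = cfg$eoo$step,
                    ratio_threshold = cfg$eoo$ratio_threshold)
  eoo <- rasterize_and_clip(hull, cfg$grid, w$env$light_valid, id,
                            fine_factor = cfg$eoo$fine_factor)
  data.frame(species_id = id, alpha_final = hull$alpha,
             hull_area_deg2 = hull$area,
             contained_fraction = hull$contained_fraction,
             eoo_cells = sum(eoo$mask), eoo_km2 = sum(areas[eoo$mask]))
})
eoo_summary <- do.call(rbind, rows)
write.csv(eoo_summary, file.path(RESULTS_DIR, "eoo_summary.csv"),
          row.names = FALSE)

cat(sprintf("alpha_final: median %.3f (range %.3f-%.3f); median EOO %d cells\n",
            median(eoo_summary$alpha_final), min(eoo_summary$alpha_final),
            max(eoo_summary$alpha_final),
            as.integer(median(eoo_summary$eoo_cells))))
cat("wrote results/eoo_summary.csv\n")
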