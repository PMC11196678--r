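# Shared configuration for the analysis drivers. Every stage regenerates
# deterministic inputs (environment, species) from this config, so each
# numbered script can be run on its own.

library(macrocast)

ANALYSIS_SEED <- 1
RESULTS_DIR <- "results"
RUN_DIR <- file.path(RESULTS_DIR, "run")

analysis_config <- function() default_config(seed = ANALYSIS_SEED)

ensure_results <- function() {
  dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)
}

# the present-day world and community, regenerated on demand
analysis_world <- function(cfg = analysis_config()) {
  env <- generate_environment(cfg$scenarios[[1]], cfg$grid,
                              child_seed(cfg$seed, 1L, 1L))
  species <- generate_species(cfg$n_species, env, child_seed(cfg$seed, 2L),
                              cfg$species_params)
  list(cfg = cfg, env = env, species = species)
}
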