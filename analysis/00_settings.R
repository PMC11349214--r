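# Shared settings for the analysis workflow. Each numbered script can be run
# on its own (earlier outputs are rebuilt on demand) from the repository root:
#   Rscript analysis/01_simulate_cohort.R
suppressMessages(library(copdgraph))

SEED <- 20260927L
RESULTS <- "results"
COHORT_DIR <- file.path(RESULTS, "cohort")
GRAPH_DIR <- file.path(RESULTS, "graph")
MODEL_DIR <- file.path(RESULTS, "models")
for (d in c(RESULTS, COHORT_DIR, GRAPH_DIR, MODEL_DIR))
  dir.create(d, showWarnings = FALSE, recursive = TRUE)

# study conditions: 2,114 training subjects, ~20.3% leaving GOLD 0,
# 30 mixed baseline variables, 3 latent confounders, 6 informative variables
study_spec <- function() cohort_spec(n_subjects = 2114, n_observed = 30,
                                     n_latent = 3, mb_size = 6,
                                     minority_rate = 0.203,
                                     missing_rate = 0.03, seed = SEED)

regenerate_cohort <- function() {
  co <- make_copd_like(study_spec(), include_derived = TRUE)
  saveRDS_safe <- NULL  # plain-text artifacts only; rebuild in memory instead
  co
}
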