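# Generate the synthetic GOLD 0 cohort with known causal ground truth.
#
# The generator emulates the study's training table: mixed continuous and
# categorical baseline variables (spirometry, CT-derived and demographic
# analogs, SNP-like 3-level categoricals), latent confounders, two latent
# follow-up spirometric axes whose thresholds (FEV1/FVC < 0.70,
# FEV1 %pred < 0.80) define the binary outcome, a ~20.3% event rate, and
# MCAR missingness for the imputation stage.
source("analysis/00_settings.R")

co <- regenerate_cohort()
paths <- write_dataset(co$data, file.path(COHORT_DIR, "training.csv"))

truth <- co$truth
edges <- data.frame(parent = rep(names(truth$dag$parents),
                                 lengths(truth$dag$parents)))
edges$child <- rep(names(truth$dag$parents), lengths(truth$dag$parents))
edges <- do.call(rbind, lapply(names(truth$dag$parents), function(ch)
  if (length(truth$dag$parents[[ch]]))
    data.frame(parent = truth$dag$parents[[ch]], child = ch) else NULL))
edges$latent <- edges$parent %in% truth$dag$nodes$name[truth$dag$nodes$kind == "latent"]
utils::write.table(edges, file.path(COHORT_DIR, "truth_edges.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(truth$mb, file.path(COHORT_DIR, "true_markov_blanket.txt"))

ext <- make_copd_like(cohort_spec(n_subjects = 150, n_observed = 12,
                                  minority_rate = 0.167, seed = SEED + 1))
write_dataset(ext$data, file.path(COHORT_DIR, "external.csv"))

y <- outcome_vector(co$data)
cat(sprintf("training cohort: %d subjects, %d variables, %.1f%% leave GOLD 0\n",
            n_subjects(co$data), ncol(co$data$values) - 1, 100 * mean(y)))
cat(sprintf("external cohort: %d subjects, %.1f%% leave GOLD 0\n",
            n_subjects(ext$data), 100 * mean(outcome_vector(ext$data))))
cat("true Markov blanket:", paste(truth$mb, collapse = ", "), "\n")
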