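# Predictive models of leaving GOLD 0: the blanket-restricted logistic model
# (with its coefficient table and axis-specific subgroup refits) against an
# all-variable random forest and elastic net; Shapley attributions rank the
# forest's features.
source("analysis/00_settings.R")

data <- read_dataset(file.path(COHORT_DIR, "limited_spirometry.csv"))
sel <- jsonlite::read_json(file.path(GRAPH_DIR, "selection.json"),
                           simplifyVector = TRUE)
mb <- sel$markov_blanket

fit <- fit_logistic(data, mb)
cat("blanket-restricted logistic model:\n")
print(fit$coefficients, digits = 3)
utils::write.csv(fit$coefficients, file.path(MODEL_DIR, "logistic_coefficients.csv"),
                 row.names = FALSE)

# subgroup models need the generative subtype labels (obstruction vs PRISm)
co <- regenerate_cohort()
sub <- fit_subgroup_models(data, intersect(mb, variables(data)), co$truth$subtype)
utils::write.csv(sub$copd_fit$coefficients,
                 file.path(MODEL_DIR, "copd_specific_coefficients.csv"), row.names = FALSE)
utils::write.csv(sub$prism_fit$coefficients,
                 file.path(MODEL_DIR, "prism_specific_coefficients.csv"), row.names = FALSE)
cat("\nobstruction-specific vs PRISm-specific fits written\n")
if ("pi10" %in% mb)
  cat(sprintf("pi10 p-values: %.3g (COPD-specific), %.3g (PRISm-specific)\n",
              sub$copd_fit$coefficients$p_value[sub$copd_fit$coefficients$term == "pi10"],
              sub$prism_fit$coefficients$p_value[sub$prism_fit$coefficients$term == "pi10"]))

rf <- fit_random_forest(data, n_folds = 10, seed = SEED + 3)
en <- fit_elastic_net(data, n_folds = 10, seed = SEED + 4)
mb_auc <- max(utils::read.csv(file.path(GRAPH_DIR, "alpha_selection.csv"))$mean_val_auroc)
cat(sprintf("cross-validated AUROC: logistic (MB) %.3f, random forest %.3f, elastic net %.3f\n",
            mb_auc, rf$auroc$train_mean, en$auroc$train_mean))

phi <- shapley_importance(rf, data, n_mc = 50, seed = SEED + 5, subjects = 1:200)
imp <- attr(phi, "importance")
utils::write.csv(data.frame(variable = names(imp), mean_abs_shapley = unname(imp)),
                 file.path(MODEL_DIR, "rf_shapley_importance.csv"), row.names = FALSE)
cat("top forest features by mean |Shapley|:",
    paste(utils::head(names(imp), 5), collapse = ", "), "\n")
jsonlite::write_json(list(random_forest = rf$auroc, elastic_net = en$auroc,
                          rf_tuning = rf$tuning),
                     file.path(MODEL_DIR, "comparators.json"),
                     auto_unbox = TRUE, digits = NA)
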