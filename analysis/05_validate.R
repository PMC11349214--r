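# Validation: held-out performance on fresh subjects from the same ground
# truth, comparison against the generative Bayes bound, evaluation on the
# small external-style cohort, and the refit-without-Pi10 transfer check
# (the external table lacks the airway-wall variable).
source("analysis/00_settings.R")

data <- read_dataset(file.path(COHORT_DIR, "limited_spirometry.csv"))
sel <- jsonlite::read_json(file.path(GRAPH_DIR, "selection.json"),
                           simplifyVector = TRUE)
mb <- sel$markov_blanket
fit <- fit_logistic(data, mb)

co <- regenerate_cohort()
fresh <- simulate_from_truth(co$truth, 20000, seed = SEED + 6)
y_fresh <- outcome_vector(fresh$data)
test_auc <- auroc(predict(fit, fresh$data), y_fresh)

big <- simulate_from_truth(co$truth, 1e5, seed = SEED + 7)
bayes_auc <- auroc(bayes_risk(co$truth, big$data), outcome_vector(big$data))
cat(sprintf("held-out AUROC %.3f vs generative Bayes bound %.3f\n",
            test_auc, bayes_auc))

rc <- roc_curve(predict(fit, fresh$data), y_fresh)
utils::write.csv(data.frame(threshold = rc$thresholds,
                            sensitivity = rc$sensitivity,
                            one_minus_specificity = rc$fpr),
                 file.path(MODEL_DIR, "roc_heldout.csv"), row.names = FALSE)

res <- list(test_auroc = test_auc, bayes_auroc = bayes_auc)
if ("pi10" %in% mb && length(mb) > 1) {
  refit <- refit_without(fit, "pi10", data, fresh$data)
  res$test_auroc_without_pi10 <- refit$auroc$validation
  cat(sprintf("refit without pi10: held-out AUROC %.3f (change %+.3f)\n",
              refit$auroc$validation, refit$auroc$validation - test_auc))
}
jsonlite::write_json(res, file.path(MODEL_DIR, "validation.json"),
                     auto_unbox = TRUE, digits = NA)
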