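# Data-quality ladder: sparse-category merging, variable filtering
# (constants, duplicates, missingness, correlated pairs), Gower-KNN
# imputation (k = 5), and construction of the limited-spirometry and
# no-spirometry variable sets.
source("analysis/00_settings.R")

data <- read_dataset(file.path(COHORT_DIR, "training.csv"))

data <- merge_sparse_categories(data, min_count = 10)
fl <- filter_variables(data, missing_max = 0.2, min_category_count = 10,
                       corr_max = 0.9)
cat(sprintf("filtering: retained %d variables, dropped %d\n",
            fl$report$retained_count, nrow(fl$report$dropped)))
if (nrow(fl$report$dropped)) print(table(fl$report$dropped$reason))
jsonlite::write_json(list(dropped = fl$report$dropped,
                          correlation_pairs = fl$report$correlation_pairs),
                     file.path(COHORT_DIR, "filter_report.json"),
                     auto_unbox = TRUE, digits = NA)

imp <- knn_impute(fl$data, k = 5)
cat(sprintf("imputation: %d cells filled\n", sum(imp$mask)))

sets <- make_variable_sets(imp)
write_dataset(sets$limited_spirometry, file.path(COHORT_DIR, "limited_spirometry.csv"))
write_dataset(sets$no_spirometry, file.path(COHORT_DIR, "no_spirometry.csv"))
cat(sprintf("variable sets: limited %d, no-spirometry %d columns\n",
            ncol(sets$limited_spirometry$values), ncol(sets$no_spirometry$values)))
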