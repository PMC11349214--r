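#' Configuration-driven end-to-end pipeline
#'
#' Ties the stages into one reproducible run: (optional) synthetic-cohort
#' simulation, quality filtering and imputation, variable-set construction,
#' nested cross-validation with Markov-blanket logistic modeling, comparator
#' models, and plain-text artifacts plus a content-addressed manifest.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{out_dir}{output directory (created if absent; required)}
#'     \item{input, meta}{paths of an existing cohort CSV + metadata sidecar;
#'       omit to simulate}
#'     \item{simulate}{list of [cohort_spec()] arguments (used when no input
#'       is given)}
#'     \item{variant}{`"limited_spirometry"` (default) or `"no_spirometry"`}
#'     \item{missing_max, corr_max, min_category_count, k_impute}{preprocessing
#'       thresholds (defaults 0.2, 0.9, 10, 5)}
#'     \item{grid_n, grid_min, grid_max}{alpha grid (defaults 10, 1e-5, 1e-1)}
#'     \item{n_folds}{folds (default 10)}
#'     \item{lambda}{MGM penalty override (optional)}
#'     \item{models}{character subset of `c("logistic", "random_forest",
#'       "elastic_net")`}
#'     \item{seed}{integer seed (required: no silent nondeterminism)}
#'   }
#' @return the run manifest (list, also written as `manifest.json`):
#'   config echo, per-stage output files with MD5 checksums, warnings
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  if (is.null(config$seed)) stop("config$seed is mandatory")
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, stages = list(), warnings = character(0))
  artifact <- function(stage, file) {
    manifest$stages[[stage]] <<- c(manifest$stages[[stage]],
                                   stats::setNames(unname(tools::md5sum(file)), basename(file)))
    file
  }

  # stage: simulate or read
  if (!is.null(config$input)) {
    data <- read_dataset(config$input, config$meta)
    truth <- NULL
  } else {
    spec <- do.call(cohort_spec, c(config$simulate %||% list(), list(seed = seed)))
    cohort <- make_copd_like(spec, include_derived = TRUE)
    data <- cohort$data
    truth <- cohort$truth
    paths <- write_dataset(data, file.path(out_dir, "cohort.csv"))
    artifact("simulate", paths[["table"]]); artifact("simulate", paths[["meta"]])
    el <- data.frame(child = rep(names(truth$dag$parents), lengths(truth$dag$parents)),
                     parent = unlist(truth$dag$parents))
    gf <- file.path(out_dir, "truth_graph.tsv")
    utils::write.table(el[, c("parent", "child")], gf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifact("simulate", gf)
  }

  # stage: preprocess
  data <- merge_sparse_categories(data, config$min_category_count %||% 10)
  fl <- filter_variables(data,
                         missing_max = config$missing_max %||% 0.2,
                         min_category_count = config$min_category_count %||% 10,
                         corr_max = config$corr_max %||% 0.9)
  data <- fl$data
  rep_file <- file.path(out_dir, "filter_report.json")
  jsonlite::write_json(list(dropped = fl$report$dropped,
                            retained_count = fl$report$retained_count,
                            correlation_pairs = fl$report$correlation_pairs),
                       rep_file, auto_unbox = TRUE, digits = NA)
  artifact("preprocess", rep_file)
  if (anyNA(data$values)) data <- knn_impute(data, k = config$k_impute %||% 5)

  variant <- config$variant %||% "limited_spirometry"
  sets <- make_variable_sets(data)
  data <- sets[[variant]]
  if (is.null(data)) stop("unknown variant: ", variant)

  # stage: nested CV + final Markov-blanket model
  grid <- alpha_grid(config$grid_n %||% 10, config$grid_min %||% 1e-5,
                     config$grid_max %||% 1e-1)
  cv <- nested_cv(data, grid = grid, n_folds = config$n_folds %||% 10,
                  seed = child_seed(seed, 2L), lambda = config$lambda)
  write_pag(cv$final_pag, file.path(out_dir, "pag.tsv"))
  artifact("graph", file.path(out_dir, "pag.tsv"))
  stab_file <- file.path(out_dir, "stability.csv")
  utils::write.csv(as.data.frame(cv$stability$counts), stab_file)
  artifact("analyze", stab_file)
  coef_file <- file.path(out_dir, "coefficients.csv")
  utils::write.csv(cv$final_fit$coefficients, coef_file, row.names = FALSE)
  artifact("analyze", coef_file)
  fitj <- file.path(out_dir, "fit.json")
  jsonlite::write_json(list(selected_alpha = cv$selected_alpha,
                            markov_blanket = cv$final_mb$members,
                            cv_auroc_mean = unname(cv$mean_auroc),
                            grid = grid,
                            auroc = cv$final_fit$auroc,
                            n_ci_tests = cv$n_tests),
                       fitj, auto_unbox = TRUE, digits = NA)
  artifact("analyze", fitj)

  # stage: comparator models
  models <- config$models %||% "logistic"
  scores <- list()
  if ("random_forest" %in% models) {
    rf <- fit_random_forest(data, n_folds = config$n_folds %||% 10,
                            seed = child_seed(seed, 3L))
    scores$random_forest <- rf$auroc
  }
  if ("elastic_net" %in% models) {
    en <- fit_elastic_net(data, n_folds = config$n_folds %||% 10,
                          seed = child_seed(seed, 4L))
    scores$elastic_net <- en$auroc
  }
  if (length(scores)) {
    cmp_file <- file.path(out_dir, "comparators.json")
    jsonlite::write_json(scores, cmp_file, auto_unbox = TRUE, digits = NA)
    artifact("models", cmp_file)
  }

  manifest$stages <- lapply(manifest$stages, as.list)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
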