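#' Markov blanket extraction and outcome prediction
#'
#' The outcome's Markov blanket is read off a learned partial ancestral
#' graph, selected inside a nested cross-validation over the CI-test level
#' alpha by validation AUROC, and used as the feature set of a logistic
#' model; all-variable random forests and elastic nets serve as comparators.
#'
#' @name mb_predict
NULL

#' The logarithmic significance-level grid
#'
#' Ten levels logarithmically spaced between `1e-5` and `1e-1` by default.
#'
#' @param n number of levels
#' @param min,max grid end points
#' @return ascending numeric vector
#' @export
alpha_grid <- function(n = 10, min = 1e-5, max = 1e-1) {
  stopifnot(n >= 2, min > 0, max > min)
  10^seq(log10(min), log10(max), length.out = n)
}

#' Markov blanket of a target in a PAG
#'
#' Members are the nodes adjacent to the target plus the possible spouses:
#' any `x` with an edge `x *-> c` (definite arrowhead at `c`) into a possible
#' child `c` of the target, where a possible child is a neighbor whose
#' target-side edge carries an arrowhead or a circle at `c` (circles are
#' treated permissively, favoring recall).
#'
#' @param pag a `pag`
#' @param target node name
#' @return object of class `markov_blanket`: `target`, `members` (sorted),
#'   `edges` (induced PAG edge list)
#' @export
extract_mb <- function(pag, target) {
  stopifnot(target %in% pag$nodes)
  M <- pag$M
  nodes <- pag$nodes
  adj <- nodes[M[target, ] > 0]
  kids <- nodes[M[target, ] %in% c(1L, 2L)]      # possible children
  spouses <- character(0)
  for (cc in kids) {
    sp <- nodes[M[, cc] == 2L & nodes != target & nodes != cc]
    spouses <- union(spouses, sp[M[cc, match(sp, nodes)] > 0 | TRUE])
  }
  members <- sort(setdiff(union(adj, spouses), target))
  sub <- c(members, target)
  e <- pag_edges(pag)
  e <- e[e$a %in% sub & e$b %in% sub, , drop = FALSE]
  structure(list(target = target, members = members, edges = e),
            class = "markov_blanket")
}

#' @export
print.markov_blanket <- function(x, ...) {
  cat("<markov_blanket> of ", x$target, ": ",
      if (length(x$members)) paste(x$members, collapse = ", ") else "(empty)",
      "\n", sep = "")
  invisible(x)
}

#' Area under the ROC curve (concordance form)
#'
#' Mann-Whitney concordance probability with ties counted 1/2; identical to
#' the trapezoidal area under the ROC curve.
#'
#' @param scores numeric risk scores
#' @param labels binary labels (0/1 or logical)
#' @return area in `[0, 1]`
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("auroc undefined: both classes must be present")
  (sum(rank(scores)[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve with trapezoidal area
#'
#' @param scores numeric risk scores
#' @param labels binary labels
#' @return object of class `roc_curve`: data.frame `thresholds`,
#'   `sensitivity`, `fpr` (1 - specificity), plus attribute-free `area`
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("roc_curve undefined: both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pos <- scores >= thr[i]
    sens[i] <- sum(pos & labels == 1) / n1
    fpr[i] <- sum(pos & labels == 0) / n0
  }
  area <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(list(thresholds = thr, sensitivity = sens, fpr = fpr, area = area),
            class = "roc_curve")
}

# ---- design matrices -------------------------------------------------------

# reference-coded design over `features`; continuous columns standardized
# with (frozen) centers/scales
build_design <- function(data, features, scaling = NULL) {
  stopifnot(all(features %in% names(data$values)))
  cols <- list(); terms <- character(0)
  centers <- scales <- stats::setNames(numeric(0), character(0))
  for (v in features) {
    x <- data$values[[v]]
    if (is.numeric(x)) {
      ctr <- if (!is.null(scaling)) scaling$center[[v]] else mean(x)
      scl <- if (!is.null(scaling)) scaling$scale[[v]] else stats::sd(x)
      if (!is.finite(scl) || scl < 1e-12) scl <- 1
      cols[[length(cols) + 1]] <- (x - ctr) / scl
      terms <- c(terms, v)
      centers[v] <- ctr; scales[v] <- scl
    } else {
      lev <- levels(x)
      for (l in lev[-1]) {
        cols[[length(cols) + 1]] <- as.numeric(x == l)
        terms <- c(terms, paste0(v, " [", l, "]"))
      }
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else matrix(0, nrow(data$values), 0)
  colnames(X) <- terms
  list(X = X, terms = terms,
       scaling = list(center = centers, scale = scales))
}

ridge_irls <- function(X, y, lambda = 1e-4, max_iter = 50) {
  q <- ncol(X)
  beta <- rep(0, q)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-8)
    H <- crossprod(X, X * w) + diag(lambda, q)
    g <- crossprod(X, y - p) - lambda * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  list(beta = beta, vcov = solve(crossprod(X, X * pmax(stats::plogis(drop(X %*% beta)) *
         (1 - stats::plogis(drop(X %*% beta))), 1e-8)) + diag(lambda, q)))
}

#' Logistic regression on a feature subset
#'
#' Maximum-likelihood fit with standardized continuous predictors and
#' reference-coded categorical predictors; the coefficient table reports the
#' estimate, Wald SE and p-value per term. On (quasi-)separation the fit is
#' stabilized by a small ridge penalty (`1e-4`) and flagged.
#'
#' @param data a complete `mixed_dataset` with a binary outcome
#' @param features character vector of predictor variables (may be empty:
#'   intercept-only model)
#' @param scaling optional frozen standardization (from a training fit)
#' @return object of class `fit_result` with `model_kind = "logistic"`,
#'   `features`, `coefficients` (data.frame `term`, `estimate`, `se`,
#'   `p_value`), `auroc` (in-sample), `separation` flag
#' @export
fit_logistic <- function(data, features = character(0), scaling = NULL) {
  y <- outcome_vector(data)
  des <- build_design(data, features, scaling)
  X <- cbind(`(Intercept)` = 1, des$X)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  separated <- any(abs(beta) > 12) || !fit$converged
  if (separated) {
    rr <- ridge_irls(X, y, lambda = 1e-4)
    beta <- drop(rr$beta)
    se <- sqrt(diag(rr$vcov))
  } else {
    p <- stats::plogis(drop(X %*% beta))
    w <- pmax(p * (1 - p), 1e-10)
    Hi <- tryCatch(solve(crossprod(X, X * w)), error = function(e) {
      solve(crossprod(X, X * w) + diag(1e-8, ncol(X)))
    })
    se <- sqrt(diag(Hi))
  }
  z <- beta / se
  coefs <- data.frame(term = colnames(X), estimate = unname(beta),
                      se = unname(se),
                      p_value = unname(2 * stats::pnorm(-abs(z))),
                      stringsAsFactors = FALSE)
  scores <- stats::plogis(drop(X %*% beta))
  structure(list(model_kind = "logistic", features = features,
                 coefficients = coefs, beta = beta, scaling = des$scaling,
                 outcome = data$outcome,
                 auroc = list(train = auroc(scores, y)),
                 separation = separated),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$model_kind, " on ",
      length(x$features), " feature(s)\n", sep = "")
  if (!is.null(x$coefficients)) print(x$coefficients, digits = 3)
  cat("AUROC:", paste(names(x$auroc), vapply(x$auroc, function(a) sprintf("%.3f", a), ""),
                      sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Predict event probabilities from a fitted model
#'
#' @param object a `fit_result`
#' @param newdata a `mixed_dataset` containing the model's features
#' @param ... unused
#' @return numeric vector of event probabilities
#' @export
predict.fit_result <- function(object, newdata, ...) {
  switch(object$model_kind,
    logistic = {
      des <- build_design(newdata, object$features, object$scaling)
      X <- cbind(1, des$X)
      stats::plogis(drop(X %*% object$beta))
    },
    random_forest = {
      df <- newdata$values[, object$features, drop = FALSE]
      pr <- stats::predict(object$model, data = df)$predictions
      pr[, object$event_level]
    },
    elastic_net = {
      des <- build_design(newdata, object$features, object$scaling)
      drop(stats::predict(object$model, newx = des$X, s = object$penalty,
                          type = "response"))
    },
    stop("unknown model kind: ", object$model_kind))
}

#' Subgroup-specific logistic models (COPD-type and PRISm-type leavers)
#'
#' Refits the Markov-blanket logistic model on two event definitions: the
#' COPD-specific model contrasts subjects whose FEV1/FVC fell below 0.70
#' against those who stayed in GOLD 0, the PRISm-specific model contrasts
#' subjects whose FEV1 %predicted fell below 0.80 with preserved ratio
#' against the same controls.
#'
#' @param data a complete `mixed_dataset` (the full cohort)
#' @param features predictor variables
#' @param subtype character vector per subject in
#'   `{"none", "copd", "prism"}` (e.g. `truth$subtype` from
#'   [make_copd_like()])
#' @param min_events minimum events per subgroup (default 10)
#' @return list with `copd_fit` and `prism_fit` (`fit_result`s)
#' @export
fit_subgroup_models <- function(data, features, subtype, min_events = 10) {
  stopifnot(length(subtype) == nrow(data$values))
  one <- function(event_type) {
    keep <- subtype %in% c("none", event_type)
    if (sum(subtype == event_type) < min_events)
      stop("subgroup '", event_type, "' has fewer than ", min_events, " events")
    sub <- md_subset(data, rows = which(keep))
    lev <- levels(sub$values[[sub$outcome]])
    oc <- factor(ifelse(subtype[keep] == event_type, lev[2], lev[1]), levels = lev)
    sub$values[[sub$outcome]] <- oc
    fit_logistic(sub, features)
  }
  list(copd_fit = one("copd"), prism_fit = one("prism"))
}

#' Random forest comparator on all variables
#'
#' Probability forest over every non-outcome variable; the tree count and the
#' per-split feature count are tuned on stratified folds by out-of-fold
#' AUROC, and the out-of-fold AUROC of the winning configuration is reported.
#'
#' @param data a complete `mixed_dataset`
#' @param n_folds folds for tuning (default 10)
#' @param seed integer seed
#' @param num_trees,mtry candidate grids (defaults: 250/500 trees;
#'   `sqrt(p)` and `p/3` features per split)
#' @return a `fit_result` with `model_kind = "random_forest"`
#' @export
fit_random_forest <- function(data, n_folds = 10, seed = 1,
                              num_trees = c(250, 500), mtry = NULL) {
  y <- outcome_vector(data)
  feats <- setdiff(names(data$values), data$outcome)
  p <- length(feats)
  if (is.null(mtry)) mtry <- unique(pmax(1, c(floor(sqrt(p)), floor(p / 3))))
  df <- data$values[, feats, drop = FALSE]
  oc <- data$values[[data$outcome]]
  folds <- stratified_folds(y, n_folds, child_seed(seed, 101L))
  grid <- expand.grid(num_trees = num_trees, mtry = mtry)
  cv_auc <- matrix(NA_real_, n_folds, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      rf <- ranger::ranger(x = df[tr, , drop = FALSE], y = oc[tr],
                           probability = TRUE,
                           num.trees = grid$num_trees[g], mtry = grid$mtry[g],
                           seed = child_seed(seed, 7L * g + f),
                           num.threads = 1)
      pr <- stats::predict(rf, data = df[!tr, , drop = FALSE])$predictions
      cv_auc[f, g] <- auroc(pr[, levels(oc)[2]], y[!tr])
    }
  }
  best <- which.max(colMeans(cv_auc))
  model <- ranger::ranger(x = df, y = oc, probability = TRUE,
                          num.trees = grid$num_trees[best], mtry = grid$mtry[best],
                          seed = child_seed(seed, 999L), num.threads = 1)
  structure(list(model_kind = "random_forest", features = feats,
                 coefficients = NULL, model = model,
                 event_level = levels(oc)[2],
                 tuning = cbind(grid, mean_auc = colMeans(cv_auc)),
                 auroc = list(train_mean = mean(cv_auc[, best]),
                              train_sd = stats::sd(cv_auc[, best])),
                 outcome = data$outcome),
            class = "fit_result")
}

#' Elastic net comparator on all variables
#'
#' Logistic elastic net over every non-outcome variable; the mixing parameter
#' and the penalty are tuned on the same stratified folds by
#' cross-validated AUROC.
#'
#' @param data a complete `mixed_dataset`
#' @param n_folds folds for tuning
#' @param seed integer seed
#' @param mixing candidate elastic-net mixing values (1 = lasso)
#' @param penalty optional fixed penalty (skips tuning)
#' @return a `fit_result` with `model_kind = "elastic_net"`; `features`
#'   lists the variables with a nonzero coefficient
#' @export
fit_elastic_net <- function(data, n_folds = 10, seed = 1,
                            mixing = c(0.25, 0.5, 0.75, 1), penalty = NULL) {
  y <- outcome_vector(data)
  feats <- setdiff(names(data$values), data$outcome)
  des <- build_design(data, feats)
  folds <- stratified_folds(y, n_folds, child_seed(seed, 303L))
  best <- list(auc = -Inf)
  for (mx in mixing) {
    if (is.null(penalty)) {
      cv <- with_seed(child_seed(seed, round(1000 * mx)), {
        glmnet::cv.glmnet(des$X, y, family = "binomial", alpha = mx,
                          foldid = folds, type.measure = "auc")
      })
      auc <- max(cv$cvm)
      lam <- cv$lambda[which.max(cv$cvm)]
      mod <- cv$glmnet.fit
    } else {
      mod <- glmnet::glmnet(des$X, y, family = "binomial", alpha = mx,
                            lambda = penalty)
      lam <- penalty
      auc <- auroc(drop(stats::predict(mod, newx = des$X, s = lam,
                                       type = "response")), y)
    }
    if (auc > best$auc) best <- list(auc = auc, mixing = mx, penalty = lam, model = mod)
  }
  cf <- as.matrix(stats::coef(best$model, s = best$penalty))[-1, 1]
  active_terms <- names(cf)[cf != 0]
  active_vars <- unique(sub(" \\[.*$", "", active_terms))
  structure(list(model_kind = "elastic_net", features = feats,
                 active = intersect(feats, active_vars),
                 coefficients = data.frame(term = c("(Intercept)", names(cf)),
                                           estimate = c(as.matrix(stats::coef(best$model, s = best$penalty))[1, 1], unname(cf)),
                                           se = NA_real_, p_value = NA_real_,
                                           stringsAsFactors = FALSE),
                 model = best$model, penalty = best$penalty, mixing = best$mixing,
                 scaling = des$scaling,
                 auroc = list(train_mean = if (is.null(penalty)) best$auc else NA_real_),
                 outcome = data$outcome),
            class = "fit_result")
}

#' Monte-Carlo Shapley feature attributions
#'
#' Permutation-sampling estimate of each feature's contribution to each
#' subject's predicted event probability, with the training data as
#' background: for every draw a random feature permutation and a random
#' background record are taken, and the prediction change from switching
#' each feature (in permutation order) from the background value to the
#' subject's value is credited to that feature. Importance ranking uses the
#' mean absolute value per feature.
#'
#' @param model a `fit_result`
#' @param data a complete `mixed_dataset`: background and (by default)
#'   evaluation records
#' @param n_mc number of Monte-Carlo permutations (at least 10)
#' @param seed integer seed
#' @param subjects optional row indices to evaluate (default: all)
#' @return matrix of Shapley values (subjects x features), with attribute
#'   `"importance"` (named, sorted mean absolute values) and `"base_rate"`
#'   (mean background prediction)
#' @export
shapley_importance <- function(model, data, n_mc = 100, seed = 1,
                               subjects = NULL) {
  if (n_mc < 10) stop("n_mc must be at least 10 for usable Shapley estimates")
  feats <- model$features
  p <- length(feats)
  vals <- data$values
  if (is.null(subjects)) subjects <- seq_len(nrow(vals))
  ns <- length(subjects)
  phi <- matrix(0, ns, p, dimnames = list(NULL, feats))
  base <- 0
  with_seed(seed, {
    for (m in seq_len(n_mc)) {
      perm <- sample(p)
      bg <- sample(nrow(vals), 1)
      # build the p+1 step records for every subject in one frame
      frames <- vector("list", p + 1)
      cur <- vals[rep(bg, ns), , drop = FALSE]
      frames[[1]] <- cur
      for (s in seq_len(p)) {
        v <- feats[perm[s]]
        cur[[v]] <- vals[[v]][subjects]
        frames[[s + 1]] <- cur
      }
      stacked <- do.call(rbind, frames)
      rownames(stacked) <- NULL
      md <- data; md$values <- stacked
      md$mask <- matrix(FALSE, nrow(stacked), ncol(stacked),
                        dimnames = list(NULL, names(stacked)))
      pr <- predict.fit_result(model, md)
      pr <- matrix(pr, ns, p + 1)
      base <- base + mean(pr[, 1])
      for (s in seq_len(p))
        phi[, perm[s]] <- phi[, perm[s]] + (pr[, s + 1] - pr[, s])
    }
  })
  phi <- phi / n_mc
  imp <- sort(colMeans(abs(phi)), decreasing = TRUE)
  attr(phi, "importance") <- imp
  attr(phi, "base_rate") <- base / n_mc
  phi
}

#' Refit a model without one variable
#'
#' @param fit a `fit_result`
#' @param drop variable to remove (must be a model feature)
#' @param train complete `mixed_dataset` to refit on
#' @param eval complete `mixed_dataset` for held-out AUROC
#' @return a `fit_result` of the same kind, with `auroc$validation` on `eval`
#' @export
refit_without <- function(fit, drop, train, eval) {
  if (!drop %in% fit$features) stop("'", drop, "' is not a model feature")
  feats <- setdiff(fit$features, drop)
  if (!length(feats)) stop("refusing to refit with an empty feature set")
  new_fit <- switch(fit$model_kind,
    logistic = fit_logistic(train, feats),
    random_forest = {
      sub <- md_subset(train, cols = c(feats, train$outcome))
      fit_random_forest(sub, seed = 1)
    },
    stop("refit_without supports logistic and random_forest fits"))
  new_fit$auroc$validation <- auroc(predict.fit_result(new_fit, eval),
                                    outcome_vector(eval))
  new_fit
}

#' Markov-blanket stability table
#'
#' Counts, for every variable and significance level, the number of
#' cross-validation folds in which the variable appeared in the Markov
#' blanket at that graph sparsity.
#'
#' @param mbs data.frame with columns `fold`, `alpha`, `variable` (one row
#'   per blanket membership), e.g. `fold_mbs` from [nested_cv()]
#' @return object of class `stability_table`: `counts` matrix (variables x
#'   alpha, ordered by total count descending), `n_folds`
#' @export
stability_table <- function(mbs) {
  stopifnot(all(c("fold", "alpha", "variable") %in% names(mbs)))
  alphas <- sort(unique(mbs$alpha))
  if (nrow(mbs) == 0)
    return(structure(list(counts = matrix(0, 0, length(alphas)),
                          n_folds = 0L), class = "stability_table"))
  tab <- table(mbs$variable, factor(mbs$alpha, levels = alphas))
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = list(rownames(tab), as.character(signif(alphas, 6))))
  counts <- counts[order(-rowSums(counts), rownames(counts)), , drop = FALSE]
  structure(list(counts = counts, n_folds = max(mbs$fold)),
            class = "stability_table")
}

#' @export
print.stability_table <- function(x, ...) {
  cat("<stability_table> ", nrow(x$counts), " variables x ",
      ncol(x$counts), " sparsity levels\n", sep = "")
  print(utils::head(x$counts, 15))
  invisible(x)
}

#' Nested cross-validation over graph sparsity
#'
#' For every stratified fold and significance level: rebalance the
#' fold-training portion with SMOTE-NC, learn the PAG (MGM + FCI-max),
#' extract the outcome's Markov blanket, fit the blanket-restricted logistic
#' model, and score it on the untouched fold-validation portion. The level
#' maximizing mean validation AUROC is selected (ties to the sparser,
#' smaller level), the final model is refit on the full training data at
#' that level, and per-fold blanket memberships feed the stability table.
#' An empty blanket scores 0.5 (intercept-only model). The MGM skeleton and
#' the CI-test cache are shared across the grid within each fold.
#'
#' @param data a complete `mixed_dataset` with binary outcome
#' @param grid ascending significance levels (default [alpha_grid()])
#' @param n_folds number of folds (default 10)
#' @param seed integer seed
#' @param lambda MGM penalty (`NULL`: `lambda_scale * sqrt(log p / n)` with
#'   `n` the pre-rebalancing sample size)
#' @param lambda_scale scale of the fold-level skeleton penalty; the default
#'   0.6 keeps the outcome's true adjacencies (measured superset property)
#'   while holding the CI search tractable
#' @param max_cond,pd_path_len FCI search bounds
#' @param k_smote SMOTE-NC neighbor count
#' @param smote rebalance fold-training data (default TRUE)
#' @param verbose print per-fold progress
#' @return object of class `nested_cv_result`: `selected_alpha`, `cv_auroc`
#'   (folds x grid matrix), `mean_auroc`, `fold_mbs` (long data.frame),
#'   `stability`, `final_mb`, `final_fit` (with `auroc$train_mean/train_sd`
#'   at the selected level), `grid`, `n_tests`
#' @export
nested_cv <- function(data, grid = alpha_grid(), n_folds = 10, seed = 1,
                      lambda = NULL, lambda_scale = 0.6, max_cond = 3,
                      pd_path_len = 3, k_smote = 5, smote = TRUE,
                      verbose = FALSE) {
  stopifnot(n_folds >= 2)
  y <- outcome_vector(data)
  grid <- sort(grid)
  folds <- stratified_folds(y, n_folds, child_seed(seed, 1L))
  cv <- matrix(NA_real_, n_folds, length(grid),
               dimnames = list(NULL, as.character(signif(grid, 6))))
  mb_rows <- list()
  n_tests <- 0L
  p <- ncol(data$values)
  for (f in seq_len(n_folds)) {
    tr_idx <- which(folds != f); va_idx <- which(folds == f)
    tr <- md_subset(data, rows = tr_idx)
    va <- md_subset(data, rows = va_idx)
    # rebalancing serves the classifier only: the CI tests are likelihood
    # ratios whose null calibration an interpolated synthetic sample breaks
    # (inflated n, within-class dependence), so the graph is learned on the
    # raw fold-training data and SMOTE-NC feeds the logistic fit
    tr_fit <- if (smote) smote_nc(tr, k = k_smote, seed = child_seed(seed, 100L + f)) else tr
    lam_f <- lambda %||% (lambda_scale * sqrt(log(p) / length(tr_idx)))
    sk <- fit_mgm(tr, lambda = lam_f)$skeleton
    ci <- ci_backend(tr)
    # descending alpha: every edge separable at a denser level stays
    # separable at a sparser one, so each level prunes the previous result
    # (and the edge count is non-decreasing in alpha by construction)
    sk_cur <- sk
    seps_all <- list()
    for (g in rev(seq_along(grid))) {
      pr <- prune_skeleton(sk_cur, ci, grid[g], max_cond = max_cond,
                           pd_path_len = pd_path_len)
      sk_cur <- pr$skeleton
      seps_all[names(pr$sepsets)] <- pr$sepsets
      pag <- orient_max_p(pr$skeleton, seps_all, ci, grid[g], max_cond = max_cond,
                          max_adj = 3)
      mb <- extract_mb(pag, data$outcome)
      if (length(mb$members)) {
        fit <- fit_logistic(tr_fit, mb$members)
        cv[f, g] <- auroc(predict.fit_result(fit, va), y[va_idx])
        mb_rows[[length(mb_rows) + 1]] <-
          data.frame(fold = f, alpha = grid[g], variable = mb$members,
                     stringsAsFactors = FALSE)
      } else {
        cv[f, g] <- 0.5
      }
      if (verbose)
        message(sprintf("fold %d alpha %.1e: |MB| = %d, val AUROC = %.3f",
                        f, grid[g], length(mb$members), cv[f, g]))
    }
    n_tests <- n_tests + ci$env$count
  }
  mean_auc <- colMeans(cv)
  sel <- grid[which.max(mean_auc)]   # which.max takes the first (sparser) tie
  full_fit_data <- if (smote) smote_nc(data, k = k_smote, seed = child_seed(seed, 999L)) else data
  lam_full <- lambda %||% (lambda_scale * sqrt(log(p) / nrow(data$values)))
  pag <- learn_pag(data, sel, lambda = lam_full, max_cond = max_cond,
                   pd_path_len = pd_path_len)
  final_mb <- extract_mb(pag, data$outcome)
  final_fit <- fit_logistic(full_fit_data, final_mb$members)
  final_fit$selected_alpha <- sel
  final_fit$auroc$train_mean <- mean(cv[, which.max(mean_auc)])
  final_fit$auroc$train_sd <- stats::sd(cv[, which.max(mean_auc)])
  fold_mbs <- if (length(mb_rows)) do.call(rbind, mb_rows) else
    data.frame(fold = integer(0), alpha = numeric(0), variable = character(0))
  structure(list(selected_alpha = sel, cv_auroc = cv, mean_auroc = mean_auc,
                 fold_mbs = fold_mbs, stability = stability_table(fold_mbs),
                 final_mb = final_mb, final_fit = final_fit, final_pag = pag,
                 grid = grid, n_tests = n_tests + attr(pag, "n_tests")),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat("<nested_cv_result> selected alpha = ", format(x$selected_alpha),
      " (mean validation AUROC ", sprintf("%.3f", max(x$mean_auroc)), ")\n", sep = "")
  cat("final Markov blanket: ",
      if (length(x$final_mb$members)) paste(x$final_mb$members, collapse = ", ")
      else "(empty)", "\n", sep = "")
  invisible(x)
}
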