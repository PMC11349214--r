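#' Gower distance between two mixed-type records
#'
#' Mean over the variables observed in both records of the range-normalized
#' absolute difference (continuous) or the mismatch indicator (categorical).
#' Variables missing in either record are excluded from the mean.
#'
#' @param a,b named lists or one-row data.frames; numeric entries are treated
#'   as continuous, factors/characters as categorical
#' @param ranges named numeric vector of strictly positive ranges for every
#'   continuous variable
#' @return a distance in `[0, 1]`
#' @export
gower_distance <- function(a, b, ranges) {
  a <- as.list(a); b <- as.list(b)
  vars <- intersect(names(a), names(b))
  if (!length(vars)) stop("records share no variables")
  num <- den <- 0
  for (v in vars) {
    av <- a[[v]]; bv <- b[[v]]
    if (is.na(av) || is.na(bv)) next
    if (is.numeric(av)) {
      r <- ranges[[v]]
      if (is.null(r) || !is.finite(r) || r <= 0) stop("missing or nonpositive range for '", v, "'")
      num <- num + min(abs(av - bv) / r, 1)
    } else {
      num <- num + as.numeric(as.character(av) != as.character(bv))
    }
    den <- den + 1
  }
  if (den == 0) stop("no commonly observed variable between the two records")
  num / den
}

#' Ranges of continuous variables for Gower scaling
#'
#' @param data a `mixed_dataset`
#' @return named numeric vector (observed max - min per continuous variable);
#'   zero-range columns get range 1 so they contribute zero distance
#' @export
gower_ranges <- function(data) {
  cont <- data$meta$name[data$meta$kind == "continuous"]
  r <- vapply(cont, function(v) {
    x <- data$values[[v]]
    diff(range(x, na.rm = TRUE))
  }, 0)
  r[!is.finite(r) | r <= 0] <- 1
  r
}

# Vectorized Gower distances between the rows of A and the rows of B
# (data.frames over the same variables). NA cells are excluded pairwise.
gower_matrix <- function(A, B, ranges, exclude = character(0)) {
  vars <- setdiff(names(A), exclude)
  nA <- nrow(A); nB <- nrow(B)
  num <- matrix(0, nA, nB); den <- matrix(0, nA, nB)
  for (v in vars) {
    av <- A[[v]]; bv <- B[[v]]
    if (is.numeric(av)) {
      d <- abs(outer(av, bv, "-")) / ranges[[v]]
      d[d > 1] <- 1
    } else {
      d <- outer(as.character(av), as.character(bv), "!=") * 1
    }
    ok <- !is.na(d)
    d[!ok] <- 0
    num <- num + d
    den <- den + ok
  }
  out <- num / den
  out[den == 0] <- NA
  out
}

#' Cramer's V between two categorical variables
#'
#' `V = sqrt(chi^2 / (n * min(r - 1, c - 1)))` from the pairwise-complete
#' contingency table (no continuity correction).
#'
#' @param x,y factors (or vectors coercible to factor)
#' @return statistic in `[0, 1]`
#' @export
cramers_v <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  tab <- table(droplevels(factor(x[ok])), droplevels(factor(y[ok])))
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("Cramer's V undefined: a variable has fewer than 2 observed levels")
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  v2 <- chi2 / (n * min(nrow(tab) - 1, ncol(tab) - 1))
  sqrt(max(min(v2, 1), 0))
}

#' Screen variables for quality and redundancy
#'
#' Applies the data-quality ladder: drop variables carrying future-visit
#' information (role `"future"`), constant columns and exact duplicates,
#' columns with too many missing values, categorical columns without at least
#' two adequately populated levels, and one member of every highly correlated
#' pair (R-squared for continuous pairs, Cramer's V for categorical pairs; the
#' member with more missingness is dropped, ties going to the later column).
#' The outcome is never dropped.
#'
#' @param data a `mixed_dataset`
#' @param missing_max maximum tolerated missing fraction, in (0, 1]
#' @param min_category_count minimum level count for a categorical level to be
#'   considered populated
#' @param corr_max correlation threshold in (0, 1]
#' @return list with elements `data` (filtered `mixed_dataset`) and `report`
#'   (class `filter_report`: `dropped` data.frame with `variable`/`reason`,
#'   `retained_count`, `correlation_pairs`)
#' @export
filter_variables <- function(data, missing_max = 0.2, min_category_count = 10,
                             corr_max = 0.9) {
  stopifnot(missing_max > 0, missing_max <= 1, corr_max > 0, corr_max <= 1)
  if (!is.null(data$outcome) && anyNA(data$values[[data$outcome]]))
    stop("outcome column must be complete")
  values <- data$values; meta <- data$meta
  n <- nrow(values)
  protected <- data$outcome %||% character(0)
  dropped <- data.frame(variable = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop <- function(v, reason) {
    if (v %in% protected) return(invisible(NULL))
    dropped <<- rbind(dropped, data.frame(variable = v, reason = reason,
                                          stringsAsFactors = FALSE))
  }

  for (v in meta$name[meta$role == "future"]) drop(v, "future-info")

  live <- function() setdiff(names(values), dropped$variable)

  # constant columns and exact duplicates
  sig <- vapply(live(), function(v) paste(as.character(values[[v]]), collapse = "\r"), "")
  for (j in seq_along(sig)) {
    v <- names(sig)[j]
    x <- values[[v]]
    if (length(unique(x[!is.na(x)])) <= 1) { drop(v, "duplicate/constant"); next }
    if (j > 1 && sig[j] %in% sig[seq_len(j - 1)]) drop(v, "duplicate/constant")
  }

  miss_frac <- colMeans(is.na(values))
  for (v in live()) if (miss_frac[[v]] > missing_max) drop(v, "too-missing")

  for (v in live()) {
    if (meta$kind[meta$name == v] != "categorical") next
    cnt <- table(values[[v]])
    if (sum(cnt >= min_category_count) < 2) drop(v, "sparse-category")
  }

  # pairwise redundancy
  keep <- live()
  kinds <- stats::setNames(meta$kind, meta$name)
  pairs <- data.frame(varA = character(0), varB = character(0),
                      statistic = numeric(0), kind = character(0),
                      stringsAsFactors = FALSE)
  if (length(keep) > 1) {
    for (a_i in seq_len(length(keep) - 1)) for (b_i in (a_i + 1):length(keep)) {
      a <- keep[a_i]; b <- keep[b_i]
      if (kinds[a] != kinds[b]) next  # cont-cat screening intentionally omitted
      stat <- if (kinds[a] == "continuous") {
        r <- suppressWarnings(stats::cor(values[[a]], values[[b]],
                                         use = "pairwise.complete.obs"))
        if (is.na(r)) 0 else r^2
      } else {
        tryCatch(cramers_v(values[[a]], values[[b]]), error = function(e) 0)
      }
      if (is.finite(stat) && stat > corr_max)
        pairs <- rbind(pairs, data.frame(
          varA = a, varB = b, statistic = stat,
          kind = if (kinds[a] == "continuous") "r-squared" else "cramers-v",
          stringsAsFactors = FALSE))
    }
    if (nrow(pairs)) {
      pairs <- pairs[order(-pairs$statistic, pairs$varA, pairs$varB), , drop = FALSE]
      for (i in seq_len(nrow(pairs))) {
        a <- pairs$varA[i]; b <- pairs$varB[i]
        if (any(c(a, b) %in% dropped$variable)) next
        if (a %in% protected) { drop(b, "too-correlated"); next }
        if (b %in% protected) { drop(a, "too-correlated"); next }
        ma <- miss_frac[[a]]; mb <- miss_frac[[b]]
        loser <- if (ma > mb) a else if (mb > ma) b else {
          # tie: later column order loses
          if (match(a, names(values)) > match(b, names(values))) a else b
        }
        drop(loser, "too-correlated")
      }
    }
  }

  keep <- setdiff(names(values), dropped$variable)
  out <- md_subset(data, cols = keep)
  report <- structure(list(dropped = dropped, retained_count = length(keep),
                           correlation_pairs = pairs),
                      class = "filter_report")
  list(data = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> retained ", x$retained_count, " variables; dropped ",
      nrow(x$dropped), "\n", sep = "")
  if (nrow(x$dropped)) print(table(x$dropped$reason))
  invisible(x)
}

#' Merge sparse categorical levels
#'
#' Iteratively merges the rarest level into the next-rarest until every level
#' has at least `min_count` members and the level count is at most 3. Binary
#' variables are untouched; merged level names are the sorted constituent
#' names joined by `"+"`. A variable collapsing to a single level is flagged
#' in the `"collapsed"` attribute (for the filter stage) rather than silently
#' kept.
#'
#' @param data a `mixed_dataset`
#' @param min_count minimum members per level (>= 1)
#' @return a `mixed_dataset` with updated level sets
#' @export
merge_sparse_categories <- function(data, min_count = 10) {
  stopifnot(min_count >= 1)
  values <- data$values; meta <- data$meta
  collapsed <- character(0)
  for (j in which(meta$kind == "categorical")) {
    v <- meta$name[j]
    if (identical(v, data$outcome)) next
    x <- as.character(values[[v]])
    lev <- meta$levels[[j]]
    if (length(lev) <= 2) next
    repeat {
      cnt <- table(factor(x, levels = lev))
      if ((min(cnt) >= min_count && length(lev) <= 3) || length(lev) <= 2) break
      ord <- order(cnt, seq_along(cnt))  # rarest first, stable in level order
      rare <- lev[ord[1]]; into <- lev[ord[2]]
      merged <- paste(sort(c(rare, into)), collapse = "+")
      x[x %in% c(rare, into)] <- merged
      lev <- c(setdiff(lev, c(rare, into)), merged)
    }
    if (length(lev) <= 1 || length(unique(x[!is.na(x)])) <= 1)
      collapsed <- c(collapsed, v)
    meta$levels[[j]] <- lev
    values[[v]] <- factor(x, levels = lev)
  }
  out <- mixed_dataset(values, meta, outcome = data$outcome, mask = data$mask)
  attr(out, "collapsed") <- collapsed
  out
}

#' K-nearest-neighbor imputation with Gower distance
#'
#' Each missing cell is filled from the `k` nearest records (Gower distance on
#' the commonly observed variables) among those observed in that variable:
#' continuous cells get the unweighted neighbor mean, categorical cells the
#' neighbor mode with ties broken by smaller distance and then level order.
#' Observed cells are never altered; the returned mask still records which
#' cells were imputed.
#'
#' @param data a `mixed_dataset`
#' @param k number of donors (default 5)
#' @param ranges optional frozen Gower ranges (e.g. from the training
#'   partition); defaults to [gower_ranges()] of `data`
#' @return a complete `mixed_dataset`
#' @export
knn_impute <- function(data, k = 5, ranges = NULL) {
  stopifnot(k >= 1)
  if (is.null(ranges)) ranges <- gower_ranges(data)
  values <- data$values
  missing <- is.na(as.matrix(values))
  if (!any(missing)) return(data)
  for (v in colnames(missing)[colSums(missing) > 0]) {
    need <- which(missing[, v])
    donors <- which(!missing[, v])
    if (!length(donors)) stop("no donor records observed in '", v, "'")
    if (length(donors) < k)
      warning("only ", length(donors), " donor(s) for '", v, "' (k = ", k, ")")
    D <- gower_matrix(values[need, , drop = FALSE], values[donors, , drop = FALSE],
                      ranges, exclude = v)
    kk <- min(k, length(donors))
    dv <- data$values[[v]][donors]
    for (i in seq_along(need)) {
      d <- D[i, ]
      d[is.na(d)] <- Inf
      nn <- order(d)[seq_len(kk)]
      values[need[i], v] <- if (is.numeric(dv)) mean(dv[nn]) else {
        vals <- as.character(dv[nn])
        cnt <- table(vals)
        top <- names(cnt)[cnt == max(cnt)]
        if (length(top) == 1) top else {
          # ties: smaller Gower distance, then declared level order
          best_d <- vapply(top, function(lv) min(d[nn][vals == lv]), 0)
          cand <- top[best_d == min(best_d)]
          lev <- levels(data$values[[v]])
          cand[order(match(cand, lev))][1]
        }
      }
    }
  }
  mixed_dataset(values, data$meta, outcome = data$outcome, mask = missing | data$mask)
}

#' SMOTE-NC rebalancing of a binary outcome
#'
#' Appends synthetic minority records until the class counts are equal. Each
#' synthetic record interpolates a random minority seed record towards one of
#' its `k` nearest minority neighbors (Gower distance): continuous features
#' are `seed + u * (neighbor - seed)` with `u ~ Uniform(0, 1)`, categorical
#' features take the mode among the `k` neighbors (ties keep the seed's
#' value). Original records appear unchanged as a prefix; synthetic rows are
#' flagged in the `"synthetic"` attribute.
#'
#' @param data a complete `mixed_dataset` with a binary outcome
#' @param k number of minority neighbors (default 5)
#' @param seed integer seed
#' @return a class-balanced `mixed_dataset`
#' @export
smote_nc <- function(data, k = 5, seed = 1) {
  if (is.null(data$outcome)) stop("smote_nc needs a designated binary outcome")
  if (anyNA(data$values)) stop("smote_nc requires complete data; run knn_impute first")
  y <- data$values[[data$outcome]]
  cnt <- table(y)
  if (any(cnt == 0)) stop("both outcome classes must be present")
  if (cnt[1] == cnt[2]) {
    attr(data, "synthetic") <- rep(FALSE, nrow(data$values))
    return(data)
  }
  min_lev <- names(cnt)[which.min(cnt)]
  n_min <- min(cnt); n_new <- abs(diff(cnt))
  if (n_min <= k)
    stop("minority count (", n_min, ") must exceed k = ", k,
         "; lower k to at most ", n_min - 1)
  idx_min <- which(y == min_lev)
  ranges <- gower_ranges(data)
  feat <- setdiff(names(data$values), data$outcome)
  Xm <- data$values[idx_min, feat, drop = FALSE]
  D <- gower_matrix(Xm, Xm, ranges)
  diag(D) <- Inf
  nn_idx <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))

  synth <- with_seed(seed, {
    seeds <- sample(n_min, n_new, replace = TRUE)
    nb <- nn_idx[cbind(seeds, sample(k, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    out <- Xm[seeds, , drop = FALSE]
    for (v in feat) {
      if (is.numeric(Xm[[v]])) {
        out[[v]] <- Xm[[v]][seeds] + u * (Xm[[v]][nb] - Xm[[v]][seeds])
      } else {
        # mode among the k nearest minority neighbors; ties keep the seed value
        lev <- levels(Xm[[v]])
        codes <- matrix(as.integer(Xm[[v]])[nn_idx], nrow(nn_idx), k)
        cnt <- vapply(seq_along(lev), function(l) rowSums(codes == l),
                      numeric(nrow(nn_idx)))
        if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1)
        top <- max.col(cnt, ties.method = "first")
        unique_top <- rowSums(cnt == cnt[cbind(seq_len(nrow(cnt)), top)]) == 1
        pick <- ifelse(unique_top[seeds], top[seeds], as.integer(Xm[[v]])[seeds])
        out[[v]] <- factor(lev[pick], levels = lev)
      }
    }
    rownames(out) <- NULL
    out
  })
  synth[[data$outcome]] <- factor(min_lev, levels = levels(y))
  out_values <- rbind(data$values, synth[, names(data$values), drop = FALSE])
  rownames(out_values) <- NULL
  out <- mixed_dataset(out_values, data$meta, outcome = data$outcome)
  attr(out, "synthetic") <- c(rep(FALSE, nrow(data$values)), rep(TRUE, n_new))
  out
}

#' Build the "limited spirometry" and "no spirometry" variable sets
#'
#' The limited-spirometry set drops the outcome-defining spirometric
#' derivatives (role `"spirometry-derived"`, the FEV1/FVC-derived columns);
#' the no-spirometry set additionally drops every remaining spirometric
#' measurement (role `"spirometry"`, e.g. the FEF25-75% analog). The outcome
#' is retained in both.
#'
#' @param data a `mixed_dataset` with role annotations
#' @return list with elements `limited_spirometry` and `no_spirometry`
#' @export
make_variable_sets <- function(data) {
  roles <- data$meta$role
  if (is.null(roles) || anyNA(roles))
    stop("variable role annotations are absent or incomplete")
  keep_lim <- data$meta$name[roles != "spirometry-derived"]
  keep_nos <- data$meta$name[!(roles %in% c("spirometry-derived", "spirometry"))]
  keep_lim <- union(keep_lim, data$outcome)
  keep_nos <- union(keep_nos, data$outcome)
  list(limited_spirometry = md_subset(data, cols = intersect(names(data$values), keep_lim)),
       no_spirometry = md_subset(data, cols = intersect(names(data$values), keep_nos)))
}
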