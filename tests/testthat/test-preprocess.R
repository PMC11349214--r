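test_that("gower_distance follows the range-normalized mismatch formula", {
  a <- list(u = 2, f = factor("a", levels = c("a", "b")))
  b <- list(u = 7, f = factor("b", levels = c("a", "b")))
  expect_equal(gower_distance(a, b, c(u = 10)), (0.5 + 1) / 2)
  expect_equal(gower_distance(a, a, c(u = 10)), 0)
  # a variable missing on one side is excluded from the mean
  b_na <- b; b_na$f <- NA
  expect_equal(gower_distance(a, b_na, c(u = 10)), 0.5)
  a_na <- a; a_na$u <- NA; a_na$f <- NA
  expect_error(gower_distance(a_na, b, c(u = 10)), "commonly observed")
  expect_error(gower_distance(a, b, c(u = 0)), "range")
})

test_that("gower distances are symmetric, bounded and agree with cluster::daisy", {
  co <- small_cohort()
  vals <- co$data$values[1:40, setdiff(names(co$data$values), "dGOLD0")]
  r <- gower_ranges(md_subset(co$data, rows = 1:40))
  D <- copdgraph:::gower_matrix(vals, vals, r)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  ref <- as.matrix(cluster::daisy(vals, metric = "gower"))
  expect_equal(unname(D), unname(ref), tolerance = 1e-6)
})

test_that("cramers_v matches the chi-squared formula and is symmetric", {
  x <- factor(rep(c("a", "b"), each = 10))
  expect_equal(cramers_v(x, x), 1)
  tab <- factor(c(rep("a", 10), rep("b", 10)))
  expect_equal(cramers_v(tab, tab), 1)  # diagonal contingency table
  with_seed(1, {
    u <- factor(sample(c("a", "b"), 10000, TRUE))
    v <- factor(sample(c("a", "b"), 10000, TRUE))
    expect_lt(cramers_v(u, v), 0.05)
    expect_equal(cramers_v(u, v), cramers_v(v, u))
    chi <- suppressWarnings(stats::chisq.test(u, v, correct = FALSE)$statistic)
    expect_equal(cramers_v(u, v), sqrt(unname(chi) / 10000), tolerance = 1e-12)
  })
  expect_error(cramers_v(factor(rep("a", 5)), factor(c("x", "x", "y", "y", "y"))),
               "fewer than 2")
})

test_that("filter_variables drops constants, duplicates and correlated pairs", {
  co <- small_cohort()
  vals <- co$data$values
  vals$const <- 1
  vals$dup <- vals$age
  with_seed(2, vals$corr <- vals$height * 0.9747 +
              rnorm(nrow(vals), 0, sd(vals$height) * sqrt(1 - 0.95)))
  meta <- rbind(co$data$meta,
                data.frame(name = c("const", "dup", "corr"), kind = "continuous",
                           levels = I(list(character(0), character(0), character(0))),
                           role = "baseline"))
  md <- mixed_dataset(vals, meta, outcome = "dGOLD0")
  out <- filter_variables(md, corr_max = 0.9)
  dropped <- out$report$dropped
  expect_identical(dropped$reason[dropped$variable == "const"], "duplicate/constant")
  expect_identical(dropped$reason[dropped$variable == "dup"], "duplicate/constant")
  expect_true("corr" %in% dropped$variable)
  pair <- out$report$correlation_pairs
  hc <- pair[pair$varA %in% c("height", "corr") & pair$varB %in% c("height", "corr"), ]
  expect_equal(nrow(hc), 1)
  expect_equal(hc$statistic, 0.95, tolerance = 0.02)
  expect_true("dGOLD0" %in% variables(out$data))
  # idempotency: a second pass changes nothing
  again <- filter_variables(out$data, corr_max = 0.9)
  expect_identical(variables(again$data), variables(out$data))
})

test_that("role-tagged future-information columns are removed", {
  co <- small_cohort()
  vals <- co$data$values
  vals$fut <- rnorm(nrow(vals))
  meta <- rbind(co$data$meta,
                data.frame(name = "fut", kind = "continuous",
                           levels = I(list(character(0))), role = "future"))
  out <- filter_variables(mixed_dataset(vals, meta, outcome = "dGOLD0"))
  expect_identical(out$report$dropped$reason[out$report$dropped$variable == "fut"],
                   "future-info")
})

test_that("merge_sparse_categories enforces the 2-3 level regime", {
  n <- 1208
  x <- factor(c(rep("a", 500), rep("b", 400), rep("c", 300), rep("d", 5), rep("e", 3)),
              levels = c("a", "b", "c", "d", "e"))
  md <- mixed_dataset(data.frame(x = x, y = factor(rep(c("p", "q", "r", "s"), length.out = n))),
                      data.frame(name = c("x", "y"), kind = "categorical",
                                 levels = I(list(levels(x), c("p", "q", "r", "s")))))
  out <- merge_sparse_categories(md, min_count = 10)
  # (500, 400, 300, 5, 3): d+e merge to 8, still sparse, so they fold into c;
  # every variable ends with 2 or 3 adequately populated categories
  expect_equal(nlevels(out$values$x), 3)
  expect_true("c+d+e" %in% levels(out$values$x))
  cnt <- table(out$values$x)
  expect_true(all(cnt >= 10))
  expect_equal(nlevels(out$values$y), 3)          # 4 balanced levels: cap binds
  # binary variables untouched
  mdb <- mixed_dataset(data.frame(b = factor(c("u", "v")[c(1, 1, 1, 2)])),
                       data.frame(name = "b", kind = "categorical",
                                  levels = I(list(c("u", "v")))))
  expect_identical(merge_sparse_categories(mdb, 3)$values$b, mdb$values$b)
})

test_that("knn_impute completes data without touching observed cells", {
  # six identical records, one masked cell: imputed value is the shared value
  vals <- data.frame(u = rep(1.5, 6), f = factor(rep("a", 6), levels = c("a", "b")))
  meta <- data.frame(name = c("u", "f"), kind = c("continuous", "categorical"),
                     levels = I(list(character(0), c("a", "b"))))
  md <- mixed_dataset(vals, meta)
  md$values$u[1] <- NA; md$mask[1, "u"] <- TRUE
  out <- knn_impute(md, k = 5)
  expect_equal(out$values$u[1], 1.5)

  # k = 1 with one exact duplicate donor recovers the donor's value
  v2 <- data.frame(u = c(NA, 2, 9), w = c(5, 5, 1))
  m2 <- mixed_dataset(v2, data.frame(name = c("u", "w"), kind = "continuous"))
  out2 <- knn_impute(m2, k = 1)
  expect_equal(out2$values$u[1], 2)

  co <- small_cohort()
  masked <- inject_missing(co$data, 0.05, seed = 11)
  imp <- knn_impute(masked, k = 5)
  expect_false(anyNA(imp$values))
  obs <- !is.na(as.matrix(masked$values))
  expect_identical(as.matrix(imp$values)[obs], as.matrix(masked$values)[obs])
  # re-running on complete data is the identity
  expect_identical(knn_impute(imp, k = 5), imp)
})

test_that("knn imputation beats column-mean imputation on masked continuous cells", {
  # imputation runs on the full measured table, before the spirometric
  # derivatives are excluded, as in the processing workflow
  co <- make_copd_like(cohort_spec(n_subjects = 1000, n_observed = 12, seed = 21),
                       include_derived = TRUE)
  masked <- inject_missing(co$data, 0.05, seed = 22)
  inj <- attr(masked, "injected")
  imp <- knn_impute(masked, k = 5)
  # score the structurally related continuous block: KNN exploits
  # between-variable correlation there, whereas for the generator's
  # independent background noise the column mean is optimal by construction
  rel <- c("fef2575", "pef", "height", "pi10", "fev1pp_base", "ratio_base")
  err_knn <- err_mean <- c()
  for (v in rel) {
    idx <- which(inj$mask[, v])
    if (!length(idx)) next
    truth <- inj$original[[v]][idx]
    err_knn <- c(err_knn, imp$values[[v]][idx] - truth)
    err_mean <- c(err_mean, mean(masked$values[[v]], na.rm = TRUE) - truth)
  }
  expect_lt(sqrt(mean(err_knn^2)), sqrt(mean(err_mean^2)))
})

test_that("smote_nc balances classes by convex interpolation", {
  # training-set conditions: 430 of 2114 in the minority class
  co <- study_cohort(1)
  y <- outcome_vector(co$data)
  lev <- levels(co$data$values$dGOLD0)
  n_min <- sum(y == 1)
  out <- smote_nc(co$data, k = 5, seed = 13)
  cnt <- table(out$values$dGOLD0)
  expect_equal(unname(cnt[1]), unname(cnt[2]))     # exact balance
  # originals unchanged as a prefix; synthetic rows flagged
  expect_identical(out$values[seq_len(2114), ], co$data$values)
  flag <- attr(out, "synthetic")
  expect_identical(which(flag), seq(2115L, nrow(out$values)))
  # every synthetic continuous value lies between its seed and neighbor range
  synth <- out$values[flag, ]
  for (v in c("age", "height", "fef2575")) {
    rng <- range(co$data$values[[v]][y == 1])
    expect_true(all(synth[[v]] >= rng[1] & synth[[v]] <= rng[2]))
  }
  # already balanced input is the identity
  bal <- md_subset(co$data, rows = c(which(y == 1), which(y == 0)[seq_len(n_min)]))
  expect_identical(smote_nc(bal, seed = 1)$values, bal$values)
  expect_error(smote_nc(md_subset(co$data, rows = c(which(y == 1)[1:4], which(y == 0)[1:50])),
                        k = 5, seed = 1), "lower k")
})

test_that("variable sets drop spirometry roles but keep the outcome", {
  co <- memo("derived_cohort", make_copd_like(cohort_spec(n_subjects = 300,
                                                          n_observed = 12, seed = 9),
                                              include_derived = TRUE))
  sets <- make_variable_sets(co$data)
  lim <- sets$limited_spirometry; nos <- sets$no_spirometry
  expect_false(any(c("fev1pp_base", "ratio_base") %in% variables(lim)))
  expect_true("fef2575" %in% variables(lim))       # FEF analog survives
  expect_false(any(c("fef2575", "pef") %in% variables(nos)))
  expect_equal(ncol(lim$values) - ncol(nos$values), 2)
  expect_true(all(c(lim$outcome, nos$outcome) == "dGOLD0"))
})
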