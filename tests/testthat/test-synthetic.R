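test_that("sample_dag hits the requested Markov-blanket size exactly", {
  # brute-force MB from parents/children/co-parents, over several seeds
  for (s in 1:5) {
    d <- sample_dag(30, n_latent = 3, edge_prob = 0.15, mb_size = 6, seed = s)
    expect_length(mb_of_dag(d, "Y"), 6)
  }
  d3 <- sample_dag(3, 0, edge_prob = 1, mb_size = 2, seed = 1)
  expect_setequal(mb_of_dag(d3, "Y"), c("V1", "V2"))
  expect_error(sample_dag(5, 0, mb_size = 5, seed = 1), "infeasible")
})

test_that("sample_dag is deterministic given the seed", {
  d1 <- sample_dag(12, 2, mb_size = 4, seed = 9)
  d2 <- sample_dag(12, 2, mb_size = 4, seed = 9)
  expect_identical(d1$parents, d2$parents)
  expect_identical(d1$params, d2$params)
  d3 <- sample_dag(12, 2, mb_size = 4, seed = 10)
  expect_false(identical(d1$parents, d3$parents))
})

test_that("simulate_mixed reproduces the stated noise model", {
  # lone continuous node: sample SD within 3% of its noise SD
  d <- cont_dag("X", list(X = character(0)))
  md <- simulate_mixed(d, 10000, seed = 4)
  expect_lt(abs(sd(md$values$X) - 1), 0.03)

  # binary node with zero intercept: level frequencies 0.5 +/- 0.02
  db <- ground_truth_dag(data.frame(name = "B", kind = "categorical", levels = 2L),
                         list(B = character(0)))
  db$params$B$intercept <- c(0, 0)
  mdb <- simulate_mixed(db, 10000, seed = 5)
  expect_lt(abs(mean(mdb$values$B == "l1") - 0.5), 0.02)

  # chain X -> Y -> Z: partial correlation of (X, Z) given Y vanishes
  dc <- cont_dag(c("X", "Y", "Z"), list(Y = "X", Z = "Y"))
  dc$params$Y$coef$X <- 1; dc$params$Z$coef$Y <- 1
  mc <- simulate_mixed(dc, 5000, seed = 6)
  r <- with(mc$values, {
    rx <- residuals(lm(X ~ Y)); rz <- residuals(lm(Z ~ Y))
    cor(rx, rz)
  })
  expect_lt(abs(r), 0.05)
})

test_that("latent columns are dropped from the table but kept for debugging", {
  d <- cont_dag(c("L", "A", "B"), list(A = "L", B = "L"), latent = "L")
  md <- simulate_mixed(d, 200, seed = 1)
  expect_setequal(variables(md), c("A", "B"))
  lat <- attr(md, "latent_values")
  expect_identical(names(lat), "L")
  # projection is a column selection: observed values unchanged by latents
  expect_equal(nrow(lat), 200)
})

test_that("oracle_independent encodes d-separation including latent confounding", {
  col <- cont_dag(c("X", "Y", "Z"), list(Z = c("X", "Y")))
  expect_true(oracle_independent(col, "X", "Y"))
  expect_false(oracle_independent(col, "X", "Y", "Z"))

  lat <- cont_dag(c("L", "X", "Y"), list(X = "L", Y = "L"), latent = "L")
  expect_false(oracle_independent(lat, "X", "Y"))
  # no observed conditioning set separates a latent-confounded pair
  expect_false(oracle_independent(lat, "X", "Y", character(0)))

  ch <- cont_dag(c("X", "Y", "Z"), list(Y = "X", Z = "Y"))
  expect_false(oracle_independent(ch, "X", "Z"))
  expect_true(oracle_independent(ch, "X", "Z", "Y"))
  expect_error(oracle_independent(ch, "X", "nope"), "unknown variable")
})

test_that("partial correlations implied independent shrink like 1/sqrt(n)", {
  d <- cont_dag(c("X", "Y", "Z"), list(Y = "X", Z = "Y"))
  pcor <- function(n, seed) {
    md <- simulate_mixed(d, n, seed = seed)
    with(md$values, cor(residuals(lm(X ~ Y)), residuals(lm(Z ~ Y))))
  }
  r500 <- mean(abs(vapply(1:8, function(s) pcor(500, s), 0)))
  r5000 <- mean(abs(vapply(1:8, function(s) pcor(5000, s), 0)))
  expect_lt(r5000, r500)            # shrinks with n
  expect_lt(r5000, 3 / sqrt(5000))  # consistent with root-n scaling
})

test_that("cohort event-rate calibration holds across seeds and targets", {
  rates <- vapply(1:20, function(s) {
    mean(outcome_vector(make_copd_like(cohort_spec(n_subjects = 2114, seed = s))$data))
  }, 0)
  expect_true(all(abs(rates - 0.203) <= 0.02))

  # external-validation conditions: n = 150, 16.7% leavers -> ~25 events
  ev <- make_copd_like(cohort_spec(n_subjects = 150, n_observed = 12,
                                   minority_rate = 0.167, seed = 3))
  expect_lt(abs(sum(outcome_vector(ev$data)) - 25), 0.02 * 150 + 1)
})

test_that("the noiseless limit gives a deterministic, separable outcome", {
  # shared wiring: both axes carry the same linear signal, so the noiseless
  # outcome is one thresholded half-space and a logistic fit separates it
  co <- make_copd_like(cohort_spec(n_subjects = 800, n_observed = 12, seed = 5),
                       wiring = "shared", noise_ratio = 0)
  fit <- fit_logistic(co$data, co$truth$mb)
  expect_gt(auroc(predict(fit, co$data), outcome_vector(co$data)), 0.999)
  # study wiring is a union of two half-spaces: deterministic but not exactly
  # linearly separable
  co2 <- make_copd_like(cohort_spec(n_subjects = 800, n_observed = 12, seed = 5),
                        noise_ratio = 0)
  fit2 <- fit_logistic(co2$data, co2$truth$mb)
  expect_gt(auroc(predict(fit2, co2$data), outcome_vector(co2$data)), 0.95)
})

test_that("inject_missing masks MCAR, spares the outcome, and reproduces", {
  co <- small_cohort()
  expect_identical(inject_missing(co$data, 0), co$data)
  m1 <- inject_missing(co$data, 0.05, seed = 8)
  m2 <- inject_missing(co$data, 0.05, seed = 8)
  expect_identical(m1$values, m2$values)
  expect_false(anyNA(m1$values[[m1$outcome]]))
  n_cells <- nrow(co$data$values) * (ncol(co$data$values) - 1)
  cnt <- sum(is.na(m1$values))
  bounds <- qbinom(c(0.005, 0.995), n_cells, 0.05)
  expect_gte(cnt, bounds[1]); expect_lte(cnt, bounds[2])
  # original values are recorded so imputation error is measurable
  inj <- attr(m1, "injected")
  expect_identical(inj$original, co$data$values)
})

test_that("bayes_risk matches empirical event frequencies", {
  co <- study_cohort(1)
  big <- simulate_from_truth(co$truth, 20000, seed = 77)
  br <- bayes_risk(co$truth, big$data)
  y <- outcome_vector(big$data)
  # calibration-in-the-large and by risk decile
  expect_lt(abs(mean(br) - mean(y)), 0.01)
  dec <- cut(br, quantile(br, 0:5 / 5), include.lowest = TRUE)
  gap <- abs(tapply(br, dec, mean) - tapply(y, dec, mean))
  expect_lt(max(gap), 0.05)
})
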