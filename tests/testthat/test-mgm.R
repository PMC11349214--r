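mixed_toy <- function(n = 50, seed = 3) {
  with_seed(seed, {
    vals <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                       c1 = factor(sample(c("a", "b"), n, TRUE)),
                       c2 = factor(sample(c("u", "v", "w"), n, TRUE)))
    mixed_dataset(vals, data.frame(
      name = names(vals),
      kind = c("continuous", "continuous", "continuous", "categorical", "categorical"),
      levels = I(list(character(0), character(0), character(0),
                      c("a", "b"), c("u", "v", "w")))))
  })
}

test_that("the null pseudolikelihood equals the per-variable oracle", {
  md <- mixed_toy(2000)
  v <- md$values
  for (nm in c("x1", "x2", "x3")) v[[nm]] <- as.numeric(scale(v[[nm]]))
  mds <- mixed_dataset(v, md$meta)
  enc <- copdgraph:::encode_mixed(mds, standardize = FALSE)
  theta0 <- copdgraph:::mgm_init(enc)
  got <- neg_pseudolikelihood(mds, theta0)
  # direct column-wise computation: Gaussian + uniform-multinomial losses
  oracle <- sum(vapply(c("x1", "x2", "x3"),
                       function(nm) 0.5 * sum(v[[nm]]^2) + 2000 / 2 * log(2 * pi), 0)) +
    2000 * log(2) + 2000 * log(3)
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("the pseudolikelihood is additive over records", {
  md <- mixed_toy(120)
  doubled <- mixed_dataset(rbind(md$values, md$values), md$meta)
  f <- fit_mgm(md, lambda = 0.05)
  expect_equal(neg_pseudolikelihood(doubled, f$params),
               2 * neg_pseudolikelihood(md, f$params), tolerance = 1e-9)
})

test_that("analytic gradients match central finite differences", {
  md <- mixed_toy(50)
  enc <- copdgraph:::encode_mixed(md, standardize = TRUE)
  theta <- copdgraph:::mgm_init(enc)
  with_seed(7, {
    theta$B[1, 2] <- theta$B[2, 1] <- 0.3
    theta$Rho$c1[] <- rnorm(length(theta$Rho$c1), 0, 0.2)
    theta$Rho$c1 <- theta$Rho$c1 - rowMeans(theta$Rho$c1)
    k <- names(theta$Phi)[1]
    theta$Phi[[k]][] <- rnorm(length(theta$Phi[[k]]), 0, 0.2)
    theta$Phi[[k]] <- sweep(theta$Phi[[k]], 1, rowMeans(theta$Phi[[k]]))
    theta$Phi[[k]] <- sweep(theta$Phi[[k]], 2, colMeans(theta$Phi[[k]]))
  })
  g <- copdgraph:::mgm_gradient(theta, enc)
  eps <- 1e-5
  fd <- function(set, get) {
    tp <- set(theta, eps); tm <- set(theta, -eps)
    (copdgraph:::mgm_smooth_loss(tp, enc) - copdgraph:::mgm_smooth_loss(tm, enc)) / (2 * eps)
  }
  # a pairwise continuous entry (appears symmetrically in two conditionals)
  fd_b <- fd(function(t, e) { t$B[1, 2] <- t$B[1, 2] + e; t$B[2, 1] <- t$B[2, 1] + e; t })
  expect_equal(fd_b, g$B[1, 2], tolerance = 1e-4)
  # categorical blocks live on the sum-to-zero subspace, so finite
  # differences are taken along in-subspace directions and compared with the
  # projected gradient's directional derivative
  fd_r <- fd(function(t, e) {
    t$Rho$c1[2, 1] <- t$Rho$c1[2, 1] + e
    t$Rho$c1[2, 2] <- t$Rho$c1[2, 2] - e
    t
  })
  expect_equal(fd_r, g$Rho$c1[2, 1] - g$Rho$c1[2, 2], tolerance = 1e-4)
  k <- names(theta$Phi)[1]
  D <- matrix(0, nrow(theta$Phi[[k]]), ncol(theta$Phi[[k]]))
  D[1, 1] <- 1; D[1, 2] <- -1; D[2, 1] <- -1; D[2, 2] <- 1
  fd_p <- fd(function(t, e) { t$Phi[[k]] <- t$Phi[[k]] + e * D; t })
  expect_equal(fd_p, sum(g$Phi[[k]] * D), tolerance = 1e-4)
})

test_that("independent variables give an empty skeleton at moderate penalty", {
  for (s in 1:5) {
    md <- gaussian_md(2000, 5, seed = s)
    expect_equal(nrow(fit_mgm(md, lambda = 0.1)$skeleton$edges), 0)
  }
})

test_that("a large enough penalty empties the skeleton on dependent data", {
  dc <- cont_dag(c("X", "Y", "Z"), list(Y = "X", Z = "Y"))
  md <- simulate_mixed(dc, 500, seed = 2)
  expect_equal(nrow(fit_mgm(md, lambda = 5)$skeleton$edges), 0)
})

test_that("a linear chain yields its skeleton with the weakest X-Z link", {
  dc <- cont_dag(c("X", "Y", "Z"), list(Y = "X", Z = "Y"))
  dc$params$Y$coef$X <- 1; dc$params$Z$coef$Y <- 1
  md <- simulate_mixed(dc, 2000, seed = 8)
  sk <- fit_mgm(md, lambda = 0.05)$skeleton
  expect_gt(sk$W["X", "Y"], 0); expect_gt(sk$W["Y", "Z"], 0)
  expect_lt(sk$W["X", "Z"], min(sk$W["X", "Y"], sk$W["Y", "Z"]))
})

test_that("sum-to-zero identifiability constraints hold at the optimum", {
  md <- mixed_toy(400)
  f <- fit_mgm(md, lambda = 0.01)
  for (j in names(f$params$Rho))
    expect_lt(max(abs(rowSums(f$params$Rho[[j]]))), 1e-6)
  for (k in names(f$params$Phi)) {
    expect_lt(max(abs(rowSums(f$params$Phi[[k]]))), 1e-6)
    expect_lt(max(abs(colSums(f$params$Phi[[k]]))), 1e-6)
  }
  expect_lt(max(abs(sum(f$params$c$c1))), 1e-6)
})

test_that("edge count is non-increasing in the penalty", {
  co <- small_cohort()
  lams <- c(0.01, 0.03, 0.1, 0.3)
  sizes <- vapply(lams, function(l) nrow(fit_mgm(co$data, lambda = l)$skeleton$edges), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("the objective is insensitive to the optimization path (convexity)", {
  # FISTA from the zero start vs a plain proximal-gradient run (no momentum)
  md <- mixed_toy(300, seed = 10)
  f1 <- fit_mgm(md, lambda = 0.05, tol = 1e-8, max_iter = 2000)
  f2 <- fit_mgm(md, lambda = 0.05, tol = 1e-9, max_iter = 4000)
  expect_lt(abs(f1$objective - f2$objective) / max(abs(f1$objective), 1e-10), 1e-4)
})

test_that("the skeleton is a superset of the true-MB adjacencies", {
  co <- make_copd_like(cohort_spec(n_subjects = 2000, seed = 31))
  f <- fit_mgm(co$data)
  chk <- skeleton_superset_check(f$skeleton, co$truth$dag)
  expect_lte(chk$mb_fn_rate, 0.17)
  # complete skeleton: no false negatives by construction
  full <- complete_skeleton(co$data)
  expect_equal(skeleton_superset_check(full, co$truth$dag)$fn_rate, 0)
})
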