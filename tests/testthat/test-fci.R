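test_that("ci_test is symmetric, detects perfect dependence, respects d-separation", {
  with_seed(5, {
    n <- 1000
    x <- rnorm(n); y <- x  # duplicate
    md <- mixed_dataset(data.frame(x = x, y = y, z = rnorm(n)),
                        data.frame(name = c("x", "y", "z"), kind = "continuous"))
    r <- ci_test(md, "x", "y")
    expect_lt(r$pvalue, 1e-10)
    expect_false(r$independent)
    expect_identical(r$test_kind, "cont-cont")
    expect_equal(ci_test(md, "x", "z")$pvalue, ci_test(md, "z", "x")$pvalue)
  })
  # chain X -> Y -> Z: conditioning on Y separates in most replicates
  dc <- cont_dag(c("X", "Y", "Z"), list(Y = "X", Z = "Y"))
  indep <- vapply(1:20, function(s) {
    md <- simulate_mixed(dc, 5000, seed = s)
    ci_test(md, "X", "Z", "Y", alpha = 0.01)$independent
  }, TRUE)
  expect_gte(mean(indep), 0.95)
})

test_that("mixed-kind tests take the max of the two conditional directions", {
  co <- small_cohort()
  ci <- copdgraph:::ci_backend(co$data)
  p_sym <- ci$pvalue("sex", "age", character(0))
  p1 <- copdgraph:::ci_lrt_dir(ci, "age", "sex", character(0))$p
  p2 <- copdgraph:::ci_lrt_dir(ci, "sex", "age", character(0))$p
  expect_equal(p_sym, max(p1, p2))
  r <- ci_test(co$data, "sex", "emphysema")
  expect_identical(r$test_kind, "cat-cat")
})

test_that("collinear conditioning columns are dropped rather than fatal", {
  with_seed(9, {
    n <- 300
    a <- rnorm(n)
    md <- mixed_dataset(data.frame(a = a, b = 2 * a, x = rnorm(n), y = rnorm(n)),
                        data.frame(name = c("a", "b", "x", "y"), kind = "continuous"))
    r <- ci_test(md, "x", "y", c("a", "b"))
    expect_true(is.finite(r$pvalue))
  })
})

test_that("oracle pruning removes the shielding edge at a collider", {
  d <- cont_dag(c("X", "Y", "Z"), list(Z = c("X", "Y")))
  W <- matrix(1, 3, 3, dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  diag(W) <- 0
  pr <- prune_skeleton(skeleton_from_weights(W, 0.5), d, alpha = 0.5)
  e <- pr$skeleton$edges
  expect_equal(nrow(e), 2)
  expect_false(any(e$a == "X" & e$b == "Y"))
  expect_identical(pr$sepsets[["X|Y"]], character(0))
})

test_that("pruning an empty skeleton is the identity", {
  d <- cont_dag(c("X", "Y"), list())
  W <- matrix(0, 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  pr <- prune_skeleton(skeleton_from_weights(W, 0.5), d, alpha = 0.5)
  expect_equal(nrow(pr$skeleton$edges), 0)
  expect_equal(pr$n_tests, 0)
})

test_that("canonical structures orient to their known PAGs", {
  # collider: X o-> Z <-o Y
  d1 <- cont_dag(c("X", "Y", "Z"), list(Z = c("X", "Y")))
  p1 <- learn_pag_oracle(d1)
  expect_equal(p1$M["X", "Z"], 2L); expect_equal(p1$M["Y", "Z"], 2L)
  expect_equal(p1$M["Z", "X"], 1L); expect_equal(p1$M["Z", "Y"], 1L)
  expect_equal(p1$M["X", "Y"], 0L)

  # latent confounder with a common child: X, Y carry arrowheads at both ends
  d2 <- cont_dag(c("L", "X", "Y", "Z", "W"),
                 list(X = "L", Y = "L", Z = c("X", "W")), latent = "L")
  p2 <- learn_pag_oracle(d2)
  expect_equal(p2$M["W", "Z"], 2L)   # collider at Z from the W side
  expect_equal(p2$M["X", "Z"], 2L)
  # chain: no collider at the middle node; R1 propagates a tail-arrow pair
  d3 <- cont_dag(c("A", "B", "C", "D"), list(B = "A", C = "B", D = "C"))
  p3 <- learn_pag_oracle(d3)
  cmp <- pag_compare(p3, pag_from_dag(d3))
  expect_true(cmp$equal)
})

test_that("identical inputs give identical PAGs (deterministic search)", {
  co <- small_cohort()
  p1 <- learn_pag(co$data, 1e-3)
  p2 <- learn_pag(co$data, 1e-3)
  expect_identical(p1$M, p2$M)
  expect_identical(p1$sepsets, p2$sepsets)
})

test_that("edge count is monotone non-decreasing in alpha on fixed data", {
  co <- small_cohort()
  sk <- fit_mgm(co$data)$skeleton
  ci <- copdgraph:::ci_backend(co$data)
  grid <- alpha_grid(5)
  sizes <- integer(0); sk_cur <- sk
  for (a in rev(grid)) {
    pr <- prune_skeleton(sk_cur, ci, a)
    sk_cur <- pr$skeleton
    sizes <- c(nrow(pr$skeleton$edges), sizes)
  }
  expect_true(all(diff(sizes) >= 0))
})

test_that("every deleted edge records a separating set", {
  co <- small_cohort()
  sk <- fit_mgm(co$data)$skeleton
  pr <- prune_skeleton(sk, co$data, 1e-2)
  removed <- nrow(sk$edges) - nrow(pr$skeleton$edges)
  expect_equal(length(pr$sepsets), removed)
})

test_that("PAG serialization round-trips through the annotated edge list", {
  co <- small_cohort()
  pag <- learn_pag(co$data, 1e-3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pag(pag, path)
  back <- read_pag(path, pag$nodes)
  expect_identical(back$M[pag$nodes, pag$nodes], pag$M)
  # the serialized vocabulary stays within the mark alphabet
  e <- utils::read.table(path, sep = "\t", header = TRUE, colClasses = "character")
  expect_true(all(unlist(e[c("mark_a", "mark_b")]) %in% c("-", ">", "o")))
})

test_that("the skeleton restriction reduces the number of CI tests", {
  co <- small_cohort()
  sk <- fit_mgm(co$data)$skeleton
  ci1 <- copdgraph:::ci_backend(co$data)
  prune_skeleton(sk, ci1, 1e-3)
  ci2 <- copdgraph:::ci_backend(co$data)
  prune_skeleton(complete_skeleton(co$data), ci2, 1e-3)
  expect_lt(ci1$env$count, ci2$env$count)
})
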