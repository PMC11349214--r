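test_that("mixed_dataset validates levels, outcome and metadata coverage", {
  vals <- data.frame(a = c(1.5, 2.5), b = c("x", "y"),
                     oc = c("stay", "leave"), stringsAsFactors = FALSE)
  meta <- data.frame(name = c("a", "b", "oc"),
                     kind = c("continuous", "categorical", "categorical"))
  meta$levels <- list(character(0), c("x", "y"), c("stay", "leave"))
  md <- mixed_dataset(vals, meta, outcome = "oc")
  expect_s3_class(md$values$b, "factor")
  expect_identical(md$outcome, "oc")

  bad <- vals; bad$b[1] <- "zz"
  expect_error(mixed_dataset(bad, meta), "outside declared levels")
  expect_error(mixed_dataset(vals, meta[1:2, ]), "cover")
  bad2 <- vals; bad2$oc[2] <- NA
  expect_error(mixed_dataset(bad2, meta, outcome = "oc"), "missing")
})

test_that("dataset round-trips through CSV with empty-string missing cells", {
  co <- small_cohort()
  data <- inject_missing(co$data, 0.05, seed = 3)
  dir <- withr::local_tempdir()
  write_dataset(data, file.path(dir, "d.csv"))
  back <- read_dataset(file.path(dir, "d.csv"))
  expect_identical(back$values, data$values)
  expect_identical(back$meta$kind, data$meta$kind)
  expect_identical(back$meta$role, data$meta$role)
  expect_identical(back$outcome, data$outcome)
  expect_identical(unname(back$mask), unname(is.na(as.matrix(data$values))))
})

test_that("reading rejects level violations and metadata mismatches by name", {
  dir <- withr::local_tempdir()
  co <- small_cohort()
  paths <- write_dataset(co$data, file.path(dir, "d.csv"))
  tab <- utils::read.csv(paths[["table"]], check.names = FALSE, colClasses = "character")
  tab$sex[2] <- "unknown-level"
  utils::write.csv(tab, paths[["table"]], row.names = FALSE, na = "")
  expect_error(read_dataset(paths[["table"]], paths[["meta"]]), "sex")

  tab$sex <- NULL
  utils::write.csv(tab, paths[["table"]], row.names = FALSE, na = "")
  expect_error(read_dataset(paths[["table"]], paths[["meta"]]), "mismatch")
})

test_that("md_subset keeps values, mask and metadata aligned", {
  co <- small_cohort()
  sub <- md_subset(co$data, rows = 1:100, cols = c("age", "sex", "dGOLD0"))
  expect_equal(n_subjects(sub), 100)
  expect_identical(variables(sub), c("age", "sex", "dGOLD0"))
  expect_identical(sub$outcome, "dGOLD0")
  drop_oc <- md_subset(co$data, cols = c("age", "sex"))
  expect_null(drop_oc$outcome)
})
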