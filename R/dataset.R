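#' Mixed-type cohort dataset
#'
#' The universal currency of the pipeline: a subject-by-variable table of
#' continuous and categorical baseline measurements, per-variable metadata
#' (kind, ordered level list, role) and a missingness mask. The binary
#' follow-up outcome (loss of GOLD 0 status) is an ordinary categorical
#' column singled out by `outcome`.
#'
#' @param values data.frame; continuous columns numeric, categorical columns
#'   factor (or character coercible to the declared levels). `NA` marks a
#'   missing cell.
#' @param meta data.frame with columns `name`, `kind` (`"continuous"` or
#'   `"categorical"`), `levels` (list column of character vectors, or a
#'   pipe-separated string; empty for continuous) and `role` (one of
#'   `"baseline"`, `"outcome"`, `"spirometry"`, `"spirometry-derived"`,
#'   `"snp"`, `"future"`).
#' @param outcome name of the outcome column, or `NULL` when the table has no
#'   designated outcome. When set, the column must be binary and complete.
#' @param mask optional logical matrix (subjects x variables) of missingness;
#'   defaults to `is.na(values)`.
#'
#' @return an object of class `mixed_dataset` with elements `values`, `meta`,
#'   `mask`, `outcome`.
#' @export
mixed_dataset <- function(values, meta, outcome = NULL, mask = NULL) {
  stopifnot(is.data.frame(values), is.data.frame(meta))
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  meta <- normalize_meta(meta)
  if (anyDuplicated(names(values)))
    stop("duplicated column names: ", paste(unique(names(values)[duplicated(names(values))]), collapse = ", "))
  if (!setequal(meta$name, names(values)))
    stop("metadata does not cover the table columns exactly")
  meta <- meta[match(names(values), meta$name), , drop = FALSE]
  rownames(meta) <- NULL

  for (j in seq_along(values)) {
    kind <- meta$kind[j]
    nm <- meta$name[j]
    if (kind == "continuous") {
      if (!is.numeric(values[[j]])) values[[j]] <- as.numeric(values[[j]])
    } else {
      lev <- meta$levels[[j]]
      if (length(lev) < 1) stop("categorical variable '", nm, "' has no declared levels")
      x <- as.character(values[[j]])
      bad <- !is.na(x) & !(x %in% lev)
      if (any(bad))
        stop("variable '", nm, "' has value(s) outside declared levels at row(s) ",
             paste(utils::head(which(bad), 5), collapse = ", "))
      values[[j]] <- factor(x, levels = lev)
    }
  }
  if (is.null(mask)) {
    mask <- is.na(as.matrix(values))
  } else {
    mask <- as.matrix(mask)
    stopifnot(identical(dim(mask), dim(as.matrix(values))))
  }
  dimnames(mask) <- list(NULL, names(values))

  if (!is.null(outcome)) {
    if (!outcome %in% names(values)) stop("outcome column '", outcome, "' not in table")
    oc <- values[[outcome]]
    if (anyNA(oc)) stop("outcome column '", outcome, "' has missing values")
    if (meta$kind[meta$name == outcome] != "categorical" || nlevels(droplevels(oc)) > 2 ||
        length(meta$levels[[match(outcome, meta$name)]]) != 2)
      stop("outcome column '", outcome, "' must be binary categorical")
  }
  structure(list(values = values, meta = meta, mask = mask, outcome = outcome),
            class = "mixed_dataset")
}

normalize_meta <- function(meta) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "kind") %in% names(meta)))
  if (!"role" %in% names(meta)) meta$role <- "baseline"
  if (!"levels" %in% names(meta)) meta$levels <- replicate(nrow(meta), character(0), simplify = FALSE)
  if (!is.list(meta$levels))
    meta$levels <- lapply(meta$levels, function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]]
    })
  stopifnot(all(meta$kind %in% c("continuous", "categorical")))
  meta[, c("name", "kind", "levels", "role")]
}

#' @export
print.mixed_dataset <- function(x, ...) {
  kinds <- table(x$meta$kind)
  cat("<mixed_dataset> ", nrow(x$values), " subjects x ", ncol(x$values), " variables (",
      paste(names(kinds), kinds, sep = ": ", collapse = ", "), ")\n", sep = "")
  if (!is.null(x$outcome)) {
    oc <- x$values[[x$outcome]]
    cat("  outcome: ", x$outcome, " [", paste(levels(oc), table(oc), sep = "=", collapse = ", "), "]\n", sep = "")
  }
  cat("  missing cells: ", sum(x$mask), "\n", sep = "")
  invisible(x)
}

#' Number of subjects / variable names of a mixed dataset
#' @param data a `mixed_dataset`
#' @return integer count / character vector
#' @export
n_subjects <- function(data) nrow(data$values)

#' @rdname n_subjects
#' @export
variables <- function(data) names(data$values)

#' Subset a mixed dataset
#'
#' Row subsetting keeps all metadata; column subsetting drops metadata and mask
#' columns consistently. The outcome column is retained unless explicitly
#' dropped (then `outcome` becomes `NULL`).
#'
#' @param data a `mixed_dataset`
#' @param rows integer/logical row index (optional)
#' @param cols character vector of variable names to keep (optional)
#' @return a `mixed_dataset`
#' @export
md_subset <- function(data, rows = NULL, cols = NULL) {
  values <- data$values; mask <- data$mask; meta <- data$meta
  if (!is.null(cols)) {
    stopifnot(all(cols %in% names(values)))
    values <- values[, cols, drop = FALSE]
    mask <- mask[, cols, drop = FALSE]
    meta <- meta[match(cols, meta$name), , drop = FALSE]
  }
  if (!is.null(rows)) {
    values <- values[rows, , drop = FALSE]
    rownames(values) <- NULL
    mask <- mask[rows, , drop = FALSE]
  }
  outcome <- if (!is.null(data$outcome) && data$outcome %in% names(values)) data$outcome else NULL
  out <- mixed_dataset(values, meta, outcome = outcome, mask = mask)
  for (a in c("synthetic", "truth")) if (!is.null(attr(data, a)) && is.null(cols)) {
    v <- attr(data, a)
    if (!is.null(rows) && length(v) == nrow(data$values)) v <- v[rows]
    attr(out, a) <- v
  }
  out
}

is_continuous <- function(data) data$meta$kind == "continuous"

#' Binary outcome as a 0/1 vector
#'
#' The second declared outcome level (the event, e.g. leaving GOLD 0) maps
#' to 1.
#'
#' @param data a `mixed_dataset` with a designated outcome
#' @return integer vector of 0/1
#' @export
outcome_vector <- function(data) {
  if (is.null(data$outcome)) stop("dataset has no designated outcome")
  oc <- data$values[[data$outcome]]
  as.integer(oc == levels(oc)[2])
}

#' Write / read a mixed dataset as delimited text
#'
#' The on-disk form is a UTF-8 CSV with a header row and empty cells for
#' missing values, plus a variable-metadata sidecar CSV with columns
#' `name,kind,levels,role` (levels pipe-separated) and an `outcome` marker row
#' flagged through role `outcome`.
#'
#' @param data a `mixed_dataset`
#' @param table_path path of the data CSV
#' @param meta_path path of the metadata CSV (default: `<table>_meta.csv`)
#' @return `write_dataset` returns the paths invisibly; `read_dataset` a
#'   `mixed_dataset`.
#' @export
write_dataset <- function(data, table_path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.csv$", "_meta.csv", table_path)
  out <- data$values
  for (j in seq_along(out)) {
    if (is.factor(out[[j]])) out[[j]] <- as.character(out[[j]])
    # full precision so numeric values survive the text round-trip exactly
    else if (is.numeric(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  utils::write.csv(out, table_path, row.names = FALSE, na = "")
  meta <- data$meta
  flat <- data.frame(
    name = meta$name, kind = meta$kind,
    levels = vapply(meta$levels, paste, "", collapse = "|"),
    role = meta$role,
    outcome = meta$name %in% data$outcome,
    stringsAsFactors = FALSE
  )
  utils::write.csv(flat, meta_path, row.names = FALSE, na = "")
  invisible(c(table = table_path, meta = meta_path))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(table_path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.csv$", "_meta.csv", table_path)
  if (!file.exists(table_path)) stop("no such file: ", table_path)
  if (!file.exists(meta_path)) stop("no such file: ", meta_path)
  flat <- utils::read.csv(meta_path, stringsAsFactors = FALSE, na.strings = character(0))
  values <- utils::read.csv(table_path, stringsAsFactors = FALSE,
                            na.strings = "", check.names = FALSE,
                            colClasses = "character")
  if (!setequal(names(values), flat$name))
    stop("metadata/table column mismatch: ",
         paste(symdiff_chr(names(values), flat$name), collapse = ", "))
  for (nm in flat$name[flat$kind == "continuous"])
    values[[nm]] <- as.numeric(values[[nm]])
  outcome <- if (any(flat$outcome)) flat$name[flat$outcome][1] else NULL
  mixed_dataset(values, flat[, c("name", "kind", "levels", "role")], outcome = outcome)
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))
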