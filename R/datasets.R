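#' Construct a descriptor table
#'
#' The central data container: one row per compound, named real-valued
#' molecular descriptors, a response vector of lg(IC50) values (log10 of
#' IC50 in nM) and an optional train/test split flag.
#'
#' @param compound_ids character vector of unique compound labels.
#' @param descriptors numeric matrix (rows = compounds, columns = named
#'   descriptors). A zero-column matrix is allowed (response-only tables).
#' @param response numeric vector of lg(IC50) values, one per compound.
#' @param split_flag optional factor/character vector with levels
#'   `"train"`, `"test"`, `"unassigned"`.
#' @return An object of class `descriptor_table`.
#' @export
descriptor_table <- function(compound_ids, descriptors, response,
                             split_flag = NULL) {
  compound_ids <- as.character(compound_ids)
  descriptors <- as.matrix(descriptors)
  if (is.null(colnames(descriptors)) && ncol(descriptors) > 0L) {
    stop("descriptor columns must be named", call. = FALSE)
  }
  n <- length(compound_ids)
  if (anyDuplicated(compound_ids)) {
    stop("compound ids must be unique", call. = FALSE)
  }
  if (nrow(descriptors) != n || length(response) != n) {
    stop("compound_ids, descriptors and response must have matching rows",
         call. = FALSE)
  }
  if (ncol(descriptors) > 0L && anyDuplicated(colnames(descriptors))) {
    stop("descriptor names must be unique", call. = FALSE)
  }
  if (ncol(descriptors) > 0L && !all(is.finite(descriptors))) {
    stop("descriptors contain non-finite values", call. = FALSE)
  }
  if (!all(is.finite(response))) {
    stop("response contains non-finite values", call. = FALSE)
  }
  if (is.null(split_flag)) {
    split_flag <- rep("unassigned", n)
  }
  split_flag <- as.character(split_flag)
  if (length(split_flag) != n ||
      !all(split_flag %in% c("train", "test", "unassigned"))) {
    stop("split_flag must be one of 'train', 'test', 'unassigned' per row",
         call. = FALSE)
  }
  structure(
    list(compound_ids = compound_ids,
         descriptors = descriptors,
         response = as.numeric(response),
         split_flag = split_flag),
    class = "descriptor_table"
  )
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("<descriptor_table> %d compounds, %d descriptors\n",
              length(x$compound_ids), ncol(x$descriptors)))
  tab <- table(factor(x$split_flag, c("train", "test", "unassigned")))
  cat(sprintf("  split: %d train / %d test / %d unassigned\n",
              tab[["train"]], tab[["test"]], tab[["unassigned"]]))
  cat(sprintf("  response: lg(IC50) range [%.3g, %.3g]\n",
              min(x$response), max(x$response)))
  invisible(x)
}

#' Number of compounds in a descriptor table
#' @param x a `descriptor_table`.
#' @return integer row count.
#' @export
n_compounds <- function(x) length(x$compound_ids)

#' Subset a descriptor table by row
#' @param x a `descriptor_table`.
#' @param i integer or logical row index.
#' @param ... unused.
#' @export
`[.descriptor_table` <- function(x, i, ...) {
  descriptor_table(x$compound_ids[i],
                   x$descriptors[i, , drop = FALSE],
                   x$response[i],
                   x$split_flag[i])
}

#' Read a descriptor table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row; the decimal
#' separator is `"."`. All columns other than the id and response columns
#' are treated as descriptors and must parse as real numbers.
#'
#' @param path path to a CSV file.
#' @param response_column name of the response column (lg IC50).
#' @param id_column name of the compound identifier column.
#' @return A [descriptor_table()].
#' @export
load_descriptor_table <- function(path, response_column = "response",
                                  id_column = "id") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  for (col in c(id_column, response_column)) {
    if (!col %in% names(raw)) {
      stop(sprintf("configuration error: column '%s' not present in %s",
                   col, path), call. = FALSE)
    }
  }
  desc_names <- setdiff(names(raw), c(id_column, response_column))
  parse_numeric <- function(values, column) {
    out <- suppressWarnings(as.numeric(values))
    bad <- which(is.na(out) | !is.finite(out))
    if (length(bad) > 0L) {
      stop(sprintf("parse error: non-numeric value '%s' at row %d, column '%s'",
                   values[bad[1L]], bad[1L], column), call. = FALSE)
    }
    out
  }
  descriptors <- matrix(0, nrow(raw), length(desc_names),
                        dimnames = list(NULL, desc_names))
  for (col in desc_names) {
    descriptors[, col] <- parse_numeric(raw[[col]], col)
  }
  descriptor_table(raw[[id_column]], descriptors,
                   parse_numeric(raw[[response_column]], response_column))
}

#' Write a descriptor table to CSV
#'
#' Inverse of [load_descriptor_table()] (split flags are not stored).
#'
#' @param table a `descriptor_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path) {
  df <- data.frame(id = table$compound_ids, check.names = FALSE)
  if (ncol(table$descriptors) > 0L) {
    df <- cbind(df, as.data.frame(table$descriptors, check.names = FALSE))
  }
  df$response <- table$response
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Randomly split a descriptor table into training and test sets
#'
#' Assigns `round(n * test_fraction)` compounds to the test set by seeded
#' sampling without replacement; the rest become the training set. Row
#' order is preserved. The canonical split for this kind of study is 4:1
#' (`test_fraction = 0.2`).
#'
#' @param table a `descriptor_table`.
#' @param test_fraction fraction of rows assigned to the test set, in (0,1).
#' @param seed integer seed; the same seed always yields the same split.
#' @return The table with `split_flag` set to `"train"`/`"test"`.
#' @export
split_train_test <- function(table, test_fraction, seed) {
  n <- n_compounds(table)
  if (n < 2L) stop("need at least 2 compounds to split", call. = FALSE)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  n_test <- round(n * test_fraction)
  if (n_test < 1L || n_test >= n) {
    stop("test_fraction produces an empty train or test set", call. = FALSE)
  }
  test_idx <- with_seed(seed, sample.int(n, n_test))
  flag <- rep("train", n)
  flag[test_idx] <- "test"
  table$split_flag <- flag
  table
}

# md5 of the packaged reference-prediction transcription; guards against a
# corrupted installation.
.table6_md5 <- "3d8038c782d60a189ef9311eb671d2e3"

#' Load the packaged reference-prediction table
#'
#' Returns the transcription of the published table of measured and
#' predicted lg(IC50) for the 92 EGFR L858R/T790M/C797S inhibitors: the
#' measured IC50 (nM), its base-10 logarithm, the predicted lg(IC50) of the
#' six published models (HM, RF, GEP, GBDT, Poly-SVM, MIX-SVM) and the
#' published train/test membership (19 test compounds). All values are the
#' 2-decimal reals as printed.
#'
#' @return A data.frame with 92 rows and columns `compound`,
#'   `measured_ic50_nM`, `measured`, `hm`, `rf`, `gep`, `gbdt`, `poly_svm`,
#'   `mix_svm`, `is_test`.
#' @export
load_reference_predictions <- function() {
  path <- system.file("extdata", "table6_reference.csv", package = "qsarmix",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .table6_md5)) {
    stop("integrity error: packaged reference table checksum mismatch",
         call. = FALSE)
  }
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(ref) == 92L, sum(ref$is_test) == 19L)
  ref
}

#' Reference table as a response-only descriptor table
#'
#' Convenience view of [load_reference_predictions()] with the measured
#' lg(IC50) as response, no descriptors, and the published split flags.
#'
#' @return A [descriptor_table()] with 92 compounds and 0 descriptors.
#' @export
reference_table <- function() {
  ref <- load_reference_predictions()
  descriptor_table(
    compound_ids = as.character(ref$compound),
    descriptors = matrix(numeric(0), nrow(ref), 0),
    response = ref$measured,
    split_flag = ifelse(ref$is_test, "test", "train")
  )
}
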