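#' Construct a categorical dataset
#'
#' The basic container of the package: an `n x s` table of category codes
#' together with one vocabulary per feature (the sorted set of codes observed
#' in that feature) and, optionally, a per-record class label. All codes are
#' handled as opaque symbols: `"3"` and `"10"` are category names, never
#' numbers, so no ordering of codes is ever used downstream.
#'
#' @param x A data.frame or matrix of category codes. Columns are features;
#'   everything is coerced to character. Must contain no missing values --
#'   impute first with [impute_mode()] or use [read_categorical_csv()].
#' @param labels Optional character vector of per-record class labels,
#'   length `nrow(x)`.
#' @param imputation Optional [impute_mode()] report to attach, recording how
#'   missing cells were filled before construction.
#'
#' @return An object of class `catfuzz_dataset`: a list with elements
#'   `cells` (character matrix), `codes` (integer matrix indexing each cell's
#'   position in its feature vocabulary), `vocab` (named list of sorted
#'   character vectors), `labels`, `n`, `s`, and `imputation`.
#'
#' @details At least two features are required: the co-occurrence distance of
#'   a feature is defined against every *other* feature and is undefined for
#'   a single column. Vocabularies contain only observed values and are sorted
#'   with a locale-independent (radix) order so that all downstream indexing
#'   is reproducible across machines.
#'
#' @examples
#' d <- categorical_dataset(data.frame(F1 = c("x", "x", "y"),
#'                                     F2 = c("a", "b", "b")))
#' d$vocab
#' @export
categorical_dataset <- function(x, labels = NULL, imputation = NULL) {
  cells <- as.matrix(as.data.frame(x, stringsAsFactors = FALSE))
  storage.mode(cells) <- "character"
  if (is.null(colnames(cells))) {
    colnames(cells) <- paste0("V", seq_len(ncol(cells)))
  }
  if (ncol(cells) < 2L) {
    stop("a categorical dataset needs at least 2 features (s >= 2)")
  }
  if (anyNA(cells)) {
    stop("dataset contains NA cells; impute missing values first")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(cells)) {
      stop("length(labels) must equal the number of records")
    }
  }
  vocab <- lapply(seq_len(ncol(cells)), function(l) {
    sort(unique(cells[, l]), method = "radix")
  })
  names(vocab) <- colnames(cells)
  codes <- vapply(seq_len(ncol(cells)), function(l) {
    match(cells[, l], vocab[[l]])
  }, integer(nrow(cells)))
  codes <- matrix(codes, nrow = nrow(cells),
                  dimnames = list(NULL, colnames(cells)))
  structure(
    list(cells = cells, codes = codes, vocab = vocab, labels = labels,
         n = nrow(cells), s = ncol(cells), imputation = imputation),
    class = "catfuzz_dataset"
  )
}

#' @export
print.catfuzz_dataset <- function(x, ...) {
  cat("Categorical dataset:", x$n, "records x", x$s, "features\n")
  sizes <- vapply(x$vocab, length, integer(1))
  cat("Vocabulary sizes:", paste(names(sizes), sizes, sep = "=",
                                 collapse = ", "), "\n")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("Labels:", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
  }
  if (!is.null(x$imputation) && x$imputation$n_cells > 0L) {
    cat("Imputed cells:", x$imputation$n_cells, "in",
        x$imputation$n_records, "records\n")
  }
  invisible(x)
}

#' Replace missing categorical cells by the per-feature mode
#'
#' Every missing cell is replaced by the most frequent non-missing value of
#' its column; ties are broken by taking the lexicographically smallest code.
#' Imputation is a one-off preprocessing step performed on the full table
#' before any clustering.
#'
#' @param x A data.frame or character matrix of category codes.
#' @param missing_token Symbol marking a missing cell (default `"?"`).
#'   `NA` cells are treated as missing too.
#' @return A list with `data` (the imputed character matrix) and `report`,
#'   itself a list with `features` (a data.frame with one row per feature
#'   that had missing cells: `feature`, `mode`, `n_imputed`), `n_cells`
#'   (total imputed cells) and `n_records` (records touched).
#' @examples
#' impute_mode(data.frame(F1 = c("1", "1", "2", "?"),
#'                        F2 = c("a", "?", "b", "b")))$data
#' @export
impute_mode <- function(x, missing_token = "?") {
  cells <- as.matrix(as.data.frame(x, stringsAsFactors = FALSE))
  storage.mode(cells) <- "character"
  if (is.null(colnames(cells))) {
    colnames(cells) <- paste0("V", seq_len(ncol(cells)))
  }
  miss <- is.na(cells) | cells == missing_token
  rows <- list()
  for (l in seq_len(ncol(cells))) {
    ml <- miss[, l]
    if (!any(ml)) next
    observed <- cells[!ml, l]
    if (length(observed) == 0L) {
      stop("feature '", colnames(cells)[l], "' has no observed values")
    }
    counts <- table(observed)
    best <- max(counts)
    # ties: lexicographically smallest code wins
    mode_val <- sort(names(counts)[counts == best], method = "radix")[1L]
    cells[ml, l] <- mode_val
    rows[[length(rows) + 1L]] <- data.frame(
      feature = colnames(cells)[l], mode = mode_val,
      n_imputed = sum(ml), stringsAsFactors = FALSE)
  }
  features <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(), mode = character(),
               n_imputed = integer(), stringsAsFactors = FALSE)
  list(data = cells,
       report = list(features = features,
                     n_cells = sum(miss),
                     n_records = sum(rowSums(miss) > 0L)))
}

#' Read a categorical dataset from a generic CSV file
#'
#' Reads a UTF-8, comma-delimited file with a header row. Every non-label
#' column is treated as a categorical feature whose cells are opaque symbols.
#' Missing cells (the `missing_token`) are mode-imputed via [impute_mode()];
#' the imputation report is attached to the returned dataset.
#'
#' @param path Path to the CSV file.
#' @param label_column Optional name of the column holding class labels; it is
#'   split off from the feature table.
#' @param missing_token Symbol marking missing cells (default `"?"`).
#' @return A [categorical_dataset()] with `imputation` filled in.
#' @export
read_categorical_csv <- function(path, label_column = NULL,
                                 missing_token = "?") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df)) {
      stop("label column '", label_column, "' not found in header")
    }
    labels <- df[[label_column]]
    df <- df[setdiff(names(df), label_column)]
  }
  imp <- impute_mode(df, missing_token = missing_token)
  categorical_dataset(imp$data, labels = labels, imputation = imp$report)
}

#' Write a categorical dataset to CSV
#'
#' Inverse of [read_categorical_csv()]: cells plus, when present, the labels
#' as a final `label` column. Re-reading with `label_column = "label"` round
#' trips cells, vocabularies and labels exactly.
#'
#' @param dataset A [categorical_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_categorical_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "catfuzz_dataset"))
  df <- as.data.frame(dataset$cells, stringsAsFactors = FALSE)
  if (!is.null(dataset$labels)) df$label <- dataset$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Feature names of the Wisconsin breast cancer table, in file column order.
wbc_feature_names <- function() {
  c("clump_thickness", "uniformity_of_cell_size", "uniformity_of_cell_shape",
    "marginal_adhesion", "single_epithelial_cell_size", "bare_nuclei",
    "bland_chromatin", "normal_nucleoli", "mitoses")
}

#' Read the Wisconsin breast cancer file
#'
#' Reader for the UCI "breast-cancer-wisconsin.data" dialect: headerless,
#' eleven comma-separated fields per line. Field 1 is a sample id (dropped),
#' fields 2--10 are the nine cytological features coded as categories, and
#' field 11 is the class, `2` for benign and `4` for malignant. Missing
#' feature cells are written as `"?"` and are mode-imputed.
#'
#' @param path Path to the data file.
#' @return A [categorical_dataset()] with `s = 9`, named features, labels
#'   `"benign"`/`"malignant"`, and the imputation report attached.
#' @export
read_wbc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = FALSE, colClasses = "character")
  if (ncol(df) != 11L) {
    stop("expected 11 comma-separated columns, found ", ncol(df))
  }
  cls <- df[[11L]]
  bad <- setdiff(unique(cls), c("2", "4"))
  if (length(bad)) {
    stop("unexpected class code(s): ", paste(bad, collapse = ", "),
         " (expected 2=benign, 4=malignant)")
  }
  feats <- df[, 2:10]
  names(feats) <- wbc_feature_names()
  labels <- ifelse(cls == "2", "benign", "malignant")
  imp <- impute_mode(feats, missing_token = "?")
  categorical_dataset(imp$data, labels = labels, imputation = imp$report)
}
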