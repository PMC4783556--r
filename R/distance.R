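#' Conditional co-occurrence probabilities between two features
#'
#' For a source feature `i` and a target feature `j`, estimates
#' `p(v | x) = #\{feature_i = x, feature_j = v\} / #\{feature_i = x\}` for
#' every source value `x` and target value `v`. These conditional rows are
#' the raw material of the co-occurrence distance: two values of feature `i`
#' are similar when they drag the same distribution of feature-`j` values
#' along with them.
#'
#' @param dataset A [categorical_dataset()].
#' @param i,j Feature indices (1-based) or feature names; `i != j`.
#' @return A row-stochastic matrix with one row per value of feature `i`
#'   and one column per value of feature `j`, of class `catfuzz_cpt`, with
#'   attributes `source_feature` and `target_feature`.
#' @examples
#' d <- categorical_dataset(data.frame(F1 = c("x","x","x","y"),
#'                                     F2 = c("a","a","b","b")))
#' conditional_probability_table(d, 1, 2)
#' @export
conditional_probability_table <- function(dataset, i, j) {
  stopifnot(inherits(dataset, "catfuzz_dataset"))
  i <- resolve_feature(dataset, i)
  j <- resolve_feature(dataset, j)
  if (i == j) stop("source and target feature must differ (i != j)")
  counts <- table(
    factor(dataset$cells[, i], levels = dataset$vocab[[i]]),
    factor(dataset$cells[, j], levels = dataset$vocab[[j]])
  )
  p <- unclass(counts) / rowSums(counts)
  structure(p, class = c("catfuzz_cpt", class(p)),
            source_feature = colnames(dataset$cells)[i],
            target_feature = colnames(dataset$cells)[j])
}

resolve_feature <- function(dataset, i) {
  if (is.character(i)) {
    k <- match(i, colnames(dataset$cells))
    if (is.na(k)) stop("unknown feature: ", i)
    return(k)
  }
  i <- as.integer(i)
  if (i < 1L || i > dataset$s) stop("feature index out of range: ", i)
  i
}

#' Co-occurrence distance between two values of one feature, against one
#' co-feature
#'
#' The distance between values `x` and `y` of a feature, measured against a
#' single other feature, is the largest probability advantage any event can
#' achieve between the two conditional co-occurrence rows: the maximum over
#' subsets `w` of the co-feature's values of `p(w | x) + p(not w | y) - 1`.
#' The maximizing subset is `\{v : p(v|x) > p(v|y)\}`, and the maximum equals
#' the total-variation distance between the rows,
#' `sum(pmax(p(.|x), p(.|y))) - 1 = 0.5 * sum(|p(.|x) - p(.|y)|)`,
#' which is how it is computed here (no subset enumeration).
#'
#' @param cpt A [conditional_probability_table()] for the feature pair.
#' @param x,y Values of the source feature (row names of `cpt`).
#' @return A list with `distance` (in `[0, 1]`) and `witness`, the maximizing
#'   subset of co-feature values. Ties `p(v|x) == p(v|y)` are excluded from
#'   the witness; including them would not change the maximum.
#' @export
value_pair_distance <- function(cpt, x, y) {
  stopifnot(inherits(cpt, "catfuzz_cpt"))
  if (!x %in% rownames(cpt)) stop("unknown source value: ", x)
  if (!y %in% rownames(cpt)) stop("unknown source value: ", y)
  px <- cpt[x, ]
  py <- cpt[y, ]
  list(distance = sum(pmax(px, py)) - 1,
       witness = colnames(cpt)[px > py])
}

#' Build the table of distances between category values
#'
#' For every feature, computes the symmetric matrix of dissimilarities
#' between that feature's values. Two kinds are available:
#'
#' * `"cooccurrence"`: the distance between values `x` and `y` of feature
#'   `i` is the average, over every other feature `j`, of the per-pair
#'   co-occurrence distance (see [value_pair_distance()]); the denominator
#'   is `s - 1`. Each per-pair term is a total-variation distance, so every
#'   entry lies in `[0, 1]`, the diagonal is zero and the triangle
#'   inequality holds within each feature.
#' * `"hamming"`: 0 on the diagonal, 1 off it (simple matching).
#'
#' The table is computed once from the full dataset and is held fixed while
#' clustering iterates.
#'
#' @param dataset A [categorical_dataset()].
#' @param kind `"cooccurrence"` (default) or `"hamming"`.
#' @return An object of class `value_distance_table`: list with `tables`
#'   (named list of symmetric matrices, one per feature), `kind`, and `s`.
#' @export
value_distance_table <- function(dataset,
                                 kind = c("cooccurrence", "hamming")) {
  stopifnot(inherits(dataset, "catfuzz_dataset"))
  kind <- match.arg(kind)
  s <- dataset$s
  tables <- vector("list", s)
  names(tables) <- colnames(dataset$cells)
  for (i in seq_len(s)) {
    vi <- dataset$vocab[[i]]
    p <- length(vi)
    if (kind == "hamming") {
      D <- 1 - diag(p)
    } else {
      D <- matrix(0, p, p)
      for (j in setdiff(seq_len(s), i)) {
        cpt <- conditional_probability_table(dataset, i, j)
        # TV distance between all pairs of conditional rows at once
        D <- D + as.matrix(stats::dist(unclass(cpt),
                                       method = "manhattan")) / 2
      }
      D <- D / (s - 1)
    }
    dimnames(D) <- list(vi, vi)
    tables[[i]] <- D
  }
  structure(list(tables = tables, kind = kind, s = s),
            class = "value_distance_table")
}

#' @export
print.value_distance_table <- function(x, ...) {
  cat("Value distance table (", x$kind, "), ", x$s, " features\n", sep = "")
  for (nm in names(x$tables)) {
    cat("--", nm, "--\n")
    print(round(x$tables[[nm]], 4))
  }
  invisible(x)
}

#' Flatten a value distance table to a data.frame
#'
#' One row per unordered pair of values (diagonal included), with columns
#' `feature`, `value_a`, `value_b`, `delta`. This long form is what
#' [write_distance_table()] serializes.
#'
#' @param table A [value_distance_table()].
#' @return A data.frame.
#' @export
distance_table_df <- function(table) {
  stopifnot(inherits(table, "value_distance_table"))
  out <- lapply(names(table$tables), function(nm) {
    D <- table$tables[[nm]]
    idx <- which(upper.tri(D, diag = TRUE), arr.ind = TRUE)
    data.frame(feature = nm,
               value_a = rownames(D)[idx[, 1]],
               value_b = colnames(D)[idx[, 2]],
               delta = D[idx],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write / read a value distance table
#'
#' `write_distance_table()` writes the long CSV form (columns `feature`,
#' `value_a`, `value_b`, `delta`) and, when `json` is given, a nested JSON
#' document (`feature -> value_a -> value_b -> delta`). `read_distance_table()`
#' rebuilds the `value_distance_table` object from the CSV.
#'
#' @param table A [value_distance_table()].
#' @param csv Path of the CSV file to write/read.
#' @param json Optional path of a JSON file to write.
#' @param kind Distance kind to record when reading (stored nowhere in the
#'   CSV payload; defaults to `"cooccurrence"`).
#' @return `write_distance_table()` returns `csv` invisibly;
#'   `read_distance_table()` returns a [value_distance_table()].
#' @export
write_distance_table <- function(table, csv, json = NULL) {
  df <- distance_table_df(table)
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  if (!is.null(json)) {
    nested <- lapply(table$tables, function(D) {
      rows <- lapply(rownames(D), function(a) as.list(D[a, ]))
      names(rows) <- rownames(D)
      rows
    })
    jsonlite::write_json(list(kind = table$kind, distances = nested),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv)
}

#' @rdname write_distance_table
#' @export
read_distance_table <- function(csv, kind = "cooccurrence") {
  df <- utils::read.csv(csv, colClasses = c("character", "character",
                                            "character", "numeric"))
  tables <- lapply(split(df, df$feature), function(part) {
    vals <- sort(unique(c(part$value_a, part$value_b)), method = "radix")
    D <- matrix(0, length(vals), length(vals), dimnames = list(vals, vals))
    D[cbind(part$value_a, part$value_b)] <- part$delta
    D[cbind(part$value_b, part$value_a)] <- part$delta
    D
  })
  tables <- tables[unique(df$feature)]
  structure(list(tables = tables, kind = kind, s = length(tables)),
            class = "value_distance_table")
}
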