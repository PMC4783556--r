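#' Harden fuzzy memberships
#'
#' Assigns each record to its maximum-membership cluster; ties go to the
#' lowest cluster index.
#'
#' @param U `n x K` membership matrix with unit row sums.
#' @return Integer vector of cluster indices in `1..K`.
#' @export
defuzzify <- function(U) {
  U <- as.matrix(U)
  max.col(U, ties.method = "first")
}

#' Class-by-cluster confusion matrix
#'
#' @param labels Per-record class labels.
#' @param assignments Per-record cluster ids.
#' @return Integer matrix, classes as rows (sorted), clusters as columns
#'   (sorted); row sums are per-class counts and the total is `n`.
#' @export
confusion_matrix <- function(labels, assignments) {
  if (length(labels) != length(assignments)) {
    stop("labels and assignments must have equal length")
  }
  tab <- table(class = factor(labels), cluster = factor(assignments))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

# all injective maps from seq_len(k) into seq_len(p), as a matrix of rows
injective_maps <- function(k, p) {
  if (k == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  out <- matrix(seq_len(p), ncol = 1L)
  for (step in seq_len(k - 1L)) {
    grown <- lapply(seq_len(nrow(out)), function(r) {
      rest <- setdiff(seq_len(p), out[r, ])
      cbind(matrix(out[r, ], length(rest), step, byrow = TRUE), rest)
    })
    out <- do.call(rbind, grown)
  }
  out
}

#' Clustering error under the optimal cluster-to-class matching
#'
#' Finds the one-to-one assignment of clusters to classes that maximizes the
#' total count of records landing in their class's matched cluster, and
#' reports the complement as a percentage:
#' `error = 100 * (n - matched) / n`. The search is exhaustive over injective
#' maps of the smaller dimension into the larger (fine up to 8 clusters or
#' classes, which covers the intended desk scale).
#'
#' @param cm A [confusion_matrix()] (classes x clusters), or any
#'   non-negative count matrix.
#' @return List with `error` (percent, in `[0, 100]`), `mapping` (named
#'   character vector, cluster id -> class label), `matched` (count) and
#'   `n` (total).
#' @export
clustering_error <- function(cm) {
  cm <- as.matrix(cm)
  if (length(cm) == 0L || sum(cm) == 0) stop("empty confusion matrix")
  n <- sum(cm)
  r <- nrow(cm)  # classes
  k <- ncol(cm)  # clusters
  if (min(r, k) > 8L) {
    stop("exhaustive matching supports at most 8 clusters/classes")
  }
  if (k <= r) {
    # map each cluster to a distinct class
    maps <- injective_maps(k, r)
    scores <- apply(maps, 1L, function(mp) sum(cm[cbind(mp, seq_len(k))]))
    best <- maps[which.max(scores), ]
    mapping <- stats::setNames(rownames(cm)[best] %||% as.character(best),
                               colnames(cm) %||% as.character(seq_len(k)))
  } else {
    # more clusters than classes: each class claims a distinct cluster,
    # the surplus clusters stay unmatched
    maps <- injective_maps(r, k)
    scores <- apply(maps, 1L, function(mp) sum(cm[cbind(seq_len(r), mp)]))
    best <- maps[which.max(scores), ]
    mapping <- stats::setNames(rownames(cm) %||% as.character(seq_len(r)),
                               colnames(cm)[best] %||% as.character(best))
  }
  matched <- max(scores)
  list(error = 100 * (n - matched) / n, mapping = mapping,
       matched = as.integer(matched), n = as.integer(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean and standard deviation of per-run errors
#'
#' Aggregates the error percentages of repeated runs. The standard deviation
#' uses the population convention (divisor equal to the number of runs).
#'
#' @param errors Non-empty numeric vector of per-run error percentages.
#' @return List with `mean` and `sd`.
#' @export
aggregate_runs <- function(errors) {
  if (length(errors) == 0L) stop("no run errors supplied")
  mu <- mean(errors)
  list(mean = mu, sd = sqrt(mean((errors - mu)^2)))
}

#' Score one clustering against class labels
#'
#' Hardens the memberships, builds the confusion matrix and computes the
#' clustering error under the optimal cluster-to-class matching.
#'
#' @param result A [fuzzy_cluster()] result (or a bare membership matrix).
#' @param labels Per-record class labels.
#' @return List with `confusion`, `error`, `mapping`, `assignments`.
#' @export
evaluate_clustering <- function(result, labels) {
  U <- if (inherits(result, "fuzzy_clustering")) result$membership else result
  assignments <- defuzzify(U)
  cm <- confusion_matrix(labels, assignments)
  ce <- clustering_error(cm)
  list(confusion = cm, error = ce$error, mapping = ce$mapping,
       assignments = assignments)
}

#' Repeated-run evaluation protocol
#'
#' Runs the clustering `runs` times from different random initializations
#' (seeds derived from `config$seed`), scores every run against the labels,
#' and aggregates. Because averaging confusion matrices over runs has no
#' unique definition, the reported matrix is the one of the run whose error
#' is closest to the mean error (ties to the earliest run); all per-run
#' errors are returned alongside.
#'
#' @param dataset A [categorical_dataset()] with labels (or pass `labels`).
#' @param config A [clustering_config()].
#' @param runs Number of repetitions (default 100).
#' @param labels Class labels; default `dataset$labels`.
#' @param table Optional precomputed [value_distance_table()].
#' @return Object of class `evaluation_report`: list with `per_run_errors`,
#'   `mean`, `sd`, `confusion` and `mapping` (representative run),
#'   `representative_run`, `runs`, `config`, and `results` (the run list).
#' @export
evaluate_runs <- function(dataset, config = clustering_config(),
                          runs = 100L, labels = dataset$labels,
                          table = NULL) {
  if (is.null(labels)) stop("no class labels available for evaluation")
  results <- fuzzy_cluster_runs(dataset, config, runs = runs, table = table)
  evals <- lapply(results, evaluate_clustering, labels = labels)
  errors <- vapply(evals, `[[`, numeric(1), "error")
  agg <- aggregate_runs(errors)
  rep_run <- which.min(abs(errors - agg$mean))
  structure(list(per_run_errors = errors, mean = agg$mean, sd = agg$sd,
                 confusion = evals[[rep_run]]$confusion,
                 mapping = evals[[rep_run]]$mapping,
                 representative_run = rep_run,
                 runs = length(errors), config = config,
                 results = results),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Clustering evaluation over", x$runs, "run(s)\n")
  cat(sprintf("Mean error: %.1f%%  (sd %.1f)\n",
              round_half_up(x$mean, 1), round_half_up(x$sd, 1)))
  cat("Confusion matrix (representative run", x$representative_run, "):\n")
  print(x$confusion)
  cat("Cluster -> class mapping:",
      paste(names(x$mapping), x$mapping, sep = " -> ", collapse = ", "),
      "\n")
  invisible(x)
}

# display rounding: half-up at `digits` decimals
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Write an evaluation report to files
#'
#' JSON report (per-run errors, mean, sd, mapping, representative run) plus
#' a CSV confusion matrix.
#'
#' @param report An [evaluate_runs()] report.
#' @param json Path of the JSON report.
#' @param confusion_csv Optional path for the confusion-matrix CSV.
#' @return `json`, invisibly.
#' @export
write_evaluation_report <- function(report, json, confusion_csv = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  payload <- list(
    runs = report$runs,
    per_run_errors = report$per_run_errors,
    mean_error = report$mean,
    sd_error = report$sd,
    mapping = as.list(report$mapping),
    representative_run = report$representative_run
  )
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
  if (!is.null(confusion_csv)) {
    df <- as.data.frame(report$confusion)
    df <- cbind(class = rownames(report$confusion), df)
    utils::write.csv(df, confusion_csv, row.names = FALSE)
  }
  invisible(json)
}

#' Membership profile ordered by class
#'
#' Per-record memberships with records sorted by class label (then original
#' order), the layout used to inspect how crisply each class is captured by
#' each cluster.
#'
#' @param result A [fuzzy_cluster()] result.
#' @param labels Per-record class labels.
#' @return A data.frame with columns `record`, `class`, and one membership
#'   column per cluster.
#' @export
membership_profile <- function(result, labels) {
  U <- if (inherits(result, "fuzzy_clustering")) result$membership else result
  if (length(labels) != nrow(U)) stop("labels/membership length mismatch")
  ord <- order(factor(labels), seq_along(labels))
  df <- data.frame(record = ord, class = labels[ord])
  for (j in seq_len(ncol(U))) df[[paste0("cluster_", j)]] <- U[ord, j]
  df
}
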