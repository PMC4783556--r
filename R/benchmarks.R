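#' Published benchmark confusion matrices for the Wisconsin data
#'
#' The reference 100-run experiments on the Wisconsin breast cancer dataset
#' (699 records, 458 benign / 241 malignant) report, for each fuzzifier
#' setting `m` in \{1.1, 1.5, 1.9\} and each value distance (co-occurrence
#' vs Hamming, both with fuzzy centroids), a representative two-cluster
#' confusion matrix. These six matrices are bundled so that the evaluation
#' arithmetic (optimal cluster-to-class matching and clustering error) can
#' be exercised and reproduced without downloading the data.
#'
#' @return A named list of six 2x2 integer matrices (rows `benign`,
#'   `malignant`; columns `cluster_1`, `cluster_2`). Names are
#'   `"<distance>_m<m>"`, e.g. `"cooccurrence_m1.1"`.
#' @examples
#' cm <- wbc_reference_confusions()[["cooccurrence_m1.1"]]
#' clustering_error(cm)$error
#' @export
wbc_reference_confusions <- function() {
  mk <- function(b1, b2, m1, m2) {
    matrix(as.integer(c(b1, m1, b2, m2)), 2, 2,
           dimnames = list(c("benign", "malignant"),
                           c("cluster_1", "cluster_2")))
  }
  list(
    "cooccurrence_m1.1" = mk(11, 447, 217, 24),
    "hamming_m1.1"      = mk(9, 449, 177, 64),
    "cooccurrence_m1.5" = mk(12, 446, 220, 21),
    "hamming_m1.5"      = mk(14, 444, 183, 58),
    "cooccurrence_m1.9" = mk(12, 446, 218, 23),
    "hamming_m1.9"      = mk(9, 449, 182, 59)
  )
}

#' Published benchmark error summary for the Wisconsin data
#'
#' The mean clustering error (percent, with standard deviation over 100
#' random initializations) reported for the same six settings as
#' [wbc_reference_confusions()].
#'
#' @return A data.frame with columns `m`, `distance`, `mean_error`, `sd`.
#' @export
wbc_reference_errors <- function() {
  data.frame(
    m = rep(c(1.1, 1.5, 1.9), each = 2),
    distance = rep(c("cooccurrence", "hamming"), 3),
    mean_error = c(5.0, 10.4, 4.7, 10.3, 5.0, 9.7),
    sd = c(0.3, 0.8, 0.4, 0.7, 0.6, 1.1),
    stringsAsFactors = FALSE
  )
}
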