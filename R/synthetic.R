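#' Specification of a mixture-of-multinomials categorical generator
#'
#' Synthetic categorical data are drawn from a finite mixture: each record
#' first draws a latent cluster from `mixing`, then draws every feature
#' independently from that cluster's per-feature category distribution.
#' An optional redundancy map post-processes the table by splitting a latent
#' category into several surface codes with fixed split probabilities --
#' records carrying the latent code are relabelled with one of its surface
#' codes at random. Conditional independence of features given the cluster
#' is deliberate: it is the simplest structure under which co-occurrence
#' statistics consistently estimate value similarity.
#'
#' @param n Number of records.
#' @param s Number of features.
#' @param K Number of latent clusters.
#' @param mixing Length-`K` proportions summing to 1.
#' @param emissions List of `K` elements, each a list of `s` named numeric
#'   vectors (category distributions, each summing to 1).
#' @param redundancy Optional named list (feature name -> list mapping a
#'   latent category to a named vector of surface-code split probabilities).
#' @param seed Integer seed.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n, s, K, mixing = rep(1 / K, K), emissions,
                           redundancy = NULL, seed = 1L) {
  n <- as.integer(n); s <- as.integer(s); K <- as.integer(K)
  if (length(mixing) != K) stop("mixing must have K entries")
  if (any(mixing < 0) || abs(sum(mixing) - 1) > 1e-12) {
    stop("mixing must be non-negative and sum to 1")
  }
  if (length(emissions) != K) stop("emissions must have one entry per cluster")
  for (k in seq_len(K)) {
    if (length(emissions[[k]]) != s) {
      stop("cluster ", k, " must have one emission row per feature")
    }
    for (l in seq_len(s)) {
      p <- emissions[[k]][[l]]
      if (is.null(names(p))) stop("emission rows must be named by category")
      if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
        stop("emission row (cluster ", k, ", feature ", l,
             ") must be a probability vector")
      }
    }
  }
  structure(list(n = n, s = s, K = K, mixing = mixing,
                 emissions = emissions, redundancy = redundancy,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Draw a synthetic categorical dataset
#'
#' Samples records from a [generator_spec()]; deterministic given the spec's
#' seed. Labels are the latent cluster ids (`"c1"`, `"c2"`, ...).
#'
#' @param spec A [generator_spec()].
#' @return A [categorical_dataset()] with true labels.
#' @export
generate_categorical <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  withr::with_seed(spec$seed, {
    z <- sample.int(spec$K, spec$n, replace = TRUE, prob = spec$mixing)
    cells <- matrix("", spec$n, spec$s,
                    dimnames = list(NULL, paste0("F", seq_len(spec$s))))
    for (k in seq_len(spec$K)) {
      idx <- which(z == k)
      if (!length(idx)) next
      for (l in seq_len(spec$s)) {
        p <- spec$emissions[[k]][[l]]
        cells[idx, l] <- sample(names(p), length(idx), replace = TRUE,
                                prob = p)
      }
    }
    if (!is.null(spec$redundancy)) {
      for (nm in names(spec$redundancy)) {
        l <- match(nm, colnames(cells))
        if (is.na(nm) || is.na(l)) stop("redundancy map names unknown feature: ", nm)
        for (latent in names(spec$redundancy[[nm]])) {
          split <- spec$redundancy[[nm]][[latent]]
          idx <- which(cells[, l] == latent)
          if (!length(idx)) next
          cells[idx, l] <- sample(names(split), length(idx), replace = TRUE,
                                  prob = split)
        }
      }
    }
    categorical_dataset(cells, labels = paste0("c", z))
  })
}

#' Well-separated mixture scenario
#'
#' Each cluster concentrates mass on its own preferred category at every
#' feature, with the remainder spread uniformly: the emission is the mixture
#' `(1 - separation) * pointmass(preferred) + separation * uniform`, so
#' `separation = 0` gives disjoint cluster supports and `separation = 1`
#' removes all structure (identical emissions). Categories per feature
#' default to `K` (one preferred category per cluster).
#'
#' @param n,s,K As in [generator_spec()].
#' @param separation Overlap parameter in `[0, 1]`.
#' @param seed Integer seed.
#' @param n_categories Vocabulary size per feature (default `K`).
#' @return A [generator_spec()].
#' @export
make_separable_scenario <- function(n, s, K = 2L, separation = 0.1,
                                    seed = 1L, n_categories = K) {
  if (separation < 0 || separation > 1) stop("separation must be in [0, 1]")
  p <- as.integer(n_categories)
  if (p < K) stop("need at least one category per cluster")
  cats <- paste0("a", seq_len(p))
  emissions <- lapply(seq_len(K), function(k) {
    lapply(seq_len(s), function(l) {
      e <- rep(separation / p, p)
      e[k] <- e[k] + (1 - separation)
      stats::setNames(e, cats)
    })
  })
  generator_spec(n = n, s = s, K = K, emissions = emissions, seed = seed)
}

#' Redundant-category scenario: where Hamming distance goes blind
#'
#' A two-cluster mixture in which, on two-thirds of the features, each
#' cluster's preferred latent category is split 50/50 into two surface
#' codes. Two records of the same cluster then disagree on about half of
#' the redundantly coded features under simple matching, while the sibling
#' codes keep identical co-occurrence profiles against every other feature,
#' so the learned co-occurrence distance between siblings is near 0 and the
#' latent structure stays fully visible to it.
#'
#' The split deliberately covers only a subset of the features
#' (`ceiling(2 s / 3)` of them). When every feature is split the same way,
#' the two distances induce the same two-cluster discriminant up to a
#' common scale factor and recover identical partitions; with a partial
#' split, Hamming effectively halves the evidence carried by the
#' redundantly coded features relative to the plainly coded ones, while
#' the co-occurrence distance restores their weight by recognizing sibling
#' codes as near-identical.
#'
#' The latent overlap is fixed at `separation = 0.5` per feature, a
#' moderately noisy regime in which a few percent of records are genuinely
#' ambiguous, so the quality of the feature weighting actually shows up in
#' the clustering error.
#'
#' @param n Number of records.
#' @param s Number of features, at least 3.
#' @param seed Integer seed.
#' @return A [generator_spec()] whose `redundancy` names the sibling codes
#'   (`a1`/`a2` for the first cluster's category, `b1`/`b2` for the
#'   second's) on the split features.
#' @export
make_redundant_scenario <- function(n, s, seed = 1L) {
  if (s < 3L) stop("the redundant scenario needs s >= 3 features")
  separation <- 0.5
  cats <- c("a", "b")
  emissions <- lapply(1:2, function(k) {
    lapply(seq_len(s), function(l) {
      e <- rep(separation / 2, 2)
      e[k] <- e[k] + (1 - separation)
      stats::setNames(e, cats)
    })
  })
  split_feats <- seq_len(ceiling(2 * s / 3))
  redundancy <- stats::setNames(lapply(split_feats, function(l) {
    list(a = c(a1 = 0.5, a2 = 0.5), b = c(b1 = 0.5, b2 = 0.5))
  }), paste0("F", split_feats))
  generator_spec(n = n, s = s, K = 2L, emissions = emissions,
                 redundancy = redundancy, seed = seed)
}
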