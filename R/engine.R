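#' Clustering configuration
#'
#' Bundles the tunable parameters of the alternating-optimization loop.
#'
#' @param K Number of clusters, `>= 2`.
#' @param m Fuzzifier, `> 1`. Controls how soft memberships are; as `m`
#'   approaches 1 assignments become nearly hard. Default 1.1.
#' @param epsilon Stopping threshold on the change of the objective between
#'   consecutive iterations (default `1e-6`).
#' @param max_iter Iteration cap (default 100).
#' @param distance Value-distance kind: `"cooccurrence"` (default) or
#'   `"hamming"`. Ignored when `centroid = "mode"`, which always scores
#'   points against the hard centre by Hamming distance.
#' @param centroid `"fuzzy"` (distribution-valued centres, default) or
#'   `"mode"` (hard single-value centres, the fuzzy K-modes baseline).
#' @param seed Integer seed for the random membership initialization.
#' @return A list of class `clustering_config`.
#' @export
clustering_config <- function(K = 2L, m = 1.1, epsilon = 1e-6,
                              max_iter = 100L,
                              distance = c("cooccurrence", "hamming"),
                              centroid = c("fuzzy", "mode"),
                              seed = 42L) {
  distance <- match.arg(distance)
  centroid <- match.arg(centroid)
  K <- as.integer(K)
  max_iter <- as.integer(max_iter)
  if (K < 2L) stop("K must be >= 2")
  if (!is.numeric(m) || m <= 1) stop("the fuzzifier m must be > 1")
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  structure(list(K = K, m = m, epsilon = epsilon, max_iter = max_iter,
                 distance = distance, centroid = centroid,
                 seed = as.integer(seed)),
            class = "clustering_config")
}

#' Random row-stochastic membership matrix
#'
#' Draws `n x K` uniform numbers and normalizes each row to sum to 1, the
#' classic random start of fuzzy c-means. Deterministic given `seed`.
#'
#' @param n Number of records; `n >= K`.
#' @param K Number of clusters.
#' @param seed Integer seed.
#' @return An `n x K` matrix with non-negative entries and unit row sums.
#' @export
initialize_membership <- function(n, K, seed) {
  if (n < K) stop("need n >= K")
  withr::with_seed(as.integer(seed), random_membership(n, K))
}

# unseeded core, used inside a seeded run
random_membership <- function(n, K) {
  U <- matrix(stats::runif(n * K), n, K)
  rs <- rowSums(U)
  while (any(rs == 0)) {   # null-probability guard: redraw degenerate rows
    bad <- rs == 0
    U[bad, ] <- matrix(stats::runif(sum(bad) * K), ncol = K)
    rs <- rowSums(U)
  }
  U / rs
}

#' Fuzzy centroids for categorical data
#'
#' A cluster centre is represented, per feature, by a weight vector over that
#' feature's vocabulary rather than by a single value. The weight of value
#' `A[l,k]` in cluster `c` is `N[l,k,c] / N[c]`, where
#' `N[l,k,c] = sum_i 1(x[i,l] == A[l,k]) * u[i,c]^m` and
#' `N[c] = sum_i u[i,c]^m` is the cluster's fuzzy mass. With hard memberships
#' the weights reduce to the empirical within-cluster category frequencies.
#'
#' If a cluster's mass underflows (below `1e-12`), its centroid is reset to
#' the point-mass profile of a uniformly drawn record and a warning is
#' emitted; the run continues.
#'
#' @param dataset A [categorical_dataset()].
#' @param U Membership matrix, `n x K`, rows summing to 1.
#' @param m Fuzzifier, `> 1`.
#' @return An object of class `fuzzy_centroids`: list with `weights` (one
#'   `p_l x K` matrix per feature, columns summing to 1), `mass` (length-`K`
#'   vector of `N[c]`) and `m`.
#' @export
update_centroids <- function(dataset, U, m) {
  stopifnot(inherits(dataset, "catfuzz_dataset"))
  Um <- U^m
  mass <- colSums(Um)
  empty <- mass < 1e-12
  if (any(empty)) {
    warning("empty cluster(s) ", paste(which(empty), collapse = ", "),
            "; resetting to a random record's profile")
  }
  weights <- vector("list", dataset$s)
  names(weights) <- colnames(dataset$cells)
  for (l in seq_len(dataset$s)) {
    cl <- dataset$codes[, l]
    p <- length(dataset$vocab[[l]])
    N <- rowsum(Um, group = factor(cl, levels = seq_len(p)))
    W <- sweep(N, 2, pmax(mass, 1e-12), "/")
    rownames(W) <- dataset$vocab[[l]]
    weights[[l]] <- W
  }
  if (any(empty)) {
    for (c in which(empty)) {
      r <- sample.int(dataset$n, 1L)
      for (l in seq_len(dataset$s)) {
        weights[[l]][, c] <- 0
        weights[[l]][dataset$codes[r, l], c] <- 1
      }
    }
  }
  structure(list(weights = weights, mass = mass, m = m),
            class = "fuzzy_centroids")
}

#' Distances between every record and every fuzzy centroid
#'
#' For a record with value `Z` on feature `l`, the per-feature distance to a
#' centroid is the centroid-weighted average of value distances,
#' `Omega_l = sum_t w[l,t] * delta_l(Z, A[l,t])`, and the record--centroid
#' distance is the sum of `Omega_l` over all features. With the Hamming
#' value distance this reduces to `Omega_l = 1 - w[l, Z]`, one minus the
#' centroid's weight on the record's own value.
#'
#' @param dataset A [categorical_dataset()].
#' @param centroids A [update_centroids()] result.
#' @param table A [value_distance_table()] for the same dataset.
#' @return An `n x K` matrix of non-negative distances.
#' @export
point_centroid_distances <- function(dataset, centroids, table) {
  stopifnot(inherits(dataset, "catfuzz_dataset"),
            inherits(centroids, "fuzzy_centroids"),
            inherits(table, "value_distance_table"))
  K <- length(centroids$mass)
  D <- matrix(0, dataset$n, K)
  for (l in seq_len(dataset$s)) {
    nm <- colnames(dataset$cells)[l]
    delta <- table$tables[[nm]]
    if (is.null(delta)) stop("feature '", nm, "' absent from distance table")
    omega <- delta %*% centroids$weights[[l]]   # p_l x K
    D <- D + omega[dataset$codes[, l], , drop = FALSE]
  }
  unname(D)
}

#' Distance from a single record to each centroid
#'
#' Convenience wrapper around the same arithmetic as
#' [point_centroid_distances()] for one record given as a vector of category
#' codes (in feature order).
#'
#' @param values Character vector of length `s` of category codes.
#' @param centroids A [update_centroids()] result.
#' @param table A [value_distance_table()].
#' @return Numeric vector of length `K`.
#' @export
point_centroid_distance <- function(values, centroids, table) {
  stopifnot(inherits(centroids, "fuzzy_centroids"),
            inherits(table, "value_distance_table"))
  feats <- names(centroids$weights)
  if (length(values) != length(feats)) {
    stop("record has ", length(values), " values; expected ", length(feats))
  }
  K <- length(centroids$mass)
  d <- numeric(K)
  for (l in seq_along(feats)) {
    delta <- table$tables[[feats[l]]]
    if (!values[l] %in% rownames(delta)) {
      stop("value '", values[l], "' absent from distance table of feature '",
           feats[l], "'")
    }
    d <- d + drop(delta[values[l], ] %*% centroids$weights[[l]])
  }
  d
}

#' Membership update from record-centroid distances
#'
#' The row-wise minimizer of the fuzzy objective given distances:
#' `u[i,j] = 1 / sum_k (d[i,j] / d[i,k])^(1/(m-1))`, i.e. memberships
#' proportional to `d^(-1/(m-1))`. Rows with one or more zero distances get
#' their full membership split equally among the zero-distance clusters
#' (the formula is undefined there; this is the standard fuzzy c-means
#' convention). Computed with a row-minimum rescaling so that the large
#' exponents arising at small `m` cannot overflow.
#'
#' @param D `n x K` matrix of non-negative distances.
#' @param m Fuzzifier, `> 1`.
#' @return `n x K` membership matrix with unit row sums.
#' @export
update_membership <- function(D, m) {
  if (any(D < 0)) stop("distances must be non-negative")
  e <- 1 / (m - 1)
  dmin <- do.call(pmin, as.data.frame(D))
  R <- (dmin / D)^e           # entries in [0,1]; 0/0 -> NaN on zero rows
  zero <- D == 0
  has0 <- rowSums(zero) > 0L
  if (any(has0)) {
    R[has0, ] <- zero[has0, , drop = FALSE] / rowSums(zero[has0, , drop = FALSE])
  }
  U <- R / rowSums(R)
  unname(U)
}

#' Fuzzy clustering objective
#'
#' `J = sum_j sum_i u[i,j]^m * d[i,j]`, the quantity the alternating loop
#' drives down.
#'
#' @param U `n x K` membership matrix.
#' @param D `n x K` distance matrix.
#' @param m Fuzzifier.
#' @return A single number.
#' @export
compute_objective <- function(U, D, m) {
  if (!all(dim(U) == dim(D))) stop("U and D must have the same shape")
  sum(U^m * D)
}

#' Hard (mode) centroids and their Hamming distances
#'
#' The fuzzy K-modes centre: for each cluster and feature, the single
#' category with the largest fuzzy association `N[l,k,c]` (ties broken by
#' vocabulary order, i.e. lexicographically smallest code). Points are scored
#' against such a centre by Hamming distance summed over features.
#'
#' @inheritParams update_centroids
#' @return Object of class `mode_centroids`: list with `values` (`K x s`
#'   character matrix of centre codes) and `mass`.
#' @export
mode_centroid <- function(dataset, U, m) {
  cen <- update_centroids(dataset, U, m)
  K <- length(cen$mass)
  values <- matrix("", K, dataset$s,
                   dimnames = list(NULL, colnames(dataset$cells)))
  for (l in seq_len(dataset$s)) {
    W <- cen$weights[[l]]
    # which.max takes the first maximum; vocab rows are sorted, so ties go
    # to the lexicographically smallest code
    values[, l] <- dataset$vocab[[l]][apply(W, 2, which.max)]
  }
  structure(list(values = values, mass = cen$mass, m = m),
            class = "mode_centroids")
}

mode_centroid_distances <- function(dataset, centres) {
  K <- nrow(centres$values)
  D <- matrix(0, dataset$n, K)
  for (j in seq_len(K)) {
    D[, j] <- rowSums(dataset$cells !=
                        matrix(centres$values[j, ], dataset$n,
                               dataset$s, byrow = TRUE))
  }
  D
}

#' Run the fuzzy clustering loop
#'
#' Alternating optimization for categorical data: build the value-distance
#' table once, draw a random row-stochastic membership matrix, then repeat
#' \{update centroids; compute all record--centroid distances; update
#' memberships; evaluate the objective `J`\} until `|J_t - J_(t-1)| <=
#' epsilon` or `max_iter` is hit. With `centroid = "fuzzy"` centres are
#' distribution-valued and distances go through the value-distance table
#' (co-occurrence or Hamming); with `centroid = "mode"` centres are hard and
#' distances are plain Hamming counts (the fuzzy K-modes baseline).
#'
#' The convergence test at the first iteration compares against the
#' objective of the *initial* memberships under the first centroids, so a
#' very large `epsilon` stops after exactly one iteration.
#'
#' @param dataset A [categorical_dataset()].
#' @param config A [clustering_config()].
#' @param table Optional precomputed [value_distance_table()] matching
#'   `config$distance`; building it is the dominant cost for repeated runs
#'   on the same data, so multi-run drivers pass it in.
#' @param init Optional `n x K` initial membership matrix (rows summing
#'   to 1); when given, it replaces the seeded random initialization.
#' @return Object of class `fuzzy_clustering`: list with `membership`
#'   (`n x K`), `centroids` (last update), `distances` (`n x K`),
#'   `objective_trace` (one `J` per iteration), `iterations`, `converged`,
#'   and `config`.
#' @seealso [fuzzy_cluster_runs()] for the repeated-run protocol.
#' @export
fuzzy_cluster <- function(dataset, config = clustering_config(),
                          table = NULL, init = NULL) {
  stopifnot(inherits(dataset, "catfuzz_dataset"),
            inherits(config, "clustering_config"))
  if (dataset$n < config$K) stop("need at least K records")
  use_modes <- config$centroid == "mode"
  if (!use_modes && is.null(table)) {
    table <- value_distance_table(dataset, config$distance)
  }
  if (!is.null(init) && !all(dim(init) == c(dataset$n, config$K))) {
    stop("init must be an n x K membership matrix")
  }
  withr::with_seed(config$seed, {
    U <- if (is.null(init)) random_membership(dataset$n, config$K) else init
    trace <- numeric(0)
    converged <- FALSE
    J_prev <- NULL
    iter <- 0L
    while (iter < config$max_iter) {
      iter <- iter + 1L
      if (use_modes) {
        centroids <- mode_centroid(dataset, U, config$m)
        D <- mode_centroid_distances(dataset, centroids)
      } else {
        centroids <- update_centroids(dataset, U, config$m)
        D <- point_centroid_distances(dataset, centroids, table)
      }
      if (is.null(J_prev)) J_prev <- compute_objective(U, D, config$m)
      U <- update_membership(D, config$m)
      J <- compute_objective(U, D, config$m)
      trace <- c(trace, J)
      if (abs(J - J_prev) <= config$epsilon) {
        converged <- TRUE
        break
      }
      J_prev <- J
    }
    structure(list(membership = U, centroids = centroids, distances = D,
                   objective_trace = trace, iterations = iter,
                   converged = converged, config = config),
              class = "fuzzy_clustering")
  })
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cfg <- x$config
  cat("Fuzzy clustering: K =", cfg$K, " m =", cfg$m,
      " distance =", if (cfg$centroid == "mode") "hamming (mode centres)"
      else cfg$distance, "\n")
  cat("Iterations:", x$iterations,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  cat("Final objective:", utils::tail(x$objective_trace, 1), "\n")
  sizes <- table(factor(max.col(x$membership, ties.method = "first"),
                        levels = seq_len(cfg$K)))
  cat("Hard cluster sizes:", paste(sizes, collapse = " / "), "\n")
  invisible(x)
}

#' Repeat clustering runs with derived seeds
#'
#' Runs [fuzzy_cluster()] `runs` times with seeds `seed, seed + 1, ...`
#' (run `r` uses `config$seed + r - 1`), sharing one value-distance table.
#' This is the repeated-random-initialization protocol used to report
#' average clustering quality.
#'
#' @inheritParams fuzzy_cluster
#' @param runs Number of repetitions.
#' @return List of `fuzzy_clustering` objects, with the run seeds in
#'   attribute `"seeds"`.
#' @export
fuzzy_cluster_runs <- function(dataset, config = clustering_config(),
                               runs = 100L, table = NULL) {
  runs <- as.integer(runs)
  if (runs < 1L) stop("runs must be >= 1")
  if (config$centroid != "mode" && is.null(table)) {
    table <- value_distance_table(dataset, config$distance)
  }
  seeds <- config$seed + seq_len(runs) - 1L
  out <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    fuzzy_cluster(dataset, cfg, table = table)
  })
  attr(out, "seeds") <- seeds
  out
}

#' Export a clustering result to files
#'
#' Writes the membership matrix as CSV (`n` rows, `K` columns), the centroids
#' as JSON (`cluster -> feature -> value -> weight` for fuzzy centres;
#' `cluster -> feature -> value` for mode centres), the objective trace as
#' CSV, and run metadata as JSON.
#'
#' @param result A [fuzzy_cluster()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"run"`).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_clustering_result <- function(result, dir, prefix = "run") {
  stopifnot(inherits(result, "fuzzy_clustering"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    membership = file.path(dir, paste0(prefix, "_membership.csv")),
    centroids = file.path(dir, paste0(prefix, "_centroids.json")),
    trace = file.path(dir, paste0(prefix, "_objective.csv")),
    meta = file.path(dir, paste0(prefix, "_meta.json"))
  )
  U <- as.data.frame(result$membership)
  names(U) <- paste0("cluster_", seq_along(U))
  utils::write.csv(U, paths[["membership"]], row.names = FALSE)
  cen <- result$centroids
  if (inherits(cen, "fuzzy_centroids")) {
    K <- length(cen$mass)
    cjson <- lapply(seq_len(K), function(c) {
      lapply(cen$weights, function(W) as.list(W[, c]))
    })
  } else {
    K <- nrow(cen$values)
    cjson <- lapply(seq_len(K), function(c) as.list(cen$values[c, ]))
  }
  names(cjson) <- paste0("cluster_", seq_len(K))
  jsonlite::write_json(cjson, paths[["centroids"]], auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(
    data.frame(iteration = seq_along(result$objective_trace),
               objective = result$objective_trace),
    paths[["trace"]], row.names = FALSE)
  meta <- c(unclass(result$config),
            list(iterations = result$iterations,
                 converged = result$converged,
                 final_objective = utils::tail(result$objective_trace, 1)))
  jsonlite::write_json(meta, paths[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
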