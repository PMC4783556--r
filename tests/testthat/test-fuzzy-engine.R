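test_that("membership initialization is row-stochastic and seeded", {
  U <- initialize_membership(5, 2, seed = 1)
  expect_equal(dim(U), c(5L, 2L))
  expect_true(all(U >= 0))
  expect_equal(rowSums(U), rep(1, 5))
  expect_identical(U, initialize_membership(5, 2, seed = 1))
  expect_false(isTRUE(all.equal(U, initialize_membership(5, 2, seed = 2))))
  expect_error(initialize_membership(1, 2, seed = 1), "n >= K")
})

test_that("centroid weights reduce to frequencies at the extremes", {
  d <- toy4()
  # hard memberships: per-cluster empirical category frequencies
  U_hard <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  cen <- update_centroids(d, U_hard, m = 1.7)
  expect_equal(cen$weights$F1[, 1], c(x = 1, y = 0))
  expect_equal(cen$weights$F2[, 1], c(a = 1, b = 0))
  expect_equal(cen$weights$F1[, 2], c(x = 0.5, y = 0.5))
  # uniform memberships: every cluster mirrors the global frequencies
  U_unif <- matrix(1 / 2, 4, 2)
  cen <- update_centroids(d, U_unif, m = 2)
  expect_equal(cen$weights$F1[, 1], c(x = 0.75, y = 0.25))
  expect_equal(cen$weights$F1[, 2], c(x = 0.75, y = 0.25))
})

test_that("centroid weights match the hand-computed fuzzy association", {
  d <- toy4()
  U <- cbind(c(0.9, 0.6, 0.1, 0.2), c(0.1, 0.4, 0.9, 0.8))
  cen <- update_centroids(d, U, m = 2)
  expect_equal(cen$mass[1], 0.81 + 0.36 + 0.01 + 0.04)
  expect_equal(unname(cen$weights$F1["x", 1]), 1.18 / 1.22,
               tolerance = 1e-12)
  expect_equal(unname(cen$weights$F1["y", 1]), 0.04 / 1.22,
               tolerance = 1e-12)
  # weights are distributions
  expect_equal(unname(colSums(cen$weights$F1)), c(1, 1))
  expect_equal(unname(colSums(cen$weights$F2)), c(1, 1))
})

test_that("an emptied cluster is reseeded from a record with a warning", {
  d <- toy4()
  U <- cbind(rep(1, 4), rep(0, 4))
  expect_warning(cen <- update_centroids(d, U, m = 2), "empty cluster")
  expect_equal(unname(colSums(cen$weights$F1)), c(1, 1))
  expect_true(any(cen$weights$F1[, 2] == 1))  # point mass on some record
})

test_that("point-centroid distance composes value distances and weights", {
  d <- toy4()
  vt <- value_distance_table(d, "cooccurrence")
  U <- cbind(c(0.9, 0.6, 0.1, 0.2), c(0.1, 0.4, 0.9, 0.8))
  cen <- update_centroids(d, U, m = 2)
  dists <- point_centroid_distance(c("y", "b"), cen, vt)
  # F1 part: weight(x) * delta(y, x) = 0.96721 * 2/3
  omega_f1 <- (1.18 / 1.22) * (2 / 3)
  # F2 part: weight(a) * delta(b, a) = (1.17/1.22) * 1/2
  omega_f2 <- (1.17 / 1.22) * (1 / 2)
  expect_equal(dists[1], omega_f1 + omega_f2, tolerance = 1e-12)
  # matrix and single-record paths agree
  D <- point_centroid_distances(d, cen, vt)
  expect_equal(D[4, ], dists)
  expect_error(point_centroid_distance(c("zzz", "b"), cen, vt), "absent")
})

test_that("a point-mass centroid on the record's values is at distance 0", {
  d <- toy4()
  vt <- value_distance_table(d, "cooccurrence")
  U <- cbind(c(1, 0, 0, 0), c(0, 1, 1, 1))
  cen <- update_centroids(d, U, m = 3)
  # cluster 1 is exactly record 1 = (x, a)
  expect_equal(point_centroid_distance(c("x", "a"), cen, vt)[1], 0)
})

test_that("with Hamming values the distance is one minus the own weight", {
  d <- random_dataset(30, 3, seed = 4)
  vt <- value_distance_table(d, "hamming")
  U <- initialize_membership(30, 2, seed = 9)
  cen <- update_centroids(d, U, m = 1.5)
  D <- point_centroid_distances(d, cen, vt)
  own <- matrix(0, d$n, 2)
  for (l in seq_len(d$s)) {
    own <- own + (1 - cen$weights[[l]][d$codes[, l], ])
  }
  expect_equal(D, unname(own), tolerance = 1e-12)
})

test_that("membership update solves the row-wise weighted problem", {
  expect_equal(update_membership(matrix(c(0.4, 0.4), 1), m = 1.3),
               matrix(0.5, 1, 2))
  expect_equal(update_membership(matrix(c(0, 0.7), 1), m = 2),
               matrix(c(1, 0), 1))
  expect_equal(update_membership(matrix(c(0, 0, 0.5), 1), m = 2),
               matrix(c(0.5, 0.5, 0), 1))
  expect_equal(update_membership(matrix(c(0.2, 0.8), 1), m = 2),
               matrix(c(0.8, 0.2), 1))
  expect_error(update_membership(matrix(c(-0.1, 1), 1), m = 2),
               "non-negative")
})

test_that("membership update minimizes J over the simplex", {
  # 3 records, K = 2, fixed distances: compare with numerical minimization
  D <- matrix(c(0.3, 0.9, 0.05,
                0.6, 0.2, 0.45), nrow = 3)
  m <- 1.6
  U <- update_membership(D, m)
  for (i in 1:3) {
    obj <- function(u1) u1^m * D[i, 1] + (1 - u1)^m * D[i, 2]
    opt <- stats::optimize(obj, c(0, 1), tol = 1e-10)
    expect_equal(U[i, 1], opt$minimum, tolerance = 1e-6)
  }
  expect_equal(rowSums(U), rep(1, 3))
})

test_that("the objective is the fuzzily weighted distance total", {
  expect_equal(compute_objective(matrix(1, 2, 2) / 2,
                                 matrix(0, 2, 2), m = 2), 0)
  expect_equal(compute_objective(matrix(c(1, 0), 1),
                                 matrix(c(0.3, 9), 1), m = 4), 0.3)
  expect_equal(compute_objective(matrix(c(0.8, 0.2), 1),
                                 matrix(c(0.2, 0.8), 1), m = 2), 0.16)
  expect_error(compute_objective(matrix(0, 2, 2), matrix(0, 2, 3), 2),
               "shape")
})

test_that("mode centres take the weighted modal category", {
  d <- toy4()
  # hard memberships: plain per-cluster mode
  U_hard <- cbind(c(1, 1, 1, 0), c(0, 0, 0, 1))
  mc <- mode_centroid(d, U_hard, m = 2)
  expect_equal(unname(mc$values[1, ]), c("x", "a"))
  expect_equal(unname(mc$values[2, ]), c("y", "b"))
  # fuzzy association from the hand-worked example: x outweighs y
  U <- cbind(c(0.9, 0.6, 0.1, 0.2), c(0.1, 0.4, 0.9, 0.8))
  mc <- mode_centroid(d, U, m = 2)
  expect_equal(unname(mc$values[1, "F1"]), "x")
  # exact tie: lexicographically first category
  d2 <- categorical_dataset(data.frame(F1 = c("p", "q"), F2 = c("1", "2")))
  mc2 <- mode_centroid(d2, cbind(c(0.5, 0.5), c(0.5, 0.5)), m = 2)
  expect_equal(unname(mc2$values[, "F1"]), c("p", "p"))
})

test_that("two homogeneous blocks are separated exactly", {
  # blocks differing in every feature; the block partition is the unique
  # J-minimizing hard assignment (verified by enumerating all 2^8 hard
  # labelings with mode centres, the minimizer of J given hard U)
  cells <- rbind(matrix(rep(c("a", "a", "a"), 4), ncol = 3, byrow = TRUE),
                 matrix(rep(c("b", "b", "b"), 4), ncol = 3, byrow = TRUE))
  colnames(cells) <- paste0("F", 1:3)
  d <- categorical_dataset(cells, labels = rep(c("A", "B"), each = 4))
  # oracle: enumerate hard partitions, score J with Hamming mode centres
  best <- Inf; best_assign <- NULL
  for (mask in 0:(2^8 - 1)) {
    z <- as.integer(intToBits(mask))[1:8] + 1L
    if (length(unique(z)) < 2) next
    U <- cbind(z == 1L, z == 2L) * 1
    mc <- mode_centroid(d, U, m = 2)
    D <- matrix(0, 8, 2)
    for (j in 1:2) D[, j] <- rowSums(cells != rep(mc$values[j, ], each = 8))
    J <- compute_objective(U, D, m = 2)
    if (J < best - 1e-12) { best <- J; best_assign <- z }
  }
  expect_equal(best, 0)
  expect_true(all(best_assign[1:4] != best_assign[5:8]))
  # the fuzzy loop finds that partition from a random start
  for (dist in c("cooccurrence", "hamming")) {
    fit <- fuzzy_cluster(d, clustering_config(K = 2, m = 1.5,
                                              distance = dist, seed = 3))
    ev <- evaluate_clustering(fit, d$labels)
    expect_equal(ev$error, 0)
  }
})

test_that("a huge epsilon stops after exactly one iteration", {
  d <- random_dataset(20, 3, seed = 6)
  fit <- fuzzy_cluster(d, clustering_config(K = 2, epsilon = 1e9, seed = 1))
  expect_equal(fit$iterations, 1L)
  expect_true(fit$converged)
  expect_length(fit$objective_trace, 1L)
})

test_that("runs are bit-reproducible for a fixed seed", {
  d <- random_dataset(40, 4, seed = 2)
  cfg <- clustering_config(K = 3, m = 1.2, seed = 17)
  f1 <- fuzzy_cluster(d, cfg)
  f2 <- fuzzy_cluster(d, cfg)
  expect_identical(f1$objective_trace, f2$objective_trace)
  expect_identical(f1$membership, f2$membership)
})

test_that("memberships and centroid weights stay normalized throughout", {
  d <- random_dataset(60, 4, seed = 10)
  vt <- value_distance_table(d, "cooccurrence")
  U <- initialize_membership(60, 3, seed = 5)
  for (it in 1:8) {
    cen <- update_centroids(d, U, m = 1.1)
    for (W in cen$weights) {
      expect_equal(unname(colSums(W)), rep(1, 3), tolerance = 1e-9)
      expect_true(all(W >= 0))
    }
    D <- point_centroid_distances(d, cen, vt)
    expect_true(all(D >= 0))
    U <- update_membership(D, m = 1.1)
    expect_equal(rowSums(U), rep(1, 60), tolerance = 1e-9)
  }
})

test_that("permuting the initial membership columns permutes the result", {
  d <- random_dataset(50, 3, seed = 12)
  vt <- value_distance_table(d, "cooccurrence")
  cfg <- clustering_config(K = 3, m = 1.3, seed = 1)
  U0 <- initialize_membership(50, 3, seed = 33)
  perm <- c(3L, 1L, 2L)
  f1 <- fuzzy_cluster(d, cfg, table = vt, init = U0)
  f2 <- fuzzy_cluster(d, cfg, table = vt, init = U0[, perm])
  # cluster j of the permuted run is cluster perm[j] of the original
  expect_equal(f2$membership, f1$membership[, perm], tolerance = 1e-9)
  expect_equal(f1$objective_trace, f2$objective_trace, tolerance = 1e-9)
})

test_that("memberships are nearly hard as the fuzzifier approaches one", {
  spec <- make_separable_scenario(n = 150, s = 6, K = 2, separation = 0.05,
                                  seed = 3)
  d <- generate_categorical(spec)
  fit <- fuzzy_cluster(d, clustering_config(K = 2, m = 1.01, seed = 2))
  expect_true(all(apply(fit$membership, 1, max) >= 0.99))
})

test_that("the mode-centroid variant scores by Hamming distance", {
  d <- random_dataset(40, 3, seed = 14)
  fit <- fuzzy_cluster(d, clustering_config(K = 2, m = 1.2,
                                            centroid = "mode", seed = 4))
  mc <- fit$centroids
  expect_s3_class(mc, "mode_centroids")
  expected <- matrix(0, d$n, 2)
  for (j in 1:2) {
    expected[, j] <- rowSums(d$cells != rep(mc$values[j, ], each = d$n))
  }
  expect_equal(fit$distances, expected)
})

test_that("clustering results serialize to readable artifacts", {
  d <- random_dataset(20, 3, seed = 15)
  fit <- fuzzy_cluster(d, clustering_config(K = 2, seed = 5))
  out <- tempfile()
  paths <- write_clustering_result(fit, out)
  U <- utils::read.csv(paths[["membership"]])
  expect_equal(dim(U), c(20L, 2L))
  expect_equal(rowSums(as.matrix(U)), rep(1, 20), tolerance = 1e-9)
  cj <- jsonlite::read_json(paths[["centroids"]])
  expect_named(cj, c("cluster_1", "cluster_2"))
  w <- unlist(cj$cluster_1[[1]])
  expect_equal(sum(w), 1, tolerance = 1e-9)
  tr <- utils::read.csv(paths[["trace"]])
  expect_equal(tr$objective, fit$objective_trace)
})
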