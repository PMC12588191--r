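test_that("K-Means handles the enumerable 1-D instance and determinism", {
  E <- matrix(c(0, 1, 10, 11), 4, 1)
  km <- kmeans_cluster(E, 2, seed = 1)
  expect_equal(sort(as.vector(km$centroids)), c(0.5, 10.5))
  expect_equal(km$inertia, 1)
  expect_equal(km$labels[1], km$labels[2])
  expect_equal(km$labels[3], km$labels[4])

  kn <- kmeans_cluster(E, 4, seed = 1)
  expect_equal(kn$inertia, 0)
  expect_equal(sort(kn$labels), 1:4)
  expect_error(kmeans_cluster(E, 5), "k must be")

  set.seed(21)
  X <- matrix(rnorm(200 * 2), 200)
  expect_identical(kmeans_cluster(X, 3, seed = 7)$labels,
                   kmeans_cluster(X, 3, seed = 7)$labels)
})

test_that("Lloyd inertia is non-increasing and multi-start is at least as good", {
  set.seed(22)
  X <- matrix(rnorm(300 * 2), 300)
  init <- X[1:4, ]
  inertia <- vapply(1:6, function(it) {
    suppressWarnings(stats::kmeans(X, centers = init, iter.max = it,
                                   algorithm = "Lloyd"))$tot.withinss
  }, 0)
  expect_true(all(diff(inertia) <= 1e-9))
  multi <- kmeans_cluster(X, 4, seed = 1, n_init = 10)
  single <- kmeans_cluster(X, 4, seed = 1, n_init = 1)
  expect_lte(multi$inertia, single$inertia + 1e-9)
})

test_that("validity indices match hand computations on {0,1} vs {10,11}", {
  E <- matrix(c(0, 1, 10, 11), 4, 1)
  l <- c(1, 1, 2, 2)
  expect_equal(silhouette_score(E, l), 0.8997, tolerance = 1e-4)
  expect_equal(davies_bouldin(E, l), 0.1, tolerance = 1e-12)
  expect_equal(calinski_harabasz(E, l), 200, tolerance = 1e-12)
})

test_that("validity indices equal brute-force oracles on random instances", {
  set.seed(23)
  for (rep in 1:3) {
    E <- matrix(rnorm(50 * 2), 50)
    l <- sample(1:3, 50, replace = TRUE)
    expect_equal(silhouette_score(E, l), oracle_silhouette(E, l),
                 tolerance = 1e-8)
    expect_equal(davies_bouldin(E, l), oracle_davies_bouldin(E, l),
                 tolerance = 1e-8)
    expect_equal(calinski_harabasz(E, l), oracle_calinski_harabasz(E, l),
                 tolerance = 1e-8)
  }
  # independent library cross-check for the silhouette
  E <- matrix(rnorm(40 * 2), 40)
  l <- sample(1:3, 40, replace = TRUE)
  ref <- mean(cluster::silhouette(l, dist(E))[, 3])
  expect_equal(silhouette_score(E, l), ref, tolerance = 1e-8)
})

test_that("validity indices guard their degenerate cases", {
  E <- matrix(c(0, 0, 0, 0), 4, 1)
  l <- c(1, 1, 2, 2)
  # two clusters drawn from the same distribution: ~0 by symmetry
  set.seed(26)
  Eco <- matrix(rnorm(400 * 2), 400)
  expect_equal(silhouette_score(Eco, rep(1:2, each = 200)), 0,
               tolerance = 0.05)
  expect_error(davies_bouldin(E, l), "coincident")
  expect_error(silhouette_score(E, rep(1, 4)), "at least 2")
  expect_equal(calinski_harabasz(matrix(c(0, 0, 5, 5), 4, 1), l), Inf)
  expect_error(calinski_harabasz(E, seq_len(4)), "1 < k < n")
})

test_that("the elbow rule maximizes the inertia second difference", {
  expect_equal(preictal:::elbow_from_inertia(1:5, c(100, 20, 10, 8, 7)), 2)
  expect_error(preictal:::elbow_from_inertia(1:4, c(5, 5, 6, 7)),
               "degenerate inertia")
})

test_that("select_k recovers four planted blobs in >= 95% of 20 replicates", {
  hits <- 0L
  for (r in 1:20) {
    blobs <- make_blobs(4, 75, rbind(c(0, 0), c(8, 0), c(0, 8), c(8, 8)),
                        sd = 0.6, seed = 100 + r)
    sel <- suppressWarnings(select_k(blobs$X, 2:10, seed = r))
    hits <- hits + (sel$k == 4L)
  }
  expect_gte(hits / 20, 0.95)
})

test_that("DBSCAN and Ward baselines recover planted partitions", {
  blobs <- make_blobs(2, 60, rbind(c(0, 0), c(12, 12)), sd = 0.5, seed = 24)
  db <- dbscan_baseline(blobs$X)
  expect_equal(db$k, 2)
  expect_lt(mean(db$labels == -1), 0.05)
  expect_error(dbscan_baseline(blobs$X[1:5, ]), "at least 10")
  expect_error(dbscan_baseline(blobs$X, eps = 1e-9), "noise")

  E <- matrix(c(0, 1, 10, 11), 4, 1)
  wd <- ward_baseline(E, 2)
  expect_equal(wd$labels[1], wd$labels[2])
  expect_equal(wd$labels[3], wd$labels[4])
  expect_true(wd$labels[1] != wd$labels[3])

  cmp <- baseline_comparison(blobs$X, 2, seed = 1)
  expect_equal(cmp$method, c("kmeans", "dbscan", "ward"))
  expect_true(all(c("silhouette", "davies_bouldin", "calinski_harabasz")
                  %in% names(cmp)))
})

test_that("noise filtering removes only undersized clusters and keeps points", {
  set.seed(25)
  E <- rbind(matrix(rnorm(150 * 2), 150),
             matrix(rnorm(80 * 2, mean = 10), 80),
             matrix(rnorm(19 * 2, mean = c(-10, 10)), 19))
  res <- structure(list(labels = rep(c(1L, 2L, 3L), c(150, 80, 19)), k = 3L,
                        centroids = NULL, inertia = 1, method = "kmeans",
                        seed = 1L), class = "cluster_result")
  nf <- noise_filter(res, E, min_size = 20)
  expect_equal(sum(nf$removed_mask), 19)
  expect_equal(sum(nf$result$labels != -1), 230)
  expect_equal(nf$result$k, 2)
  expect_equal(length(nf$result$labels), 249)          # nothing dropped
  expect_equal(sum(nf$removed_mask) + sum(nf$result$labels != -1), 249)
  expect_true(all(table(nf$result$labels[nf$result$labels != -1]) >= 20))
  expect_equal(nf$report_pre$stage, "pre_filter")
  expect_equal(nf$report_post$stage, "post_filter")

  # all sizes >= threshold: identity
  res2 <- res; res2$labels <- rep(c(1L, 2L), c(150, 99))
  nf2 <- noise_filter(res2, E, min_size = 20)
  expect_identical(nf2$result$labels, res2$labels)
  expect_equal(nf2$report_pre$silhouette, nf2$report_post$silhouette)

  # boundary: a cluster of exactly min_size points is retained
  res3 <- res; res3$labels <- rep(c(1L, 2L), c(229, 20))
  nf3 <- noise_filter(res3, E, min_size = 20)
  expect_equal(sum(nf3$removed_mask), 0)

  res4 <- res; res4$labels <- rep(c(1L, 2L), c(10, 239))
  expect_error(noise_filter(res4, E, min_size = 300), "fewer than")
})
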