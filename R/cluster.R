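# Clustering: K-Means with k-means++ multi-start, elbow/silhouette model
# selection, DBSCAN and Ward baselines, internal validity indices, and
# minimum-size noise filtering. Distances are Euclidean throughout; validity
# is computed in whatever space the labels were fitted in (the 2-D embedding
# in the default pipeline).

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  if (k > 1) {
    for (j in 2:k) {
      prob <- if (sum(d2) == 0) rep(1 / n, n) else d2 / sum(d2)
      idx <- sample.int(n, 1, prob = prob)
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
  }
  centers
}

#' K-Means clustering with k-means++ multi-start
#'
#' Lloyd iterations (via [stats::kmeans()]) from seeded k-means++
#' initializations; the best of `n_init` starts by within-cluster sum of
#' squares is returned. Deterministic given `seed`.
#'
#' @param E Numeric matrix of points (rows), e.g. a 2-D embedding.
#' @param k Number of clusters (1 <= k <= n).
#' @param seed Integer seed (default 1).
#' @param n_init Number of restarts (default 10).
#' @param iter_max Lloyd iteration cap per start (default 100).
#' @return A `cluster_result`: labels (1..k), k, centroids, inertia,
#'   method = "kmeans", seed.
#' @export
kmeans_cluster <- function(E, k, seed = 1L, n_init = 10L, iter_max = 100L) {
  E <- as.matrix(E)
  n <- nrow(E)
  if (k < 1 || k > n) stopf("k must be in 1..n (k = %d, n = %d)", k, n)
  if (k == n) {
    return(structure(list(labels = seq_len(n), k = n, centroids = E,
                          inertia = 0, method = "kmeans", seed = seed),
                     class = "cluster_result"))
  }
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_init)) {
      init <- kmeanspp_init(E, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(E, centers = init, iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stopf("all %d K-Means starts failed", n_init)
  structure(list(labels = as.integer(best$cluster), k = k,
                 centroids = best$centers, inertia = best$tot.withinss,
                 method = "kmeans", seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  tab <- table(x$labels[x$labels >= 0])
  cat(sprintf("<cluster_result> %s: k = %d, inertia = %.4g, sizes = %s%s\n",
              x$method, x$k, x$inertia, paste(tab, collapse = "/"),
              if (any(x$labels == -1)) sprintf(" (+%d noise)", sum(x$labels == -1)) else ""))
  invisible(x)
}

pairwise_sq <- function(E) {
  G <- tcrossprod(E)
  d <- diag(G)
  pmax(outer(d, d, `+`) - 2 * G, 0)
}

centroid_matrix <- function(E, labels, cl) {
  cm <- vapply(cl, function(c0) colMeans(E[labels == c0, , drop = FALSE]),
               numeric(ncol(E)))
  if (is.matrix(cm)) t(cm) else matrix(cm, ncol = 1)
}

#' Mean silhouette score
#'
#' For each point, `s = (b - a) / max(a, b)` with `a` the mean distance to
#' its own cluster and `b` the minimum over other clusters of the mean
#' distance; singleton clusters score 0. Points labelled -1 are excluded.
#'
#' @param E Numeric matrix of points.
#' @param labels Integer labels (same length as rows of `E`).
#' @return Mean silhouette over points, in [-1, 1].
#' @export
silhouette_score <- function(E, labels) {
  E <- as.matrix(E)
  keep <- labels != -1
  E <- E[keep, , drop = FALSE]
  labels <- labels[keep]
  cl <- sort(unique(labels))
  if (length(cl) < 2) stopf("silhouette needs at least 2 clusters")
  D <- sqrt(pairwise_sq(E))
  ind <- outer(labels, cl, `==`)            # n x k membership
  sizes <- colSums(ind)
  sums <- D %*% ind                         # n x k: sum of distances to each cluster
  own <- match(labels, cl)
  n <- length(labels)
  a <- numeric(n); b <- numeric(n)
  for (i in seq_len(n)) {
    j <- own[i]
    a[i] <- if (sizes[j] > 1) sums[i, j] / (sizes[j] - 1) else NA_real_
    b[i] <- min(sums[i, -j] / sizes[-j])
  }
  s <- ifelse(is.na(a), 0, (b - a) / pmax(a, b))
  mean(s)
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst ratio `(S_i + S_j) / M_ij`, with `S` the
#' mean distance of members to their centroid and `M` the centroid
#' distance. Lower is better. Errors if two centroids coincide.
#'
#' @inheritParams silhouette_score
#' @return Davies-Bouldin index (>= 0).
#' @export
davies_bouldin <- function(E, labels) {
  E <- as.matrix(E)
  keep <- labels != -1
  E <- E[keep, , drop = FALSE]
  labels <- labels[keep]
  cl <- sort(unique(labels))
  k <- length(cl)
  if (k < 2) stopf("Davies-Bouldin needs at least 2 clusters")
  cents <- centroid_matrix(E, labels, cl)
  S <- vapply(seq_len(k), function(j) {
    pts <- E[labels == cl[j], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cents[j, ])^2)))
  }, 0)
  M <- sqrt(pairwise_sq(cents))
  if (any(M[upper.tri(M)] == 0)) stopf("coincident cluster centroids: Davies-Bouldin undefined")
  r <- vapply(seq_len(k), function(i) {
    max(((S[i] + S[-i]) / M[i, -i]))
  }, 0)
  mean(r)
}

#' Calinski-Harabasz score
#'
#' Between-cluster dispersion over within-cluster dispersion, scaled by
#' degrees of freedom: `[B / (k - 1)] / [W / (n - k)]`. Higher is better.
#' Returns `Inf` when all within-cluster scatter is zero.
#'
#' @inheritParams silhouette_score
#' @return Calinski-Harabasz score (>= 0, possibly `Inf`).
#' @export
calinski_harabasz <- function(E, labels) {
  E <- as.matrix(E)
  keep <- labels != -1
  E <- E[keep, , drop = FALSE]
  labels <- labels[keep]
  cl <- sort(unique(labels))
  k <- length(cl)
  n <- nrow(E)
  if (k <= 1 || k >= n) stopf("Calinski-Harabasz needs 1 < k < n")
  grand <- colMeans(E)
  B <- 0; W <- 0
  for (c0 in cl) {
    pts <- E[labels == c0, , drop = FALSE]
    cen <- colMeans(pts)
    B <- B + nrow(pts) * sum((cen - grand)^2)
    W <- W + sum(sweep(pts, 2, cen)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Validity report for a labelling
#'
#' @inheritParams silhouette_score
#' @param stage Either `"pre_filter"` or `"post_filter"`.
#' @return A `validation_report`: silhouette, Davies-Bouldin,
#'   Calinski-Harabasz, per-cluster sizes, stage.
#' @export
validation_report <- function(E, labels, stage = "pre_filter") {
  sizes <- table(labels[labels != -1])
  structure(list(silhouette = silhouette_score(E, labels),
                 davies_bouldin = davies_bouldin(E, labels),
                 calinski_harabasz = calinski_harabasz(E, labels),
                 cluster_sizes = sizes,
                 n_noise = sum(labels == -1),
                 stage = stage),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> [%s] silhouette %.3f | DB %.3f | CH %.1f | sizes %s\n",
              x$stage, x$silhouette, x$davies_bouldin, x$calinski_harabasz,
              paste(x$cluster_sizes, collapse = "/")))
  invisible(x)
}

# Elbow rule: the interior k maximizing the second difference of the
# inertia curve, (I[k-1] - I[k]) - (I[k] - I[k+1]). Errors on a curve that
# never decreases.
elbow_from_inertia <- function(ks, inertia) {
  if (all(diff(inertia) >= 0)) {
    stopf("degenerate inertia curve (non-decreasing over the whole scan)")
  }
  sec <- diff(inertia, differences = 2)     # at ks[2..len-1]
  ks[which.max(sec) + 1L]
}

#' Select the number of clusters by elbow and silhouette scans
#'
#' Runs K-Means over `k_range` (inertia is also computed for k = 1 so the
#' elbow is defined at the smallest scanned k). The elbow choice maximizes
#' the second difference of the inertia curve; the silhouette choice
#' maximizes the mean silhouette (smallest k wins ties). The returned `k`
#' is the silhouette choice, with a warning when the two disagree.
#'
#' @param E Numeric matrix of points.
#' @param k_range Candidate cluster counts (default 2:10).
#' @param seed Integer seed.
#' @param n_init K-Means restarts per k.
#' @return List with `k`, `elbow_k`, `silhouette_k` and a `diagnostics`
#'   data frame (k, inertia, mean silhouette).
#' @export
select_k <- function(E, k_range = 2:10, seed = 1L, n_init = 10L) {
  E <- as.matrix(E)
  n <- nrow(E)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > n - 1) {
    stopf("k_range must lie within [2, n - 1]")
  }
  ks <- c(min(k_range) - 1L, k_range)       # include k - 1 for the elbow
  inertia <- numeric(length(ks))
  sil <- rep(NA_real_, length(ks))
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    if (k == 1) {
      inertia[i] <- sum(sweep(E, 2, colMeans(E))^2)
    } else {
      fit <- kmeans_cluster(E, k, seed = derive_seed(seed, paste0("k", k)),
                            n_init = n_init)
      fits[[i]] <- fit
      inertia[i] <- fit$inertia
      sil[i] <- silhouette_score(E, fit$labels)
    }
  }
  elbow_k <- elbow_from_inertia(ks, inertia)
  scan <- which(ks >= min(k_range))
  sil_scan <- sil[scan]
  silhouette_k <- ks[scan][which.max(sil_scan)]  # which.max takes first: smallest k on ties
  if (elbow_k != silhouette_k) {
    warnf("elbow (k = %d) and silhouette (k = %d) disagree; using silhouette",
          elbow_k, silhouette_k)
  }
  list(k = silhouette_k, elbow_k = elbow_k, silhouette_k = silhouette_k,
       best_fit = fits[[scan[which.max(sil_scan)]]],
       diagnostics = data.frame(k = ks, inertia = inertia, silhouette = sil))
}

#' DBSCAN baseline
#'
#' Density-based clustering with `eps` chosen automatically from the knee of
#' the sorted k-distance curve (k = 2 * dimension) unless supplied;
#' `min_samples = 5`. Noise points receive label -1.
#'
#' @param E Numeric matrix of points (n >= 10).
#' @param eps Neighborhood radius; `NULL` (default) for the knee heuristic.
#' @param min_samples Core-point threshold (default 5).
#' @return A `cluster_result` with method = "dbscan".
#' @export
dbscan_baseline <- function(E, eps = NULL, min_samples = 5L) {
  E <- as.matrix(E)
  n <- nrow(E)
  if (n < 10) stopf("DBSCAN baseline needs at least 10 points")
  D <- sqrt(pairwise_sq(E))
  if (is.null(eps)) {
    kk <- 2L * ncol(E)
    kdist <- sort(apply(D, 1, function(r) sort(r)[kk + 1L]))
    # knee: farthest point of the curve from the chord between its endpoints
    x <- seq_along(kdist); y <- kdist
    x1 <- x[1]; y1 <- y[1]; x2 <- x[n]; y2 <- y[n]
    num <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1)
    eps <- kdist[which.max(num)]
    if (eps <= 0) eps <- stats::median(kdist)
  }
  nb <- D <= eps
  core <- rowSums(nb) >= min_samples         # includes self
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (!core[q]) next
      for (j in which(nb[q, ])) {
        if (labels[j] == -1L) {
          labels[j] <- cl
          if (core[j]) queue <- c(queue, j)
        }
      }
    }
  }
  if (cl == 0L) stopf("DBSCAN found no clusters (all points noise at eps = %.4g)", eps)
  cents <- centroid_matrix(E, labels, seq_len(cl))
  inertia <- sum(vapply(seq_len(cl), function(c0) {
    sum(sweep(E[labels == c0, , drop = FALSE], 2, cents[c0, ])^2)
  }, 0))
  structure(list(labels = labels, k = cl, centroids = cents, inertia = inertia,
                 method = "dbscan", seed = NA_integer_, eps = eps,
                 min_samples = min_samples),
            class = "cluster_result")
}

#' Ward agglomerative baseline
#'
#' Hierarchical clustering minimizing the within-cluster variance increase
#' (Ward's criterion on Euclidean distances), cut at `k` clusters.
#'
#' @param E Numeric matrix of points.
#' @param k Number of clusters.
#' @return A `cluster_result` with method = "ward".
#' @export
ward_baseline <- function(E, k) {
  E <- as.matrix(E)
  if (k < 1 || k > nrow(E)) stopf("k must be in 1..n")
  hc <- stats::hclust(stats::dist(E), method = "ward.D2")
  labels <- as.integer(stats::cutree(hc, k = k))
  cents <- centroid_matrix(E, labels, seq_len(k))
  inertia <- sum(vapply(seq_len(k), function(c0) {
    sum(sweep(E[labels == c0, , drop = FALSE], 2, cents[c0, ])^2)
  }, 0))
  structure(list(labels = labels, k = k, centroids = cents, inertia = inertia,
                 method = "ward", seed = NA_integer_),
            class = "cluster_result")
}

#' Side-by-side validity comparison of clustering methods
#'
#' @param E Numeric matrix of points.
#' @param k Cluster count for K-Means and Ward.
#' @param seed Seed for K-Means.
#' @return Data frame with one row per method (kmeans, dbscan, ward) and
#'   columns optimal_clusters, silhouette, davies_bouldin,
#'   calinski_harabasz.
#' @export
baseline_comparison <- function(E, k, seed = 1L) {
  fits <- list(kmeans = kmeans_cluster(E, k, seed = seed),
               dbscan = dbscan_baseline(E),
               ward = ward_baseline(E, k))
  do.call(rbind, lapply(names(fits), function(m) {
    f <- fits[[m]]
    data.frame(method = m,
               optimal_clusters = f$k,
               silhouette = silhouette_score(E, f$labels),
               davies_bouldin = davies_bouldin(E, f$labels),
               calinski_harabasz = calinski_harabasz(E, f$labels),
               stringsAsFactors = FALSE)
  }))
}

#' Remove undersized clusters as noise
#'
#' Members of clusters with fewer than `min_size` points are relabelled -1
#' (retained in the output with a removal mask, never dropped), and the
#' validity metrics are recomputed on the retained points.
#'
#' @param result A `cluster_result`.
#' @param E The points the result was fitted on (for metric recomputation).
#' @param min_size Strict threshold: clusters with size < `min_size` are
#'   removed; size == `min_size` is retained (default 20).
#' @return List with `result` (filtered labels, updated k), `removed_mask`
#'   (logical), `report_pre` and `report_post` (validity before/after).
#' @export
noise_filter <- function(result, E, min_size = 20L) {
  labels <- result$labels
  sizes <- table(labels[labels != -1])
  undersized <- as.integer(names(sizes)[sizes < min_size])
  if (length(undersized) == length(sizes)) {
    stopf("every cluster has fewer than %d points", min_size)
  }
  report_pre <- validation_report(E, labels, stage = "pre_filter")
  removed_mask <- labels %in% undersized
  new_labels <- labels
  new_labels[removed_mask] <- -1L
  filtered <- result
  filtered$labels <- new_labels
  filtered$k <- length(unique(new_labels[new_labels != -1]))
  report_post <- validation_report(E, new_labels, stage = "post_filter")
  list(result = filtered, removed_mask = removed_mask,
       report_pre = report_pre, report_post = report_post)
}

#' Write cluster labels as TSV
#'
#' @param result A `cluster_result`.
#' @param path Output TSV path.
#' @param row_ids Optional row identifiers.
#' @param removed_mask Optional logical mask of noise-filtered rows.
#' @return `path`, invisibly.
#' @export
write_labels <- function(result, path, row_ids = NULL, removed_mask = NULL) {
  df <- data.frame(row_id = row_ids %||% seq_along(result$labels),
                   label = result$labels,
                   removed = removed_mask %||% (result$labels == -1L))
  write_tsv(df, path)
  invisible(path)
}
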