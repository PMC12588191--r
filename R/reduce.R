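# Dimensionality reduction: column-standardized PCA with a cumulative
# explained-variance threshold, then a 2-D fuzzy-neighbor embedding.

#' Variance-thresholded PCA
#'
#' Standardizes columns (zero mean, unit variance; zero-variance columns are
#' dropped with a warning), performs PCA, and retains the smallest number of
#' leading components whose cumulative explained variance reaches
#' `var_threshold`.
#'
#' @param X Numeric matrix (n x p) or a `feature_matrix`.
#' @param var_threshold Cumulative explained-variance target (default 0.95).
#' @return List with `scores` (n x n_components), `n_components`,
#'   `cumulative_variance`, `explained_variance_ratio` (all components) and
#'   `dropped_columns`.
#' @export
fit_pca <- function(X, var_threshold = 0.95) {
  if (inherits(X, "feature_matrix")) X <- X$values
  X <- as.matrix(X)
  if (nrow(X) < 2) stopf("PCA needs at least 2 rows")
  mu <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2, mu)^2) * nrow(X) / (nrow(X) - 1))
  drop_idx <- which(sds == 0 | !is.finite(sds))
  if (length(drop_idx)) {
    warnf("dropping %d zero-variance column(s) before PCA", length(drop_idx))
    X <- X[, -drop_idx, drop = FALSE]
    mu <- mu[-drop_idx]; sds <- sds[-drop_idx]
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  # eigendecomposition of the (smaller of the two) Gram/covariance matrices
  n <- nrow(Xs); p <- ncol(Xs)
  if (n <= p) {
    G <- tcrossprod(Xs) / (n - 1)
    eg <- eigen(G, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    evr <- ev / sum(ev)
    ncomp <- which(cumsum(evr) >= var_threshold - 1e-12)[1]
    scores <- eg$vectors[, seq_len(ncomp), drop = FALSE] %*%
      diag(sqrt(ev[seq_len(ncomp)] * (n - 1)), ncomp)
  } else {
    C <- crossprod(Xs) / (n - 1)
    eg <- eigen(C, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    evr <- ev / sum(ev)
    ncomp <- which(cumsum(evr) >= var_threshold - 1e-12)[1]
    scores <- Xs %*% eg$vectors[, seq_len(ncomp), drop = FALSE]
  }
  list(scores = scores, n_components = ncomp,
       cumulative_variance = sum(evr[seq_len(ncomp)]),
       explained_variance_ratio = evr,
       dropped_columns = drop_idx)
}

# Fit the attraction-curve parameters (a, b) so that 1 / (1 + a d^(2b))
# approximates the piecewise target exp(-(d - min_dist)) beyond min_dist.
find_ab <- function(min_dist, spread = 1) {
  d <- seq(0, 3 * spread, length.out = 300)
  target <- ifelse(d <= min_dist, 1, exp(-(d - min_dist) / spread))
  obj <- function(par) {
    a <- par[1]; b <- par[2]
    if (a <= 0 || b <= 0) return(1e6)
    sum((1 / (1 + a * d^(2 * b)) - target)^2)
  }
  fit <- stats::optim(c(1, 1), obj, method = "Nelder-Mead")
  list(a = fit$par[1], b = fit$par[2])
}

smooth_knn_sigma <- function(dists, rho, target, n_iter = 64, tol = 1e-5) {
  lo <- 0; hi <- Inf; mid <- 1
  for (it in seq_len(n_iter)) {
    val <- sum(exp(-pmax(dists - rho, 0) / mid))
    if (abs(val - target) < tol) break
    if (val > target) {
      hi <- mid; mid <- (lo + hi) / 2
    } else {
      lo <- mid
      mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2
    }
  }
  mid
}

#' Two-dimensional fuzzy-neighbor embedding
#'
#' Builds a fuzzy k-nearest-neighbor graph (per-point distance offset `rho`
#' and smooth-kNN bandwidth calibrated to log2(k), symmetrized by fuzzy
#' union) and lays it out in 2-D by stochastic gradient descent on the
#' cross-entropy with negative sampling, PCA-initialized. Deterministic
#' given `seed`.
#'
#' @param scores Numeric matrix (n x d), e.g. PCA scores.
#' @param n_neighbors Neighborhood size (default 15); must be < n.
#' @param min_dist Minimum embedding distance parameter (default 0.1).
#' @param metric Distance metric; only "euclidean" is supported.
#' @param seed Integer seed (default 42).
#' @param n_epochs SGD epochs (default 200).
#' @return n x 2 coordinate matrix with attributes `params`.
#' @export
fit_embedding <- function(scores, n_neighbors = 15, min_dist = 0.1,
                          metric = "euclidean", seed = 42, n_epochs = 200) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (!identical(metric, "euclidean")) stopf("only the euclidean metric is supported")
  if (n <= n_neighbors) {
    stopf("n (%d) must exceed n_neighbors (%d); use a smaller n_neighbors", n, n_neighbors)
  }
  dm <- as.matrix(stats::dist(scores))
  knn_idx <- matrix(0L, n, n_neighbors)
  knn_dist <- matrix(0, n, n_neighbors)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ])[-1][seq_len(n_neighbors)]   # drop self
    knn_idx[i, ] <- ord
    knn_dist[i, ] <- dm[i, ord]
  }
  target <- log2(n_neighbors)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- knn_dist[i, ]
    pos <- di[di > 0]
    rho <- if (length(pos)) min(pos) else 0
    sigma <- smooth_knn_sigma(di, rho, target)
    W[i, knn_idx[i, ]] <- exp(-pmax(di - rho, 0) / sigma)
  }
  Wsym <- W + t(W) - W * t(W)                         # fuzzy union
  ab <- find_ab(min_dist)
  # PCA initialization scaled to a +/-10 box with a tiny seeded jitter
  pc <- fit_pca_init(scores)
  init <- pc / max(abs(pc)) * 10
  init <- init + with_seed(seed, matrix(rnorm(2 * n, sd = 1e-4), n, 2))
  edges <- which(Wsym > 0, arr.ind = TRUE)
  wts <- Wsym[edges]
  keep <- wts >= max(wts) / n_epochs
  edges <- edges[keep, , drop = FALSE]
  wts <- wts[keep]
  eps <- max(wts) / wts                               # epochs per sample
  emb <- embed_sgd_cpp(init, as.integer(edges[, 1] - 1L),
                       as.integer(edges[, 2] - 1L), eps, ab$a, ab$b,
                       as.integer(n_epochs), 1.0, 5L, as.numeric(seed))
  attr(emb, "params") <- list(n_neighbors = n_neighbors, min_dist = min_dist,
                              metric = metric, seed = seed, n_epochs = n_epochs,
                              a = ab$a, b = ab$b)
  emb
}

fit_pca_init <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  sv <- La.svd(Xc, nu = 0, nv = 2)
  Xc %*% t(sv$vt)
}

#' Run the two-step reduction (PCA then embedding)
#'
#' @param fm A `feature_matrix` or numeric matrix.
#' @param var_threshold PCA cumulative-variance threshold (default 0.95).
#' @param n_neighbors,min_dist,seed,n_epochs Passed to [fit_embedding()].
#' @return A `reduction_result`: list with `pca` (from [fit_pca()]),
#'   `embedding` (n x 2) and `params`.
#' @export
reduce_features <- function(fm, var_threshold = 0.95, n_neighbors = 15,
                            min_dist = 0.1, seed = 42, n_epochs = 200) {
  pca <- fit_pca(fm, var_threshold)
  emb <- fit_embedding(pca$scores, n_neighbors = n_neighbors,
                       min_dist = min_dist, seed = seed, n_epochs = n_epochs)
  structure(list(pca = pca, embedding = emb,
                 params = attr(emb, "params")),
            class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("<reduction_result> %d points: %d PCs (%.1f%% variance) -> 2-D embedding\n",
              nrow(x$embedding), x$pca$n_components,
              100 * x$pca$cumulative_variance))
  invisible(x)
}

#' Write an embedding as TSV with a JSON sidecar
#'
#' @param red A `reduction_result`.
#' @param path Output TSV path.
#' @param row_ids Optional row identifiers.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(red, path, row_ids = NULL) {
  df <- data.frame(row_id = row_ids %||% seq_len(nrow(red$embedding)),
                   x = red$embedding[, 1], y = red$embedding[, 2])
  write_tsv(df, path)
  write_json_sidecar(c(list(n_components = red$pca$n_components,
                            cumulative_variance = red$pca$cumulative_variance),
                       red$params),
                     paste0(path, ".json"))
  invisible(path)
}
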