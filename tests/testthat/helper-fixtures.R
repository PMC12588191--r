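# Shared fixtures and independent oracles. Expensive synthetic datasets are
# generated once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# one default synthetic window with ground truth
fixture_window <- function(seed = 7) {
  cached(paste0("window", seed),
         generate_window(default_spec(42), seed = seed))
}

# 200 default windows + truths (used by several recovery invariants)
fixture_recovery_windows <- function() {
  cached("recovery200", {
    spec <- default_spec(42)
    set.seed(21)
    lapply(seq_len(200), function(i) generate_window(spec))
  })
}

# a single-channel test window wrapper
toy_window <- function(x, fs = 256, label = "FP1-F7", subject = "T01") {
  preictal_window(matrix(x, nrow = 1), fs = fs, channel_labels = label,
                  subject_id = subject)
}

# cheap multi-channel window of the given duration (low sampling rate)
cheap_window <- function(duration_s = 30, fs = 4, n_ch = 2, subject = "T01",
                         seizure_index = 1L) {
  preictal_window(matrix(seq_len(n_ch * duration_s * fs) * 1.0, nrow = n_ch),
                  fs = fs, channel_labels = paste0("C", seq_len(n_ch)),
                  subject_id = subject, seizure_index = seizure_index,
                  window_id = sprintf("%s_w%02d", subject, seizure_index))
}

# --- brute-force oracles -----------------------------------------------------

oracle_silhouette <- function(E, labels) {
  E <- as.matrix(E)
  n <- nrow(E)
  D <- as.matrix(dist(E))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_davies_bouldin <- function(E, labels) {
  E <- as.matrix(E)
  cl <- sort(unique(labels))
  k <- length(cl)
  cen <- lapply(cl, function(c0) colMeans(E[labels == c0, , drop = FALSE]))
  S <- vapply(seq_len(k), function(j) {
    pts <- E[labels == cl[j], , drop = FALSE]
    mean(sqrt(rowSums((pts - matrix(cen[[j]], nrow(pts), ncol(E),
                                    byrow = TRUE))^2)))
  }, 0)
  r <- numeric(k)
  for (i in seq_len(k)) {
    r[i] <- max(vapply(setdiff(seq_len(k), i), function(j) {
      (S[i] + S[j]) / sqrt(sum((cen[[i]] - cen[[j]])^2))
    }, 0))
  }
  mean(r)
}

oracle_calinski_harabasz <- function(E, labels) {
  E <- as.matrix(E)
  cl <- sort(unique(labels))
  n <- nrow(E); k <- length(cl)
  grand <- colMeans(E)
  B <- 0; W <- 0
  for (c0 in cl) {
    pts <- E[labels == c0, , drop = FALSE]
    cen <- colMeans(pts)
    B <- B + nrow(pts) * sum((cen - grand)^2)
    W <- W + sum((pts - matrix(cen, nrow(pts), ncol(E), byrow = TRUE))^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

oracle_sampen <- function(x, m = 2, r = 0.2 * sqrt(mean((x - mean(x))^2))) {
  n <- length(x)
  B <- 0; A <- 0
  for (i in seq_len(n - m)) {
    for (j in seq_len(n - m)) {
      if (j <= i) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(list(value = 0, B = B, A = A))
  list(value = -log(A / B), B = B, A = A)
}

oracle_perm_entropy <- function(x, order = 3, delay = 1) {
  n <- length(x)
  pats <- character(0)
  for (i in seq_len(n - (order - 1) * delay)) {
    v <- x[i + (0:(order - 1)) * delay]
    pats <- c(pats, paste(order(v), collapse = ""))  # order(): stable, first-occurrence ties
  }
  p <- table(pats) / length(pats)
  -sum(p * log(p)) / log(factorial(order))
}

# gaussian blobs for clustering tests
make_blobs <- function(k, n_per, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per), 2,
          centers[i, ], "+")
  }))
  list(X = X, labels = rep(seq_len(k), each = n_per))
}
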