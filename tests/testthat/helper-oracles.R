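# Independent oracles and small fixtures, deliberately written without
# reference to the package's own code paths.

# random non-negative 32x32 frame
random_frame <- function(seed, rows = 32L, cols = 32L) {
  withr::with_seed(seed, matrix(runif(rows * cols), rows, cols))
}

# brute-force sample covariance between all column pairs, divisor n - 1
oracle_covariance <- function(m) {
  n <- nrow(m)
  p <- ncol(m)
  out <- matrix(0, p, p)
  for (a in seq_len(p)) {
    for (b in seq_len(p)) {
      xa <- m[, a] - mean(m[, a])
      xb <- m[, b] - mean(m[, b])
      out[a, b] <- sum(xa * xb) / (n - 1)
    }
  }
  out
}

# power iteration with deflation: top-k eigenvalues of a symmetric PSD matrix
oracle_top_eigenvalues <- function(s, k, iters = 50000L, tol = 1e-12) {
  s <- (s + t(s)) / 2
  vals <- numeric(k)
  for (j in seq_len(k)) {
    v <- rep(1 / sqrt(nrow(s)), nrow(s))
    lam_old <- Inf
    for (it in seq_len(iters)) {
      w <- s %*% v
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) break
      v <- as.vector(w / nw)
      lam <- as.numeric(crossprod(v, s %*% v))
      if (abs(lam - lam_old) < tol * max(1, abs(lam))) break
      lam_old <- lam
    }
    lam <- as.numeric(crossprod(v, s %*% v))
    vals[j] <- lam
    s <- s - lam * tcrossprod(v)
  }
  vals
}

# exhaustive best-matching-unit scan
oracle_bmu <- function(x, weights) {
  d <- apply(weights, 1L, function(w) sqrt(sum((x - w)^2)))
  list(index = which(d == min(d))[1L], distance = min(d))
}

# four-way one-vs-rest partition by explicit cell loop
oracle_ovr <- function(cm, cls) {
  classes <- rownames(cm)
  tp <- fp <- fn <- tn <- 0
  for (a in classes) {
    for (p in classes) {
      v <- cm[a, p]
      if (a == cls && p == cls) tp <- tp + v
      else if (a == cls) fn <- fn + v
      else if (p == cls) fp <- fp + v
      else tn <- tn + v
    }
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# small labeled feature set from the synthetic generator (pooled basis)
make_features <- function(n_per_class, seed, ...) {
  ds <- generate_dataset(n_per_class, seed = seed, ...)
  list(features = frames_to_features(ds, mode = "pooled"),
       labels = ds$meta$label, dataset = ds)
}
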