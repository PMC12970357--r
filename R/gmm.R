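# Full-covariance Gaussian mixture fitted by EM, initialised from a
# k-means partition. Covariances carry a small diagonal regulariser so
# min-max-scaled features (which can be locally degenerate) stay
# well-conditioned.

gmm_log_density <- function(X, mean, cov) {
  d <- ncol(X)
  ch <- chol(cov)
  logdet <- 2 * sum(log(diag(ch)))
  Xc <- sweep(X, 2, mean)
  q <- colSums(backsolve(ch, t(Xc), transpose = TRUE)^2)
  -0.5 * (d * log(2 * pi) + logdet + q)
}

# n x k matrix of log posterior responsibilities (up to the row constant)
gmm_log_responsibilities <- function(X, gmm) {
  k <- length(gmm$weights)
  L <- vapply(seq_len(k), function(j)
    log(gmm$weights[j]) + gmm_log_density(X, gmm$means[j, ], gmm$covariances[[j]]),
    numeric(nrow(X)))
  if (!is.matrix(L)) L <- matrix(L, nrow = nrow(X))
  L
}

fit_gmm <- function(X, k, reg = 1e-6, max_iter = 200, tol = 1e-8) {
  n <- nrow(X); d <- ncol(X)
  km <- run_kmeans(X, k, n_init = 10)
  lab <- km$cluster
  weights <- tabulate(lab, k) / n
  means <- km$centers
  covariances <- lapply(seq_len(k), function(j) {
    idx <- lab == j
    S <- if (sum(idx) > 1) stats::cov(X[idx, , drop = FALSE]) else diag(d)
    S + diag(reg, d)
  })
  gmm <- list(weights = weights, means = means, covariances = covariances)
  ll_old <- -Inf; it <- 0L
  for (it in seq_len(max_iter)) {
    L <- gmm_log_responsibilities(X, gmm)
    mx <- apply(L, 1, max)
    R <- exp(L - mx)
    rs <- rowSums(R)
    ll <- sum(mx + log(rs))
    R <- R / rs
    nk <- colSums(R)
    nk[nk < 1e-10] <- 1e-10
    gmm$weights <- nk / n
    gmm$means <- sweep(t(R) %*% X, 1, nk, `/`)
    for (j in seq_len(k)) {
      Xc <- sweep(X, 2, gmm$means[j, ])
      S <- t(Xc * R[, j]) %*% Xc / nk[j]
      gmm$covariances[[j]] <- S + diag(reg, d)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(centroids = gmm$means, gmm = gmm, iterations = it, objective = -ll_old)
}
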