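#' Subspace k-means
#'
#' Jointly learns an orthogonal transformation `V` splitting feature
#' space into an m-dimensional clustered subspace and its (d-m)-
#' dimensional noise complement, together with a k-partition, by
#' alternating minimisation:
#'
#' 1. assign each point to the centroid nearest in the projection onto
#'    the first `m` columns of `V`;
#' 2. update centroids as cluster means (the noise-space "centroid" is
#'    the global data mean);
#' 3. update `V` from the eigendecomposition of the difference between
#'    the pooled within-cluster scatter and the total scatter, taking
#'    eigenvectors in ascending eigenvalue order and setting `m` to the
#'    number of negative eigenvalues.
#'
#' The objective (projected within-cluster scatter plus noise-space
#' scatter around the global mean) is non-increasing across iterations;
#' the loop stops at an assignment fixpoint or `max_iter`. Restarted
#' `n_init` times from random orthogonal bases; best objective kept.
#'
#' @param X feature matrix.
#' @param k number of clusters.
#' @param m_init initial clustered-subspace dimension (default
#'   `floor(d/2)`).
#' @param seed integer seed.
#' @param n_init number of restarts.
#' @param max_iter iteration cap per restart.
#' @return a `cluster_model` with a `subspace` component (`V`, `m`) and
#'   the per-iteration `objective_trace` of the winning restart.
#' @export
fit_subkmeans <- function(X, k, m_init = NULL, seed = 1L, n_init = 10, max_iter = 100) {
  fit_clustering(X, k, algorithm = "subkmeans", seed = seed,
                 m_init = m_init, n_init = n_init, max_iter = max_iter)
}

subkmeans_objective <- function(X, V, m, centroids, lab, gmean) {
  d <- ncol(X)
  Vm <- V[, seq_len(m), drop = FALSE]
  within <- sum(((X - centroids[lab, , drop = FALSE]) %*% Vm)^2)
  if (m < d) {
    Vn <- V[, (m + 1):d, drop = FALSE]
    noise <- sum((sweep(X, 2, gmean) %*% Vn)^2)
  } else noise <- 0
  within + noise
}

subkmeans_once <- function(X, k, m, max_iter) {
  n <- nrow(X); d <- ncol(X)
  gmean <- colMeans(X)
  Xc <- sweep(X, 2, gmean)
  S_D <- crossprod(Xc)
  V <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
  centroids <- X[sample.int(n, k), , drop = FALSE]
  lab <- rep(0L, n)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    Vm <- V[, seq_len(m), drop = FALSE]
    new_lab <- max.col(-dist2_to_centroids(X %*% Vm, centroids %*% Vm),
                       ties.method = "first")
    # re-seed empty clusters at the point farthest from its centroid
    for (j in which(tabulate(new_lab, k) == 0)) {
      far <- which.max(rowSums(((X - centroids[new_lab, , drop = FALSE]) %*% Vm)^2))
      centroids[j, ] <- X[far, ]
      new_lab[far] <- j
    }
    if (identical(new_lab, lab)) break
    lab <- new_lab
    for (j in seq_len(k)) centroids[j, ] <- colMeans(X[lab == j, , drop = FALSE])
    S <- matrix(0, d, d)
    for (j in seq_len(k)) {
      Cc <- sweep(X[lab == j, , drop = FALSE], 2, centroids[j, ])
      S <- S + crossprod(Cc)
    }
    eg <- eigen(S - S_D, symmetric = TRUE)
    ord <- order(eg$values)
    V <- eg$vectors[, ord, drop = FALSE]
    m <- max(1L, sum(eg$values < 0))
    trace <- c(trace, subkmeans_objective(X, V, m, centroids, lab, gmean))
  }
  list(V = V, m = m, centroids = centroids, lab = lab, iterations = it,
       objective = subkmeans_objective(X, V, m, centroids, lab, gmean),
       trace = trace)
}

fit_subkmeans_impl <- function(X, k, m_init = NULL, n_init = 10, max_iter = 100) {
  d <- ncol(X)
  m0 <- m_init %||% max(1L, floor(d / 2))
  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- subkmeans_once(X, k, m0, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  list(centroids = best$centroids,
       subspace = list(V = best$V, m = as.integer(best$m)),
       iterations = best$iterations, objective = best$objective,
       objective_trace = best$trace)
}
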