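# squared Euclidean distances of rows of X to rows of C
dist2_to_centroids <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), `+`) - 2 * X %*% t(C)
  d2[d2 < 0] <- 0
  d2
}

# k-means++ seeding: first centre uniform, then prob proportional to the
# squared distance to the nearest chosen centre
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (sum(d2) > 0) {
      pick <- sample.int(n, 1, prob = d2)
    } else pick <- sample.int(n, 1)
    centers[j + 1, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j + 1, ], n, ncol(X), byrow = TRUE))^2))
  }
  centers
}

run_kmeans <- function(X, k, n_init = 10, iter.max = 100) {
  if (k == nrow(X))  # stats::kmeans requires k < n; this partition is trivial
    return(list(centers = X, cluster = seq_len(k), tot.withinss = 0, iter = 0L))
  best <- NULL
  for (i in seq_len(n_init)) {
    init <- kmeanspp_init(X, k)
    if (anyDuplicated(init)) {
      # fewer distinct points than k in a degenerate (re)sample: jitter
      # duplicated seeds so the fit proceeds; duplicates end up empty-ish
      dup <- duplicated(init)
      init[dup, ] <- init[dup, , drop = FALSE] +
        matrix(rnorm(sum(dup) * ncol(X), sd = 1e-9), sum(dup))
    }
    fit <- tryCatch(suppressWarnings(kmeans(X, centers = init, iter.max = iter.max)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed on all restarts")
  best
}

run_minibatch <- function(X, k, batch_size = 1024, iterations = 100) {
  n <- nrow(X)
  b <- min(batch_size, n)
  C <- kmeanspp_init(X, k)
  counts <- rep(0, k)
  for (it in seq_len(iterations)) {
    idx <- sample.int(n, b, replace = FALSE)
    B <- X[idx, , drop = FALSE]
    a <- max.col(-dist2_to_centroids(B, C), ties.method = "first")
    for (j in seq_len(b)) {
      c <- a[j]
      counts[c] <- counts[c] + 1
      lr <- 1 / counts[c]
      C[c, ] <- (1 - lr) * C[c, ] + lr * B[j, ]
    }
  }
  C
}

#' Fit a clustering model
#'
#' Uniform front end over the partitioning algorithms evaluated by the
#' stability framework: `"kmeans"` (k-means++ seeding, 10 restarts, best
#' objective kept), `"minibatch_kmeans"` (batch size 1024),
#' `"gmm"` (full-covariance EM with 1e-6 diagonal regularisation) and
#' `"subkmeans"` (joint subspace + partition, see [fit_subkmeans()]).
#' All algorithms are deterministic under `seed`.
#'
#' @param X numeric feature matrix (rows = observations).
#' @param k number of clusters, `2 <= k <= nrow(X)` (k = n is allowed
#'   and gives a zero-objective partition).
#' @param algorithm one of `"kmeans"`, `"minibatch_kmeans"`, `"gmm"`,
#'   `"subkmeans"`.
#' @param seed integer seed.
#' @param ... algorithm hyperparameters (`n_init`, `batch_size`,
#'   `iterations`, `m_init`, `max_iter`).
#' @return object of class `cluster_model`: `algorithm`, `k`,
#'   `centroids` (k x d, feature space), optional `subspace`
#'   (orthogonal `V`, clustered dimension `m`), optional `gmm`
#'   (weights/means/covariances), `seed`, `iterations`, `objective`.
#' @export
fit_clustering <- function(X, k, algorithm = c("kmeans", "minibatch_kmeans",
                                               "gmm", "subkmeans"),
                           seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  X <- stopifnot_finite_matrix(X)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(X)) stop("k (", k, ") exceeds the number of rows (", nrow(X), ")")
  dots <- list(...)
  with_seed(seed, {
    model <- switch(algorithm,
      kmeans = {
        fit <- run_kmeans(X, k, n_init = dots$n_init %||% 10)
        list(centroids = fit$centers, iterations = fit$iter,
             objective = fit$tot.withinss)
      },
      minibatch_kmeans = {
        C <- run_minibatch(X, k, batch_size = dots$batch_size %||% 1024,
                           iterations = dots$iterations %||% 100)
        a <- max.col(-dist2_to_centroids(X, C), ties.method = "first")
        list(centroids = C, iterations = dots$iterations %||% 100,
             objective = sum((X - C[a, , drop = FALSE])^2))
      },
      gmm = fit_gmm(X, k, reg = dots$reg %||% 1e-6,
                    max_iter = dots$max_iter %||% 200),
      subkmeans = fit_subkmeans_impl(X, k, m_init = dots$m_init %||% NULL,
                                     n_init = dots$n_init %||% 10,
                                     max_iter = dots$max_iter %||% 100)
    )
    structure(c(model, list(algorithm = algorithm, k = as.integer(k),
                            seed = as.integer(seed))),
              class = "cluster_model")
  })
}

#' Assign observations to the clusters of a fitted model
#'
#' Nearest centroid in Euclidean distance (within the clustered subspace
#' for subKmeans); maximum posterior responsibility for GMM. Ties break
#' to the lowest cluster index. Assignment is deterministic given the
#' model.
#'
#' @param model a [fit_clustering()] result.
#' @param X feature matrix in the model's feature space.
#' @return integer vector of 1-based cluster labels.
#' @export
assign_clusters <- function(model, X) {
  X <- stopifnot_finite_matrix(X)
  if (ncol(X) != ncol(model$centroids))
    stop("X has ", ncol(X), " features but the model expects ", ncol(model$centroids))
  if (model$algorithm == "gmm") {
    r <- gmm_log_responsibilities(X, model$gmm)
    return(max.col(r, ties.method = "first"))
  }
  C <- model$centroids
  if (!is.null(model$subspace)) {
    Vm <- model$subspace$V[, seq_len(model$subspace$m), drop = FALSE]
    X <- X %*% Vm
    C <- C %*% Vm
  }
  max.col(-dist2_to_centroids(X, C), ties.method = "first")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> ", x$algorithm, ", k=", x$k,
      if (!is.null(x$subspace)) paste0(", subspace m=", x$subspace$m),
      ", objective=", format(x$objective), "\n", sep = "")
  invisible(x)
}

#' Serialise a cluster model to JSON
#'
#' Stores everything needed to reapply the selected clustering to a new
#' cohort (centroids, subspace, mixture parameters, metadata).
#'
#' @param model a `cluster_model`.
#' @param path JSON path.
#' @export
write_cluster_model <- function(model, path) {
  x <- unclass(model)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$centroids <- as.matrix(x$centroids)
  if (!is.null(x$subspace)) x$subspace$V <- as.matrix(x$subspace$V)
  if (!is.null(x$gmm)) {
    x$gmm$means <- as.matrix(x$gmm$means)
    cv <- x$gmm$covariances
    if (is.array(cv) && length(dim(cv)) == 3) {  # simplified to k x d x d
      cv <- lapply(seq_len(dim(cv)[1]), function(j) cv[j, , ])
    } else cv <- lapply(cv, as.matrix)
    x$gmm$covariances <- cv
  }
  if (!is.null(x$cluster_order)) x$cluster_order <- as.integer(x$cluster_order)
  structure(x, class = "cluster_model")
}
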