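#' Jaccard index between two member sets
#'
#' `|a intersect b| / |a union b|`, the overlap score underlying
#' bootstrap cluster stability: 0 means no overlap in assignments, 1
#' identical assignments. Defined as 1 when both sets are empty.
#'
#' @param a,b vectors of observation indices over the same universe.
#' @return score in [0, 1].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Bootstrap Jaccard stability of a clustering
#'
#' Fits a reference model on all of `X`, then for each of `B` bootstrap
#' resamples (with replacement, size n) refits the algorithm and extends
#' the bootstrap clustering to the complete set of observations via
#' [assign_clusters()], so stability is always evaluated on the same
#' universe and no direct centroid mapping is needed (which is
#' unreliable when clusters split or merge across resamples). Each
#' reference cluster's stability against one bootstrap replicate is the
#' maximum Jaccard overlap between its member set and any bootstrap
#' cluster's member set; per-cluster stability is the mean over the `B`
#' replicates, each observation inherits its reference cluster's
#' stability, and global stability is the mean over clusters.
#'
#' @param X feature matrix.
#' @param k number of clusters.
#' @param algorithm passed to [fit_clustering()].
#' @param B number of bootstrap iterations (default 20).
#' @param seed integer seed; results are deterministic under it.
#' @param ... hyperparameters forwarded to [fit_clustering()].
#' @return list: `per_cluster`, `per_observation`, `global`, the
#'   reference `model` and `ref_labels`, `flagged_iterations` (bootstrap
#'   replicates in which some extended cluster came back empty; their
#'   scores are computed as-is under the empty-set Jaccard rule).
#' @export
bootstrap_stability <- function(X, k, algorithm = "kmeans", B = 20, seed = 1L, ...) {
  X <- stopifnot_finite_matrix(X)
  n <- nrow(X)
  if (B < 1) stop("B must be >= 1")
  if (n < 5 * k) stop("need at least 5*k rows for a meaningful bootstrap (n=", n, ")")
  seeds <- child_seeds(seed, 2L * B + 1L)
  model <- fit_clustering(X, k, algorithm = algorithm, seed = seeds[1], ...)
  ref <- assign_clusters(model, X)
  ref_members <- lapply(seq_len(k), function(c) which(ref == c))

  scores <- matrix(0, B, k)
  flagged <- integer(0)
  for (b in seq_len(B)) {
    idx <- with_seed(seeds[2 * b], sample.int(n, n, replace = TRUE))
    mb <- fit_clustering(X[idx, , drop = FALSE], k, algorithm = algorithm,
                         seed = seeds[2 * b + 1], ...)
    bl <- assign_clusters(mb, X)
    boot_members <- lapply(seq_len(k), function(c) which(bl == c))
    if (any(lengths(boot_members) == 0)) flagged <- c(flagged, b)
    for (c in seq_len(k)) {
      scores[b, c] <- max(vapply(boot_members, jaccard_index,
                                 numeric(1), a = ref_members[[c]]))
    }
  }
  per_cluster <- colMeans(scores)
  list(per_cluster = per_cluster,
       per_observation = per_cluster[ref],
       global = mean(per_cluster),
       model = model, ref_labels = ref,
       B = B, seed = as.integer(seed),
       flagged_iterations = flagged)
}

#' Build a stability profile over algorithms and cluster counts
#'
#' For each algorithm and each k in `k_range`, runs `n_repeats`
#' independent [bootstrap_stability()] replicates on disjoint seed
#' streams and retains the most stable replicate's clustering; the
#' profile records that replicate's global stability per (algorithm, k).
#' The reported profile belongs to the algorithm whose best k attains
#' the highest stability.
#'
#' @param X feature matrix.
#' @param algorithms character vector of engine names.
#' @param k_range candidate cluster counts (default 2:7).
#' @param B bootstrap iterations per replicate (default 20).
#' @param n_repeats replicates per (algorithm, k) (default 5);
#'   `n_repeats = 1` reduces to a single [bootstrap_stability()] run.
#' @param seed integer seed.
#' @param ... forwarded to [fit_clustering()].
#' @return object of class `stability_profile`: `table` (algorithm, k,
#'   stability of the retained replicate, mean over repeats), `results`
#'   (retained replicate per algorithm and k), `algorithm` (the winning
#'   engine), `k_range`, `B`, `n_repeats`, `seed`.
#' @export
stability_profile <- function(X, algorithms = "kmeans", k_range = 2:7,
                              B = 20, n_repeats = 5, seed = 1L, ...) {
  if (length(k_range) == 0) stop("k_range is empty")
  rows <- list(); results <- list()
  seeds <- child_seeds(seed, length(algorithms) * length(k_range) * n_repeats)
  s <- 0L
  for (alg in algorithms) {
    results[[alg]] <- list()
    for (k in k_range) {
      reps <- vector("list", n_repeats)
      for (r in seq_len(n_repeats)) {
        s <- s + 1L
        reps[[r]] <- bootstrap_stability(X, k, algorithm = alg, B = B,
                                         seed = seeds[s], ...)
      }
      globals <- vapply(reps, `[[`, numeric(1), "global")
      best <- which.max(globals)
      results[[alg]][[as.character(k)]] <- reps[[best]]
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = alg, k = k, stability = globals[best],
        mean_stability = mean(globals), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  best_by_alg <- vapply(split(tab$stability, tab$algorithm), max, numeric(1))
  structure(list(table = tab,
                 results = results,
                 algorithm = names(best_by_alg)[which.max(best_by_alg)],
                 k_range = k_range, B = B, n_repeats = n_repeats,
                 seed = as.integer(seed)),
            class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat("<stability_profile> algorithms:",
      paste(unique(x$table$algorithm), collapse = ", "),
      "| selected engine:", x$algorithm, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Select the optimal number of clusters from a stability profile
#'
#' The optimal k is the largest k in the evaluated range whose stability
#' strictly exceeds `threshold` (default 0.90, the conventional bar for
#' well-separated clusters). When no k qualifies, returns
#' `none-above-threshold` with the argmax k recorded as a suggestion.
#'
#' @param profile a [stability_profile()] or a named numeric vector of
#'   stabilities keyed by k (the winning algorithm's values are used for
#'   a profile object).
#' @param threshold stability bar (strict inequality).
#' @return list: `selected_k` (integer, or `NA` if none qualifies),
#'   `status` (`"selected"` or `"none-above-threshold"`),
#'   `suggestion` (argmax k), `trace` (the stabilities consulted).
#' @export
select_optimal_k <- function(profile, threshold = 0.90) {
  if (inherits(profile, "stability_profile")) {
    tab <- profile$table[profile$table$algorithm == profile$algorithm, ]
    stab <- setNames(tab$stability, tab$k)
  } else {
    stab <- profile
    if (is.null(names(stab))) stop("stabilities must be named by k")
  }
  ks <- as.integer(names(stab))
  ok <- stab > threshold
  if (any(ok)) {
    list(selected_k = max(ks[ok]), status = "selected",
         suggestion = ks[which.max(stab)], trace = stab)
  } else {
    list(selected_k = NA_integer_, status = "none-above-threshold",
         suggestion = ks[which.max(stab)], trace = stab)
  }
}

#' Stable-centroid estimation and burden-ordered relabelling
#'
#' Re-estimates each centroid from the member observations whose
#' stability strictly exceeds `threshold`, then reindexes clusters by
#' increasing median total WMH volume of their members (cluster 1 =
#' lowest burden). A cluster with no observation above the threshold
#' keeps its raw centroid and is flagged.
#'
#' @param model a `cluster_model`.
#' @param per_observation per-row stability vector aligned to `X`.
#' @param X feature matrix the model was fitted on.
#' @param total_wmh per-row total WMH volumes used for ordering.
#' @param threshold stability bar (default 0.90).
#' @return the model with updated, reordered `centroids`, plus
#'   `cluster_medians` (ordered median totals), `stable_flag` (clusters
#'   whose centroid could not be re-estimated), and `cluster_order`
#'   (old index of each new cluster).
#' @export
stable_centroids <- function(model, per_observation, X, total_wmh, threshold = 0.90) {
  X <- stopifnot_finite_matrix(X)
  if (length(per_observation) != nrow(X))
    stop("per_observation stability must align with the rows of X")
  lab <- assign_clusters(model, X)
  k <- model$k
  cent <- model$centroids
  flagged <- logical(k)
  for (c in seq_len(k)) {
    sel <- lab == c & per_observation > threshold
    if (any(sel)) cent[c, ] <- colMeans(X[sel, , drop = FALSE])
    else flagged[c] <- TRUE
  }
  med <- vapply(seq_len(k), function(c) median(total_wmh[lab == c]), numeric(1))
  ord <- order(med)
  model$centroids <- cent[ord, , drop = FALSE]
  if (!is.null(model$gmm)) {
    model$gmm$means <- model$gmm$means[ord, , drop = FALSE]
    model$gmm$weights <- model$gmm$weights[ord]
    model$gmm$covariances <- model$gmm$covariances[ord]
  }
  model$cluster_medians <- med[ord]
  model$stable_flag <- flagged[ord]
  model$cluster_order <- ord
  model
}
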