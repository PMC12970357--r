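#' Gradient-boosted tree classifier
#'
#' Binary classifier built by gradient boosting with logistic loss:
#' stage-wise regression trees are fitted to the pseudo-residuals
#' `y - p`, leaf values are set by a Newton step
#' `sum(w (y - p)) / sum(w p (1 - p))`, and the additive score is
#' updated with shrinkage `learning_rate`. Per-observation weights
#' implement inverse class weighting. Tree growth is exhaustive over
#' midpoint splits (no stochastic subsampling), so fitting is
#' deterministic for fixed inputs.
#'
#' @param X numeric predictor matrix.
#' @param y 0/1 (or logical) response.
#' @param weights per-observation weights (default inverse class
#'   frequency, normalised to mean 1).
#' @param n_trees number of boosting rounds.
#' @param max_depth maximum tree depth.
#' @param learning_rate shrinkage (default 0.1).
#' @param min_leaf minimum observations per leaf.
#' @return object of class `gbt_model`.
#' @export
fit_gbt <- function(X, y, weights = NULL, n_trees = 100, max_depth = 3,
                    learning_rate = 0.1, min_leaf = 5) {
  X <- stopifnot_finite_matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2) stop("training data contains a single class")
  w <- weights %||% inverse_class_weights(y)
  pbar <- sum(w * y) / sum(w)
  f0 <- log(pbar / (1 - pbar))
  Fhat <- rep(f0, nrow(X))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    p <- stats::plogis(Fhat)
    resid <- y - p
    tree <- gbt_grow_tree(X, resid, w, as.integer(max_depth), as.integer(min_leaf))
    leaf <- gbt_leaf_index(tree, X)
    h <- w * p * (1 - p)
    num <- tapply(w * resid, leaf, sum)
    den <- tapply(h, leaf, sum)
    gamma <- numeric(length(tree$feature))
    gamma[as.integer(names(num))] <- pmax(-4, pmin(4, num / pmax(den, 1e-12)))
    tree$gamma <- gamma
    trees[[t]] <- tree
    Fhat <- Fhat + learning_rate * gamma[leaf]
  }
  structure(list(f0 = f0, trees = trees, learning_rate = learning_rate,
                 n_trees = n_trees, max_depth = max_depth,
                 feature_names = colnames(X)),
            class = "gbt_model")
}

inverse_class_weights <- function(y) {
  freq <- table(y) / length(y)
  w <- 1 / as.numeric(freq[as.character(y)])
  w / mean(w)
}

#' @rdname fit_gbt
#' @param object a `gbt_model`.
#' @param newdata predictor matrix.
#' @param type `"prob"` for P(y = 1) or `"class"` for 0/1 predictions
#'   (threshold 0.5).
#' @param ... unused.
#' @export
predict.gbt_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- stopifnot_finite_matrix(newdata)
  Fhat <- rep(object$f0, nrow(X))
  for (tree in object$trees)
    Fhat <- Fhat + object$learning_rate * tree$gamma[gbt_leaf_index(tree, X)]
  p <- stats::plogis(Fhat)
  if (type == "prob") p else as.integer(p > 0.5)
}
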