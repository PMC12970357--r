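#' Annualised change in total WMH volume
#'
#' For every participant with a baseline (timepoint 0) and at least one
#' follow-up row, computes `(V_follow - V_base) / interval` after both
#' volumes are normalised by the participant's baseline ICV and rescaled
#' to the reference ICV, i.e. mm^3/year on the reference-ICV scale. If a
#' participant has several follow-ups, the earliest within
#' `interval_window` is used.
#'
#' @param table cohort table with `timepoint` and `interval_years`.
#' @param reference_icv_mm3 reference ICV (e.g. the fitted transform's
#'   `reference_icv_mm3`); volumes are put on this common scale.
#' @param interval_window inclusive follow-up interval window in years
#'   (default 1-7).
#' @return data.frame: `participant_id`, `baseline_total_mm3` (reference
#'   scale), `change_mm3_per_year`, `interval_years`.
#' @export
annualised_change <- function(table, reference_icv_mm3, interval_window = c(1, 7)) {
  base <- table[table$timepoint == 0, ]
  fu <- table[table$timepoint > 0 &
                table$interval_years >= interval_window[1] &
                table$interval_years <= interval_window[2], ]
  if (nrow(fu) == 0) stop("no follow-up rows within the interval window")
  fu <- fu[order(fu$participant_id, fu$interval_years), ]
  fu <- fu[!duplicated(fu$participant_id), ]
  m <- match(fu$participant_id, base$participant_id)
  if (anyNA(m)) stop("follow-up rows without a baseline row: ",
                     paste(head(fu$participant_id[is.na(m)]), collapse = ", "))
  b <- base[m, ]
  if (any(fu$interval_years <= 0)) stop("non-positive follow-up interval")
  scale <- reference_icv_mm3 / b$icv_mm3
  data.frame(participant_id = fu$participant_id,
             baseline_total_mm3 = b$total_wmh_mm3 * scale,
             change_mm3_per_year = (fu$total_wmh_mm3 - b$total_wmh_mm3) *
               scale / fu$interval_years,
             interval_years = fu$interval_years,
             stringsAsFactors = FALSE)
}

#' Dichotomise annualised change into progression groups
#'
#' A participant is a progressor iff the annualised change strictly
#' exceeds the threshold (default 250 mm^3/year on the reference-ICV
#' scale); boundary cases are non-progressors.
#'
#' @param changes output of [annualised_change()] (or a numeric vector).
#' @param threshold mm^3/year.
#' @return the input with a `progressor` logical column (or a logical
#'   vector for numeric input).
#' @export
label_progression <- function(changes, threshold = 250) {
  if (is.numeric(changes)) return(changes > threshold)
  changes$progressor <- changes$change_mm3_per_year > threshold
  changes
}

#' Remove the effect of covariates from a continuous variable
#'
#' OLS residuals of `x` on the covariates (complete cases; other
#' entries return NA). Residuals are orthogonal to the fitted covariate
#' columns by construction.
#'
#' @param x numeric vector.
#' @param covariates data.frame of covariates aligned to `x`.
#' @return numeric vector of residuals.
#' @export
residualize <- function(x, covariates) {
  covariates <- as.data.frame(covariates)
  num <- vapply(covariates, is.numeric, logical(1))
  if (any(vapply(covariates[num], function(v) var(v, na.rm = TRUE) == 0, logical(1))))
    stop("constant covariate in residualisation")
  cc <- complete.cases(covariates) & !is.na(x)
  out <- rep(NA_real_, length(x))
  fit <- lm(x[cc] ~ ., data = covariates[cc, , drop = FALSE])
  out[cc] <- residuals(fit)
  out
}

#' Compare variables between progressors and non-progressors
#'
#' Continuous variables are residualised on age and sex and compared
#' with Mann-Whitney U tests; categorical variables are compared with
#' Pearson chi-squared tests on the raw contingency table (no
#' continuity correction; tables with expected cell counts below 5 are
#' flagged). All p-values are BH-adjusted as one family.
#'
#' @param data data.frame of baseline rows.
#' @param group logical (or two-level) vector: progressor indicator.
#' @param variables character vector of columns of `data` to test.
#' @param residualize_on covariates removed from continuous variables
#'   (default age and sex); skipped for the covariates themselves.
#' @return data.frame: `variable`, `test`, `statistic`, `p`,
#'   `p_adjusted`, `flag`.
#' @export
compare_groups <- function(data, group, variables,
                           residualize_on = c("age", "sex")) {
  g <- as.logical(group)
  if (!any(g) || !all(is.na(g) | g | !g) || all(g, na.rm = TRUE))
    if (length(unique(g[!is.na(g)])) < 2) stop("both groups must be nonempty")
  rows <- list()
  for (v in variables) {
    x <- data[[v]]
    if (is.numeric(x)) {
      covs <- setdiff(residualize_on, v)
      xr <- if (length(covs)) residualize(x, data[, covs, drop = FALSE]) else x
      wt <- suppressWarnings(wilcox.test(xr[g], xr[!g]))
      rows[[v]] <- data.frame(variable = v, test = "mann-whitney",
                              statistic = unname(wt$statistic), p = wt$p.value,
                              flag = "", stringsAsFactors = FALSE)
    } else {
      tab <- table(x, g)
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      flag <- if (any(ct$expected < 5)) "expected<5" else ""
      rows[[v]] <- data.frame(variable = v, test = "chi-squared",
                              statistic = unname(ct$statistic), p = ct$p.value,
                              flag = flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[, c("variable", "test", "statistic", "p", "p_adjusted", "flag")]
}

#' Build train-fitted predictor sets for progression prediction
#'
#' Defines the baseline predictor families and fits every data-derived
#' parameter on the training rows only: the PCA of regional volumes
#' (components kept = the minimal count explaining more than
#' `pca_variance` cumulative variance) and the ICV reference come from
#' `train`; test or external rows are later transformed with these
#' stored parameters. Available base sets: `RF` (age, sex indicator,
#' systolic blood pressure), `WMHV` (total volume), `RWMHV` (36
#' regional volumes), `distance` (Euclidean distances to the k cluster
#' centroids), `clusters` (one-hot cluster assignment), `PCV` (PC
#' scores of RWMHV). Unions are written `"RWMHV+PCV+RF"`.
#'
#' @param train baseline training rows of a cohort table.
#' @param model fitted `cluster_model` (needed for `distance`/`clusters`).
#' @param transform fitted `feature_transform`.
#' @param pca_variance cumulative-variance rule for `PCV` (default 0.8).
#' @return object of class `predictor_sets`; use [predictor_matrix()] to
#'   realise a named set on any table.
#' @export
build_predictor_sets <- function(train, model = NULL, transform = NULL,
                                 pca_variance = 0.8) {
  regions <- bullseye_regions()
  ref <- if (!is.null(transform)) transform$reference_icv_mm3 else median(train$icv_mm3)
  R <- as.matrix(train[, regions]) / train$icv_mm3 * ref
  pca <- prcomp(R, center = TRUE, scale. = FALSE)
  cumvar <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  ncomp <- which(cumvar > pca_variance)[1]
  structure(list(model = model, transform = transform,
                 reference_icv_mm3 = ref,
                 pca_center = pca$center,
                 pca_rotation = pca$rotation[, seq_len(ncomp), drop = FALSE],
                 n_components = as.integer(ncomp),
                 pca_cumvar = cumvar[ncomp]),
            class = "predictor_sets")
}

#' Realise a predictor set as a numeric matrix
#'
#' @param sets a [build_predictor_sets()] object.
#' @param table cohort table rows to transform (train, test or external).
#' @param name set name, e.g. `"RWMHV"` or `"RWMHV+distance+RF"`.
#' @return numeric matrix with one row per row of `table`.
#' @export
predictor_matrix <- function(sets, table, name) {
  regions <- bullseye_regions()
  ref <- sets$reference_icv_mm3
  R <- as.matrix(table[, regions]) / table$icv_mm3 * ref
  part <- function(nm) {
    switch(nm,
      RF = cbind(age = table$age,
                 sex_female = as.numeric(table$sex == "female"),
                 sbp = table$sbp),
      WMHV = cbind(total_wmh = table$total_wmh_mm3 / table$icv_mm3 * ref),
      RWMHV = R,
      PCV = {
        S <- sweep(R, 2, sets$pca_center) %*% sets$pca_rotation
        colnames(S) <- paste0("PC", seq_len(ncol(S)))
        S
      },
      distance = {
        if (is.null(sets$model)) stop("distance set requires a cluster model")
        f <- cohort_features(table, sets$transform)
        if (length(f$rows) != nrow(table))
          stop("distance set undefined for zero-WMH rows")
        D <- centroid_distances(f$features, sets$model)$distance
        colnames(D) <- paste0("dist", seq_len(ncol(D)))
        D
      },
      clusters = {
        if (is.null(sets$model)) stop("clusters set requires a cluster model")
        f <- cohort_features(table, sets$transform)
        if (length(f$rows) != nrow(table))
          stop("clusters set undefined for zero-WMH rows")
        lab <- assign_clusters(sets$model, f$features)
        oh <- vapply(seq_len(sets$model$k), function(c) as.numeric(lab == c),
                     numeric(length(lab)))
        if (!is.matrix(oh)) oh <- matrix(oh, nrow = 1)
        colnames(oh) <- paste0("cluster", seq_len(sets$model$k))
        oh
      },
      stop("unknown predictor set '", nm, "'"))
  }
  parts <- lapply(strsplit(name, "+", fixed = TRUE)[[1]], part)
  do.call(cbind, parts)
}

#' Train the progression classifier with hyperparameter tuning
#'
#' Gradient-boosted trees tuned over the grid {50, 100, 200} estimators
#' x tree depth {2, 3, 4, 5} by stratified 5-fold cross-validated
#' balanced accuracy, with inverse class weights re-derived within each
#' training fold; the winning configuration is refitted on the full
#' training set. Deterministic under `seed`.
#'
#' @param X training predictor matrix.
#' @param y 0/1 progression labels.
#' @param grid data.frame with columns `n_trees`, `max_depth`.
#' @param n_folds CV folds (default 5).
#' @param seed integer seed (drives fold assignment).
#' @param learning_rate shrinkage passed to [fit_gbt()].
#' @return list: `model` (refitted `gbt_model`), `best` (chosen row),
#'   `cv_results` (grid with `cv_balanced_accuracy`), `seed`.
#' @export
train_progression_classifier <- function(X, y,
                                         grid = expand.grid(n_trees = c(50, 100, 200),
                                                            max_depth = 2:5),
                                         n_folds = 5, seed = 1L,
                                         learning_rate = 0.1) {
  X <- stopifnot_finite_matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("training data contains a single class")
  folds <- with_seed(seed, {
    f <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    f
  })
  cv <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    accs <- numeric(n_folds)
    for (fd in seq_len(n_folds)) {
      tr <- folds != fd
      fit <- fit_gbt(X[tr, , drop = FALSE], y[tr],
                     weights = inverse_class_weights(y[tr]),
                     n_trees = grid$n_trees[g], max_depth = grid$max_depth[g],
                     learning_rate = learning_rate)
      pred <- predict(fit, X[!tr, , drop = FALSE], type = "class")
      accs[fd] <- balanced_accuracy(pred, y[!tr])
    }
    cv[g] <- mean(accs)
  }
  best <- which.max(cv)
  model <- fit_gbt(X, y, weights = inverse_class_weights(y),
                   n_trees = grid$n_trees[best], max_depth = grid$max_depth[best],
                   learning_rate = learning_rate)
  list(model = model, best = grid[best, , drop = FALSE],
       cv_results = cbind(grid, cv_balanced_accuracy = cv),
       seed = as.integer(seed))
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity, robust to class imbalance.
#'
#' @param pred predicted 0/1 labels.
#' @param truth true 0/1 labels (both classes must be present).
#' @return value in [0, 1].
#' @export
balanced_accuracy <- function(pred, truth) {
  truth <- as.numeric(truth); pred <- as.numeric(pred)
  for (cls in c(0, 1)) if (!any(truth == cls))
    stop("class ", cls, " is absent from the evaluation labels")
  sens <- mean(pred[truth == 1] == 1)
  spec <- mean(pred[truth == 0] == 0)
  (sens + spec) / 2
}

#' Evaluate a classifier with a bootstrap confidence interval
#'
#' Percentile bootstrap over the test rows (default 1000 resamples);
#' resamples missing one class contribute nothing to the interval.
#'
#' @param model a `gbt_model`.
#' @param X,y test predictors and 0/1 labels.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param conf_level interval level (default 0.95).
#' @return list: `balanced_accuracy`, `ci` (length 2), `n_boot_used`.
#' @export
evaluate_classifier <- function(model, X, y, n_boot = 1000, seed = 1L,
                                conf_level = 0.95) {
  pred <- predict(model, X, type = "class")
  ba <- balanced_accuracy(pred, y)
  n <- length(y)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) < 2) return(NA_real_)
      balanced_accuracy(pred[idx], y[idx])
    }, numeric(1))
  })
  boots <- boots[!is.na(boots)]
  alpha <- (1 - conf_level) / 2
  list(balanced_accuracy = ba,
       ci = unname(quantile(boots, c(alpha, 1 - alpha))),
       n_boot_used = length(boots))
}

#' McNemar comparison of two classifiers on the same test set
#'
#' Chi-squared test with continuity correction on the discordant-pair
#' counts (A correct/B wrong vs A wrong/B correct); returns p = 1 when
#' there are no discordant pairs.
#'
#' @param pred_a,pred_b predicted labels from the two models.
#' @param truth true labels.
#' @return list: `b`, `c` (discordant counts), `statistic`, `p`.
#' @export
mcnemar_compare <- function(pred_a, pred_b, truth) {
  ca <- pred_a == truth; cb <- pred_b == truth
  b <- sum(ca & !cb); cc <- sum(!ca & cb)
  if (b + cc == 0) return(list(b = b, c = cc, statistic = 0, p = 1))
  stat <- (abs(b - cc) - 1)^2 / (b + cc)
  list(b = b, c = cc, statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

#' Compare predictor sets for progression prediction
#'
#' Trains one tuned classifier per predictor set on the training rows,
#' evaluates each on the test rows with bootstrap CIs, and compares all
#' pairs with BH-adjusted McNemar tests.
#'
#' @param sets a [build_predictor_sets()] object (train-fitted).
#' @param train,test baseline cohort rows with a `progressor` column.
#' @param set_names character vector of set names (unions allowed).
#' @param seed integer seed.
#' @param n_boot bootstrap resamples for test CIs.
#' @param ... forwarded to [train_progression_classifier()].
#' @return object of class `prediction_report`: `results` (per-set CV
#'   and test balanced accuracies with CIs, chosen hyperparameters),
#'   `mcnemar` (pairwise comparisons with `p_adjusted`).
#' @export
compare_predictor_sets <- function(sets, train, test, set_names, seed = 1L,
                                   n_boot = 1000, ...) {
  seeds <- child_seeds(seed, length(set_names) + 1L)
  y_tr <- as.numeric(train$progressor)
  y_te <- as.numeric(test$progressor)
  fits <- list(); preds <- list(); rows <- list()
  for (i in seq_along(set_names)) {
    nm <- set_names[i]
    Xtr <- predictor_matrix(sets, train, nm)
    Xte <- predictor_matrix(sets, test, nm)
    tr <- train_progression_classifier(Xtr, y_tr, seed = seeds[i], ...)
    ev <- evaluate_classifier(tr$model, Xte, y_te, n_boot = n_boot,
                              seed = seeds[length(seeds)])
    fits[[nm]] <- tr
    preds[[nm]] <- predict(tr$model, Xte, type = "class")
    rows[[nm]] <- data.frame(
      set = nm,
      cv_balanced_accuracy = max(tr$cv_results$cv_balanced_accuracy),
      test_balanced_accuracy = ev$balanced_accuracy,
      ci_lower = ev$ci[1], ci_upper = ev$ci[2],
      n_trees = tr$best$n_trees, max_depth = tr$best$max_depth,
      stringsAsFactors = FALSE)
  }
  mc <- list()
  if (length(set_names) > 1) {
    for (i in seq_along(set_names)) for (j in seq_along(set_names)) if (i < j) {
      m <- mcnemar_compare(preds[[i]], preds[[j]], y_te)
      mc[[length(mc) + 1L]] <- data.frame(set_a = set_names[i], set_b = set_names[j],
                                          b = m$b, c = m$c, p = m$p,
                                          stringsAsFactors = FALSE)
    }
    mc <- do.call(rbind, mc)
    mc$p_adjusted <- bh_adjust(mc$p)
  } else mc <- NULL
  structure(list(results = do.call(rbind, rows), mcnemar = mc, fits = fits,
                 seed = as.integer(seed)),
            class = "prediction_report")
}
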