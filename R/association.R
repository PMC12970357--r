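#' Distances and proximities to cluster centroids
#'
#' Euclidean distances in the clustering feature space; proximity is the
#' literal inverse distance `1 / (d + eps)` with a small guard `eps` so
#' rows lying exactly at a centroid receive the maximum finite
#' proximity. Proximity is strictly decreasing in distance.
#'
#' @param X feature matrix (rows in the centroids' feature space).
#' @param centroids k x d centroid matrix (or a `cluster_model`).
#' @param eps guard added to the distance (default 1e-8).
#' @return list: `distance` (n x k), `proximity` (n x k).
#' @export
centroid_distances <- function(X, centroids, eps = 1e-8) {
  if (inherits(centroids, "cluster_model")) centroids <- centroids$centroids
  X <- stopifnot_finite_matrix(X)
  if (ncol(X) != ncol(centroids))
    stop("X has ", ncol(X), " features but centroids have ", ncol(centroids))
  d <- sqrt(dist2_to_centroids(X, centroids))
  list(distance = d, proximity = 1 / (d + eps))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: sorted p-values are scaled by
#' `m / rank` and a running minimum from the largest rank down enforces
#' monotonicity; results are capped at 1 and returned in input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1) return(p)
  ord <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[ord] * m / seq(m, 1)))
  adj[order(ord)]
}

# min-max scale the continuous model variables to [0,1]; categorical
# variables become indicator columns against their stated reference level
riskfactor_reference_levels <- function() {
  list(sex = "male", smoking = "never", ethnicity = "white",
       diabetes = "no", hypertension = "no",
       med_chol = "no", med_bp = "no", med_dm = "no", apoe4 = "0")
}

encode_predictor <- function(data, name) {
  refs <- riskfactor_reference_levels()
  x <- data[[name]]
  if (is.null(x)) stop("risk factor '", name, "' not found in the table")
  if (name %in% names(refs)) {
    x <- as.character(x)
    ref <- refs[[name]]
    levels <- setdiff(unique(x), ref)
    levels <- levels[order(match(levels, c("female", "ever", "current",
                                           "yes", "1", "2")), levels)]
    if (length(levels) == 0)   # constant at the reference level: no columns
      return(as.data.frame(matrix(numeric(0), nrow = length(x), ncol = 0)))
    cols <- lapply(levels, function(l) as.numeric(x == l))
    names(cols) <- paste0(name, "_", levels)
    as.data.frame(cols, check.names = FALSE)
  } else {
    setNames(data.frame(minmax01(as.numeric(x))), name)
  }
}

#' Cross-sectional association of one risk factor with one cluster
#'
#' Ordinary least squares of centroid proximity on the risk factor,
#' adjusted for age, sex and baseline total WMH volume. Continuous
#' predictors are min-max normalised to [0,1] (which makes the estimate
#' invariant to affine rescalings of the raw factor); categorical
#' factors enter as indicators against their reference level (sex:
#' male; smoking: never; ethnicity: white; diagnoses/medications: no;
#' APOE4: 0 alleles). Complete-case analysis; the proximity outcome is
#' used unscaled.
#'
#' @param data data.frame containing the risk factor, the covariates and
#'   a proximity column.
#' @param proximity name of the proximity outcome column (or a numeric
#'   vector aligned to `data`).
#' @param risk_factor name of the risk-factor column.
#' @param cluster cluster index reported in the result rows.
#' @param covariates adjustment set (default age, sex, total baseline
#'   WMH volume; the risk factor itself is dropped from the set when it
#'   coincides with a covariate).
#' @param conf_level confidence level for the t-based interval.
#' @return data.frame of class `association_result`, one row per
#'   non-reference level: `cluster`, `risk_factor`, `term`, `beta`,
#'   `ci_lower`, `ci_upper`, `p`, `n`.
#' @export
fit_association <- function(data, proximity, risk_factor, cluster = NA_integer_,
                            covariates = c("age", "sex", "total_wmh_mm3"),
                            conf_level = 0.95) {
  y <- if (is.character(proximity)) data[[proximity]] else proximity
  covariates <- setdiff(covariates, risk_factor)
  vars <- c(risk_factor, covariates)
  cc <- complete.cases(data[, vars, drop = FALSE]) & !is.na(y)
  d <- data[cc, , drop = FALSE]
  y <- y[cc]
  enc <- lapply(vars, encode_predictor, data = d)
  Xd <- do.call(cbind, enc)
  p_rf <- ncol(enc[[1]])
  if (p_rf == 0)
    stop("risk factor '", risk_factor, "' is constant (reference level only)")
  if (nrow(Xd) < ncol(Xd) + 2)
    stop("too few complete cases (", nrow(Xd), ") for the model")
  const <- vapply(Xd, function(col) var(col) == 0, logical(1))
  if (any(const[seq_len(p_rf)]))
    stop("risk factor '", risk_factor, "' is constant in the complete cases")
  fit <- lm(y ~ ., data = cbind(data.frame(y = y), Xd[!const]))
  sm <- summary(fit)$coefficients
  terms <- names(Xd)[seq_len(p_rf)]
  rows <- lapply(terms, function(tm) {
    tm_r <- make.names(tm)
    est <- sm[tm_r, "Estimate"]
    se <- sm[tm_r, "Std. Error"]
    tq <- qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
    data.frame(cluster = cluster, risk_factor = risk_factor, term = tm,
               beta = est, ci_lower = est - tq * se, ci_upper = est + tq * se,
               p = sm[tm_r, "Pr(>|t|)"], n = length(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("association_result", class(out))
  out
}

#' Associate a set of risk factors with all cluster centroids
#'
#' Runs one [fit_association()] model per (risk factor, cluster) pair —
#' proximity to that cluster's centroid as the outcome — and adjusts all
#' resulting p-values jointly with [bh_adjust()] (the BH family is the
#' full factor-by-cluster grid of one analysis run).
#'
#' @param table cohort table (baseline rows).
#' @param model fitted `cluster_model`.
#' @param transform fitted `feature_transform`.
#' @param risk_factors character vector of risk-factor columns.
#' @param covariates adjustment set for each model.
#' @param eps proximity guard, see [centroid_distances()].
#' @return tidy data.frame (factor-level x cluster) with `p_adjusted`.
#' @export
associate_risk_factors <- function(table, model, transform,
                                   risk_factors = names(riskfactor_baselines()),
                                   covariates = c("age", "sex", "total_wmh_mm3"),
                                   eps = 1e-8) {
  feats <- cohort_features(table, transform)
  tab <- table[feats$rows, , drop = FALSE]
  prox <- centroid_distances(feats$features, model, eps = eps)$proximity
  res <- list()
  for (c in seq_len(model$k)) {
    for (rf in risk_factors) {
      res[[length(res) + 1L]] <-
        fit_association(tab, prox[, c], rf, cluster = c, covariates = covariates)
    }
  }
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
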