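#' ICV normalisation of WMH volumes
#'
#' Divides total and regional WMH volumes by the participant's baseline
#' intracranial volume to account for head size, the normalisation being
#' less affected by atrophy than brain-volume scaling. For reporting in
#' volumetric units, normalised values are rescaled to a common
#' reference ICV (the median baseline ICV of the fitting dataset).
#'
#' @param x numeric vector (or matrix of rows) of volumes in mm^3.
#' @param icv_mm3 the participant's baseline ICV (scalar, or one value
#'   per row of a matrix), must be > 0.
#' @return `x / icv_mm3` (dimensionless).
#' @export
normalize_by_icv <- function(x, icv_mm3) {
  if (any(icv_mm3 <= 0)) stop("icv_mm3 must be > 0")
  if (is.matrix(x)) x / icv_mm3 else x / icv_mm3
}

#' @rdname normalize_by_icv
#' @param transform a fitted [fit_feature_transform()] result (supplies
#'   `reference_icv_mm3`).
#' @export
rescale_to_reference <- function(x, transform) {
  if (!isTRUE(transform$fitted)) stop("feature transform is not fitted")
  x * transform$reference_icv_mm3
}

#' Relative spatial distribution of WMH
#'
#' Divides regional volumes by the row total so the 36 proportions sum
#' to 1. Rows with zero total WMH have no defined spatial distribution
#' and are excluded (their indices returned in attribute `dropped`),
#' since relative distributions are undefined at zero burden.
#'
#' @param volumes numeric matrix (rows = observations, 36 columns) or a
#'   single vector of regional volumes in mm^3.
#' @return matrix (or vector) of proportions; attribute `dropped` lists
#'   excluded zero-total row indices.
#' @export
relative_distribution <- function(volumes) {
  vec <- !is.matrix(volumes)
  V <- if (vec) matrix(volumes, 1) else volumes
  if (any(V < 0)) stop("regional volumes must be >= 0")
  tot <- rowSums(V)
  drop <- which(tot == 0)
  if (vec && length(drop)) stop("relative distribution undefined for zero total WMH")
  keep <- tot > 0
  P <- V[keep, , drop = FALSE] / tot[keep]
  if (vec) return(P[1, ])
  if (length(drop))
    message(length(drop), " row(s) with zero total WMH excluded from relative distribution")
  attr(P, "dropped") <- drop
  P
}

#' Fit the clustering feature transform
#'
#' Clustering features are the 36 regional proportions after elementwise
#' square-root transformation and per-feature min-max scaling to [0,1],
#' with extrema learned on the fitting dataset and stored for
#' out-of-sample application. Constant features scale to 0 with a
#' warning.
#'
#' @param proportions matrix of regional proportions (rows sum to 1).
#' @param icv_mm3 optional vector of baseline ICVs of the fitting
#'   dataset; its median becomes `reference_icv_mm3`.
#' @return list with `transform` (class `feature_transform`: per-feature
#'   `min`/`max` on the sqrt scale, `reference_icv_mm3`, `fitted`) and
#'   `features` (the transformed fitting matrix).
#' @export
fit_feature_transform <- function(proportions, icv_mm3 = NULL) {
  P <- as.matrix(proportions)
  if (nrow(P) < 2) stop("need at least 2 rows to fit the feature transform")
  S <- sqrt(P)
  fmin <- apply(S, 2, min)
  fmax <- apply(S, 2, max)
  if (any(fmax - fmin <= 0))
    warning(sum(fmax - fmin <= 0), " constant feature(s) scaled to 0")
  transform <- structure(list(
    feature_names = colnames(P) %||% bullseye_regions(),
    min = fmin, max = fmax,
    reference_icv_mm3 = if (is.null(icv_mm3)) 1 else median(icv_mm3),
    fitted = TRUE), class = "feature_transform")
  list(transform = transform, features = apply_feature_transform(transform, P))
}

#' Apply a fitted feature transform to new data
#'
#' Out-of-range values (possible on follow-up or external data) clip to
#' [0,1]; the number of clipped entries is reported in attribute
#' `n_clipped` rather than extrapolating silently.
#'
#' @param transform a `feature_transform`.
#' @param proportions matrix of regional proportions.
#' @return feature matrix in [0,1] with attribute `n_clipped`.
#' @export
apply_feature_transform <- function(transform, proportions) {
  if (!isTRUE(transform$fitted)) stop("feature transform is not fitted")
  S <- sqrt(as.matrix(proportions))
  rng <- transform$max - transform$min
  rng[rng <= 0] <- Inf                      # constant features -> 0
  X <- sweep(sweep(S, 2, transform$min), 2, rng, `/`)
  # the counter flags genuine extrapolation, not round-trip ulp noise
  n_clipped <- sum(X < -1e-9 | X > 1 + 1e-9)
  X[X < 0] <- 0; X[X > 1] <- 1
  attr(X, "n_clipped") <- n_clipped
  X
}

#' Serialise a feature transform to JSON
#'
#' @param transform a `feature_transform`.
#' @param path JSON file path.
#' @export
write_feature_transform <- function(transform, path) {
  jsonlite::write_json(unclass(transform), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_transform
#' @export
read_feature_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$min <- setNames(as.numeric(x$min), x$feature_names)
  x$max <- setNames(as.numeric(x$max), x$feature_names)
  structure(x, class = "feature_transform")
}

# cohort table -> clustering feature matrix (plus kept-row indices)
cohort_features <- function(table, transform = NULL) {
  regions <- bullseye_regions()
  V <- as.matrix(table[, regions])
  tot <- rowSums(V)
  keep <- which(tot > 0)
  P <- V[keep, , drop = FALSE] / tot[keep]
  if (is.null(transform)) {
    ft <- fit_feature_transform(P, icv_mm3 = table$icv_mm3[keep])
    list(features = ft$features, transform = ft$transform, rows = keep)
  } else {
    list(features = apply_feature_transform(transform, P), transform = transform,
         rows = keep)
  }
}
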