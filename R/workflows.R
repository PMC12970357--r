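#' Pipeline run configuration
#'
#' Collects every tunable of the phenotyping pipeline with its default:
#' algorithms and k range 2-7 for clustering, 20 bootstrap iterations
#' and 5 repeats for stability with selection threshold 0.90, the
#' 250 mm^3/year progression threshold with follow-up window 1-7 years
#' (18-30 months for the transition workflow), and the sensitivity
#' strata (total-volume bands 0-4 and 4-8 mL, age band 67-72). Any
#' override is recorded in the returned object.
#'
#' @param ... named overrides of the defaults.
#' @return object of class `run_config`; `overrides` lists what was
#'   changed from the defaults.
#' @export
run_config <- function(...) {
  defaults <- list(
    algorithms = "kmeans",
    k_range = 2:7,
    B = 20L,
    n_repeats = 5L,
    stability_threshold = 0.90,
    progression_threshold = 250,
    interval_window = c(1, 7),
    transition_window = c(1.5, 2.5),
    volume_bands_mL = list(c(0, 4), c(4, 8)),
    age_band = c(67, 72),
    proximity_eps = 1e-8,
    pca_variance = 0.8,
    seed = 1L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]  # replace wholesale
  cfg$overrides <- names(overrides) %||% character(0)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  x <- unclass(config); x$overrides <- NULL
  # stable content hash without extra dependencies
  s <- jsonlite::toJSON(x[order(names(x))], digits = NA, auto_unbox = TRUE)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)) %% .Machine$integer.max)
}

#' Full cross-sectional phenotyping workflow
#'
#' Composes the pipeline: relative distributions and the sqrt/min-max
#' feature transform are fitted on the table (zero-WMH rows excluded),
#' the stability profile is built over the configured algorithms and k
#' range, the optimal k is selected, stable centroids are estimated and
#' clusters reindexed by median total burden, and every row receives a
#' cluster assignment and its per-observation stability.
#'
#' @param table cohort table (baseline rows are used).
#' @param config a [run_config()].
#' @return list of artifacts: `transform`, `profile`, `selection`,
#'   `model` (burden-ordered; `NULL` when no k exceeds the threshold),
#'   `table` (baseline rows with `cluster` and `stability` columns),
#'   `config`, `config_hash`.
#' @export
run_phenotyping <- function(table, config = run_config()) {
  base <- table[table$timepoint == 0, , drop = FALSE]
  feats <- cohort_features(base)
  prof <- stability_profile(feats$features, algorithms = config$algorithms,
                            k_range = config$k_range, B = config$B,
                            n_repeats = config$n_repeats, seed = config$seed)
  sel <- select_optimal_k(prof, threshold = config$stability_threshold)
  model <- NULL
  out <- base
  out$cluster <- NA_integer_
  out$stability <- NA_real_
  if (!is.na(sel$selected_k)) {
    res <- prof$results[[prof$algorithm]][[as.character(sel$selected_k)]]
    ref_icv <- feats$transform$reference_icv_mm3
    totals <- base$total_wmh_mm3[feats$rows] / base$icv_mm3[feats$rows] * ref_icv
    model <- stable_centroids(res$model, res$per_observation, feats$features,
                              totals, threshold = config$stability_threshold)
    out$cluster[feats$rows] <- assign_clusters(model, feats$features)
    # stability is a property of the pre-ordering reference clusters
    out$stability[feats$rows] <- res$per_observation
  }
  list(transform = feats$transform, profile = prof, selection = sel,
       model = model, table = out, config = config,
       config_hash = config_hash(config))
}

#' Stratified sensitivity re-clustering
#'
#' Repeats the full phenotyping workflow independently within strata of
#' baseline total WMH volume (reference-ICV mL bands, half-open
#' `[low, high)`) and within the configured age band. Empty strata are
#' skipped with a warning.
#'
#' @param table cohort table.
#' @param config a [run_config()].
#' @return named list of [run_phenotyping()] artifact sets, one per
#'   nonempty stratum, each carrying `stratum` metadata.
#' @export
run_stratified <- function(table, config = run_config()) {
  base <- table[table$timepoint == 0, , drop = FALSE]
  ref_icv <- median(base$icv_mm3)
  total_mL <- base$total_wmh_mm3 / base$icv_mm3 * ref_icv / 1000
  strata <- list()
  for (band in config$volume_bands_mL) {
    nm <- sprintf("volume_%g_%gmL", band[1], band[2])
    strata[[nm]] <- which(total_mL >= band[1] & total_mL < band[2])
  }
  ab <- config$age_band
  strata[[sprintf("age_%g_%g", ab[1], ab[2])]] <-
    which(base$age >= ab[1] & base$age < ab[2])
  out <- list()
  for (nm in names(strata)) {
    idx <- strata[[nm]]
    if (length(idx) == 0) { warning("stratum ", nm, " is empty; skipped"); next }
    art <- run_phenotyping(base[idx, , drop = FALSE], config)
    art$stratum <- nm
    art$n <- length(idx)
    out[[nm]] <- art
  }
  out
}

#' Within-participant transitions between location patterns
#'
#' Restricts to participants whose follow-up interval falls in the
#' transition window (default 18-30 months), transforms baseline and
#' follow-up rows with the baseline-fitted feature transform, assigns
#' both with the baseline model, and summarises: the k x k transition
#' count matrix, the diagonal retention fraction, and mean distances to
#' the assigned baseline centroid for stayers versus movers at both
#' timepoints.
#'
#' @param table longitudinal cohort table.
#' @param model baseline-derived `cluster_model`.
#' @param transform baseline-fitted `feature_transform`.
#' @param config a [run_config()] (supplies `transition_window`).
#' @return list: `transitions` (k x k counts, baseline in rows),
#'   `retention` (fraction on the diagonal), `n_pairs`, and
#'   `distance_summary` (mean distance to the baseline-assigned
#'   centroid for stayers/movers at baseline and follow-up).
#' @export
run_transitions <- function(table, model, transform, config = run_config()) {
  win <- config$transition_window
  fu <- table[table$timepoint > 0 &
                table$interval_years >= win[1] & table$interval_years <= win[2], ]
  if (nrow(fu) == 0) stop("no follow-up rows within the transition window")
  fu <- fu[order(fu$participant_id, fu$interval_years), ]
  fu <- fu[!duplicated(fu$participant_id), ]
  base <- table[table$timepoint == 0 &
                  table$participant_id %in% fu$participant_id, ]
  base <- base[match(fu$participant_id, base$participant_id), ]

  fb <- cohort_features(base, transform)
  ff <- cohort_features(fu, transform)
  keep <- intersect(fb$rows, ff$rows)
  if (length(keep) == 0) stop("no eligible baseline/follow-up pairs")
  bi <- match(keep, fb$rows); fi <- match(keep, ff$rows)
  Xb <- fb$features[bi, , drop = FALSE]
  Xf <- ff$features[fi, , drop = FALSE]
  lb <- assign_clusters(model, Xb)
  lf <- assign_clusters(model, Xf)
  k <- model$k
  trans <- matrix(0L, k, k, dimnames = list(baseline = seq_len(k),
                                            followup = seq_len(k)))
  for (i in seq_along(lb)) trans[lb[i], lf[i]] <- trans[lb[i], lf[i]] + 1L
  stay <- lb == lf
  db <- centroid_distances(Xb, model)$distance
  df <- centroid_distances(Xf, model)$distance
  d_base <- db[cbind(seq_along(lb), lb)]
  d_fu <- df[cbind(seq_along(lf), lb)]
  summ <- data.frame(
    group = c("stayers", "movers"),
    mean_distance_baseline = c(mean(d_base[stay]), mean(d_base[!stay])),
    mean_distance_followup = c(mean(d_fu[stay]), mean(d_fu[!stay])),
    n = c(sum(stay), sum(!stay)))
  list(transitions = trans, retention = mean(stay), n_pairs = length(lb),
       distance_summary = summ)
}
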