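#' Define a synthetic WMH cluster profile
#'
#' A cluster profile describes one planted spatial subtype: its mixing
#' weight in the cohort, a Dirichlet concentration vector over the 36
#' bullseye cells governing the relative spatial distribution of lesions,
#' a log-normal total-burden model parameterised by its median (WMH
#' volumes are right-skewed, so the median — the exponential of the
#' log-mean — is the natural location parameter), and optional additive
#' shifts on risk-factor distributions for members of the cluster.
#'
#' Concentration vectors whose sum is at least `1e8` are treated as the
#' deterministic limit of the Dirichlet: proportions are exactly
#' `alpha / sum(alpha)`. This gives tests a way to build degenerate,
#' zero-variance cohorts.
#'
#' @param label cluster index (1-based).
#' @param mixing_weight fraction of the cohort drawn from this profile.
#' @param region_concentration positive numeric vector of 36 Dirichlet
#'   concentration parameters, ordered as [bullseye_regions()].
#' @param burden_median_mL median total WMH volume in mL.
#' @param burden_log_sd standard deviation of log total volume.
#' @param riskfactor_shifts named list; for continuous risk factors a
#'   single additive shift on the mean, for categorical factors a named
#'   numeric vector of additive log-odds shifts per level.
#' @return an object of class `cluster_profile`.
#' @export
cluster_profile <- function(label, mixing_weight, region_concentration,
                            burden_median_mL, burden_log_sd = 0.55,
                            riskfactor_shifts = list()) {
  if (length(region_concentration) != 36L)
    stop("profile ", label, ": region_concentration must have 36 entries")
  if (any(!is.finite(region_concentration) & region_concentration <= 0) ||
      any(region_concentration <= 0))
    stop("profile ", label, ": all concentration parameters must be > 0")
  if (!is.numeric(burden_median_mL) || burden_median_mL <= 0)
    stop("profile ", label, ": burden_median_mL must be > 0")
  if (mixing_weight < 0 || mixing_weight > 1)
    stop("profile ", label, ": mixing_weight must be in [0,1]")
  structure(list(label = as.integer(label),
                 mixing_weight = mixing_weight,
                 region_concentration = setNames(region_concentration, bullseye_regions()),
                 burden_median_mL = burden_median_mL,
                 burden_log_sd = burden_log_sd,
                 riskfactor_shifts = riskfactor_shifts),
            class = "cluster_profile")
}

# Relative spatial emphasis -> concentration vector with total mass alpha0.
# `lobe_mult` multiplies whole lobes, `layer_mult` multiplies layers
# (1 = periventricular .. 4 = juxtacortical) on top of a periventricular-
# dominant base gradient typical of WMH.
region_pattern <- function(lobe_mult = rep(1, 9), layer_mult = c(4, 2, 1, 0.5),
                           alpha0 = 60) {
  w <- lobe_mult[region_lobe_index()] * layer_mult[region_layer_index()]
  w / sum(w) * alpha0
}

#' Default synthetic cluster profiles
#'
#' Five profiles emulating the qualitative structure of the five WMH
#' location patterns the pipeline is designed to recover: three
#' low-burden patterns (medians 0.9, 1.5 and 1.9 mL) emphasising the
#' basal-ganglia/thalamus region, the occipital lobes and symmetric
#' periventricular involvement respectively, and two high-burden
#' patterns (4.4 and 6.4 mL) with frontal predominance extending into
#' deeper layers and widespread frontal-parietal involvement of the
#' three inner layers. Risk-factor shifts plant an age gradient across
#' clusters and adverse vascular profiles (blood pressure, smoking,
#' diabetes) in the high-burden clusters.
#'
#' @param alpha0 total Dirichlet concentration per profile; larger values
#'   give tighter, better-separated clusters.
#' @return list of 5 [cluster_profile()] objects.
#' @export
default_cluster_profiles <- function(alpha0 = 60) {
  lob <- bullseye_lobes()
  mult <- function(...) {
    m <- setNames(rep(1, 9), lob); v <- list(...)
    for (nm in names(v)) m[nm] <- v[[nm]]
    m
  }
  list(
    cluster_profile(1L, 0.25,
      region_pattern(mult(bgit = 6), c(4, 2, 1, 0.5), alpha0),
      burden_median_mL = 0.9,
      riskfactor_shifts = list(age = -4, creatinine = -4, glucose = -0.2,
                               triglycerides = -0.15)),
    cluster_profile(2L, 0.20,
      region_pattern(mult(occipital_l = 5, occipital_r = 5), c(4, 2, 1, 0.5), alpha0),
      burden_median_mL = 1.5,
      riskfactor_shifts = list(age = -2)),
    cluster_profile(3L, 0.25,
      region_pattern(rep(1, 9), c(8, 2, 0.5, 0.2), alpha0),
      burden_median_mL = 1.9,
      riskfactor_shifts = list(age = 1, sex = c(female = 0.25))),
    cluster_profile(4L, 0.17,
      region_pattern(mult(frontal_l = 4, frontal_r = 4), c(2, 2, 1.5, 1), alpha0),
      burden_median_mL = 4.4,
      riskfactor_shifts = list(age = 3, sbp = 8, dbp = 3,
                               diabetes = c(yes = 0.7), hypertension = c(yes = 0.5),
                               sex = c(female = 0.25), triglycerides = 0.15)),
    cluster_profile(5L, 0.13,
      region_pattern(mult(frontal_l = 3, frontal_r = 3, parietal_l = 3, parietal_r = 3),
                     c(3, 2.5, 1.5, 0.2), alpha0),
      burden_median_mL = 6.4,
      riskfactor_shifts = list(age = 5, sbp = 10, dbp = 4,
                               diabetes = c(yes = 0.9), hypertension = c(yes = 0.7),
                               smoking = c(current = 0.8)))
  )
}

# Baseline (reference-cluster) risk-factor distributions, located near the
# descriptive medians of large ageing-cohort studies. Continuous entries
# are Normal(mean, sd) (truncated at > 0 where physically required);
# categorical entries are level probabilities.
riskfactor_baselines <- function() {
  list(
    age           = list(type = "continuous", mean = 66, sd = 7, positive = TRUE),
    sex           = list(type = "categorical", levels = c("male", "female"),
                         probs = c(0.47, 0.53)),
    ethnicity     = list(type = "categorical",
                         levels = c("white", "asian", "black", "mixed", "other"),
                         probs = c(0.960, 0.018, 0.011, 0.005, 0.006)),
    sbp           = list(type = "continuous", mean = 135, sd = 18, positive = TRUE),
    dbp           = list(type = "continuous", mean = 81, sd = 10, positive = TRUE),
    smoking       = list(type = "categorical", levels = c("never", "ever", "current"),
                         probs = c(0.627, 0.340, 0.033)),
    diabetes      = list(type = "categorical", levels = c("no", "yes"),
                         probs = c(0.957, 0.043)),
    hypertension  = list(type = "categorical", levels = c("no", "yes"),
                         probs = c(0.696, 0.304)),
    med_chol      = list(type = "categorical", levels = c("no", "yes"),
                         probs = c(0.743, 0.257)),
    med_bp        = list(type = "categorical", levels = c("no", "yes"),
                         probs = c(0.746, 0.254)),
    med_dm        = list(type = "categorical", levels = c("no", "yes"),
                         probs = c(0.990, 0.010)),
    glucose       = list(type = "continuous", mean = 3.6, sd = 0.6, positive = TRUE),
    hba1c         = list(type = "continuous", mean = 34.6, sd = 4.0, positive = TRUE),
    hdl           = list(type = "continuous", mean = 1.3, sd = 0.35, positive = TRUE),
    ldl           = list(type = "continuous", mean = 1.7, sd = 0.4, positive = TRUE),
    triglycerides = list(type = "continuous", mean = 1.2, sd = 0.55, positive = TRUE),
    wbcc          = list(type = "continuous", mean = 6.4, sd = 1.6, positive = TRUE),
    creatinine    = list(type = "continuous", mean = 66, sd = 13, positive = TRUE),
    apoe4         = list(type = "categorical", levels = c("0", "1", "2"),
                         probs = c(0.724, 0.253, 0.023))
  )
}

#' Specify a synthetic cohort
#'
#' @param n_participants number of participants.
#' @param profiles list of [cluster_profile()]s; mixing weights must sum to 1.
#' @param icv_mean_mm3,icv_sd_mm3 intracranial-volume Normal parameters
#'   (truncated at > 0).
#' @param followup_fraction fraction of participants receiving a second
#'   timepoint in [generate_longitudinal()].
#' @param interval_range_years min/max follow-up interval in years.
#' @param progression_model list with numeric vectors `mean` and `sd`
#'   (one entry per profile): annualised total-volume change in mm^3/year.
#' @param drift_rate per-year mixing coefficient pulling follow-up
#'   regional proportions toward the cluster's mean pattern; kept small
#'   by default because spatial patterns are largely preserved over
#'   follow-up in this population.
#' @param seed integer seed driving all randomness for this spec.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 2000L,
                        profiles = default_cluster_profiles(),
                        icv_mean_mm3 = 1.5e6, icv_sd_mm3 = 1.4e5,
                        followup_fraction = 0.5,
                        interval_range_years = c(1, 7),
                        progression_model = list(
                          mean = c(60, 110, 160, 340, 480),
                          sd   = c(70, 90, 110, 140, 170)),
                        drift_rate = 0.1,
                        seed = 1L) {
  K <- length(profiles)
  w <- vapply(profiles, `[[`, numeric(1), "mixing_weight")
  if (abs(sum(w) - 1) > 1e-12)
    stop("mixing weights must sum to 1 (got ", format(sum(w), digits = 15), ")")
  if (n_participants < K)
    stop("n_participants must be at least the number of profiles")
  if (interval_range_years[1] <= 0)
    stop("interval_range_years minimum must be > 0")
  if (followup_fraction < 0 || followup_fraction > 1)
    stop("followup_fraction must be in [0,1]")
  if (length(progression_model$mean) != K || length(progression_model$sd) != K)
    stop("progression_model must supply mean and sd per profile")
  structure(list(n_participants = as.integer(n_participants), profiles = profiles,
                 icv_mean_mm3 = icv_mean_mm3, icv_sd_mm3 = icv_sd_mm3,
                 followup_fraction = followup_fraction,
                 interval_range_years = interval_range_years,
                 progression_model = progression_model,
                 drift_rate = drift_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

# one Dirichlet draw per row; rows of `alpha` (n x 36) may differ
rdirichlet_rows <- function(alpha) {
  g <- matrix(rgamma(length(alpha), shape = alpha), nrow(alpha), ncol(alpha))
  sums <- rowSums(g)
  # guard against all-zero gamma draws under tiny concentrations
  zero <- sums == 0
  if (any(zero)) { g[zero, ] <- 1; sums[zero] <- ncol(alpha) }
  g / sums
}

rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

draw_categorical <- function(n, base, shift = NULL) {
  logit <- log(base$probs)
  if (!is.null(shift)) {
    unknown <- setdiff(names(shift), base$levels)
    if (length(unknown)) stop("unknown level(s) in risk-factor shift: ",
                              paste(unknown, collapse = ", "))
    logit[match(names(shift), base$levels)] <-
      logit[match(names(shift), base$levels)] + shift
  }
  p <- exp(logit - max(logit)); p <- p / sum(p)
  base$levels[sample.int(length(p), n, replace = TRUE, prob = p)]
}

draw_riskfactors <- function(cluster, profiles) {
  base <- riskfactor_baselines()
  n <- length(cluster)
  out <- vector("list", length(base)); names(out) <- names(base)
  for (nm in names(base)) {
    b <- base[[nm]]
    if (b$type == "continuous") {
      col <- numeric(n)
      for (p in profiles) {
        idx <- cluster == p$label
        if (!any(idx)) next
        shift <- p$riskfactor_shifts[[nm]] %||% 0
        col[idx] <- rnorm_pos(sum(idx), b$mean + shift, b$sd)
      }
    } else {
      col <- character(n)
      for (p in profiles) {
        idx <- cluster == p$label
        if (!any(idx)) next
        col[idx] <- draw_categorical(sum(idx), b, p$riskfactor_shifts[[nm]])
      }
      if (nm == "apoe4") col <- as.integer(col)
    }
    out[[nm]] <- col
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Generate a cross-sectional synthetic cohort
#'
#' Each participant is assigned a planted cluster from the mixing
#' weights; regional proportions are drawn from that cluster's Dirichlet,
#' total burden from its log-normal, and regional volumes are
#' `proportions * total`. ICV is truncated-Normal and risk factors are
#' drawn from baseline distributions shifted per cluster. Fully
#' deterministic under `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` cohort table: `participant_id`, `timepoint`,
#'   the 36 region columns of [bullseye_regions()] (mm^3),
#'   `total_wmh_mm3`, `icv_mm3`, `true_cluster`, the 19 risk-factor
#'   columns, and `interval_years` (0 at baseline).
#' @export
generate_cross_sectional <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- child_seeds(spec$seed, 2L)
  with_seed(seeds[1], {
    n <- spec$n_participants
    K <- length(spec$profiles)
    w <- vapply(spec$profiles, `[[`, numeric(1), "mixing_weight")
    cluster <- sample.int(K, n, replace = TRUE, prob = w)

    alpha <- t(vapply(spec$profiles, `[[`, numeric(36), "region_concentration"))
    med   <- vapply(spec$profiles, `[[`, numeric(1), "burden_median_mL") * 1000
    lsd   <- vapply(spec$profiles, `[[`, numeric(1), "burden_log_sd")

    A <- alpha[cluster, , drop = FALSE]
    props <- rdirichlet_rows(A)
    det_rows <- rowSums(A) >= 1e8          # deterministic Dirichlet limit
    if (any(det_rows)) props[det_rows, ] <- A[det_rows, ] / rowSums(A[det_rows, , drop = FALSE])

    total <- exp(rnorm(n, log(med[cluster]), lsd[cluster]))
    regional <- props * total
    icv <- rnorm_pos(n, spec$icv_mean_mm3, spec$icv_sd_mm3)
    rf <- draw_riskfactors(cluster, spec$profiles)

    tab <- data.frame(participant_id = sprintf("P%05d", seq_len(n)),
                      timepoint = 0L, stringsAsFactors = FALSE)
    regional <- as.data.frame(regional)
    names(regional) <- bullseye_regions()
    tab <- cbind(tab, regional,
                 total_wmh_mm3 = rowSums(regional),
                 icv_mm3 = icv, true_cluster = cluster, rf,
                 interval_years = 0)
    rownames(tab) <- NULL
    tab
  })
}

#' Add follow-up timepoints to a cross-sectional cohort
#'
#' For a seeded random subset of participants (`spec$followup_fraction`),
#' adds a timepoint-1 row: the interval is uniform on
#' `spec$interval_range_years`, total volume changes by
#' `interval * Normal(mean, sd)` (per-cluster annualised progression
#' model), floored at 0, and regional proportions drift toward the
#' cluster's mean spatial pattern with per-year mixing `spec$drift_rate`.
#'
#' @param base the output of [generate_cross_sectional()].
#' @param spec the [cohort_spec()] used to generate `base`.
#' @return cohort table with baseline and follow-up rows.
#' @export
generate_longitudinal <- function(base, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$followup_fraction < 0 || spec$followup_fraction > 1)
    stop("followup_fraction must be in [0,1]")
  seeds <- child_seeds(spec$seed, 2L)
  regions <- bullseye_regions()
  with_seed(seeds[2], {
    n <- nrow(base)
    n_fu <- round(spec$followup_fraction * n)
    if (n_fu == 0) return(base)
    idx <- sort(sample.int(n, n_fu))
    fu <- base[idx, , drop = FALSE]
    cl <- fu$true_cluster
    interval <- runif(n_fu, spec$interval_range_years[1], spec$interval_range_years[2])
    change <- rnorm(n_fu, spec$progression_model$mean[cl], spec$progression_model$sd[cl])
    new_total <- pmax(0, fu$total_wmh_mm3 + interval * change)

    alpha <- t(vapply(spec$profiles, `[[`, numeric(36), "region_concentration"))
    target <- alpha / rowSums(alpha)
    p0 <- as.matrix(fu[, regions]) / ifelse(fu$total_wmh_mm3 > 0, fu$total_wmh_mm3, 1)
    wmix <- pmin(1, spec$drift_rate * interval)
    p1 <- (1 - wmix) * p0 + wmix * target[cl, , drop = FALSE]

    fu[, regions] <- p1 * new_total
    fu$total_wmh_mm3 <- rowSums(fu[, regions])
    fu$timepoint <- 1L
    fu$interval_years <- interval
    fu$age <- fu$age + interval
    out <- rbind(base, fu)
    out <- out[order(out$participant_id, out$timepoint), ]
    rownames(out) <- NULL
    out
  })
}

#' Read or write a cohort table as tab-separated text
#'
#' @param table cohort table `data.frame`.
#' @param path file path.
#' @return `read_cohort_table` returns the `data.frame`.
#' @export
write_cohort_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
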