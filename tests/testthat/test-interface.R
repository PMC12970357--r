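# Workflow tests run on reduced bootstrap settings; the full default
# configuration is exercised by the planted-k acceptance criterion.
fast_config <- function(seed = 1L, ...) {
  run_config(B = 5L, n_repeats = 2L, seed = seed, ...)
}

test_that("run_config holds the stated defaults and records overrides", {
  cfg <- run_config()
  expect_identical(cfg$k_range, 2:7)
  expect_identical(cfg$B, 20L)
  expect_identical(cfg$n_repeats, 5L)
  expect_equal(cfg$stability_threshold, 0.90)
  expect_equal(cfg$progression_threshold, 250)
  expect_equal(cfg$interval_window, c(1, 7))
  expect_equal(cfg$transition_window, c(1.5, 2.5))
  expect_equal(cfg$volume_bands_mL, list(c(0, 4), c(4, 8)))
  expect_equal(cfg$age_band, c(67, 72))
  expect_identical(cfg$overrides, character(0))
  cfg2 <- run_config(B = 5L)
  expect_identical(cfg2$overrides, "B")
  expect_error(run_config(bogus = 1), "unknown config")
})

test_that("YAML configs load with overrides applied", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("B: 7", "seed: 42", "k_range: [2, 3, 4]"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$B, 7)
  expect_equal(cfg$seed, 42)
  expect_equal(unlist(cfg$k_range), 2:4)
  expect_setequal(cfg$overrides, c("B", "seed", "k_range"))
})

test_that("phenotyping workflow recovers the planted structure end to end", {
  tab <- generate_cross_sectional(cohort_spec(n_participants = 800, seed = 10))
  art <- run_phenotyping(tab, fast_config(seed = 10, k_range = 2:6))
  expect_identical(art$selection$selected_k, 5L)
  expect_gte(ari(art$table$cluster, art$table$true_cluster), 0.9)
  # burden ordering: cluster medians increase with the index
  med <- tapply(art$table$total_wmh_mm3, art$table$cluster, median)
  expect_true(all(diff(med) > 0))
  expect_true(all(art$table$stability >= 0 & art$table$stability <= 1, na.rm = TRUE))
})

test_that("workflow artifacts are deterministic under config + seed", {
  tab <- generate_cross_sectional(cohort_spec(n_participants = 300, seed = 20))
  cfg <- fast_config(seed = 21, k_range = 2:4)
  a1 <- run_phenotyping(tab, cfg)
  a2 <- run_phenotyping(tab, cfg)
  expect_identical(a1$profile$table, a2$profile$table)
  expect_identical(a1$model$centroids, a2$model$centroids)
  expect_identical(a1$table$cluster, a2$table$cluster)
  expect_identical(a1$config_hash, a2$config_hash)
})

test_that("a single-k range produces a single-row profile", {
  tab <- generate_cross_sectional(cohort_spec(n_participants = 200, seed = 31))
  art <- run_phenotyping(tab, fast_config(seed = 3, k_range = 2:2))
  expect_equal(nrow(art$profile$table), 1)
})

test_that("stratified runs partition rows and degrade k within narrow bands", {
  tab <- generate_cross_sectional(cohort_spec(n_participants = 900, seed = 17))
  cfg <- fast_config(seed = 17, k_range = 2:6)
  strat <- run_stratified(tab, cfg)
  ref_icv <- median(tab$icv_mm3)
  total_mL <- tab$total_wmh_mm3 / tab$icv_mm3 * ref_icv / 1000
  in_bands <- sum(total_mL >= 0 & total_mL < 4) + sum(total_mL >= 4 & total_mL < 8)
  expect_equal(strat[["volume_0_4mL"]]$n + strat[["volume_4_8mL"]]$n, in_bands)
  # restricting to low burden leaves at most the planted number of patterns
  k_low <- strat[["volume_0_4mL"]]$selection$selected_k
  expect_true(is.na(k_low) || k_low <= 5)
})

test_that("a stratum equal to the whole dataset reproduces run_phenotyping", {
  tab <- generate_cross_sectional(cohort_spec(n_participants = 300, seed = 23))
  cfg <- fast_config(seed = 5, k_range = 2:3,
                     volume_bands_mL = list(c(0, Inf)), age_band = c(0, 1))
  strat <- suppressWarnings(run_stratified(tab, cfg))
  whole <- run_phenotyping(tab, cfg)
  expect_equal(strat[["volume_0_InfmL"]]$profile$table, whole$profile$table)
  expect_identical(strat[["volume_0_InfmL"]]$table$cluster, whole$table$cluster)
})

test_that("zero-drift longitudinal cohorts retain their pattern perfectly", {
  spec <- cohort_spec(n_participants = 400, followup_fraction = 1,
                      interval_range_years = c(1.5, 2.5),
                      progression_model = list(mean = rep(0, 5), sd = rep(0, 5)),
                      drift_rate = 0, seed = 8)
  tab <- generate_longitudinal(generate_cross_sectional(spec), spec)
  base <- tab[tab$timepoint == 0, ]
  f <- wmhpheno:::cohort_features(base)
  model <- fit_clustering(f$features, 5, seed = 2)
  res <- run_transitions(tab, model, f$transform)
  expect_equal(res$retention, 1)
  expect_equal(sum(res$transitions) - sum(diag(res$transitions)), 0)
  expect_equal(res$n_pairs, 400)
})

test_that("a constructed relabel fixture yields the constructed transition matrix", {
  spec <- cohort_spec(n_participants = 200, followup_fraction = 1,
                      interval_range_years = c(1.5, 2.5),
                      progression_model = list(mean = rep(0, 5), sd = rep(0, 5)),
                      drift_rate = 0, seed = 12)
  tab <- generate_longitudinal(generate_cross_sectional(spec), spec)
  base <- tab[tab$timepoint == 0, ]
  f <- wmhpheno:::cohort_features(base)
  model <- fit_clustering(f$features, 5, seed = 4)
  lab <- assign_clusters(model, f$features)

  # move the follow-up rows of every cluster-1 participant onto the
  # centroid of cluster 2 (in raw-volume space through the transform)
  movers <- base$participant_id[lab == 1]
  c2 <- model$centroids[2, ]
  p2 <- (c2 * (f$transform$max - f$transform$min) + f$transform$min)^2
  p2 <- p2 / sum(p2)
  fu_idx <- which(tab$timepoint == 1 & tab$participant_id %in% movers)
  tab[fu_idx, bullseye_regions()] <-
    matrix(p2, length(fu_idx), 36, byrow = TRUE) * tab$total_wmh_mm3[fu_idx]
  res <- run_transitions(tab, model, f$transform)
  expect_equal(res$transitions[1, 2], sum(lab == 1))
  expect_equal(res$transitions[1, 1], 0)
  expect_equal(sum(diag(res$transitions)), sum(lab != 1))
  # movers sat exactly at their baseline positions, so at baseline the
  # movers' mean distance to their original centroid reflects cluster 1
  expect_equal(res$distance_summary$n, c(sum(lab != 1), sum(lab == 1)))
})

test_that("movers are already further from their centroid at baseline on a
           drift-toward-boundary fixture", {
  spec <- cohort_spec(n_participants = 600, followup_fraction = 1,
                      interval_range_years = c(1.8, 2.2),
                      drift_rate = 0, seed = 29)
  base <- generate_cross_sectional(spec)
  f <- wmhpheno:::cohort_features(base)
  model <- fit_clustering(f$features, 5, seed = 3)
  lab <- assign_clusters(model, f$features)
  d <- centroid_distances(f$features, model)$distance
  own <- d[cbind(seq_along(lab), lab)]
  # follow-up: the quarter of each cluster farthest from its centroid
  # drifts half-way toward the nearest other centroid
  fu <- base; fu$timepoint <- 1L; fu$interval_years <- 2
  d2 <- d; d2[cbind(seq_along(lab), lab)] <- Inf
  other <- max.col(-d2, ties.method = "first")
  far <- which(own > quantile(own, 0.75))
  P0 <- as.matrix(base[, bullseye_regions()]) / base$total_wmh_mm3
  for (i in far) {
    co <- model$centroids[other[i], ]
    pc <- (co * (f$transform$max - f$transform$min) + f$transform$min)^2
    pc <- pc / sum(pc)
    mixed <- 0.2 * P0[i, ] + 0.8 * pc
    fu[i, bullseye_regions()] <- mixed * base$total_wmh_mm3[i]
  }
  res <- run_transitions(rbind(base, fu), model, f$transform)
  expect_gt(res$distance_summary$mean_distance_baseline[2],
            res$distance_summary$mean_distance_baseline[1])
  expect_lt(res$retention, 1)
})

test_that("the CLI simulate and phenotype subcommands run end to end", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "cohort.tsv")
  suppressMessages(wmh_cli(c("simulate", "--n", "300", "--seed", "6",
                             "--out", tsv, "--followup", "0.3")))
  expect_true(file.exists(tsv))
  cfg <- file.path(dir, "cfg.yaml")
  writeLines(c("B: 4", "n_repeats: 1", "k_range: [2, 3, 4, 5]"), cfg)
  out <- file.path(dir, "artifacts")
  suppressMessages(wmh_cli(c("phenotype", "--table", tsv, "--config", cfg,
                             "--seed", "6", "--out", out)))
  expect_true(file.exists(file.path(out, "transform.json")))
  expect_true(file.exists(file.path(out, "profile.json")))
  expect_true(file.exists(file.path(out, "clustered.tsv")))
  prof <- jsonlite::read_json(file.path(out, "profile.json"), simplifyVector = TRUE)
  expect_true(all(prof$profile$stability >= 0 & prof$profile$stability <= 1))
})

test_that("CLI option parsing and error paths", {
  expect_error(wmh_cli(character(0)), "usage")
  expect_error(wmh_cli("frobnicate"), "unknown subcommand")
  opts <- wmhpheno:::parse_cli_options(c("--a", "1", "--flag", "--b", "x"))
  expect_equal(opts$a, "1")
  expect_true(opts$flag)
  expect_equal(opts$b, "x")
})
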