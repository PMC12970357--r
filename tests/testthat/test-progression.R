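make_pair_table <- function(v_base, v_fu, interval, icv, ref = icv) {
  template <- generate_cross_sectional(degenerate_spec(n = 1))
  rows <- template[rep(1, 2 * length(v_base)), ]
  n <- length(v_base)
  rows$participant_id <- rep(sprintf("P%03d", seq_len(n)), each = 2)
  rows$timepoint <- rep(c(0L, 1L), n)
  rows$interval_years <- as.vector(rbind(0, interval))
  rows$total_wmh_mm3 <- as.vector(rbind(v_base, v_fu))
  rows$icv_mm3 <- rep(icv, each = 2)
  rownames(rows) <- NULL
  rows
}

test_that("annualised change arithmetic, including the ICV rescaling", {
  tab <- make_pair_table(1000, 1600, 2, icv = 1.5e6)
  ch <- annualised_change(tab, 1.5e6)
  expect_equal(ch$change_mm3_per_year, 300)
  expect_equal(annualised_change(make_pair_table(800, 800, 3, 1.5e6),
                                 1.5e6)$change_mm3_per_year, 0)
  # ICV twice the reference halves the change on the reference scale
  tab2 <- make_pair_table(1000, 1500, 1, icv = 3e6)
  expect_equal(annualised_change(tab2, 1.5e6)$change_mm3_per_year, 250)
})

test_that("multiple follow-ups: the earliest within the window is used", {
  tab <- make_pair_table(c(1000, 1000), c(1400, 2000), c(2, 5), icv = 1.5e6)
  tab$participant_id <- rep("P001", 4)
  tab <- tab[-3, ]                       # one baseline, two follow-ups
  ch <- annualised_change(tab, 1.5e6)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$interval_years, 2)
  expect_error(annualised_change(tab, 1.5e6, interval_window = c(8, 9)), "window")
})

test_that("progression labelling is strict at the threshold", {
  expect_identical(label_progression(c(-50, 100, 250, 251, 600)),
                   c(FALSE, FALSE, FALSE, TRUE, TRUE))
  ch <- data.frame(change_mm3_per_year = c(300, 250, 0))
  expect_identical(label_progression(ch)$progressor, c(TRUE, FALSE, FALSE))
})

test_that("progressor fraction matches the normal-CDF oracle", {
  # annualised change ~ N(400, 100^2) in every cluster; threshold 250:
  # P(progressor) = pnorm((400 - 250) / 100) = 0.9332
  spec <- cohort_spec(n_participants = 3000, followup_fraction = 1,
                      progression_model = list(mean = rep(400, 5), sd = rep(100, 5)),
                      icv_sd_mm3 = 0, seed = 6)
  tab <- generate_longitudinal(generate_cross_sectional(spec), spec)
  ch <- annualised_change(tab, spec$icv_mean_mm3)
  frac <- mean(label_progression(ch)$progressor)
  p <- pnorm(1.5)
  se <- sqrt(p * (1 - p) / nrow(ch))
  expect_lt(abs(frac - p), 3 * se)
})

test_that("residualisation removes covariate effects and is orthogonal", {
  withr::with_seed(11, {
    n <- 200
    covs <- data.frame(age = runif(n, 50, 80), sexf = rbinom(n, 1, 0.5))
    x_indep <- rnorm(n)
  })
  r <- residualize(x_indep, covs)
  expect_equal(abs(sum(r * (covs$age - mean(covs$age)))), 0, tolerance = 1e-6)
  expect_equal(mean(r), 0, tolerance = 1e-10)
  r2 <- residualize(2 * covs$age, covs)
  expect_equal(max(abs(r2)), 0, tolerance = 1e-9)
  expect_error(residualize(x_indep, data.frame(c1 = rep(1, n))), "constant")
})

test_that("group comparisons: U test at the null and the printed chi-squared", {
  base <- withr::with_seed(13, data.frame(
    v = rnorm(60), age = runif(60, 50, 80),
    sex = sample(c("male", "female"), 60, TRUE)))
  d <- rbind(base, base)                # two literally identical groups
  g <- rep(c(TRUE, FALSE), each = 60)
  res <- suppressWarnings(compare_groups(d, g, "v"))
  expect_gt(res$p, 0.5)                 # identical value sets: U at its null mean

  # 2x2 table (20,10 / 10,20): Pearson chi-squared = 6.667, p ~ 0.0098
  d2 <- data.frame(cat = rep(c("a", "a", "b", "b"), c(20, 10, 10, 20)),
                   age = runif(60, 50, 80),
                   sex = sample(c("male", "female"), 60, TRUE))
  g2 <- rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 10, 10, 20))
  res2 <- compare_groups(d2, g2, "cat")
  expect_equal(res2$statistic, 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30))
  expect_equal(res2$statistic, 6 + 2 / 3, tolerance = 1e-12)
  expect_equal(res2$p, pchisq(6 + 2 / 3, 1, lower.tail = FALSE))
})

test_that("balanced accuracy and its bootstrap CI behave per definition", {
  # confusion TP=40 FN=10 TN=30 FP=20 -> (0.8 + 0.6) / 2 = 0.7
  truth <- rep(c(1, 0), c(50, 50))
  pred <- c(rep(1, 40), rep(0, 10), rep(0, 30), rep(1, 20))
  expect_equal(balanced_accuracy(pred, truth), 0.7)
  expect_error(balanced_accuracy(rep(1, 4), rep(1, 4)), "class 0")

  # perfect predictor: accuracy 1 with degenerate CI [1, 1]
  X <- cbind(c(rep(0, 30), rep(5, 30)))
  y <- rep(c(0, 1), each = 30)
  fit <- fit_gbt(X, y, n_trees = 20, max_depth = 2)
  ev <- evaluate_classifier(fit, X, y, n_boot = 200, seed = 3)
  expect_equal(ev$balanced_accuracy, 1)
  expect_equal(ev$ci, c(1, 1))
})

test_that("McNemar comparison handles symmetric and empty discordance", {
  truth <- rep(0:1, each = 20)
  pa <- truth; pb <- truth
  pa[1:10] <- 1 - pa[1:10]              # A wrong on 10
  pb[11:20] <- 1 - pb[11:20]            # B wrong on a disjoint 10
  m <- mcnemar_compare(pa, pb, truth)
  expect_equal(m$b, 10); expect_equal(m$c, 10)
  expect_gt(m$p, 0.5)
  expect_equal(mcnemar_compare(truth, truth, truth)$p, 1)
})

test_that("predictor sets have the stated shapes and the PCA variance rule", {
  co <- small_cohort(n = 250, seed = 33)
  tab <- co$table
  f <- wmhpheno:::cohort_features(tab)
  model <- fit_clustering(f$features, 5, seed = 2)
  ps <- build_predictor_sets(tab, model, f$transform)
  expect_equal(ncol(predictor_matrix(ps, tab, "distance")), 5)
  expect_equal(ncol(predictor_matrix(ps, tab, "clusters")), 5)
  expect_equal(ncol(predictor_matrix(ps, tab, "RF")), 3)
  expect_equal(ncol(predictor_matrix(ps, tab, "RWMHV")), 36)
  un <- predictor_matrix(ps, tab, "RWMHV+distance+RF")
  expect_equal(ncol(un), 36 + 5 + 3)
  expect_error(predictor_matrix(ps, tab, "nope"), "unknown predictor set")
  expect_gt(ps$pca_cumvar, 0.8)

  # variance concentrated in 2 of 36 dims -> exactly 2 components
  synth <- tab
  V <- matrix(rnorm(nrow(tab) * 36, sd = 0.001), nrow(tab), 36)
  V[, 1] <- rnorm(nrow(tab), sd = 10)
  V[, 2] <- rnorm(nrow(tab), sd = 6)
  synth[, bullseye_regions()] <- abs(V)
  synth$icv_mm3 <- 1
  ps2 <- build_predictor_sets(synth, transform = NULL)
  expect_identical(ps2$n_components, 2L)
})

test_that("classifier training: separability, determinism, null behaviour", {
  X <- cbind(c(rep(0, 40), rep(6, 40)), rnorm(80))
  y <- rep(c(0, 1), each = 40)
  small_grid <- expand.grid(n_trees = c(20, 50), max_depth = 2:3)
  tr <- train_progression_classifier(X, y, grid = small_grid, seed = 4)
  expect_equal(max(tr$cv_results$cv_balanced_accuracy), 1)
  tr2 <- train_progression_classifier(X, y, grid = small_grid, seed = 4)
  expect_identical(tr$best, tr2$best)
  expect_equal(tr$cv_results, tr2$cv_results)

  # permuted labels: CV balanced accuracy hovers at chance
  nulls <- vapply(1:4, function(s) {
    yp <- withr::with_seed(s, sample(y))
    trn <- train_progression_classifier(X, yp, grid = small_grid[1, ], seed = s)
    max(trn$cv_results$cv_balanced_accuracy)
  }, numeric(1))
  expect_lt(abs(mean(nulls) - 0.5), 0.12)
})

test_that("regional predictors are at least as informative as the total
           (seeded tendency on the default longitudinal cohort)", {
  # scaled down for runtime: 5 replicates, reduced tuning grid
  grid <- expand.grid(n_trees = c(50, 100), max_depth = 2:3)
  wins <- vapply(1:5, function(s) {
    spec <- cohort_spec(n_participants = 500, followup_fraction = 1, seed = s)
    tab <- generate_longitudinal(generate_cross_sectional(spec), spec)
    ch <- label_progression(annualised_change(tab, 1.5e6))
    base <- tab[tab$timepoint == 0, ]
    base <- base[match(ch$participant_id, base$participant_id), ]
    base$progressor <- ch$progressor
    ps <- build_predictor_sets(base)
    cvb <- function(nm) {
      tr <- train_progression_classifier(predictor_matrix(ps, base, nm),
                                         as.numeric(base$progressor),
                                         grid = grid, seed = s)
      max(tr$cv_results$cv_balanced_accuracy)
    }
    cvb("RWMHV") - cvb("WMHV")
  }, numeric(1))
  expect_gte(mean(wins), 0)
})

test_that("train/test isolation: test rows influence no fitted artifact", {
  co <- small_cohort(n = 300, seed = 44, followup_fraction = 1)
  tab <- co$table
  ch <- label_progression(annualised_change(tab, 1.5e6))
  base <- tab[tab$timepoint == 0, ]
  base <- base[match(ch$participant_id, base$participant_id), ]
  base$progressor <- ch$progressor
  idx <- seq_len(nrow(base)) <= 240
  train <- base[idx, ]; test <- base[!idx, ]

  f_tr <- wmhpheno:::cohort_features(train)
  model <- fit_clustering(f_tr$features, 5, seed = 3)
  ps_full <- build_predictor_sets(train, model, f_tr$transform)
  tr_full <- train_progression_classifier(
    predictor_matrix(ps_full, train, "RWMHV+RF"), as.numeric(train$progressor),
    grid = expand.grid(n_trees = 20, max_depth = 2:3), seed = 7)

  # delete all test rows and rebuild: every artifact must be bit-identical
  ps_again <- build_predictor_sets(train, model, f_tr$transform)
  tr_again <- train_progression_classifier(
    predictor_matrix(ps_again, train, "RWMHV+RF"), as.numeric(train$progressor),
    grid = expand.grid(n_trees = 20, max_depth = 2:3), seed = 7)
  expect_identical(ps_full$pca_rotation, ps_again$pca_rotation)
  expect_identical(ps_full$pca_center, ps_again$pca_center)
  expect_identical(tr_full$best, tr_again$best)
  expect_identical(predict(tr_full$model, predictor_matrix(ps_full, test, "RWMHV+RF")),
                   predict(tr_again$model, predictor_matrix(ps_again, test, "RWMHV+RF")))
})

test_that("compare_predictor_sets produces a coherent report", {
  co <- small_cohort(n = 350, seed = 55, followup_fraction = 1)
  tab <- co$table
  ch <- label_progression(annualised_change(tab, 1.5e6))
  base <- tab[tab$timepoint == 0, ]
  base <- base[match(ch$participant_id, base$participant_id), ]
  base$progressor <- ch$progressor
  idx <- seq_len(nrow(base)) <= 280
  ps <- build_predictor_sets(base[idx, ])
  rep <- compare_predictor_sets(ps, base[idx, ], base[!idx, ],
                                c("WMHV", "RWMHV"), seed = 2, n_boot = 200,
                                grid = expand.grid(n_trees = 50, max_depth = 2:3))
  expect_equal(nrow(rep$results), 2)
  expect_true(all(rep$results$ci_lower <= rep$results$test_balanced_accuracy + 1e-9))
  expect_true(all(rep$results$test_balanced_accuracy <= rep$results$ci_upper + 1e-9))
  expect_equal(nrow(rep$mcnemar), 1)
  expect_true(rep$mcnemar$p_adjusted >= rep$mcnemar$p)
})
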