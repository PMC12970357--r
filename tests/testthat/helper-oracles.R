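# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever they check one.

# adjusted Rand index between two label vectors (contingency formula)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  e <- sa * sb / choose(n, 2)
  (si - e) / ((sa + sb) / 2 - e)
}

# brute-force per-cluster max-Jaccard between two labelings, by exhaustive
# enumeration over all (ref cluster, boot cluster) pairs with set ops done
# via logical vectors rather than index sets
brute_max_jaccard <- function(ref_labels, boot_labels, k) {
  vapply(seq_len(k), function(c) {
    a <- ref_labels == c
    best <- 0
    for (j in sort(unique(boot_labels))) {
      b <- boot_labels == j
      inter <- sum(a & b); un <- sum(a | b)
      jac <- if (un == 0) 1 else inter / un
      best <- max(best, jac)
    }
    if (!any(a) && !length(unique(boot_labels))) best <- 1
    best
  }, numeric(1))
}

# small well-separated planted mixture in d dims; deterministic corner
# means (mu_j = sep * e_j) so separation does not depend on the seed
planted_blobs <- function(n, k, d = 4, sep = 6, sd = 0.3, seed = 1) {
  stopifnot(d >= k)
  mu <- matrix(0, k, d)
  mu[cbind(seq_len(k), seq_len(k))] <- sep
  lab <- rep_len(seq_len(k), n)
  withr::with_seed(seed, {
    list(X = mu[lab, , drop = FALSE] + matrix(rnorm(n * d, sd = sd), n, d),
         labels = lab)
  })
}

# a compact synthetic cohort for tests that only need structure, not scale
small_cohort <- function(n = 400, seed = 7, followup_fraction = 0) {
  spec <- cohort_spec(n_participants = n, followup_fraction = followup_fraction,
                      seed = seed)
  tab <- generate_cross_sectional(spec)
  if (followup_fraction > 0) tab <- generate_longitudinal(tab, spec)
  list(spec = spec, table = tab)
}

# degenerate single-profile spec: deterministic proportions and totals
degenerate_spec <- function(n = 5, burden_mL = 2, seed = 1) {
  prof <- cluster_profile(1L, 1, rep(1e12, 36), burden_median_mL = burden_mL,
                          burden_log_sd = 0)
  cohort_spec(n_participants = n, profiles = prof |> list(),
              progression_model = list(mean = 0, sd = 0), seed = seed)
}
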