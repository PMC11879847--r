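# Association statistics: exact and asymptotic behaviour against
# enumeration, permutation and closed-form oracles, plus NMDS geometry.

test_that("Mann-Whitney exact enumeration matches known values", {
  # fully separated small groups: one-sided 1/20, two-sided 1/10
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 1 / 10)
  expect_equal(r$statistic, 0)

  # identical multisets: symmetric case gives p = 1
  r2 <- mann_whitney(c(1, 2, 5), c(1, 2, 5))
  expect_equal(r2$p_value, 1)

  # exact p agrees with wilcox.test where the latter is exact (no ties)
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(6)
    y <- rnorm(7, 0.5)
    expect_equal(mann_whitney(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }

  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("Mann-Whitney normal approximation tracks a permutation oracle", {
  set.seed(8)
  x <- round(rnorm(15, 0, 1), 1)   # rounding forces ties
  y <- round(rnorm(15, 0.8, 1), 1)
  p_norm <- mann_whitney(x, y)$p_value
  # permutation estimate of the two-sided p for U
  pool <- c(x, y)
  r_all <- rank(pool)
  u_obs <- sum(r_all[1:15]) - 15 * 16 / 2
  u_perm <- replicate(1e5, {
    idx <- sample(30, 15)
    sum(rank(pool)[idx]) - 15 * 16 / 2
  })
  dev_obs <- abs(u_obs - 112.5)
  p_perm <- mean(abs(u_perm - 112.5) >= dev_obs - 1e-9)
  expect_lt(abs(p_norm - p_perm), 0.01)
})

test_that("Kruskal-Wallis matches the rank formula and is calibrated", {
  # {1,2},{3,4},{5,6}: H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1)
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  H <- 12 / (6 * 7) * (2 * 1.5^2 + 2 * 3.5^2 + 2 * 5.5^2) - 3 * 7
  r <- kruskal_wallis(groups)
  expect_equal(r$statistic, H, tolerance = 1e-12)
  expect_equal(r$df, 2)

  # two groups: agrees with the Mann-Whitney normal approximation
  set.seed(21)
  x <- rnorm(50)
  y <- rnorm(50, 0.3)
  expect_lt(abs(kruskal_wallis(list(x, y))$p_value -
                  mann_whitney(x, y)$p_value), 0.02)

  # type-I calibration on shuffled identical-distribution groups
  set.seed(77)
  rej <- replicate(500, {
    v <- sample(rnorm(30))
    kruskal_wallis(split(v, rep(1:3, each = 10)))$p_value < 0.05
  })
  expect_lte(mean(rej), 0.06)

  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
})

test_that("Dunn post hoc flags the shifted group and adjusts upward", {
  # two groups: single pair, adjustment is a no-op
  d2 <- dunn_posthoc(list(a = c(1, 3, 5), b = c(2, 4, 6)))
  expect_equal(nrow(d2), 1)
  expect_equal(d2$p_adjusted, d2$p_value)

  # deterministic constructed data: g3 far from g1 and g2
  g1 <- seq(1, 10)
  g2 <- seq(1.2, 10.2)
  g3 <- seq(101, 110)
  d3 <- dunn_posthoc(list(g1 = g1, g2 = g2, g3 = g3))
  far <- d3$group2 == "g3" | d3$group1 == "g3"
  expect_true(all(d3$p_adjusted[far] < 0.05))
  expect_true(all(d3$p_adjusted[!far] > 0.05))
  expect_true(all(d3$p_adjusted >= d3$p_value))

  # z statistics match a direct evaluation of the pooled-midrank formula
  vals <- c(g1, g2, g3)
  rk <- rank(vals)
  grp <- rep(1:3, each = 10)
  rb <- tapply(rk, grp, mean)
  N <- 30
  se <- sqrt((N * (N + 1) / 12) * (1 / 10 + 1 / 10))  # no ties here
  expect_equal(d3$z[d3$group1 == "g1" & d3$group2 == "g2"],
               unname((rb[1] - rb[2]) / se), tolerance = 1e-12)
})

test_that("two-proportion Z-test matches the pooled formula and calibrates", {
  r0 <- two_proportion_ztest(10, 40, 10, 40)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 0.5)

  # hand evaluation for (30/40 vs 15/40)
  p1 <- 30 / 40; p2 <- 15 / 40; pool <- 45 / 80
  z_hand <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / 40 + 1 / 40))
  r <- two_proportion_ztest(30, 40, 15, 40)
  expect_equal(r$statistic, z_hand, tolerance = 1e-12)
  expect_equal(r$p_value, pnorm(z_hand, lower.tail = FALSE), tolerance = 1e-12)

  # two-tailed variant doubles the tail
  r2 <- two_proportion_ztest(30, 40, 15, 40, tail = "two")
  expect_equal(r2$p_value, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)

  expect_warning(two_proportion_ztest(0, 10, 0, 10), "degenerate")

  set.seed(15)
  rej <- replicate(2000, {
    two_proportion_ztest(rbinom(1, 40, 0.5), 40,
                         rbinom(1, 40, 0.5), 40)$p_value < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("NMDS recovers planted geometry and is deterministic under seed", {
  # 1-D gradient
  x <- seq(0, 10, length.out = 25)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:25), paste0("s", 1:25))
  nm <- nmds(d, dims = 1, n_restarts = 50, seed = 3)
  expect_gte(abs(cor(nm$coordinates[, 1], x, method = "spearman")), 0.99)
  expect_lt(nm$stress, 0.02)

  # perfectly embeddable 2-D configuration
  set.seed(9)
  pts <- matrix(rnorm(20 * 2), 20)
  d2 <- as.matrix(dist(pts))
  nm2 <- nmds(d2, dims = 2, n_restarts = 50, seed = 5)
  expect_lt(nm2$stress, 0.01)

  # determinism and restart monotonicity under a shared seed stream
  nm2b <- nmds(d2, dims = 2, n_restarts = 50, seed = 5)
  expect_identical(nm2$coordinates, nm2b$coordinates)
  s_few <- nmds(d2, dims = 2, n_restarts = 3, seed = 5)$stress
  expect_lte(nm2$stress, s_few + 1e-12)

  expect_error(nmds(d2[1:3, 1:3], dims = 2, seed = 1), "dims")
})

test_that("axis t-test matches the pooled-variance closed form", {
  co <- c(a = 0, b = 1, c = 2, d = 10, e = 11, f = 12)
  grp <- c(a = "R", b = "R", c = "R", d = "NR", e = "NR", f = "NR")
  r <- axis_ttest(co, grp)
  # pooled variance 1, se = sqrt(2/3)
  expect_equal(abs(r$statistic), 10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-10 / sqrt(2 / 3), df = 4), tolerance = 1e-12)

  # identical distributions: t = 0, p = 1
  co2 <- c(a = 1, b = 2, c = 1, d = 2)
  r2 <- axis_ttest(co2, c(a = "R", b = "R", c = "NR", d = "NR"))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)

  # exchanging labels flips only the sign
  grp_sw <- c(a = "NR", b = "NR", c = "NR", d = "R", e = "R", f = "R")
  r3 <- axis_ttest(co, grp_sw)
  expect_equal(abs(r3$statistic), abs(r$statistic))
  expect_equal(r3$p_value, r$p_value)

  expect_error(axis_ttest(co, c(a = "R", b = "NR", c = "NR", d = "NR",
                                e = "NR", f = "NR")), ">= 2")
})

run_suite_on_cohort <- function(seed, hexa_fold = 2, lps_fold = 1.3,
                                with_clusters = FALSE) {
  cfg <- simulation_config(n_species = 80, n_samples_per_arm = 25,
                           hexa_fold_responder = hexa_fold,
                           total_lps_fold_nonresponder = lps_fold,
                           seed = seed)
  co <- simulate_cohort(cfg)
  calls <- classify_pangenome(co$pangenome)
  ab <- category_abundance(co$taxa, calls)
  filtered <- filter_rare_features(co$genes$counts)
  feats <- co$genes$features[
    co$genes$features$feature_id %in% rownames(filtered), ]
  cpm <- compute_cpm(filtered)
  et <- NULL
  if (with_clusters) {
    ko <- rowsum(filtered, feats$ko[match(rownames(filtered),
                                          feats$feature_id)])
    et <- select_k(jsd_distance(t(ko) / colSums(ko)), 2:4)
  }
  run_association_suite(cpm, feats, ab, co$metadata, enterotypes = et)
}

test_that("the association suite is deterministic and runs every analysis", {
  s1 <- run_suite_on_cohort(42, with_clusters = TRUE)
  s2 <- run_suite_on_cohort(42, with_clusters = TRUE)
  expect_identical(s1$summary, s2$summary)
  expect_true(all(c("total_lps_genes", "lpxL_genes", "lpxJ_genes",
                    "lpxM_genes", "lpxM_lpxL_gene_ratio", "hexa_penta_ratio",
                    "total_lps_taxa") %in% s1$summary$analysis))
  expect_true(all(s1$summary$p_value >= 0 & s1$summary$p_value <= 1))
  expect_true(!is.null(s1$enterotype_responder_ztests))
  expect_true(all(s1$total_lps_by_enterotype_dunn$p_adjusted >=
                    s1$total_lps_by_enterotype_dunn$p_value))
})

test_that("responder-vs-non-responder tests calibrate on null cohorts", {
  # folds = 1: the arm label is independent of every feature, so the family
  # of R-vs-NR p values should reject near the nominal rate. 20 cohorts x 9
  # correlated tests; the bound allows for the within-cohort correlation.
  ps <- unlist(lapply(1:20, function(s) {
    run_suite_on_cohort(s + 900, hexa_fold = 1, lps_fold = 1)$summary$p_value
  }))
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("the suite detects the planted hexa enrichment", {
  hits <- vapply(1:30, function(s) {
    sm <- run_suite_on_cohort(s)$summary
    sm$p_value[sm$analysis == "hexa_penta_ratio"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
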