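# JSD distances, PAM clustering, cluster-number selection, and ordinations.

test_that("sqrt-JSD matches the double-loop KL oracle and its bounds", {
  a <- c(0.5, 0.5)
  b <- c(0.9, 0.1)
  d <- jsd_distance(rbind(s1 = a, s2 = b))
  expect_equal(d["s1", "s2"], oracle_sqrt_jsd(a, b), tolerance = 1e-12)
  expect_equal(d["s1", "s1"], 0)
  expect_equal(d["s1", "s2"], d["s2", "s1"])

  # identical rows -> 0; disjoint support -> the JSD maximum sqrt(ln 2)
  d2 <- jsd_distance(rbind(x = c(1, 0, 3), y = c(1, 0, 3), z = c(0, 5, 0)))
  expect_equal(d2["x", "y"], 0)
  expect_equal(d2["x", "z"], sqrt(log(2)), tolerance = 1e-12)

  set.seed(10)
  for (i in 1:20) {
    p <- matrix(rgamma(2 * 15, 0.5), 2)
    dd <- jsd_distance(p)
    expect_equal(dd[1, 2], oracle_sqrt_jsd(p[1, ], p[2, ]), tolerance = 1e-10)
  }

  expect_error(jsd_distance(rbind(c(-1, 2), c(1, 1))), "negative")
  expect_error(jsd_distance(rbind(a = c(0, 0), b = c(1, 1))), "a")
})

test_that("sqrt-JSD is a metric on random triples; plain JSD need not be", {
  set.seed(11)
  p <- matrix(rgamma(3000 * 8, 0.3) + 1e-12, ncol = 8)
  viol <- 0L
  for (i in 1:1000) {
    rows <- p[(3 * i - 2):(3 * i), , drop = FALSE]
    d <- jsd_distance(rows)
    if (d[1, 2] > d[1, 3] + d[2, 3] + 1e-12 ||
        d[1, 3] > d[1, 2] + d[2, 3] + 1e-12 ||
        d[2, 3] > d[1, 2] + d[1, 3] + 1e-12) viol <- viol + 1L
    expect_true(all(d >= 0 & d <= sqrt(log(2)) + 1e-12))
  }
  expect_equal(viol, 0L)
})

test_that("PAM recovers separable clouds and the brute-force optimum", {
  d <- toy_two_clouds()
  fit <- pam_cluster(d, 2)
  cl <- fit$assignments
  expect_equal(length(unique(cl[1:4])), 1)
  expect_equal(length(unique(cl[5:7])), 1)
  expect_false(cl[1] == cl[5])

  # k = 1: medoid equals the exhaustive 1-medoid minimizer
  fit1 <- pam_cluster(d, 1)
  expect_equal(fit1$objective, min(rowSums(d)))

  # n = 7, k = 2: objective equals the exhaustive minimum over medoid pairs
  expect_equal(fit$objective, oracle_pam_objective(d, 2))

  expect_error(pam_cluster(d, 0), "range")
  expect_error(pam_cluster(d, 7), "range")
})

test_that("PAM equals the brute-force optimum on all small instances", {
  set.seed(20)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    k <- sample(2:3, 1)
    d <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    fit <- pam_cluster(d, k)
    expect_equal(fit$objective, oracle_pam_objective(d, k), tolerance = 1e-12)
    # never worse than the reference implementation
    ref <- cluster::pam(as.dist(d), k)
    expect_lte(fit$objective, sum(ref$clusinfo[, "size"] *
                                    ref$clusinfo[, "av_diss"]) + 1e-9)
  }
})

test_that("the swap-phase route matches the exact route on separable data", {
  # same instance solved with and without the enumeration shortcut
  d <- toy_two_clouds()
  exact <- pam_cluster(d, 2)
  swap <- pam_cluster(d, 2, exact_limit = 1)
  expect_equal(swap$objective, exact$objective)
  expect_equal(swap$assignments, exact$assignments)
})

test_that("Calinski-Harabasz from distances matches the centroid formula in Euclidean space", {
  set.seed(12)
  pts <- rbind(matrix(rnorm(20, 0), ncol = 2),
               matrix(rnorm(20, 4), ncol = 2),
               matrix(rnorm(20, 8), ncol = 2))
  lab <- rep(1:3, each = 10)
  d <- as.matrix(dist(pts))
  ch_dist <- calinski_harabasz(d, lab)
  # direct centroid computation
  n <- nrow(pts)
  k <- 3
  cent <- rowsum(pts, lab) / as.vector(table(lab))
  w <- sum((pts - cent[lab, ])^2)
  b <- sum(as.vector(table(lab)) * rowSums(sweep(cent, 2, colMeans(pts))^2))
  ch_direct <- (b / (k - 1)) / (w / (n - k))
  expect_equal(ch_dist, ch_direct, tolerance = 1e-9)
})

test_that("CH-guided selection finds planted clusters and resists duplication", {
  hits_k <- ari_ok <- logical(20)
  for (s in 1:20) {
    g <- generate_functional_clusters(n_samples = 45, seed = s + 400)
    d <- jsd_distance(g$profiles)
    fit <- select_k(d, 2:6)
    hits_k[s] <- fit$k == 3
    ari_ok[s] <- mclust::adjustedRandIndex(pam_cluster(d, 3)$assignments,
                                           g$cluster) >= 0.9
  }
  expect_gte(mean(hits_k), 0.9)
  expect_gte(mean(ari_ok), 0.9)

  # duplicating every sample must not change the selected k
  g <- generate_functional_clusters(n_samples = 30, seed = 3)
  prof2 <- rbind(g$profiles, g$profiles)
  rownames(prof2) <- paste0("r", seq_len(nrow(prof2)))
  fit1 <- select_k(jsd_distance(g$profiles), 2:5)
  fit2 <- select_k(jsd_distance(prof2), 2:5)
  expect_equal(fit2$k, fit1$k)

  # uninformative (all-equal) distances are rejected
  dflat <- matrix(1, 6, 6) - diag(6)
  dimnames(dflat) <- list(paste0("s", 1:6), paste0("s", 1:6))
  expect_error(select_k(dflat, 2:3), "non-informative")

  # medoids belong to their own clusters; CH argmax is the pick
  fit <- select_k(jsd_distance(g$profiles), 2:5)
  med_cl <- fit$assignments[fit$medoids]
  expect_equal(sort(unname(med_cl)), seq_along(fit$medoids))
  expect_equal(unname(fit$k),
               as.integer(names(fit$ch_scores)[which.max(fit$ch_scores)]))
})

test_that("between-class analysis separates planted classes and calibrates under permutation", {
  g <- generate_functional_clusters(n_samples = 36, seed = 23)
  # two classes -> exactly one axis, ordered by class means
  two <- g$cluster %in% 1:2
  prof <- g$profiles[two, ]
  cls <- g$cluster[two]
  b <- between_class_analysis(prof, cls)
  expect_equal(ncol(b$coordinates), 1)
  m1 <- mean(b$coordinates[cls == 1, 1])
  m2 <- mean(b$coordinates[cls == 2, 1])
  expect_gt(abs(m1 - m2), 0)

  # planted classes: observed inertia ratio beats the 95th permutation percentile
  obs <- between_class_analysis(g$profiles, g$cluster)$inertia_ratio
  set.seed(99)
  null <- replicate(199, {
    between_class_analysis(g$profiles, sample(g$cluster))$inertia_ratio
  })
  expect_gt(obs, quantile(null, 0.95))
  # random labels: observed ratio is typical of its own null
  rnd <- sample(g$cluster)
  obs_r <- between_class_analysis(g$profiles, rnd)$inertia_ratio
  expect_lt(obs_r, quantile(null, 0.999))

  expect_error(between_class_analysis(g$profiles, rep(1, nrow(g$profiles))),
               "two classes")
})

test_that("PCoA reproduces Euclidean geometry", {
  x <- seq(0, 5, length.out = 12)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:12), paste0("s", 1:12))
  ord <- pcoa(d, n_axes = 2)
  expect_equal(abs(cor(ord$coordinates[, 1], x, method = "spearman")), 1)

  set.seed(14)
  pts <- matrix(rnorm(10 * 3), 10)
  d2 <- as.matrix(dist(pts))
  ord2 <- pcoa(d2, n_axes = 3)
  rec <- as.matrix(dist(ord2$coordinates))
  expect_lt(max(abs(rec - d2)), 1e-8)
  # eigenvalues are reported in decreasing order
  k <- ncol(ord2$coordinates)
  expect_true(all(diff(ord2$eigenvalues[1:k]) <= 1e-9))

  # a duplicated sample lands on coincident coordinates
  d3 <- as.matrix(dist(rbind(pts, pts[1, ])))
  ord3 <- pcoa(d3, n_axes = 2)
  expect_lt(max(abs(ord3$coordinates[1, ] - ord3$coordinates[11, ])), 1e-8)
})
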