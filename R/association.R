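# Group-association statistics: Mann-Whitney (exact enumeration for small
# groups, tie-corrected normal approximation otherwise), Kruskal-Wallis with
# Dunn post hoc and Bonferroni adjustment, the pooled two-proportion Z-test
# without continuity correction, NMDS with multiple restarts and a
# Procrustes convergence check, t-tests on ordination axes, and the suite
# runner that applies them across a cohort's tables.

association_report <- function(test, statistic, p_value, tail,
                               groups = NULL, extra = NULL) {
  structure(c(list(test = test, statistic = statistic, p_value = p_value,
                   tail = tail, groups = groups), extra),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 4), " (", x$tail, "-tailed)\n",
      sep = "")
  invisible(x)
}

# exact two-group rank-sum enumeration (handles ties via midranks);
# feasible for small groups only
.mw_exact_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(length(r), nx)
  u_all <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
  lo <- mean(u_all <= u_obs + 1e-9)
  hi <- mean(u_all >= u_obs - 1e-9)
  list(u = u_obs, one_sided = min(lo, hi), two_sided = min(1, 2 * min(lo, hi)))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided by default. With at most `exact_max` observations per group the
#' p value is computed by exact enumeration of all group assignments of the
#' (mid)ranks; otherwise by the tie-corrected normal approximation (no
#' continuity correction).
#'
#' @param x,y numeric samples for the two groups.
#' @param exact_max per-group size up to which the exact enumeration is
#'   used; default 8.
#' @return `association_report` with the U statistic (for `x`), p value and
#'   per-group summaries.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("empty group", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx <= exact_max && ny <= exact_max) {
    ex <- .mw_exact_p(x, y)
    p <- ex$two_sided
    method <- "exact"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - nx * ny / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation"
  }
  association_report(
    test = paste0("Mann-Whitney (", method, ")"),
    statistic = u, p_value = p, tail = "two",
    groups = data.frame(group = c("x", "y"), n = c(nx, ny),
                        median = c(stats::median(x), stats::median(y)))
  )
}

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected H statistic with a chi-square reference
#' (via [stats::kruskal.test()]).
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups).
#' @return `association_report`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) < 2) {
    stop("all values identical: Kruskal-Wallis undefined", call. = FALSE)
  }
  kt <- stats::kruskal.test(groups)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("g", seq_along(groups))
  association_report(
    test = "Kruskal-Wallis",
    statistic = unname(kt$statistic), p_value = kt$p.value, tail = "two",
    groups = data.frame(group = nms,
                        n = vapply(groups, length, integer(1)),
                        median = vapply(groups, stats::median, numeric(1))),
    extra = list(df = unname(kt$parameter))
  )
}

#' Dunn post hoc test with Bonferroni adjustment
#'
#' Pairwise z statistics from the pooled midranks with tie correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t)` over tie groups. Two-sided p values are
#' Bonferroni-adjusted over the number of pairs.
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @return data.frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) < 2) {
    stop("all values identical: Dunn test undefined", call. = FALSE)
  }
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("g", seq_along(groups))
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  r <- rank(vals)
  N <- length(vals)
  rbar <- tapply(r, g, mean)
  nn <- tapply(r, g, length)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  res <- vapply(seq_len(ncol(pairs)), function(col) {
    i <- pairs[1, col]; j <- pairs[2, col]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / nn[i] + 1 / nn[j]))
    z <- unname((rbar[i] - rbar[j]) / se)
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  }, numeric(2))
  out <- data.frame(group1 = nms[pairs[1, ]], group2 = nms[pairs[2, ]],
                    z = res["z", ], p_value = res["p", ],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "bonferroni")
  out
}

#' Two-proportion Z-test (pooled, no continuity correction)
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with the pooled proportion
#' `p`. One-tailed by default in the direction `p1 > p2`.
#'
#' @param x1,n1 successes and total in group 1.
#' @param x2,n2 successes and total in group 2.
#' @param tail `"greater"` (p1 > p2; default), `"less"` or `"two"`.
#' @return `association_report`. Degenerate pooled proportions (0 or 1)
#'   give p = 1 with a warning.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2,
                                 tail = c("greater", "less", "two")) {
  tail <- match.arg(tail)
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  if (pool %in% c(0, 1)) {
    warning("degenerate pooled proportion; test uninformative", call. = FALSE)
    return(association_report("two-proportion Z", statistic = 0, p_value = 1,
                              tail = if (tail == "two") "two" else "one"))
  }
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  p <- switch(tail,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two = 2 * stats::pnorm(-abs(z)))
  association_report(
    test = "two-proportion Z (pooled, no continuity correction)",
    statistic = z, p_value = p, tail = if (tail == "two") "two" else "one",
    groups = data.frame(group = c("1", "2"), n = c(n1, n2),
                        proportion = c(p1, p2))
  )
}

#' Non-metric multidimensional scaling with restarts
#'
#' Kruskal stress-1 NMDS (via [vegan::monoMDS()]): the first restart starts
#' from the PCoA configuration, the remaining restarts from random Gaussian
#' configurations. The lowest-stress solution is kept; convergence is
#' declared when the symmetric Procrustes RMSE between the two best
#' solutions falls below `tol`, at which point remaining restarts are
#' skipped ("iterate or the best solution achieved").
#'
#' @param dist distance matrix (or `dist`).
#' @param dims embedding dimension; default 2.
#' @param n_restarts maximum restarts; default 1000.
#' @param seed integer seed (restart stream); required for reproducibility.
#' @param tol Procrustes RMSE convergence tolerance on solutions scaled to
#'   unit total variance; default 1e-4.
#' @return object of class `nmds_solution`: list with `coordinates`
#'   (samples x dims), `stress` (Kruskal stress-1, in `[0, 1]`),
#'   `n_restarts` used and `converged` flag.
#' @export
nmds <- function(dist, dims = 2, n_restarts = 1000, seed = 1L, tol = 1e-4) {
  d <- .as_dist_matrix(dist)
  n <- nrow(d)
  if (dims >= n - 1) stop("dims must be < n - 1", call. = FALSE)
  dd <- stats::as.dist(d)
  with_local_seed(seed + 606L, {
    best <- NULL; second <- NULL
    used <- 0L; converged <- FALSE
    init0 <- stats::cmdscale(dd, k = dims)
    for (r in seq_len(n_restarts)) {
      init <- if (r == 1L) init0 else matrix(stats::rnorm(n * dims), n, dims)
      fit <- vegan::monoMDS(dd, y = init, k = dims, model = "global")
      used <- r
      if (is.null(best) || fit$stress < best$stress) {
        second <- best
        best <- fit
      } else if (is.null(second) || fit$stress < second$stress) {
        second <- fit
      }
      if (!is.null(second)) {
        pr <- vegan::procrustes(best$points, second$points, symmetric = TRUE)
        if (sqrt(pr$ss / n) < tol) {
          converged <- TRUE
          break
        }
      }
    }
    coords <- best$points
    rownames(coords) <- rownames(d)
    colnames(coords) <- paste0("NMDS", seq_len(dims))
    structure(list(coordinates = coords, stress = best$stress,
                   n_restarts = used, converged = converged),
              class = "nmds_solution")
  })
}

#' Two-sample t-test on an ordination axis
#'
#' Pooled-variance, two-tailed t-test comparing the axis coordinates of two
#' groups (e.g. responders vs non-responders on NMDS axis 1).
#'
#' @param coords named numeric vector of axis coordinates.
#' @param groups named group labels (exactly two levels, each with >= 2
#'   samples); names must cover the coordinate names.
#' @return `association_report`.
#' @export
axis_ttest <- function(coords, groups) {
  g <- factor(groups[names(coords)])
  if (nlevels(g) != 2) stop("need exactly two groups", call. = FALSE)
  if (any(table(g) < 2)) stop("each group needs >= 2 samples", call. = FALSE)
  tt <- stats::t.test(coords ~ g, var.equal = TRUE)
  association_report(
    test = "two-sample t (pooled variance)",
    statistic = unname(tt$statistic), p_value = tt$p.value, tail = "two",
    groups = data.frame(group = levels(g), n = as.integer(table(g)),
                        mean = as.numeric(tapply(coords, g, mean)))
  )
}

# sum CPM rows over a KO (gene) label
.ko_abundance <- function(cpm, features, kos) {
  sel <- features$ko %in% kos
  if (!any(sel)) return(stats::setNames(numeric(ncol(cpm)), colnames(cpm)))
  colSums(cpm[features$feature_id[sel], , drop = FALSE])
}

#' Run the cohort association suite
#'
#' Applies the study's battery of tests to a cohort: Mann-Whitney on total
#' LPS gene abundance and on each acyl-transferase gene (responder vs
#' non-responder), Mann-Whitney on category abundances and hexa:penta /
#' lpxM:lpxL ratios, one-tailed two-proportion Z-tests on responder
#' proportions between enterotypes, Kruskal-Wallis + Dunn across enterotypes,
#' and t-tests on the NMDS axes.
#'
#' @param gene_cpm normalized (CPM) gene matrix, features x samples.
#' @param features feature table (`feature_id`, `ko`, `taxon`, `length_bp`).
#' @param cat_abund samples x categories matrix from [category_abundance()].
#' @param metadata data.frame with `sample_id`, `response` (`"R"`/`"NR"`).
#' @param enterotypes optional `enterotype_fit`.
#' @param nmds_fit optional `nmds_solution`.
#' @return named list of `association_report`s / data.frames, plus a
#'   `summary` data.frame (test, p value).
#' @export
run_association_suite <- function(gene_cpm, features, cat_abund, metadata,
                                  enterotypes = NULL, nmds_fit = NULL) {
  stopifnot(all(c("sample_id", "response") %in% names(metadata)))
  samples <- colnames(gene_cpm)
  if (!all(samples %in% metadata$sample_id)) {
    stop("metadata missing for some samples", call. = FALSE)
  }
  resp <- stats::setNames(metadata$response, metadata$sample_id)[samples]
  is_r <- resp == "R"
  split_rn <- function(v) list(r = v[is_r], nr = v[!is_r])
  reports <- list()

  lps_genes <- lps_gene_vocabulary()
  tot <- .ko_abundance(gene_cpm, features, lps_genes)
  g <- split_rn(tot)
  reports$total_lps_genes <- mann_whitney(g$r, g$nr)
  for (gene in c("lpxL", "lpxJ", "lpxM")) {
    v <- .ko_abundance(gene_cpm, features, gene)
    gg <- split_rn(v)
    reports[[paste0(gene, "_genes")]] <- mann_whitney(gg$r, gg$nr)
  }

  lpxM <- .ko_abundance(gene_cpm, features, "lpxM")
  lpxL <- .ko_abundance(gene_cpm, features, "lpxL")
  gr <- gene_ratio(lpxM, lpxL)
  rr <- stats::setNames(gr$ratio, gr$sample_id)[gr$defined]
  gg <- list(r = rr[names(rr) %in% samples[is_r]],
             nr = rr[names(rr) %in% samples[!is_r]])
  reports$lpxM_lpxL_gene_ratio <- mann_whitney(gg$r, gg$nr)

  for (categ in c("total_lps", "penta", "hexa_total")) {
    v <- cat_abund[samples, categ]
    gg <- split_rn(v)
    reports[[paste0(categ, "_taxa")]] <- mann_whitney(gg$r, gg$nr)
  }
  hp <- hexa_penta_ratio(cat_abund[samples, , drop = FALSE])
  hv <- stats::setNames(hp$ratio, hp$sample_id)[hp$defined]
  gg <- list(r = hv[names(hv) %in% samples[is_r]],
             nr = hv[names(hv) %in% samples[!is_r]])
  reports$hexa_penta_ratio <- mann_whitney(gg$r, gg$nr)

  if (!is.null(enterotypes)) {
    et <- enterotypes$assignments[samples]
    ks <- sort(unique(et))
    if (length(ks) >= 2) {
      prs <- utils::combn(ks, 2)
      ztests <- lapply(seq_len(ncol(prs)), function(i) {
        a <- prs[1, i]; b <- prs[2, i]
        xa <- sum(is_r[et == a]); na <- sum(et == a)
        xb <- sum(is_r[et == b]); nb <- sum(et == b)
        # one-tailed in the observed direction, higher proportion first
        if (xa / na >= xb / nb) {
          two_proportion_ztest(xa, na, xb, nb, tail = "greater")
        } else {
          two_proportion_ztest(xb, nb, xa, na, tail = "greater")
        }
      })
      names(ztests) <- apply(prs, 2, function(ij)
        paste0("enterotype_", ij[1], "_vs_", ij[2]))
      reports$enterotype_responder_ztests <- ztests
      by_et <- function(v) split(v, et)
      reports$total_lps_by_enterotype_kw <- kruskal_wallis(by_et(tot))
      reports$total_lps_by_enterotype_dunn <- dunn_posthoc(by_et(tot))
      reports$lpxM_by_enterotype_kw <- kruskal_wallis(by_et(lpxM))
      reports$lpxM_by_enterotype_dunn <- dunn_posthoc(by_et(lpxM))
    }
  }

  if (!is.null(nmds_fit)) {
    for (ax in colnames(nmds_fit$coordinates)) {
      co <- stats::setNames(nmds_fit$coordinates[, ax],
                            rownames(nmds_fit$coordinates))
      reports[[paste0(tolower(ax), "_ttest")]] <- axis_ttest(co[samples], resp)
    }
  }

  flat <- reports[vapply(reports, inherits, logical(1), "association_report")]
  reports$summary <- data.frame(
    analysis = names(flat),
    p_value = vapply(flat, function(r) r$p_value, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  reports
}
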