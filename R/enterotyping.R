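# Functional enterotyping: Jensen-Shannon distances between samples,
# partitioning around medoids (deterministic BUILD + SWAP), cluster-number
# selection by a distance-based Calinski-Harabasz index, and the supporting
# ordinations (PCoA, between-class analysis).

#' Square-root Jensen-Shannon distance matrix
#'
#' Rows are per-sample relative-abundance profiles (renormalized if they do
#' not sum to one). `JSD(a, b) = KL(a || m)/2 + KL(b || m)/2` with
#' `m = (a + b)/2`, natural log, zero-probability features contributing
#' nothing to their own KL terms. The returned distance is `sqrt(JSD)`
#' (a metric, bounded by `sqrt(log 2)`); set `sqrt = FALSE` for plain JSD.
#'
#' @param profiles samples x features matrix of non-negative abundances.
#' @param sqrt take the square root (metric form); default `TRUE`.
#' @return symmetric samples x samples distance matrix with zero diagonal.
#' @export
jsd_distance <- function(profiles, sqrt = TRUE) {
  stopifnot(is.matrix(profiles))
  if (any(profiles < 0)) stop("negative entries in profiles", call. = FALSE)
  rs <- rowSums(profiles)
  if (any(rs == 0)) {
    stop("zero-sum profile row(s): ",
         paste(rownames(profiles)[rs == 0], collapse = ", "), call. = FALSE)
  }
  p <- profiles / rs
  # JSD(a,b) = H(m) - (H(a) + H(b))/2 with H the Shannon entropy (nats)
  ent <- function(x) {
    x <- x[x > 0]
    -sum(x * log(x))
  }
  h <- apply(p, 1, ent)
  n <- nrow(p)
  d <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m <- (p[i, ] + p[j, ]) / 2
      jsd <- ent(m) - (h[i] + h[j]) / 2
      jsd <- max(jsd, 0)  # guard tiny negative rounding
      d[i, j] <- d[j, i] <- if (sqrt) base::sqrt(jsd) else jsd
    }
  }
  d
}

.as_dist_matrix <- function(dist) {
  d <- if (inherits(dist, "dist")) as.matrix(dist) else dist
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  d
}

# objective: total distance of every point to its nearest medoid
.pam_objective <- function(d, medoids) {
  sum(apply(d[medoids, , drop = FALSE], 2, min))
}

#' Partitioning around medoids (PAM)
#'
#' k-medoids on a precomputed distance matrix, minimizing the total distance
#' of samples to their nearest medoid. Small instances (at most
#' `exact_limit` candidate medoid sets) are solved exactly by enumeration in
#' lexicographic order, since the classical local search can stall in local
#' optima that are detectable at this size; larger instances use the
#' classical BUILD phase followed by best-improvement SWAP exchanges. Both
#' routes are deterministic without a seed (ties go to the lexicographically
#' smallest medoid set; assignment ties to the lowest-index medoid).
#'
#' @param dist distance matrix (or `dist` object).
#' @param k number of clusters, `1 <= k < n` (k = 1 returns the 1-medoid
#'   minimizer).
#' @param exact_limit maximum number of medoid combinations enumerated
#'   exactly; default 2000.
#' @return object of class `pam_fit`: list with `medoids` (sample names),
#'   `assignments` (named integer cluster per sample) and `objective` (total
#'   within-cluster distance to medoids).
#' @export
pam_cluster <- function(dist, k, exact_limit = 2000) {
  d <- .as_dist_matrix(dist)
  n <- nrow(d)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k >= n) {
    stop("k out of range (need 1 <= k < n)", call. = FALSE)
  }
  k <- as.integer(k)
  if (choose(n, k) <= exact_limit) {
    # exact enumeration: strict improvement keeps the lexicographically
    # smallest optimal medoid set
    combs <- utils::combn(n, k)
    medoids <- combs[, 1]
    obj <- .pam_objective(d, medoids)
    for (j in seq_len(ncol(combs))[-1]) {
      o <- .pam_objective(d, combs[, j])
      if (o < obj - 1e-12) {
        obj <- o
        medoids <- combs[, j]
      }
    }
  } else {
    # BUILD: start from the 1-medoid minimizer, then greedily add the point
    # giving the largest objective decrease (ties -> lowest index)
    medoids <- which.min(rowSums(d))
    while (length(medoids) < k) {
      cur <- apply(d[medoids, , drop = FALSE], 2, min)
      cand <- setdiff(seq_len(n), medoids)
      gain <- vapply(cand, function(h) sum(pmax(cur - d[h, ], 0)), numeric(1))
      medoids <- c(medoids, cand[which.max(gain)])
    }
    # SWAP: best-improvement exchanges until a local optimum
    obj <- .pam_objective(d, medoids)
    repeat {
      best_obj <- obj
      best_set <- NULL
      for (mi in seq_along(medoids)) {
        for (h in setdiff(seq_len(n), medoids)) {
          trial <- medoids
          trial[mi] <- h
          tobj <- .pam_objective(d, trial)
          if (tobj < best_obj - 1e-12) {
            best_obj <- tobj
            best_set <- trial
          }
        }
      }
      if (is.null(best_set)) break
      medoids <- best_set
      obj <- best_obj
    }
  }
  medoids <- sort(medoids)
  assign <- apply(d[medoids, , drop = FALSE], 2, which.min)
  nm <- rownames(d)
  if (is.null(nm)) nm <- as.character(seq_len(n))
  names(assign) <- nm
  structure(list(medoids = nm[medoids], assignments = assign,
                 objective = .pam_objective(d, medoids)),
            class = "pam_fit")
}

#' Distance-based Calinski-Harabasz index
#'
#' Uses the Huygens identity so no coordinates are needed: for a cluster
#' `C`, the within sum of squares is the mean of squared pairwise distances,
#' `W_C = sum_{i<j in C} d_ij^2 / |C|`; the between term is the total sum of
#' squares minus the within terms. `CH = (B / (k-1)) / (W / (n-k))`.
#'
#' @param dist distance matrix.
#' @param assignments integer cluster labels per sample.
#' @return CH score (scalar).
#' @export
calinski_harabasz <- function(dist, assignments) {
  d2 <- .as_dist_matrix(dist)^2
  n <- nrow(d2)
  k <- length(unique(assignments))
  if (k < 2 || k >= n) stop("need 2 <= k < n clusters", call. = FALSE)
  tot <- sum(d2[upper.tri(d2)]) / n
  within <- sum(vapply(unique(assignments), function(cl) {
    idx <- which(assignments == cl)
    if (length(idx) < 2) return(0)
    dd <- d2[idx, idx, drop = FALSE]
    sum(dd[upper.tri(dd)]) / length(idx)
  }, numeric(1)))
  between <- tot - within
  (between / (k - 1)) / (within / (n - k))
}

#' Fit enterotypes: PAM over a range of k, selected by Calinski-Harabasz
#'
#' @param dist distance matrix (e.g. from [jsd_distance()]).
#' @param k_range candidate cluster numbers; default `2:6`.
#' @return object of class `enterotype_fit`: list with `k`, `assignments`,
#'   `medoids`, `objective` (for the selected k) and `ch_scores` (named per
#'   k). Ties in CH go to the smaller k.
#' @export
select_k <- function(dist, k_range = 2:6) {
  d <- .as_dist_matrix(dist)
  n <- nrow(d)
  if (max(k_range) >= n) stop("max(k_range) must be < number of samples",
                              call. = FALSE)
  off <- d[upper.tri(d)]
  if (length(off) == 0L || diff(range(off)) < 1e-12) {
    stop("non-informative distances: all pairwise distances are equal",
         call. = FALSE)
  }
  k_range <- sort(unique(as.integer(k_range)))
  fits <- lapply(k_range, function(k) pam_cluster(d, k))
  ch <- vapply(seq_along(k_range), function(i) {
    calinski_harabasz(d, fits[[i]]$assignments)
  }, numeric(1))
  names(ch) <- k_range
  best <- which.max(ch)  # which.max takes the first (smallest k) on ties
  fit <- fits[[best]]
  structure(list(k = k_range[best], assignments = fit$assignments,
                 medoids = fit$medoids, objective = fit$objective,
                 ch_scores = ch),
            class = "enterotype_fit")
}

#' Between-class analysis (BCA)
#'
#' Ordination with the cluster membership as instrumental variable: profiles
#' are centred per feature, class centroids are weighted by class size, and
#' the axes are the eigenvectors of the between-class covariance (at most
#' `classes - 1` of them). The ratio of between-class to total inertia
#' measures how much of the profile variance the classes explain.
#'
#' @param profiles samples x features matrix.
#' @param classes per-sample class labels (>= 2 classes).
#' @return object of class `ordination`: list with `coordinates` (samples x
#'   axes), `eigenvalues`, `inertia_ratio` and `method = "bca"`.
#' @export
between_class_analysis <- function(profiles, classes) {
  stopifnot(is.matrix(profiles), length(classes) == nrow(profiles))
  classes <- factor(classes)
  if (nlevels(classes) < 2) stop("need at least two classes", call. = FALSE)
  n <- nrow(profiles)
  x <- scale(profiles, center = TRUE, scale = FALSE)
  nk <- tabulate(classes)
  cent <- rowsum(x, classes) / nk                      # class centroids
  wc <- cent * base::sqrt(nk / n)                      # sqrt-weighted centroids
  sv <- svd(wc, nu = 0)
  n_axes <- min(nlevels(classes) - 1L, sum(sv$d > 1e-10))
  vec <- sv$v[, seq_len(n_axes), drop = FALSE]
  eig <- sv$d[seq_len(n_axes)]^2
  coords <- x %*% vec
  colnames(coords) <- paste0("BCA", seq_len(n_axes))
  total <- sum(x^2) / n
  between <- sum(nk / n * rowSums(cent^2))
  structure(list(coordinates = coords, eigenvalues = eig,
                 inertia_ratio = between / total, method = "bca"),
            class = "ordination")
}

#' Principal coordinate analysis (classical scaling)
#'
#' @param dist distance matrix.
#' @param n_axes axes requested; axes with non-positive eigenvalues are
#'   dropped.
#' @return object of class `ordination`: list with `coordinates`,
#'   `eigenvalues` (all of them, including any negative ones) and
#'   `method = "pcoa"`.
#' @export
pcoa <- function(dist, n_axes = 2) {
  d <- .as_dist_matrix(dist)
  n <- nrow(d)
  k <- min(n_axes, n - 1L)
  sc <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  eig <- sc$eig
  pos <- sum(eig[seq_len(k)] > 1e-10)
  coords <- sc$points[, seq_len(pos), drop = FALSE]
  if (pos > 0) colnames(coords) <- paste0("PCo", seq_len(pos))
  rownames(coords) <- rownames(d)
  structure(list(coordinates = coords, eigenvalues = eig, method = "pcoa"),
            class = "ordination")
}
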