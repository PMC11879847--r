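# Count normalizations (GCPM, CPM, CLR), sample/feature filters and the
# ratio statistics used downstream. All matrix functions take features x
# samples matrices and operate per sample (column); vectors are treated as a
# single sample.

.as_col_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1, dimnames = list(names(x), "sample"))
}

#' Gene count per million (GCPM)
#'
#' Length- and depth-normalized gene abundance:
#' `GCPM_i = (q_i / l_i) / sum_j(q_j / l_j) * 1e6`, where `q_i` are raw
#' mapped reads and `l_i` the gene length in bp. Columns sum to 1e6.
#'
#' @param q features x samples matrix (or vector) of raw read counts.
#' @param l gene lengths (bp), one per feature, recycled across samples.
#' @return matrix (or vector) of GCPM values.
#' @export
compute_gcpm <- function(q, l) {
  vec <- !is.matrix(q)
  q <- .as_col_matrix(q)
  if (length(l) != nrow(q)) stop("one length per feature required", call. = FALSE)
  if (any(l <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (any(q < 0)) stop("negative counts", call. = FALSE)
  rate <- q / l
  tot <- colSums(rate)
  if (any(tot == 0)) {
    bad <- colnames(q)[tot == 0]
    stop("all-zero sample(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- sweep(rate, 2, tot, "/") * 1e6
  if (vec) out[, 1] else out
}

#' Count per million (CPM)
#'
#' `CPM_i = A_i / sum(A) * 1e6` on (batch-adjusted) counts. Columns sum to
#' 1e6; invariant to a positive rescaling of a sample's counts.
#'
#' @param A features x samples matrix (or vector) of non-negative values.
#' @return matrix (or vector) of CPM values.
#' @export
compute_cpm <- function(A) {
  vec <- !is.matrix(A)
  A <- .as_col_matrix(A)
  if (any(A < 0)) stop("negative counts", call. = FALSE)
  tot <- colSums(A)
  if (any(tot == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(A)[tot == 0], collapse = ", "), call. = FALSE)
  }
  out <- sweep(A, 2, tot, "/") * 1e6
  if (vec) out[, 1] else out
}

#' Pseudocount log transform
#'
#' `log(A + pseudocount)`; the pseudocount is added before the log so zeros
#' stay finite. Natural log.
#'
#' @param A non-negative values.
#' @param pseudocount added before the log; default 1e-6.
#' @return transformed values, monotone in `A`.
#' @export
pseudolog_transform <- function(A, pseudocount = 1e-6) {
  if (any(A < 0)) stop("negative input", call. = FALSE)
  log(A + pseudocount)
}

#' Normalize a gene count matrix for pooled-cohort analysis
#'
#' Applies [simple_batch_adjust()] (when batch labels are given) and the
#' printed CPM formula; optionally follows with the pseudocount log
#' transform. The CPM-of-raw-adjusted-counts route is the default because
#' the log-scale values are sign-indefinite and cannot themselves be scaled
#' to counts per million.
#'
#' @param counts features x samples count matrix.
#' @param batch optional per-sample batch labels.
#' @param method `"cpm"` (default) or `"cpm_pseudolog"` (CPM then
#'   [pseudolog_transform()]).
#' @param pseudocount used by the pseudolog variant.
#' @return normalized matrix, with a `scale` attribute.
#' @export
normalize_genes <- function(counts, batch = NULL,
                            method = c("cpm", "cpm_pseudolog"),
                            pseudocount = 1e-6) {
  method <- match.arg(method)
  if (!is.null(batch)) counts <- simple_batch_adjust(counts, batch)
  out <- compute_cpm(counts)
  if (method == "cpm_pseudolog") out <- pseudolog_transform(out, pseudocount)
  attr(out, "scale") <- method
  out
}

#' Drop features detected in too few samples
#'
#' Features with nonzero counts in fewer than `min_samples` samples are
#' removed (a feature seen in exactly `min_samples` samples is retained).
#'
#' @param mat features x samples matrix.
#' @param min_samples detection threshold; default 5.
#' @return filtered matrix; attribute `dropped` lists removed feature names.
#' @export
filter_rare_features <- function(mat, min_samples = 5) {
  if (nrow(mat) == 0L) {
    attr(mat, "dropped") <- character(0)
    return(mat)
  }
  n_detect <- rowSums(mat != 0)
  keep <- n_detect >= min_samples
  out <- mat[keep, , drop = FALSE]
  attr(out, "dropped") <- rownames(mat)[!keep]
  out
}

#' Restrict to samples where a feature was detected
#'
#' Samples with value zero are excluded before group summaries, mirroring
#' the exclusion of undetected samples.
#'
#' @param values named per-sample values.
#' @return the nonzero subset; attribute `n_excluded` counts exclusions.
#'   Warns when everything is excluded.
#' @export
nonzero_subset <- function(values) {
  keep <- values != 0
  if (!any(keep)) warning("all samples have zero value", call. = FALSE)
  out <- values[keep]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Hexa- to penta-acylated taxa ratio per sample
#'
#' @param abund samples x categories matrix from [category_abundance()].
#' @param numerator `"hexa_total"` (default) or `"hexa_lpxM"`.
#' @return data.frame `sample_id`, `ratio`, `defined`; samples with zero
#'   penta abundance are flagged undefined (ratio `NA`) and should be
#'   excluded from summaries.
#' @export
hexa_penta_ratio <- function(abund, numerator = c("hexa_total", "hexa_lpxM")) {
  numerator <- match.arg(numerator)
  stopifnot(all(c(numerator, "penta") %in% colnames(abund)))
  den <- abund[, "penta"]
  num <- abund[, numerator]
  defined <- den > 0
  data.frame(sample_id = rownames(abund),
             ratio = ifelse(defined, num / den, NA_real_),
             defined = defined,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-sample ratio of two gene abundance vectors
#'
#' @param num_cpm,den_cpm named per-sample abundances on a common scale
#'   (e.g. CPM); names must match.
#' @return data.frame `sample_id`, `ratio`, `defined` (zero denominators are
#'   undefined).
#' @export
gene_ratio <- function(num_cpm, den_cpm) {
  if (is.null(names(num_cpm)) || is.null(names(den_cpm)) ||
      !identical(names(num_cpm), names(den_cpm))) {
    stop("numerator and denominator samples do not match", call. = FALSE)
  }
  defined <- den_cpm > 0
  data.frame(sample_id = names(num_cpm),
             ratio = ifelse(defined, num_cpm / den_cpm, NA_real_),
             defined = defined,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Centred log-ratio (CLR) normalization
#'
#' Per sample: zeros are replaced by half the smallest nonzero value in that
#' sample (multiplicative replacement), the composition is closed, and
#' `clr_i = log(x_i) - mean(log x)`. Columns sum to 0.
#'
#' @param counts features x samples matrix (or vector) of non-negative
#'   values.
#' @return CLR-transformed matrix (or vector).
#' @export
clr_normalize <- function(counts) {
  vec <- !is.matrix(counts)
  counts <- .as_col_matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  out <- apply(counts, 2, function(x) {
    if (all(x == 0)) stop("all-zero sample", call. = FALSE)
    nz <- min(x[x > 0])
    x[x == 0] <- nz / 2
    lx <- log(x / sum(x))
    lx - mean(lx)
  })
  out <- matrix(out, nrow = nrow(counts), dimnames = dimnames(counts))
  if (vec) out[, 1] else out
}

#' Normalize taxa counts by faecal pellet weight
#'
#' @param counts taxa x samples count matrix.
#' @param weights_mg named per-sample pellet weights (mg), all positive.
#' @return counts divided by sample weight (reads/mg).
#' @export
weight_normalize <- function(counts, weights_mg) {
  if (is.null(names(weights_mg))) names(weights_mg) <- colnames(counts)
  missing <- setdiff(colnames(counts), names(weights_mg))
  if (length(missing) > 0L) {
    stop("missing faecal weight for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  w <- weights_mg[colnames(counts)]
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("faecal weights must be positive", call. = FALSE)
  }
  sweep(counts, 2, w, "/")
}

#' Simple per-batch median adjustment
#'
#' A deliberately minimal stand-in for heavier batch-correction machinery:
#' for every feature, each batch's counts are rescaled by the multiplicative
#' factor that moves the batch's median log nonzero count onto the feature's
#' global median log nonzero count. Zeros stay zero, output stays
#' non-negative, and with a single batch the operation is the identity.
#'
#' @param counts features x samples matrix.
#' @param batch per-sample batch labels (length `ncol(counts)`).
#' @return adjusted matrix. Batches with a single sample are left unadjusted
#'   with a warning.
#' @export
simple_batch_adjust <- function(counts, batch) {
  stopifnot(length(batch) == ncol(counts))
  batch <- as.character(batch)
  levs <- unique(batch)
  if (length(levs) == 1L) return(counts)
  singles <- levs[tabulate(factor(batch, levels = levs)) == 1L]
  if (length(singles) > 0L) {
    warning("batch(es) with a single sample left unadjusted: ",
            paste(singles, collapse = ", "), call. = FALSE)
  }
  med_log <- function(x) {
    x <- x[x > 0]
    if (length(x) == 0L) NA_real_ else stats::median(log(x))
  }
  out <- counts
  global <- apply(counts, 1, med_log)
  for (b in setdiff(levs, singles)) {
    sel <- batch == b
    bmed <- apply(counts[, sel, drop = FALSE], 1, med_log)
    delta <- global - bmed
    delta[!is.finite(delta)] <- 0
    out[, sel] <- counts[, sel, drop = FALSE] * exp(delta)
  }
  out
}
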