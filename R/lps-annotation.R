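# Rule-based prediction of LPS structural capacity from pangenome gene content.
#
# A species is treated as encoding a gene when the gene is present in at least
# half of the genomes in its pangenome (inclusive threshold). The classifier
# works on the lipid A biosynthesis (lpx) pathway: the five-gene backbone
# lpxA/B/C/D/K builds lipid IVA, waaA (kdtA) attaches KDO, lpxL adds the fifth
# acyl chain and lpxM/lpxJ the sixth. lpxH is accepted in the vocabulary (it is
# part of the backbone operon) but is deliberately not required by the rule;
# modification genes (lpxE, lpxF, pagL, pagP) are carried through without
# affecting the acylation class.

#' Gene vocabulary recognised in pangenome tables
#'
#' @param core if `TRUE`, only the 10 genes used by the structural rule set
#'   (backbone + acyl-transferases) are returned; otherwise the full
#'   vocabulary including lipid A modification genes.
#' @return character vector of gene names.
#' @export
lps_gene_vocabulary <- function(core = FALSE) {
  core10 <- c("lpxA", "lpxB", "lpxC", "lpxD", "lpxH", "lpxK",
              "waaA", "lpxL", "lpxM", "lpxJ")
  if (core) core10 else c(core10, "lpxE", "lpxF", "pagL", "pagP")
}

# genes whose joint presence defines lipid IVA capacity
.lps_backbone <- c("lpxA", "lpxB", "lpxC", "lpxD", "lpxK")

.lps_categories <- c("non_lps", "tetra", "penta", "hexa_lpxM", "hexa_lpxJ")

.check_gene_names <- function(genes) {
  unknown <- setdiff(genes, lps_gene_vocabulary())
  if (length(unknown) > 0L) {
    stop("unknown gene name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(genes)
}

#' Merge two annotation evidence channels into one
#'
#' Pangenome tables may carry two annotation channels per gene (schema A and
#' schema B, e.g. two homology databases). The merged genome frequency is the
#' maximum over channels -- a species counts as encoding a gene if at least
#' one schema identifies it -- except for `lpxM`, for which only schema A is
#' trusted: the second schema systematically over-calls this acyl-transferase
#' in taxa known not to encode it.
#'
#' @param table a two-channel pangenome table as returned by
#'   [generate_pangenomes()]: a list with species x gene frequency matrices
#'   `schema_A` and `schema_B`, or a single-channel matrix (returned as is).
#' @return a single-channel pangenome matrix (species x genes).
#' @export
merge_annotation_evidence <- function(table) {
  if (is.matrix(table)) {
    .check_gene_names(colnames(table))
    return(table)
  }
  if (!is.list(table) || is.null(table$schema_A) || is.null(table$schema_B)) {
    stop("expected a two-channel pangenome (list with schema_A and schema_B)",
         call. = FALSE)
  }
  a <- table$schema_A
  b <- table$schema_B
  stopifnot(identical(dim(a), dim(b)), identical(dimnames(a), dimnames(b)))
  .check_gene_names(colnames(a))
  merged <- pmax(a, b)
  if ("lpxM" %in% colnames(merged)) {
    merged[, "lpxM"] <- a[, "lpxM"]
  }
  merged
}

#' Derive the gene set encoded by one species
#'
#' @param row named numeric vector of genome frequencies in `[0, 1]` for one
#'   species (single channel).
#' @param presence_threshold minimum fraction of genomes that must carry a
#'   gene; the comparison is inclusive ("at least"). Default 0.5.
#' @return character vector of genes considered encoded.
#' @export
derive_species_gene_set <- function(row, presence_threshold = 0.5) {
  if (!is.numeric(presence_threshold) || length(presence_threshold) != 1L ||
      presence_threshold <= 0 || presence_threshold > 1) {
    stop("presence_threshold must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(names(row))) stop("row must be named by gene", call. = FALSE)
  .check_gene_names(names(row))
  names(row)[row >= presence_threshold]
}

#' Classify LPS structural capacity from an encoded gene set
#'
#' Species encoding the full lipid IVA backbone (`lpxA`, `lpxB`, `lpxC`,
#' `lpxD`, `lpxK`) are LPS producers; adding `waaA` gives KDO2-lipid IVA.
#' Producers with `lpxL` and either `lpxM` or `lpxJ` can hexa-acylate lipid A
#' (both routes are recorded when both genes are present), producers with
#' `lpxL` alone are penta-acylated, and producers lacking `lpxL` are
#' tetra-acylated.
#'
#' @param genes character vector of encoded gene names (see
#'   [derive_species_gene_set()]).
#' @return an object of class `lps_structure`: list with `encodes_lps`,
#'   `kdo2`, `acylation` (one of `"none"`, `"tetra"`, `"penta"`, `"hexa"`)
#'   and `hexa_routes` (character subset of `c("lpxM", "lpxJ")`, empty unless
#'   hexa).
#' @export
classify_lps_structure <- function(genes) {
  .check_gene_names(genes)
  encodes <- all(.lps_backbone %in% genes)
  kdo2 <- encodes && "waaA" %in% genes
  routes <- character(0)
  if (!encodes) {
    acyl <- "none"
  } else if ("lpxL" %in% genes) {
    routes <- intersect(c("lpxM", "lpxJ"), genes)
    acyl <- if (length(routes) > 0L) "hexa" else "penta"
  } else {
    acyl <- "tetra"
  }
  structure(
    list(encodes_lps = encodes, kdo2 = kdo2, acylation = acyl,
         hexa_routes = routes),
    class = "lps_structure"
  )
}

#' Classify every species of a pangenome table
#'
#' Convenience wrapper: merges evidence channels if present, thresholds each
#' row and applies [classify_lps_structure()].
#'
#' @param table pangenome table (one- or two-channel).
#' @param presence_threshold passed to [derive_species_gene_set()].
#' @return named list of `lps_structure` objects, one per species.
#' @export
classify_pangenome <- function(table, presence_threshold = 0.5) {
  merged <- merge_annotation_evidence(table)
  out <- lapply(seq_len(nrow(merged)), function(i) {
    classify_lps_structure(
      derive_species_gene_set(merged[i, ], presence_threshold)
    )
  })
  names(out) <- rownames(merged)
  out
}

#' Tabulate structure calls
#'
#' @param structures named list of `lps_structure` objects.
#' @return list of counts: `n_species`, `encodes_lps`, `kdo2`, `tetra`,
#'   `penta`, `hexa`, `hexa_lpxM`, `hexa_lpxJ` (route counts; a species
#'   carrying both routes contributes to both but is counted once in `hexa`).
#' @export
tally_lps_categories <- function(structures) {
  acyl <- vapply(structures, function(s) s$acylation, character(1))
  routes <- lapply(structures, function(s) s$hexa_routes)
  list(
    n_species = length(structures),
    encodes_lps = sum(vapply(structures, function(s) s$encodes_lps, logical(1))),
    kdo2 = sum(vapply(structures, function(s) s$kdo2, logical(1))),
    tetra = sum(acyl == "tetra"),
    penta = sum(acyl == "penta"),
    hexa = sum(acyl == "hexa"),
    hexa_lpxM = sum(vapply(routes, function(r) "lpxM" %in% r, logical(1))),
    hexa_lpxJ = sum(vapply(routes, function(r) "lpxJ" %in% r, logical(1)))
  )
}

#' Aggregate taxon abundances by predicted LPS category
#'
#' Per sample, the fraction of classified reads carried by taxa in each LPS
#' category. Taxa without a structure call (absent from the pangenome
#' catalogue) are treated as non-producers.
#'
#' @param taxa taxa x samples matrix of read counts.
#' @param structures named list of `lps_structure` objects keyed by taxon.
#' @return samples x categories matrix with columns `total_lps`, `tetra`,
#'   `penta`, `hexa_lpxM`, `hexa_lpxJ`, `hexa_total`; fractions of total
#'   classified reads. `tetra + penta + hexa_total == total_lps`; a taxon
#'   carrying both hexa routes appears in both route columns but once in
#'   `hexa_total`.
#' @export
category_abundance <- function(taxa, structures) {
  stopifnot(is.matrix(taxa), !is.null(rownames(taxa)), !is.null(colnames(taxa)))
  if (any(taxa < 0)) stop("negative read counts", call. = FALSE)
  totals <- colSums(taxa)
  if (any(totals == 0)) {
    stop("sample(s) with zero classified reads: ",
         paste(colnames(taxa)[totals == 0], collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(rownames(taxa), names(structures))
  if (length(missing) > 0L) {
    message(length(missing), " taxa without a structure call treated as non-LPS")
  }
  get <- function(taxon) {
    s <- structures[[taxon]]
    if (is.null(s)) classify_lps_structure(character(0)) else s
  }
  calls <- lapply(rownames(taxa), get)
  acyl <- vapply(calls, function(s) s$acylation, character(1))
  has_m <- vapply(calls, function(s) "lpxM" %in% s$hexa_routes, logical(1))
  has_j <- vapply(calls, function(s) "lpxJ" %in% s$hexa_routes, logical(1))
  frac <- function(sel) {
    if (!any(sel)) return(numeric(ncol(taxa)) + 0)
    colSums(taxa[sel, , drop = FALSE]) / totals
  }
  out <- cbind(
    total_lps = frac(acyl != "none"),
    tetra = frac(acyl == "tetra"),
    penta = frac(acyl == "penta"),
    hexa_lpxM = frac(has_m),
    hexa_lpxJ = frac(has_j),
    hexa_total = frac(acyl == "hexa")
  )
  rownames(out) <- colnames(taxa)
  out
}

#' @export
print.lps_structure <- function(x, ...) {
  cat("LPS structure call:",
      if (!x$encodes_lps) "non-producer" else paste0(
        x$acylation, "-acylated",
        if (x$kdo2) ", KDO2-lipid IVA" else ", no KDO2",
        if (length(x$hexa_routes)) paste0(" (routes: ",
                                          paste(x$hexa_routes, collapse = ","), ")") else ""
      ), "\n")
  invisible(x)
}
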