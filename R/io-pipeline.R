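# Plain-text interchange (TSV matrices, CSV metadata, JSON reports), the
# pipeline configuration, and the end-to-end run-all orchestration with a
# reproducible manifest.

#' Read a typed matrix or gene table from TSV
#'
#' @param path TSV file; first column holds row identifiers.
#' @param kind one of `"taxa"`, `"profiles"`, `"pangenome"` (numeric matrix)
#'   or `"genes"` (gene table with `feature_id`, `ko`, `taxon`, `length_bp`
#'   columns followed by one count column per sample).
#' @return numeric matrix, or a `gene_quant` object for `kind = "genes"`.
#' @export
read_matrix <- function(path, kind = c("taxa", "profiles", "pangenome", "genes")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty input file: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L) {
    stop("ragged rows in ", path, " (rows ",
         paste(which(nf != nf[1]), collapse = ", "), ")", call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path, call. = FALSE)
  if (kind == "genes") {
    need <- c("feature_id", "ko", "taxon", "length_bp")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0L) {
      stop("gene table missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(df$feature_id)) {
      stop("duplicate feature_id: ",
           paste(unique(df$feature_id[duplicated(df$feature_id)]), collapse = ", "),
           call. = FALSE)
    }
    counts <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
    rownames(counts) <- df$feature_id
    .check_matrix_cells(counts, path)
    return(structure(list(counts = counts, features = df[, need]),
                     class = "gene_quant"))
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate row identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  .check_matrix_cells(m, path)
  if (kind == "pangenome" && any(m > 1)) {
    stop("pangenome frequencies must lie in [0, 1]", call. = FALSE)
  }
  m
}

.check_matrix_cells <- function(m, path) {
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    stop("non-numeric cell in ", path, " at row ", bad[1, 1] + 1L,
         ", column ", bad[1, 2] + 1L, call. = FALSE)
  }
  if (any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("missing value in ", path, " at row ", bad[1, 1] + 1L,
         ", column ", bad[1, 2] + 1L, call. = FALSE)
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)
    stop("negative value in ", path, " at row ", rownames(m)[bad[1, 1]],
         ", column ", colnames(m)[bad[1, 2]], call. = FALSE)
  }
  invisible(m)
}

#' Write a matrix as TSV (row identifiers in the first column)
#'
#' @param m matrix with dimnames.
#' @param path output file.
#' @param id_name header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

write_gene_table <- function(genes, path) {
  df <- cbind(genes$features, as.data.frame(genes$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the synthetic-cohort settings with the analysis thresholds. A
#' single seed drives every stochastic stage; stage seeds are derived from
#' it by fixed offsets.
#'
#' @param sim a [simulation_config()]; its seed is overridden by `seed`.
#' @param presence_threshold pangenome presence threshold; default 0.5.
#' @param min_samples rare-feature detection threshold; default 5.
#' @param pseudocount log-transform pseudocount; default 1e-6.
#' @param k_range enterotype cluster numbers; default `2:6`.
#' @param n_restarts NMDS restarts; default 100.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            presence_threshold = 0.5,
                            min_samples = 5,
                            pseudocount = 1e-6,
                            k_range = 2:6,
                            n_restarts = 100,
                            seed = 1L) {
  stopifnot(presence_threshold > 0, presence_threshold <= 1,
            min_samples >= 0, pseudocount > 0, n_restarts >= 1)
  sim$seed <- as.integer(seed)
  validate_sim_config(sim)
  structure(list(sim = sim, presence_threshold = presence_threshold,
                 min_samples = min_samples, pseudocount = pseudocount,
                 k_range = as.integer(k_range),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# md5 of an object's canonical JSON serialization
.config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.file_md5 <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> classify -> quantify -> enterotype -> associate. All stage
#' outputs are written under `outdir` as plain text, and a manifest with the
#' configuration hash, per-stage output checksums and before/after filter
#' counts is returned and written as `manifest.json`. The manifest is
#' byte-identical across runs with the same config and seed.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_all <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (missing(outdir)) stop("outdir is required", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)

  # -- simulate ------------------------------------------------------------
  cohort <- simulate_cohort(config$sim)
  write_matrix(cohort$pangenome$schema_A, p("pangenome_schema_A.tsv"), "species_id")
  write_matrix(cohort$pangenome$schema_B, p("pangenome_schema_B.tsv"), "species_id")
  write_matrix(cohort$taxa, p("taxa.tsv"), "taxon")
  write_gene_table(cohort$genes, p("genes.tsv"))
  utils::write.table(cohort$metadata, p("metadata.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  write_json_report(list(
    species_category = as.list(cohort$truth$species_category),
    planted_folds = as.list(cohort$truth$planted_folds),
    arm = as.list(cohort$truth$arm),
    batch = as.list(cohort$truth$batch)
  ), p("truth.json"))

  # -- classify ------------------------------------------------------------
  merged <- merge_annotation_evidence(cohort$pangenome)
  calls <- classify_pangenome(cohort$pangenome, config$presence_threshold)
  calls_df <- data.frame(
    species_id = names(calls),
    encodes_lps = vapply(calls, function(s) s$encodes_lps, logical(1)),
    kdo2 = vapply(calls, function(s) s$kdo2, logical(1)),
    acylation = vapply(calls, function(s) s$acylation, character(1)),
    routes = vapply(calls, function(s) paste(s$hexa_routes, collapse = ","),
                    character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  utils::write.table(calls_df, p("structure_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  tallies <- tally_lps_categories(calls)
  write_json_report(tallies, p("tallies.json"))

  # -- quantify ------------------------------------------------------------
  raw <- cohort$genes$counts
  batches <- stats::setNames(cohort$metadata$study, cohort$metadata$sample_id)
  filtered <- filter_rare_features(raw, config$min_samples)
  feats <- cohort$genes$features[
    cohort$genes$features$feature_id %in% rownames(filtered), , drop = FALSE]
  cpm <- normalize_genes(filtered, batch = batches[colnames(filtered)])
  write_matrix(round(cpm, 6), p("gene_cpm.tsv"), "feature_id")
  cat_ab <- category_abundance(cohort$taxa, calls)
  write_matrix(cat_ab, p("category_abundance.tsv"), "sample_id")
  hp <- hexa_penta_ratio(cat_ab)
  utils::write.table(hp, p("hexa_penta_ratio.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")

  # -- enterotype ----------------------------------------------------------
  ko <- rowsum(filtered, feats$ko[match(rownames(filtered), feats$feature_id)])
  profiles <- t(ko) / colSums(ko)
  dj <- jsd_distance(profiles)
  fit <- select_k(dj, config$k_range)
  utils::write.table(
    data.frame(sample_id = names(fit$assignments),
               enterotype = unname(fit$assignments)),
    p("enterotypes.csv"), sep = ",", quote = FALSE, row.names = FALSE,
    eol = "\n")
  write_json_report(list(k = fit$k, ch_scores = as.list(fit$ch_scores)),
                    p("ch_scores.json"))

  # -- associate -----------------------------------------------------------
  nm <- nmds(dj, dims = 2, n_restarts = config$n_restarts,
             seed = config$seed)
  write_matrix(round(nm$coordinates, 8), p("nmds_coordinates.tsv"), "sample_id")
  suite <- run_association_suite(cpm, feats, cat_ab, cohort$metadata,
                                 enterotypes = fit, nmds_fit = nm)
  write_json_report(
    list(summary = suite$summary,
         nmds = list(stress = nm$stress, n_restarts = nm$n_restarts,
                     converged = nm$converged)),
    p("association_report.json"))

  # -- manifest ------------------------------------------------------------
  outputs <- c("pangenome_schema_A.tsv", "pangenome_schema_B.tsv", "taxa.tsv",
               "genes.tsv", "metadata.csv", "truth.json",
               "structure_calls.tsv", "tallies.json", "gene_cpm.tsv",
               "category_abundance.tsv", "hexa_penta_ratio.tsv",
               "enterotypes.csv", "ch_scores.json", "nmds_coordinates.tsv",
               "association_report.json")
  manifest <- list(
    config = unclass(config)[c("presence_threshold", "min_samples",
                               "pseudocount", "k_range", "n_restarts", "seed")],
    sim = unclass(config$sim),
    config_hash = .config_hash(c(unclass(config)[setdiff(names(config), "sim")],
                                 list(sim = unclass(config$sim)))),
    counts = list(
      n_species = nrow(cohort$taxa),
      n_samples = ncol(cohort$taxa),
      gene_features_before_filter = nrow(raw),
      gene_features_after_filter = nrow(filtered),
      undefined_hexa_penta_ratios = sum(!hp$defined),
      enterotype_k = fit$k
    ),
    checksums = as.list(.file_md5(file.path(outdir, outputs)))
  )
  write_json_report(manifest, p("manifest.json"))
  invisible(manifest)
}
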