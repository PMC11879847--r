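# Synthetic cohort generator: pangenome tables, taxonomic profiles and
# gene-level count matrices with planted, recoverable structure. Every
# generator is a pure function of (config, seed): the global RNG state is
# saved and restored around each draw.

#' Simulation configuration for the synthetic cohort
#'
#' Defaults describe a two-arm (responder / non-responder) immunotherapy
#' cohort spread over study batches. The LPS category mix follows the
#' observed split of gut bacterial species into non-producers and
#' tetra/penta/hexa-acylated producers; responders carry a two-fold
#' enrichment of hexa-acylating taxa (the hexa:penta ratio contrast) and
#' non-responders a modest enrichment of total LPS-encoding taxa.
#'
#' @param n_species number of bacterial species in the catalogue.
#' @param n_samples_per_arm samples per response arm.
#' @param n_batches number of study batches (cohorts).
#' @param category_mix named proportions over
#'   `c("non_lps","tetra","penta","hexa_lpxM","hexa_lpxJ")`; must sum to 1.
#' @param hexa_fold_responder multiplier on hexa-encoding taxa abundance in
#'   responders (> 0).
#' @param total_lps_fold_nonresponder multiplier on all LPS-encoding taxa in
#'   non-responders (> 0).
#' @param batch_sd SD of the per-(batch, species) log-multiplicative batch
#'   effect (>= 0).
#' @param dispersion overdispersion of taxa counts: Dirichlet-multinomial
#'   with total concentration `1/dispersion` (> 0; smaller is closer to
#'   multinomial).
#' @param depth reads per sample (>= 1).
#' @param n_background_kos number of non-LPS background gene families
#'   carried in the gene count table. Real functional profiles span the
#'   whole KEGG ortholog space, so LPS genes are a small share of each
#'   sample; without background features the per-million scaling would make
#'   total LPS abundance a constant.
#' @param annotation_flip_rate per-gene, per-channel probability that the
#'   emitted annotation evidence contradicts the planted gene content.
#' @param flip_lpxM_schema_A if `FALSE` (default) schema A evidence for
#'   `lpxM` is exempt from flips, mirroring a curated-channel annotation.
#' @param seed integer seed driving all generators.
#' @return object of class `sim_config` (validated list).
#' @export
simulation_config <- function(n_species = 150,
                              n_samples_per_arm = 50,
                              n_batches = 2,
                              category_mix = c(non_lps = 0.706, tetra = 0.036,
                                               penta = 0.179, hexa_lpxM = 0.042,
                                               hexa_lpxJ = 0.037),
                              hexa_fold_responder = 2,
                              total_lps_fold_nonresponder = 1.3,
                              batch_sd = 0.3,
                              dispersion = 0.005,
                              depth = 1e5,
                              n_background_kos = 30,
                              annotation_flip_rate = 0.02,
                              flip_lpxM_schema_A = FALSE,
                              seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              n_samples_per_arm = as.integer(n_samples_per_arm),
              n_batches = as.integer(n_batches),
              category_mix = category_mix,
              hexa_fold_responder = hexa_fold_responder,
              total_lps_fold_nonresponder = total_lps_fold_nonresponder,
              batch_sd = batch_sd,
              dispersion = dispersion,
              depth = depth,
              n_background_kos = as.integer(n_background_kos),
              annotation_flip_rate = annotation_flip_rate,
              flip_lpxM_schema_A = isTRUE(flip_lpxM_schema_A),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  mix <- cfg$category_mix
  if (is.null(names(mix)) || !setequal(names(mix), .lps_categories)) {
    stop("category_mix must be named over {",
         paste(.lps_categories, collapse = ", "), "}", call. = FALSE)
  }
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    stop("category_mix must be non-negative and sum to 1", call. = FALSE)
  }
  if (cfg$hexa_fold_responder <= 0 || cfg$total_lps_fold_nonresponder <= 0) {
    stop("fold parameters must be positive", call. = FALSE)
  }
  if (cfg$batch_sd < 0) stop("batch_sd must be non-negative", call. = FALSE)
  if (cfg$dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  if (cfg$depth < 1) stop("depth must be at least 1", call. = FALSE)
  if (cfg$annotation_flip_rate < 0 || cfg$annotation_flip_rate > 1) {
    stop("annotation_flip_rate must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_background_kos < 0) {
    stop("n_background_kos must be non-negative", call. = FALSE)
  }
  if (cfg$n_species < 1 || cfg$n_samples_per_arm < 1 || cfg$n_batches < 1) {
    stop("n_species, n_samples_per_arm and n_batches must be >= 1",
         call. = FALSE)
  }
  invisible(cfg)
}

# evaluate `expr` under a fixed seed without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed %% .Machine$integer.max)
  expr
}

# deterministic largest-remainder apportionment of n among proportions p
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# planted gene complements per LPS category
category_gene_sets <- function() {
  backbone <- c("lpxA", "lpxB", "lpxC", "lpxD", "lpxH", "lpxK", "waaA")
  list(
    non_lps = character(0),
    tetra = backbone,
    penta = c(backbone, "lpxL"),
    hexa_lpxM = c(backbone, "lpxL", "lpxM"),
    hexa_lpxJ = c(backbone, "lpxL", "lpxJ")
  )
}

#' Generate a pangenome table with planted LPS categories
#'
#' Each species is assigned an LPS category (largest-remainder apportionment
#' of `category_mix`, so planted tallies are exactly reproducible) and its
#' gene-frequency row is drawn so that thresholding at 0.5 recovers the
#' category: encoded genes get frequencies in `[0.6, 1]`, absent genes in
#' `[0, 0.4]`. Two evidence channels are emitted; each (species, gene) cell
#' flips its presence call independently per channel with probability
#' `annotation_flip_rate` (schema A `lpxM` exempt by default). Lipid A
#' modification genes (`lpxE`, `lpxF`, `pagL`, `pagP`) are sprinkled over
#' LPS-encoding species without affecting the category.
#'
#' @param config a [simulation_config()].
#' @return list with `pangenome` (two-channel table: list of `schema_A` and
#'   `schema_B` species x gene matrices) and `truth` (list with
#'   `species_category` and `planted_folds`).
#' @export
generate_pangenomes <- function(config) {
  validate_sim_config(config)
  with_local_seed(config$seed + 101L, {
    n <- config$n_species
    species <- sprintf("sp%03d", seq_len(n))
    counts <- apportion(n, config$category_mix[.lps_categories])
    cat_of <- rep(.lps_categories, counts)
    names(cat_of) <- species
    vocab <- lps_gene_vocabulary()
    sets <- category_gene_sets()
    mods <- c("lpxE", "lpxF", "pagL", "pagP")

    present <- matrix(FALSE, n, length(vocab), dimnames = list(species, vocab))
    for (i in seq_len(n)) {
      present[i, sets[[cat_of[i]]]] <- TRUE
      if (cat_of[i] != "non_lps") {
        present[i, mods] <- stats::runif(length(mods)) < 0.25
      }
    }

    draw_freq <- function(p) {
      ifelse(p, stats::runif(length(p), 0.6, 1.0),
             stats::runif(length(p), 0.0, 0.4))
    }
    channel <- function(exempt_lpxM) {
      flip <- matrix(stats::runif(n * length(vocab)) < config$annotation_flip_rate,
                     n, length(vocab), dimnames = dimnames(present))
      if (exempt_lpxM) flip[, "lpxM"] <- FALSE
      evid <- xor(present, flip)
      m <- matrix(draw_freq(as.vector(evid)), n, length(vocab),
                  dimnames = dimnames(present))
      m
    }
    pangenome <- list(
      schema_A = channel(exempt_lpxM = !config$flip_lpxM_schema_A),
      schema_B = channel(exempt_lpxM = FALSE)
    )
    truth <- list(
      species_category = cat_of,
      planted_folds = c(hexa_fold_responder = config$hexa_fold_responder,
                        total_lps_fold_nonresponder = config$total_lps_fold_nonresponder)
    )
    list(pangenome = pangenome, truth = truth)
  })
}

#' Generate per-sample taxonomic profiles with planted arm effects
#'
#' Base species abundances are log-normal (meanlog 0, sdlog 1), shared by all
#' samples; responders' hexa-encoding taxa are multiplied by
#' `hexa_fold_responder`, non-responders' LPS-encoding taxa by
#' `total_lps_fold_nonresponder`, and each (batch, species) pair carries a
#' `N(0, batch_sd^2)` log-additive effect. Counts are Dirichlet-multinomial
#' around the resulting per-sample expected composition with total
#' concentration `1/dispersion`.
#'
#' @param config a [simulation_config()].
#' @param truth the `truth` element returned by [generate_pangenomes()].
#' @return list with `taxa` (taxa x samples integer count matrix),
#'   `metadata` (data.frame `sample_id`, `response`, `study`) and `truth`
#'   extended with `arm`, `batch` and `batch_effects`.
#' @export
generate_taxa_profiles <- function(config, truth) {
  validate_sim_config(config)
  stopifnot(!is.null(truth$species_category))
  with_local_seed(config$seed + 202L, {
    cat_of <- truth$species_category
    species <- names(cat_of)
    n_sp <- length(species)
    n_arm <- config$n_samples_per_arm
    samples <- sprintf("S%03d", seq_len(2L * n_arm))
    arm <- rep(c("R", "NR"), each = n_arm)
    names(arm) <- samples
    # balanced batch assignment within each arm
    batch <- stats::ave(seq_along(samples), arm,
                        FUN = function(i) ((seq_along(i) - 1L) %% config$n_batches) + 1L)
    batch <- sprintf("study%d", batch)
    names(batch) <- samples

    base <- stats::rlnorm(n_sp, 0, 1)
    names(base) <- species
    is_hexa <- cat_of %in% c("hexa_lpxM", "hexa_lpxJ")
    is_lps <- cat_of != "non_lps"

    batches <- sprintf("study%d", seq_len(config$n_batches))
    be <- matrix(stats::rnorm(config$n_batches * n_sp, 0, config$batch_sd),
                 config$n_batches, n_sp, dimnames = list(batches, species))

    conc <- 1 / config$dispersion
    counts <- matrix(0L, n_sp, length(samples),
                     dimnames = list(species, samples))
    for (s in samples) {
      mu <- base
      if (arm[s] == "R") {
        mu[is_hexa] <- mu[is_hexa] * config$hexa_fold_responder
      } else {
        mu[is_lps] <- mu[is_lps] * config$total_lps_fold_nonresponder
      }
      mu <- mu * exp(be[batch[s], ])
      p <- mu / sum(mu)
      g <- stats::rgamma(n_sp, shape = p * conc, rate = 1)
      if (sum(g) == 0) g <- p  # numerically degenerate alpha; fall back
      counts[, s] <- stats::rmultinom(1, size = config$depth, prob = g / sum(g))
    }
    metadata <- data.frame(sample_id = samples,
                           response = arm,
                           study = batch,
                           stringsAsFactors = FALSE, row.names = NULL)
    truth$arm <- arm
    truth$batch <- batch
    truth$batch_effects <- be
    list(taxa = counts, metadata = metadata, truth = truth)
  })
}

#' Default gene lengths for the simulated catalogue
#'
#' Uniform on 600--3,000 bp, the typical bacterial ORF range, so the length
#' term of GCPM is exercised.
#'
#' @param genes character vector of gene names.
#' @param seed integer seed.
#' @return named integer vector of lengths (bp).
#' @export
default_gene_lengths <- function(genes = lps_gene_vocabulary(), seed = 1L) {
  with_local_seed(seed + 303L, {
    len <- as.integer(round(stats::runif(length(genes), 600, 3000)))
    names(len) <- genes
    len
  })
}

#' Generate a gene-level count table from taxa profiles and a pangenome
#'
#' Emulates ORF-level read quantification: the expected count of gene *g* in
#' taxon *t* in sample *s* is proportional to the taxon's read count, the
#' thresholded gene presence and the gene length; expectations are scaled to
#' `depth` reads per sample and realized as Poisson draws. One feature is
#' emitted per (taxon, present gene) pair, labelled with its gene (KO) and
#' taxon. `n_background_kos` non-LPS gene families (each present in a random
#' half of the taxa, lengths drawn from the same 600--3,000 bp range) are
#' added so that LPS genes occupy a realistic minority share of each
#' sample's per-million scale.
#'
#' @param taxa taxa x samples count matrix.
#' @param pangenome one- or two-channel pangenome table.
#' @param gene_lengths named vector of gene lengths (bp); every present gene
#'   must have a length.
#' @param config a [simulation_config()].
#' @return object of class `gene_quant`: list with `counts` (features x
#'   samples matrix) and `features` (data.frame `feature_id`, `ko`, `taxon`,
#'   `length_bp`).
#' @export
generate_gene_counts <- function(taxa, pangenome, gene_lengths, config) {
  validate_sim_config(config)
  merged <- merge_annotation_evidence(pangenome)
  common <- intersect(rownames(taxa), rownames(merged))
  if (length(common) == 0L) {
    stop("taxa and pangenome share no species identifiers", call. = FALSE)
  }
  presence <- merged[common, , drop = FALSE] >= 0.5
  idx <- which(presence, arr.ind = TRUE)
  feats <- data.frame(
    taxon = rownames(presence)[idx[, 1]],
    ko = colnames(presence)[idx[, 2]],
    stringsAsFactors = FALSE
  )
  feats <- feats[order(feats$taxon, feats$ko), , drop = FALSE]
  missing_len <- setdiff(unique(feats$ko), names(gene_lengths))
  if (length(missing_len) > 0L) {
    stop("missing gene length for: ", paste(missing_len, collapse = ", "),
         call. = FALSE)
  }
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive", call. = FALSE)
  feats$length_bp <- as.numeric(gene_lengths[feats$ko])

  with_local_seed(config$seed + 404L, {
    if (config$n_background_kos > 0) {
      bg_ko <- sprintf("bgK%03d", seq_len(config$n_background_kos))
      bg_len <- round(stats::runif(config$n_background_kos, 600, 3000))
      bg_pres <- matrix(stats::runif(length(common) * length(bg_ko)) < 0.5,
                        length(common), length(bg_ko),
                        dimnames = list(common, bg_ko))
      bidx <- which(bg_pres, arr.ind = TRUE)
      bg <- data.frame(taxon = common[bidx[, 1]], ko = bg_ko[bidx[, 2]],
                       length_bp = bg_len[bidx[, 2]],
                       stringsAsFactors = FALSE)
      feats <- rbind(feats, bg)
      feats <- feats[order(feats$taxon, feats$ko), , drop = FALSE]
    }
    feats$feature_id <- paste(feats$taxon, feats$ko, sep = "|")
    feats <- feats[, c("feature_id", "ko", "taxon", "length_bp")]
    rownames(feats) <- NULL
    w <- taxa[feats$taxon, , drop = FALSE] * feats$length_bp
    counts <- matrix(0L, nrow(feats), ncol(taxa),
                     dimnames = list(feats$feature_id, colnames(taxa)))
    for (s in seq_len(ncol(taxa))) {
      tot <- sum(w[, s])
      lam <- if (tot > 0) config$depth * w[, s] / tot else rep(0, nrow(feats))
      counts[, s] <- stats::rpois(nrow(feats), lam)
    }
    structure(list(counts = counts, features = feats), class = "gene_quant")
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs [generate_pangenomes()], [generate_taxa_profiles()] and
#' [generate_gene_counts()] in sequence.
#'
#' @param config a [simulation_config()].
#' @param gene_lengths optional named length vector; defaults to
#'   [default_gene_lengths()] seeded from the config.
#' @return list with `pangenome`, `taxa`, `genes`, `gene_lengths`,
#'   `metadata`, `truth`.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            gene_lengths = NULL) {
  pg <- generate_pangenomes(config)
  tp <- generate_taxa_profiles(config, pg$truth)
  if (is.null(gene_lengths)) {
    gene_lengths <- default_gene_lengths(seed = config$seed)
  }
  genes <- generate_gene_counts(tp$taxa, pg$pangenome, gene_lengths, config)
  list(pangenome = pg$pangenome, taxa = tp$taxa, genes = genes,
       gene_lengths = gene_lengths, metadata = tp$metadata, truth = tp$truth)
}

#' Planted functional clusters for enterotype validation
#'
#' Draws relative-abundance profiles from a Dirichlet mixture: cluster
#' centres are sparse Dirichlet(0.3) compositions and samples are
#' Dirichlet(centre x concentration) draws, giving well-separated clusters at
#' the default concentration.
#'
#' @param n_samples samples to draw.
#' @param n_features profile dimension.
#' @param k number of planted clusters.
#' @param concentration within-cluster Dirichlet concentration.
#' @param seed integer seed.
#' @return list with `profiles` (samples x features relative abundances) and
#'   `cluster` (integer vector of planted labels).
#' @export
generate_functional_clusters <- function(n_samples = 60, n_features = 40,
                                         k = 3, concentration = 100,
                                         seed = 1L) {
  with_local_seed(seed + 505L, {
    rdirich <- function(alpha) {
      g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
      g / sum(g)
    }
    centres <- t(vapply(seq_len(k),
                        function(i) rdirich(rep(0.3, n_features)),
                        numeric(n_features)))
    lab <- rep(seq_len(k), length.out = n_samples)
    prof <- t(vapply(lab, function(ci) {
      rdirich(centres[ci, ] * concentration + 1e-6)
    }, numeric(n_features)))
    rownames(prof) <- sprintf("S%03d", seq_len(n_samples))
    colnames(prof) <- sprintf("F%03d", seq_len(n_features))
    list(profiles = prof, cluster = lab)
  })
}
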