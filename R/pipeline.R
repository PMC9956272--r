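# End-to-end mining pipeline: profile -> scan -> loci -> clusters ->
# elements -> families -> trees -> summaries.

#' Pipeline configuration
#'
#' Collects every stage threshold with its default: seed-protein length
#' bounds 200/600 aa, 80% seed pre-clustering, 20% gap filter, 50-aa
#' minimum hit, 1700-nt flanks, 70% locus clustering, 90% family
#' clustering, 20-nt decay match, 1000 bootstrap replicates.
#'
#' @param thresholds a [curation_thresholds()] object.
#' @param flank locus flank in nt.
#' @param locus_cluster_identity,family_cluster_identity clustering
#'   thresholds.
#' @param decay_min_match decay-filter matched-length threshold (strict
#'   `>`, nt).
#' @param bootstrap_replicates bootstrap replicate count.
#' @param n_decoys,decoy_length,calibration_quantile threshold-calibration
#'   settings, see [calibrate_threshold()].
#' @param score_threshold fixed scan threshold in bits; `NULL` calibrates
#'   from the input genomes.
#' @param run_phylogeny build protein trees for the mined families.
#' @param boundary a [boundary_params()] object.
#' @param roles a [role_params()] object.
#' @param seed integer seed driving calibration and bootstrap.
#' @return list of class `tcme_config`.
#' @export
tcme_config <- function(thresholds = curation_thresholds(),
                        flank = 1700L,
                        locus_cluster_identity = 0.70,
                        family_cluster_identity = 0.90,
                        decay_min_match = 20L,
                        bootstrap_replicates = 1000L,
                        n_decoys = 200L,
                        decoy_length = 1500L,
                        calibration_quantile = 0.999,
                        score_threshold = NULL,
                        run_phylogeny = FALSE,
                        boundary = boundary_params(),
                        roles = role_params(),
                        seed = 1L) {
  structure(list(thresholds = thresholds, flank = flank,
                 locus_cluster_identity = locus_cluster_identity,
                 family_cluster_identity = family_cluster_identity,
                 decay_min_match = decay_min_match,
                 bootstrap_replicates = bootstrap_replicates,
                 n_decoys = n_decoys, decoy_length = decoy_length,
                 calibration_quantile = calibration_quantile,
                 score_threshold = score_threshold,
                 run_phylogeny = run_phylogeny,
                 boundary = boundary, roles = roles, seed = seed),
            class = "tcme_config")
}

#' Run the TCME mining pipeline
#'
#' Executes the full cascade on a set of genomes: RuvC profile
#' construction from seed proteins, threshold calibration on shuffled
#' decoys, six-frame scanning, locus extraction and 70% clustering,
#' element annotation and classification, decay filtering, 90% family
#' clustering with known/new naming, optional protein phylogenies, and the
#' per-species summary tables.  Deterministic for a fixed `config$seed`.
#'
#' @param genomes tibble with `genome_id`, `contig_id`, `species`,
#'   `sequence`.
#' @param seed_proteins tibble (`id`, `sequence`) of seed TnpB proteins;
#'   `NULL` uses [synthetic_ruvc_seed()] drawn from `config$seed`.
#' @param reference optional reference library from [tcme_reference()].
#' @param config a [tcme_config()] object.
#' @return list of class `tcme_result` with `profile`, `threshold`,
#'   `hits`, `loci`, `locus_clusters`, `elements`, `families`,
#'   `species_table`, `group_table`, `trees`, `census`, `config` and
#'   per-stage `log` counts.
#' @export
run_tcme_pipeline <- function(genomes, seed_proteins = NULL, reference = NULL,
                              config = tcme_config()) {
  stopifnot(inherits(config, "tcme_config"))
  genomes <- tibble::as_tibble(genomes)
  need <- c("genome_id", "contig_id", "species", "sequence")
  if (!all(need %in% names(genomes))) {
    stop(sprintf("genomes must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  log <- list()
  if (is.null(seed_proteins)) {
    seed_proteins <- synthetic_ruvc_seed(seed = derive_seed(config$seed, "seed"))
  }
  profile <- build_ruvc_profile(seed_proteins, config$thresholds)
  threshold <- config$score_threshold
  if (is.null(threshold)) {
    threshold <- calibrate_threshold(
      profile, genomes, n_decoys = config$n_decoys,
      decoy_length = config$decoy_length, q = config$calibration_quantile,
      seed = derive_seed(config$seed, "calibration"))
  }
  hits <- scan_genomes(genomes, profile, threshold,
                       min_hit_len = config$thresholds$min_hit_len)
  log$n_hits <- nrow(hits)
  loci <- extract_loci(hits, genomes, flank = config$flank)
  log$n_loci <- nrow(loci)
  census <- dplyr::distinct(genomes[, c("genome_id", "species")])

  # 70% locus clustering per species (representatives summarise diversity)
  locus_clusters <- NULL
  if (nrow(loci) > 0) {
    lsp <- dplyr::left_join(loci, census, by = "genome_id")
    locus_clusters <- purrr::map_dfr(sort(unique(lsp$species)), function(sp) {
      sub <- lsp[lsp$species == sp, ]
      # narrow band: planted divergence is substitution-only, so genuine
      # pairs stay near the diagonal; distant pairs can only score lower
      cl <- greedy_cluster(tibble::tibble(id = sub$locus_id,
                                          sequence = sub$sequence),
                           config$locus_cluster_identity, band = 50L)
      cl$species <- sp
      cl
    })
    log$n_locus_clusters <- dplyr::n_distinct(
      paste(locus_clusters$species, locus_clusters$cluster_id))
  }

  elements <- annotate_elements(
    loci, profile, threshold, reference,
    bparams = config$boundary, rparams = config$roles,
    decay_min_match = config$decay_min_match)
  log$n_elements <- nrow(elements)

  fam <- if (nrow(elements) > 0) {
    cluster_families(elements, census, reference,
                     threshold = config$family_cluster_identity)
  } else {
    list(families = tibble::tibble(), elements = elements)
  }
  elements <- fam$elements
  families <- fam$families
  log$n_families <- nrow(families)

  trees <- NULL
  if (isTRUE(config$run_phylogeny) && nrow(families) >= 4) {
    trees <- list()
    prot <- tibble::tibble(id = families$family_name,
                           sequence = vapply(families$member_ids, function(ids) {
                             elements$tnpb_protein[match(ids[1],
                                                         elements$element_id)]
                           }, character(1)))
    prot <- prot[!duplicated(prot$id), ]
    if (nrow(prot) >= 4) {
      aln <- center_star_msa(prot)
      trees$tnpb <- bootstrap_support(
        aln, B = config$bootstrap_replicates,
        seed = derive_seed(config$seed, "bootstrap"))
    }
  }

  species_table <- species_summary(elements, census, loci)
  group_table <- group_summary(elements, census)

  structure(list(profile = profile, threshold = threshold, hits = hits,
                 loci = loci[, setdiff(names(loci), "sequence")],
                 locus_clusters = locus_clusters,
                 elements = elements, families = families,
                 species_table = species_table, group_table = group_table,
                 trees = trees, census = census, config = config, log = log),
            class = "tcme_result")
}

#' @export
print.tcme_result <- function(x, ...) {
  cat("<tcme_result> ", nrow(x$elements), " elements in ",
      dplyr::n_distinct(x$elements$genome_id), " genomes (",
      nrow(x$families), " families); scan threshold ",
      sprintf("%.1f", x$threshold), " bits\n", sep = "")
  invisible(x)
}

#' @rdname run_tcme_pipeline
#' @param x a `tcme_result`.
#' @param ... unused.
#' @method tidy tcme_result
#' @export
tidy.tcme_result <- function(x, ...) {
  tibble::as_tibble(x$elements)
}

#' @rdname run_tcme_pipeline
#' @method glance tcme_result
#' @export
glance.tcme_result <- function(x, ...) {
  tibble::tibble(
    n_genomes = nrow(x$census),
    n_hits = nrow(x$hits),
    n_loci = nrow(x$loci),
    n_elements = nrow(x$elements),
    n_full = sum(x$elements$completeness == "full" & !x$elements$decay_flag),
    n_decay = sum(x$elements$decay_flag),
    n_families = nrow(x$families),
    threshold_bits = as.numeric(x$threshold)
  )
}
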