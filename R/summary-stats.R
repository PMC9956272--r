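# Per-species and per-subgroup invasion/copy-number summaries mirroring the
# standard TCME survey tables.

# attach the census species to an element table (replacing any existing
# species column) and default missing bookkeeping columns
join_species <- function(elements, census) {
  elements <- elements[, setdiff(names(elements), "species")]
  if (!"decay_flag" %in% names(elements)) elements$decay_flag <- FALSE
  dplyr::left_join(elements,
                   dplyr::distinct(census[, c("genome_id", "species")]),
                   by = "genome_id")
}

check_census <- function(elements, census) {
  census <- tibble::as_tibble(census)
  if (!all(c("genome_id", "species") %in% names(census))) {
    stop("census needs columns `genome_id` and `species`", call. = FALSE)
  }
  missing <- setdiff(unique(elements$genome_id), census$genome_id)
  if (length(missing) > 0) {
    stop(sprintf("genome ids absent from the census: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  census
}

#' Per-species TCME summary
#'
#' One row per census species: genome counts, detected loci and elements,
#' the percentage of genomes containing at least one element (integer,
#' half-up), the mean and sd of copies per TCME-positive genome (2
#' decimals), and the full-element count and percentage.
#'
#' @param elements element tibble (needs `genome_id`, `completeness`).
#' @param census tibble with `genome_id`, `species` (one row per genome).
#' @param loci optional locus tibble counted as `n_loci_detected`.
#' @return tibble with one row per species.
#' @export
species_summary <- function(elements, census, loci = NULL) {
  census <- check_census(elements, census)
  per_sp <- dplyr::group_by(census, .data$species)
  base <- dplyr::summarise(per_sp, n_genomes = dplyr::n_distinct(.data$genome_id))
  el <- join_species(elements, census)
  purrr::map_dfr(seq_len(nrow(base)), function(i) {
    sp <- base$species[i]
    n_gen <- base$n_genomes[i]
    sub <- el[el$species == sp, ]
    n_loci <- if (!is.null(loci)) {
      lsub <- join_species(loci, census)
      sum(lsub$species == sp)
    } else {
      NA_integer_
    }
    copies <- table(sub$genome_id)
    n_pos <- length(copies)
    n_full <- sum(sub$completeness == "full" & !sub$decay_flag)
    tibble::tibble(
      species = sp,
      n_genomes = n_gen,
      n_loci_detected = n_loci,
      n_tcmes = nrow(sub),
      n_genomes_with_tcme = n_pos,
      pct_genomes_with_tcme = round_half_up(100 * n_pos / n_gen),
      mean_copies = if (n_pos > 0) {
        round_half_up(nrow(sub) / n_pos, 2)
      } else NA_real_,
      sd_copies = if (n_pos > 1) round_half_up(sd(as.numeric(copies)), 2)
        else NA_real_,
      n_full = n_full,
      pct_full = if (nrow(sub) > 0) {
        round_half_up(100 * n_full / nrow(sub))
      } else NA_real_
    )
  })
}

#' Table-level summary arithmetic from integer counts
#'
#' Recomputes the derived columns of a per-species survey table from its
#' integer counts: percentage of genomes containing elements (integer,
#' half-up), mean copies per positive genome (2 decimals) and the
#' full-element percentage.
#'
#' @param counts tibble with columns `species`, `n_genomes`, `n_positive`,
#'   `n_copies`, `n_full`.
#' @return `counts` with `pct_genomes`, `mean_copies`, `pct_full` added.
#' @export
summarize_counts <- function(counts) {
  dplyr::mutate(tibble::as_tibble(counts),
    pct_genomes = round_half_up(100 * .data$n_positive / .data$n_genomes),
    mean_copies = round_half_up(.data$n_copies / .data$n_positive, 2),
    pct_full = round_half_up(100 * .data$n_full / .data$n_copies))
}

#' Per-subgroup genome counts and percentages
#'
#' For every species and subgroup, the number of genomes containing at
#' least one element of that subgroup and its percentage of the species'
#' census (2 decimals, half-up); plus group totals for IS605, IS607 and
#' IS1341 (a genome carrying several subgroups counts once in its group
#' total).  Decay-flagged elements are excluded.
#'
#' @param elements element tibble.
#' @param census genome census.
#' @return tibble with `species`, `label` (subgroup or `<group>_total`),
#'   `n_genomes_containing`, `pct`.
#' @export
group_summary <- function(elements, census) {
  census <- check_census(elements, census)
  el <- join_species(elements, census)
  el <- el[!el$decay_flag & el$subgroup %in% SUBGROUPS, ]
  base <- dplyr::summarise(dplyr::group_by(census, .data$species),
                           n_genomes = dplyr::n_distinct(.data$genome_id))
  groups <- c(IS605 = "^IS605", IS607 = "^IS607", IS1341 = "^IS1341")
  purrr::map_dfr(seq_len(nrow(base)), function(i) {
    sp <- base$species[i]
    n_gen <- base$n_genomes[i]
    sub <- el[el$species == sp, ]
    rows <- purrr::map_dfr(SUBGROUPS, function(sg) {
      ng <- dplyr::n_distinct(sub$genome_id[sub$subgroup == sg])
      tibble::tibble(species = sp, label = sg, n_genomes_containing = ng,
                     pct = round_half_up(100 * ng / n_gen, 2))
    })
    tots <- purrr::map_dfr(names(groups), function(g) {
      ng <- dplyr::n_distinct(sub$genome_id[grepl(groups[[g]], sub$subgroup)])
      tibble::tibble(species = sp, label = paste0(g, "_total"),
                     n_genomes_containing = ng,
                     pct = round_half_up(100 * ng / n_gen, 2))
    })
    dplyr::bind_rows(rows, tots)
  })
}

#' Count genomes co-invaded by several element groups
#'
#' @param elements element tibble.
#' @param census genome census.
#' @param groups character vector of group labels (subset of IS605, IS607,
#'   IS1341).
#' @return tibble with `species`, `n_coinvaded`: genomes containing at
#'   least one element of every listed group.
#' @export
coinvasion_counts <- function(elements, census, groups) {
  if (length(groups) == 0) stop("groups must be nonempty", call. = FALSE)
  bad <- setdiff(groups, c("IS605", "IS607", "IS1341"))
  if (length(bad) > 0) {
    stop(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  census <- check_census(elements, census)
  el <- join_species(elements, census)
  if (!"group" %in% names(el)) {
    el$group <- sub("[abc]$", "", el$subgroup)
  }
  el <- el[!el$decay_flag & el$group %in% c("IS605", "IS607", "IS1341"), ]
  base <- dplyr::distinct(census[, c("species", "genome_id")])
  per_genome <- dplyr::summarise(
    dplyr::group_by(el, .data$species, .data$genome_id),
    has_all = all(groups %in% .data$group), .groups = "drop")
  res <- dplyr::summarise(dplyr::group_by(per_genome, .data$species),
                          n_coinvaded = sum(.data$has_all), .groups = "drop")
  out <- dplyr::left_join(
    dplyr::summarise(dplyr::group_by(base, .data$species), .groups = "drop"),
    res, by = "species")
  out$n_coinvaded[is.na(out$n_coinvaded)] <- 0L
  out
}

#' Pairwise identity statistics per protein class
#'
#' Scores all unordered pairs within each class with
#' [pairwise_identity()] and reports mean, population sd, min and max as
#' percentages.
#'
#' @param proteins tibble with columns `class`, `id`, `sequence`.
#' @return tibble with one row per class (`NA` row for classes with fewer
#'   than 2 proteins).
#' @export
identity_stats <- function(proteins) {
  purrr::map_dfr(sort(unique(proteins$class)), function(cl) {
    sub <- proteins[proteins$class == cl, ]
    n <- nrow(sub)
    if (n < 2) {
      return(tibble::tibble(class = cl, n = n, mean = NA_real_, sd = NA_real_,
                            min = NA_real_, max = NA_real_))
    }
    ids <- numeric(0)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ids <- c(ids, pairwise_identity(sub$sequence[i], sub$sequence[j]))
      }
    }
    ids <- 100 * ids
    pop_sd <- sqrt(mean((ids - mean(ids))^2))
    tibble::tibble(class = cl, n = n, mean = mean(ids), sd = pop_sd,
                   min = min(ids), max = max(ids))
  })
}

#' Published six-species survey counts
#'
#' Integer counts from a published survey of TnpB-containing mobile
#' elements across six bacterial species, bundled as plain text: per
#' species the number of genomes surveyed, genomes containing elements,
#' total element copies and full-element copies, plus per-subgroup
#' positive-genome counts.  These are the inputs for validating the
#' summary-table arithmetic ([summarize_counts()], percentage rounding).
#'
#' @return list with tibbles `species` (columns `species`, `n_genomes`,
#'   `n_positive`, `n_copies`, `n_full`) and `group` (columns `species`,
#'   `n_genomes`, `label`, `n_positive`).
#' @export
survey_counts <- function() {
  rd <- function(f) {
    tibble::as_tibble(read.table(
      system.file("extdata", f, package = "tcmescan"),
      header = TRUE, sep = "\t", stringsAsFactors = FALSE))
  }
  list(species = rd("species_counts.tsv"), group = rd("group_counts.tsv"))
}
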