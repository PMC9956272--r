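# Locus-level annotation wrapper and the element family stage.

#' Build a reference element library from templates
#'
#' Packages template sequences, ORFA/ORFB proteins, ORFA coding sequences
#' and cleavage tetramers in the layout expected by [annotate_elements()]
#' and [assign_family()]; the role played by ISfinder-style libraries in a
#' real mining run.
#'
#' @param templates template tibble from [tcme_templates()].
#' @param names optional reference element names (default: template ids).
#' @return list with `elements`, `orfA` (proteins), `orfA_cds`
#'   (nucleotide), `tnpb` (proteins) and `tetramers`.
#' @export
tcme_reference <- function(templates, names = NULL) {
  if (is.null(names)) names <- templates$template_id
  orfA_cds <- character(0)
  orfA <- list()
  for (i in seq_len(nrow(templates))) {
    f <- templates$features[[i]]
    a <- f[f$feature == "orfA", ]
    if (nrow(a) == 1) {
      cds <- substr(templates$sequence[i], a$start + 1, a$end)
      if (a$strand == "-") cds <- revcomp(cds)
      orfA_cds <- c(orfA_cds, cds)
      orfA[[length(orfA) + 1]] <- tibble::tibble(
        id = templates$template_id[i],
        role = if (grepl("^IS607", templates$subgroup[i])) "SR" else "Y1",
        sequence = templates$orfA_protein[i])
    }
  }
  list(
    elements = tibble::tibble(
      name = names, subgroup = templates$subgroup, group = templates$group,
      sequence = templates$sequence,
      le_tetramer = templates$le_tetramer,
      re_tetramer = templates$re_tetramer),
    orfA = dplyr::bind_rows(orfA),
    orfA_cds = orfA_cds,
    tnpb = tibble::tibble(id = templates$template_id,
                          sequence = templates$tnpb_protein),
    tetramers = unique(c(templates$le_tetramer, templates$re_tetramer))
  )
}

# canonical cleavage motifs reported across IS605-group elements
CANONICAL_TETRAMERS <- c("TTAT", "TCAA", "TTCA")

#' Annotate loci into classified elements
#'
#' For every locus: orients the sequence by the seeding hit strand,
#' predicts ORFs, identifies the TnpB ORF covering the hit, attaches the
#' nearest Y1/SR partner ORF within `max_partner_gap` nt, detects LE/RE
#' boundaries (direct-repeat mode when the partner is a serine
#' recombinase), calls completeness and subgroup, applies the IS1341 decay
#' filter, and drops doubly-truncated candidates whose TnpB shows no
#' homology to the reference ORFB set.  Loci without a TnpB ORF are
#' discarded.
#'
#' @param loci locus tibble from [extract_loci()].
#' @param profile a `ruvc_profile`.
#' @param threshold TnpB score threshold in bits.
#' @param reference optional reference library from [tcme_reference()].
#' @param bparams a [boundary_params()] object.
#' @param rparams a [role_params()] object.
#' @param known_tetramers accepted cleavage tetramers for completeness
#'   (default: canonical motifs plus any reference tetramers).
#' @param max_partner_gap maximum nt between TnpB and its partner ORF.
#' @param decay_min_match,decay_min_identity decay-filter thresholds.
#' @param min_tnpb_ref_identity retention threshold for doubly-truncated
#'   elements when a reference is available.
#' @return element tibble; coordinates are 0-based half-open on the forward
#'   strand of the contig, `sequence` is the element-strand sequence.
#' @export
annotate_elements <- function(loci, profile, threshold, reference = NULL,
                              bparams = boundary_params(),
                              rparams = role_params(),
                              known_tetramers = NULL,
                              max_partner_gap = 300L,
                              decay_min_match = 20L,
                              decay_min_identity = 0.8,
                              min_tnpb_ref_identity = 0.4) {
  if (is.null(known_tetramers)) {
    known_tetramers <- unique(c(CANONICAL_TETRAMERS,
                                if (!is.null(reference)) reference$tetramers))
  }
  ref_orfA <- if (!is.null(reference)) reference$orfA else NULL
  rows <- vector("list", nrow(loci))
  for (li in seq_len(nrow(loci))) {
    lc <- loci[li, ]
    rows[[li]] <- annotate_one_locus(lc, profile, threshold, ref_orfA,
                                     reference, bparams, rparams,
                                     known_tetramers, max_partner_gap,
                                     decay_min_match, decay_min_identity,
                                     min_tnpb_ref_identity)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  # two hits on one element yield identical intervals: keep the best score
  out <- dplyr::slice_max(
    dplyr::group_by(out, .data$genome_id, .data$contig_id, .data$start,
                    .data$end),
    order_by = .data$score, n = 1, with_ties = FALSE)
  out <- dplyr::ungroup(out)
  out <- dplyr::arrange(out, .data$genome_id, .data$contig_id, .data$start)
  out$element_id <- sprintf("E%05d", seq_len(nrow(out)))
  dplyr::relocate(out, "element_id")
}

annotate_one_locus <- function(lc, profile, threshold, ref_orfA, reference,
                               bparams, rparams, known_tetramers,
                               max_partner_gap, decay_min_match,
                               decay_min_identity, min_tnpb_ref_identity) {
  L <- lc$end - lc$start
  minus <- lc$strand == "-"
  oseq <- if (minus) revcomp(lc$sequence) else lc$sequence
  # hit interval in oriented locus coordinates
  hs <- lc$hit_start - lc$start
  he <- lc$hit_end - lc$start
  if (minus) {
    tmp <- hs
    hs <- L - he
    he <- L - tmp
  }
  orfs <- find_orfs(oseq, min_len = 50L)
  if (nrow(orfs) == 0) return(NULL)
  # TnpB ORF: plus-strand ORF covering the hit with the best profile score
  cand <- orfs[orfs$strand == "+" & orfs$start < he & orfs$end > hs, ]
  if (nrow(cand) == 0) return(NULL)
  scs <- vapply(cand$protein, protein_profile_score, numeric(1),
                profile = profile)
  best <- which(scs >= threshold)
  if (length(best) == 0) return(NULL)
  best <- best[order(-scs[best], cand$start[best])][1]
  tnpb <- cand[best, ]
  tnpb$role <- "TnpB"
  # partner: nearest role-assigned Y1/SR ORF within max_partner_gap
  others <- orfs[!(orfs$start == tnpb$start & orfs$end == tnpb$end &
                     orfs$strand == tnpb$strand), ]
  if (nrow(others) > 0) {
    gap <- pmax(others$start - tnpb$end, tnpb$start - others$end, 0L)
    keep <- gap <= max_partner_gap
    if (is.null(ref_orfA) || nrow(ref_orfA) == 0) {
      # without a reference, roles rest on motifs alone, so reading-frame
      # shadow ORFs inside TnpB must be excluded structurally; with a
      # reference, homology separates them (and a genuine ORFA can be
      # covered by an upstream-extended TnpB ORF prediction)
      ov <- pmax(0L, pmin(others$end, tnpb$end) -
                   pmax(others$start, tnpb$start))
      keep <- keep & ov <= 0.5 * (others$end - others$start)
    }
    others <- others[keep, ]
  }
  partner <- NULL
  if (nrow(others) > 0) {
    others <- others[order(pmax(others$start - tnpb$end,
                                tnpb$start - others$end, 0L)), ]
    for (k in seq_len(nrow(others))) {
      rl <- assign_role(others$protein[k], profile, threshold, ref_orfA,
                        rparams)
      if (rl$role %in% c("Y1", "SR")) {
        partner <- others[k, ]
        partner$role <- rl$role
        break
      }
    }
  }
  orfset <- dplyr::bind_rows(tnpb, partner)
  subgroup <- classify_subgroup(orfset)
  mode <- if (!is.null(partner) && partner$role == "SR") "direct" else "inverted"
  orf_lo <- min(orfset$start)
  orf_hi <- max(orfset$end)
  # a window truncated by the contig edge reports the side absent
  le_open <- (orf_lo - bparams$window < 0) &&
    (if (minus) lc$clipped_end else lc$clipped_start)
  re_open <- (orf_hi + bparams$window > L) &&
    (if (minus) lc$clipped_start else lc$clipped_end)
  bd <- detect_boundaries(oseq, orf_lo, orf_hi, mode, bparams,
                          le_open = le_open, re_open = re_open,
                          prefer_tetramers = known_tetramers)
  completeness <- call_completeness(bd$le, bd$re, known_tetramers)
  el_s <- if (!is.null(bd$le)) bd$le$tetramer_start else orf_lo
  el_e <- if (!is.null(bd$re)) bd$re$tetramer_start + 4L else orf_hi
  # decay filter for TnpB-only candidates
  decay <- FALSE
  if (subgroup == "IS1341" && !is.null(reference) &&
      length(reference$orfA_cds) > 0) {
    up_s <- if (!is.null(bd$le)) bd$le$end else max(0L, tnpb$start - 60L)
    dn_e <- if (!is.null(bd$re)) bd$re$start else min(L, tnpb$end + 60L)
    upstream <- if (tnpb$start > up_s) {
      substr(oseq, up_s + 1, tnpb$start)
    } else NA_character_
    downstream <- if (dn_e > tnpb$end) {
      substr(oseq, tnpb$end + 1, dn_e)
    } else NA_character_
    decay <- decay_filter(upstream, downstream, reference$orfA_cds,
                          decay_min_match, decay_min_identity)
  }
  # doubly-truncated candidates need ORFB homology to be retained
  if (completeness == "truncated_both" && !decay && !is.null(reference) &&
      nrow(reference$tnpb) > 0) {
    ids <- vapply(reference$tnpb$sequence, function(rs) {
      pairwise_identity(tnpb$protein, rs, band = 50L)
    }, numeric(1))
    if (max(ids) < min_tnpb_ref_identity) return(NULL)
  }
  group <- if (decay) "decay" else if (subgroup == "unclassified") {
    "unclassified"
  } else if (grepl("^IS605", subgroup)) "IS605" else if (
    grepl("^IS607", subgroup)) "IS607" else "IS1341"
  # map the element interval back to forward-strand contig coordinates
  if (minus) {
    f_s <- lc$start + (L - el_e)
    f_e <- lc$start + (L - el_s)
  } else {
    f_s <- lc$start + el_s
    f_e <- lc$start + el_e
  }
  tibble::tibble(
    locus_id = lc$locus_id, genome_id = lc$genome_id,
    contig_id = lc$contig_id,
    start = f_s, end = f_e, strand = lc$strand, length = f_e - f_s,
    group = group, subgroup = subgroup, completeness = completeness,
    decay_flag = decay, score = lc$score,
    tnpb_protein = tnpb$protein,
    orfA_protein = if (!is.null(partner)) partner$protein else NA_character_,
    orfA_role = if (!is.null(partner)) partner$role else NA_character_,
    le_present = !is.null(bd$le), re_present = !is.null(bd$re),
    le_tetramer = if (!is.null(bd$le)) bd$le$tetramer else NA_character_,
    re_tetramer = if (!is.null(bd$re)) bd$re$tetramer else NA_character_,
    le_stem = if (!is.null(bd$le)) bd$le$stem_len else NA_integer_,
    re_stem = if (!is.null(bd$re)) bd$re$stem_len else NA_integer_,
    repeat_kind = if (!is.null(bd$le)) bd$le$repeat_kind else if (
      !is.null(bd$re)) bd$re$repeat_kind else NA_character_,
    sequence = substr(oseq, el_s + 1, el_e)
  )
}

#' Cluster full elements into families and name them
#'
#' Per species, clusters the element-strand sequences of full elements at
#' the family identity threshold, derives a majority consensus per cluster
#' (from up to `max_msa` members), and assigns known/new family names
#' against the reference library.
#'
#' @param elements element tibble from [annotate_elements()].
#' @param census genome census tibble with `genome_id`, `species`.
#' @param reference optional library from [tcme_reference()].
#' @param threshold family identity threshold.
#' @param max_msa members used for the consensus alignment.
#' @return list with `families` (one row per family, with consensus and
#'   name) and `elements` (input with a `family_name` column; non-full
#'   elements get `NA`).
#' @export
cluster_families <- function(elements, census, reference = NULL,
                             threshold = 0.90, max_msa = 12L) {
  elements <- dplyr::left_join(
    elements, dplyr::distinct(census[, c("genome_id", "species")]),
    by = "genome_id")
  full <- elements[elements$completeness == "full" & !elements$decay_flag, ]
  fam_rows <- list()
  elements$family_name <- NA_character_
  for (sp in sort(unique(full$species))) {
    sub <- full[full$species == sp, ]
    cl <- greedy_cluster(
      tibble::tibble(id = sub$element_id, sequence = sub$sequence),
      threshold, band = 50L)
    for (ci in sort(unique(cl$cluster_id))) {
      mem_ids <- cl$member_id[cl$cluster_id == ci]
      mem <- sub[match(mem_ids, sub$element_id), ]
      pick <- mem[order(-nchar(mem$sequence), mem$element_id), ]
      pick <- utils::head(pick, max_msa)
      cons <- if (nrow(pick) >= 2) {
        consensus(center_star_msa(
          tibble::tibble(id = pick$element_id, sequence = pick$sequence)))$sequence
      } else {
        pick$sequence[1]
      }
      tet <- function(x) {
        x <- x[!is.na(x)]
        if (length(x) == 0) return(NA_character_)
        tab <- table(x)
        sort(names(tab)[tab == max(tab)])[1]
      }
      fam_rows[[length(fam_rows) + 1]] <- tibble::tibble(
        species = sp,
        family_id = sprintf("%s|%s", sp, cl$representative_id[cl$cluster_id == ci][1]),
        sequence = cons,
        le_tetramer = tet(mem$le_tetramer),
        re_tetramer = tet(mem$re_tetramer),
        boundaries_ok = all(mem$le_present & mem$re_present),
        n_members = nrow(mem),
        member_ids = list(mem_ids),
        subgroup = names(sort(table(mem$subgroup), decreasing = TRUE))[1]
      )
    }
  }
  if (length(fam_rows) == 0) {
    return(list(families = tibble::tibble(), elements = elements))
  }
  fams <- dplyr::bind_rows(fam_rows)
  fams <- assign_family(fams, if (!is.null(reference)) reference$elements,
                        identity = threshold)
  for (i in seq_len(nrow(fams))) {
    elements$family_name[elements$element_id %in% fams$member_ids[[i]]] <-
      fams$family_name[i]
  }
  list(families = fams, elements = elements)
}
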