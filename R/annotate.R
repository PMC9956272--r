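# From TnpB hits to classified elements: locus extraction, ORF prediction,
# role assignment, LE/RE boundary detection, completeness and subgroup
# calls, the IS1341 decay filter and family naming.

#' Boundary-detection parameters
#'
#' Subterminal repeats are searched in windows of up to `window` nt outside
#' the outermost ORF ends.  Inverted repeats (IS605/IS1341 palindromic
#' ends): arms of at least `min_arm` nt around a loop of `loop_range` nt
#' with at most `max_mismatch` internal mismatches (mismatched terminal arm
#' pairs are trimmed); the best call is the longest stem, ties resolved
#' towards the ORF.  Direct repeats (IS607 ends): units of `dr_unit_range`
#' nt occurring at least `dr_min_occ` times (each within `dr_max_mismatch`
#' of the seed unit) inside a `dr_window`-nt span.  The cleavage tetramer is
#' read immediately outside the accepted repeat on the element-external
#' side.
#'
#' @param window search window in nt outside the outermost ORF ends.
#' @param overhang nt by which the window reaches inside the ORF span:
#'   predicted ORF starts can over-extend past the true CDS (a spurious
#'   upstream start codon), which would otherwise hide a genuine
#'   subterminal repeat inside the "coding" span.
#' @param min_arm minimum palindrome arm length (nt).
#' @param loop_range allowed loop lengths (nt).
#' @param max_mismatch tolerated mismatches within arms of `min_arm` nt;
#'   arms of at least `strong_arm` nt tolerate `strong_max_mismatch`.
#' @param strong_arm,strong_max_mismatch relaxed mismatch allowance for
#'   long stems (long arms carry enough signal to absorb substitutions
#'   without inflating chance hits).
#' @param dr_unit_range direct-repeat unit lengths (nt).
#' @param dr_min_occ minimum direct-repeat occurrences.
#' @param dr_max_mismatch tolerated mismatches per occurrence.
#' @param dr_total_mismatch total mismatch budget across occurrences.
#' @param dr_window span containing all occurrences (nt).
#' @return a list of class `boundary_params`.
#' @export
boundary_params <- function(window = 250L, overhang = 120L, min_arm = 8L,
                            loop_range = c(3L, 15L), max_mismatch = 1L,
                            strong_arm = 12L, strong_max_mismatch = 2L,
                            dr_unit_range = c(8L, 12L), dr_min_occ = 3L,
                            dr_max_mismatch = 1L, dr_total_mismatch = 2L,
                            dr_window = 60L) {
  structure(list(window = window, overhang = overhang,
                 min_arm = min_arm, loop_range = loop_range,
                 max_mismatch = max_mismatch, strong_arm = strong_arm,
                 strong_max_mismatch = strong_max_mismatch,
                 dr_unit_range = dr_unit_range,
                 dr_min_occ = dr_min_occ, dr_max_mismatch = dr_max_mismatch,
                 dr_total_mismatch = dr_total_mismatch,
                 dr_window = dr_window),
            class = "boundary_params")
}

# admissible palindrome candidates: short arms must be near-perfect, long
# arms may absorb one more substitution
filter_palindromes <- function(pal, params) {
  keep <- (pal[, "arm"] >= params$min_arm &
             pal[, "mismatches"] <= params$max_mismatch) |
    (pal[, "arm"] >= params$strong_arm &
       pal[, "mismatches"] <= params$strong_max_mismatch)
  pal[keep, , drop = FALSE]
}

#' ORF role-assignment parameters
#'
#' Length priors (aa) for the three protein classes, the tolerance added on
#' both sides, and the identity threshold of the homology fallback used
#' when a diverged protein no longer shows its signature motif.
#'
#' @param tnpb_len,y1_len,sr_len length ranges in aa.
#' @param len_tol slack added to both ends of each range.
#' @param homology_identity minimum identity to a reference protein for the
#'   homology fallback.
#' @return a list of class `role_params`.
#' @export
role_params <- function(tnpb_len = c(340L, 489L), y1_len = c(102L, 164L),
                        sr_len = c(150L, 217L), len_tol = 30L,
                        homology_identity = 0.5) {
  structure(list(tnpb_len = tnpb_len, y1_len = y1_len, sr_len = sr_len,
                 len_tol = len_tol, homology_identity = homology_identity),
            class = "role_params")
}

#' Extract candidate loci around TnpB hits
#'
#' Extends every hit by `flank` nt on both sides, clipped to the contig.
#'
#' @param hits hit tibble from [scan_genomes()].
#' @param genomes tibble with `genome_id`, `contig_id`, `sequence`.
#' @param flank flank extension in nt.
#' @return tibble with `locus_id`, hit fields, `start`, `end` (0-based
#'   half-open locus interval), `clipped_start`/`clipped_end` flags and
#'   `sequence`.
#' @export
extract_loci <- function(hits, genomes, flank = 1700L) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(locus_id = character(0)))
  }
  gmap <- setNames(genomes$sequence, paste(genomes$genome_id, genomes$contig_id))
  purrr::pmap_dfr(hits, function(...) {
    h <- list(...)
    key <- paste(h$genome_id, h$contig_id)
    contig <- gmap[[key]]
    if (is.null(contig)) stop(sprintf("hit references unknown contig %s", key))
    L <- nchar(contig)
    s <- max(0L, h$genomic_start - flank)
    e <- min(L, h$genomic_end + flank)
    tibble::tibble(
      locus_id = sprintf("%s:%s:%d-%d", h$genome_id, h$contig_id, s, e),
      genome_id = h$genome_id, contig_id = h$contig_id,
      hit_start = h$genomic_start, hit_end = h$genomic_end,
      strand = h$strand, score = h$score,
      start = s, end = e,
      clipped_start = s == 0L && h$genomic_start - flank < 0L,
      clipped_end = e == L && h$genomic_end + flank > L,
      contig_length = L,
      sequence = substr(contig, s + 1, e)
    )
  })
}

#' Predict ORFs in a sequence
#'
#' Reports all maximal ORFs on both strands with an ATG/GTG/TTG start, an
#' in-frame stop, and at least `min_len` sense codons.  Within one
#' stop-to-stop frame segment only the longest start-to-stop ORF (earliest
#' start) is reported.
#'
#' @param sequence a DNA string.
#' @param min_len minimum ORF length in codons (start included, stop not).
#' @return tibble with `start`, `end` (0-based half-open, forward strand,
#'   stop codon included), `strand`, `frame`, `length_aa`, `protein`.
#' @export
find_orfs <- function(sequence, min_len = 50L) {
  L <- nchar(sequence)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") toupper(sequence) else revcomp(sequence)
    for (off in 0:2) {
      ncod <- (L - off) %/% 3
      if (ncod < min_len + 1) next
      cods <- substring(s, off + 3 * seq_len(ncod) - 2, off + 3 * seq_len(ncod))
      is_stop <- cods %in% c("TAA", "TAG", "TGA")
      is_start <- cods %in% START_CODONS
      stops <- which(is_stop)
      prev <- 0L
      for (st in stops) {
        if (st - prev - 1 >= min_len) {
          rng <- (prev + 1):(st - 1)
          cand <- rng[is_start[rng]]
          if (length(cand) > 0) {
            a <- cand[1]
            if (st - a >= min_len) {
              # codon interval [a, st] on this strand, 0-based nt
              nt_s <- off + 3 * (a - 1)
              nt_e <- off + 3 * st
              if (strand == "-") {
                tmp <- nt_s
                nt_s <- L - nt_e
                nt_e <- L - tmp
              }
              out[[length(out) + 1]] <- tibble::tibble(
                start = nt_s, end = nt_e, strand = strand,
                frame = if (strand == "+") off + 1L else -(off + 1L),
                length_aa = st - a,
                protein = paste0(GENETIC_CODE_11[cods[a:(st - 1)]], collapse = ""))
            }
          }
        }
        prev <- st
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          strand = character(0), frame = integer(0),
                          length_aa = integer(0), protein = character(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$strand)
}

in_range_tol <- function(len, range, tol) {
  len >= range[1] - tol && len <= range[2] + tol
}

# best local profile score of one protein, in bits
protein_profile_score <- function(protein, profile) {
  h <- cpp_pssm_scan(aa_to_int(protein), profile$scores * 2,
                     profile$gap_open, profile$gap_extend, -Inf, 1L)
  if (nrow(h) == 0) 0 else max(h[, "score"]) / 2
}

#' Assign a functional role to an ORF product
#'
#' TnpB: local RuvC-profile score at or above `threshold` and length inside
#' the TnpB prior (widened by the tolerance).  Y1 transposase: length in the
#' Y1 prior and an H-x-H triad followed by a downstream Y and then Q.
#' Serine recombinase: length in the SR prior with a serine in the central
#' third.  When a reference protein set is supplied, Y1/SR calls
#' additionally require homology to a reference protein of that role
#' (semi-global identity at or above `homology_identity`) — the motif rules
#' alone are too permissive on incidental ORFs, and homology also rescues
#' diverged copies whose signature residues are eroded; this mirrors
#' classifying candidates against a curated library.  At most one role is
#' returned; precedence TnpB > Y1 > SR.
#'
#' @param protein amino-acid string.
#' @param profile a `ruvc_profile`.
#' @param threshold TnpB score threshold in bits.
#' @param reference optional tibble with columns `role` (`"Y1"`/`"SR"`) and
#'   `sequence` of reference ORFA proteins.
#' @param params a [role_params()] object.
#' @return list with `role` (`"TnpB"`, `"Y1"`, `"SR"` or `"unknown"`) and
#'   `evidence`.
#' @export
assign_role <- function(protein, profile, threshold, reference = NULL,
                        params = role_params()) {
  len <- nchar(protein)
  tol <- params$len_tol
  if (in_range_tol(len, params$tnpb_len, tol)) {
    sc <- protein_profile_score(protein, profile)
    if (sc >= threshold) {
      return(list(role = "TnpB", evidence = sprintf("ruvc_profile:%.1f", sc)))
    }
  }
  has_ref <- !is.null(reference) && nrow(reference) > 0
  homology <- function(role) {
    refs <- reference[reference$role == role, ]
    for (rs in refs$sequence) {
      if (pairwise_identity(protein, rs) >= params$homology_identity) {
        return(TRUE)
      }
    }
    FALSE
  }
  y1_motif <- grepl("H.H.*Y.*Q", protein)
  if (in_range_tol(len, params$y1_len, tol)) {
    if (has_ref) {
      if (homology("Y1")) {
        return(list(role = "Y1",
                    evidence = if (y1_motif) "HuH-Y-Q motif + homology"
                               else "homology:Y1"))
      }
    } else if (y1_motif) {
      return(list(role = "Y1", evidence = "HuH-Y-Q motif"))
    }
  }
  if (in_range_tol(len, params$sr_len, tol)) {
    third <- substr(protein, floor(len / 3) + 1, ceiling(2 * len / 3))
    sr_motif <- grepl("S", third, fixed = TRUE)
    if (has_ref) {
      if (homology("SR")) {
        return(list(role = "SR",
                    evidence = if (sr_motif) "central serine + homology"
                               else "homology:SR"))
      }
    } else if (sr_motif) {
      return(list(role = "SR", evidence = "central catalytic serine"))
    }
  }
  list(role = "unknown", evidence = "")
}

# choose best palindrome: a candidate whose external tetramer matches a
# known cleavage motif outranks everything (the cleavage site anchors the
# boundary), then longest arm, then closest to the ORF
pick_palindrome <- function(pal, side, tet_match) {
  if (nrow(pal) == 0) return(NULL)
  ord <- if (side == "LE") {
    order(-tet_match, -pal[, "arm"], -pal[, "start"])
  } else {
    order(-tet_match, -pal[, "arm"], pal[, "start"])
  }
  pal[ord[1], , drop = FALSE]
}

pick_direct_repeat <- function(dr, side, tet_match) {
  if (nrow(dr) == 0) return(NULL)
  # a known external tetramer anchors the boundary and outranks everything
  # (repeat units can extend periodically into the spacer, shifting the
  # apparent edge); then most occurrences, fewest total mismatches,
  # longest unit, closest to the ORF
  ord <- if (side == "LE") {
    order(-tet_match, -dr[, "n_occ"], dr[, "total_mm"], -dr[, "unit_len"],
          -dr[, "start"])
  } else {
    order(-tet_match, -dr[, "n_occ"], dr[, "total_mm"], -dr[, "unit_len"],
          dr[, "start"])
  }
  dr[ord[1], , drop = FALSE]
}

#' Detect LE/RE boundaries around the ORFs of a locus
#'
#' Searches windows of up to `params$window` nt outside the outermost ORF
#' ends of an element-oriented locus sequence for subterminal repeats:
#' inverted repeats in `"inverted"` mode (IS605/IS1341 palindromic ends) or
#' short direct repeats in `"direct"` mode (IS607 ends).  The cleavage
#' tetramer is the 4 nt immediately outside the accepted repeat.  A side
#' whose window is truncated by the contig edge is reported absent.
#'
#' @param sequence locus sequence, oriented so the element strand is `+`.
#' @param orf_lo,orf_hi 0-based half-open span of the outermost ORF ends
#'   within `sequence`.
#' @param mode `"inverted"` or `"direct"`.
#' @param params a [boundary_params()] object.
#' @param le_open,re_open logical: is the corresponding window truncated by
#'   a contig edge (side then reported absent)?
#' @param prefer_tetramers optional known cleavage motifs used as a
#'   tie-break between equally good repeat candidates.
#' @return list with elements `le` and `re`, each `NULL` or a list
#'   (`side`, `repeat_kind`, `start`, `end`, `stem_len`, `loop_len`,
#'   `n_occ`, `mismatches`, `tetramer`, `tetramer_start`) in locus
#'   coordinates.
#' @export
detect_boundaries <- function(sequence, orf_lo, orf_hi,
                              mode = c("inverted", "direct"),
                              params = boundary_params(),
                              le_open = FALSE, re_open = FALSE,
                              prefer_tetramers = NULL) {
  mode <- match.arg(mode)
  L <- nchar(sequence)
  svec <- dna_to_int(sequence)
  tet_at <- function(cand_start, cand_end, side, w_s) {
    # external tetramer of a candidate repeat, locus coordinates
    pos <- if (side == "LE") w_s + cand_start - 4L else w_s + cand_end
    ifelse(pos >= 0 & pos + 4L <= L, substr(rep(sequence, length(pos)),
                                            pos + 1, pos + 4), NA)
  }
  one_side <- function(side, open) {
    if (open) return(NULL)
    if (side == "LE") {
      w_s <- max(0L, orf_lo - params$window)
      w_e <- min(L, orf_lo + params$overhang)
    } else {
      w_s <- max(0L, orf_hi - params$overhang)
      w_e <- min(L, orf_hi + params$window)
    }
    if (w_e - w_s < 2 * params$min_arm + params$loop_range[1]) return(NULL)
    win <- svec[(w_s + 1):w_e]
    if (mode == "inverted") {
      pal <- cpp_find_palindromes(win, params$min_arm, params$loop_range[1],
                                  params$loop_range[2],
                                  params$strong_max_mismatch)
      pal <- filter_palindromes(pal, params)
      tm <- if (nrow(pal) > 0 && !is.null(prefer_tetramers)) {
        tet_at(pal[, "start"], pal[, "end"], side, w_s) %in% prefer_tetramers
      } else {
        rep(FALSE, nrow(pal))
      }
      best <- pick_palindrome(pal, side, tm)
      if (is.null(best)) return(NULL)
      r_s <- unname(w_s + best[1, "start"])
      r_e <- unname(w_s + best[1, "end"])
      stem <- unname(best[1, "arm"])
      loop <- unname(best[1, "loop"])
      mm <- unname(best[1, "mismatches"])
      nocc <- NA_integer_
      kind <- "inverted"
    } else {
      dr <- cpp_find_direct_repeats(win, params$dr_unit_range[1],
                                    params$dr_unit_range[2],
                                    2L,  # weak minimum; filtered below
                                    params$dr_max_mismatch,
                                    params$dr_total_mismatch,
                                    params$dr_window)
      # two exact copies are admissible (one copy of a genuine triplet may
      # be eroded); mismatched copies need the full occurrence count
      dr <- dr[dr[, "n_occ"] >= params$dr_min_occ |
                 dr[, "total_mm"] == 0, , drop = FALSE]
      tm <- if (nrow(dr) > 0 && !is.null(prefer_tetramers)) {
        tet_at(dr[, "start"], dr[, "end"], side, w_s) %in% prefer_tetramers
      } else {
        rep(FALSE, nrow(dr))
      }
      best <- pick_direct_repeat(dr, side, tm)
      if (is.null(best)) return(NULL)
      r_s <- unname(w_s + best[1, "start"])
      r_e <- unname(w_s + best[1, "end"])
      stem <- unname(best[1, "unit_len"])
      loop <- NA_integer_
      mm <- NA_integer_
      nocc <- unname(best[1, "n_occ"])
      kind <- "direct"
    }
    if (side == "LE") {
      t_s <- r_s - 4L
      if (t_s < 0) return(NULL)  # tetramer unreadable at the edge
      tet <- substr(sequence, t_s + 1, t_s + 4)
    } else {
      t_s <- r_e
      if (t_s + 4L > L) return(NULL)
      tet <- substr(sequence, t_s + 1, t_s + 4)
    }
    list(side = side, repeat_kind = kind, start = r_s, end = r_e,
         stem_len = as.integer(stem), loop_len = as.integer(loop),
         n_occ = as.integer(nocc), mismatches = as.integer(mm),
         tetramer = tet, tetramer_start = t_s)
  }
  list(le = one_side("LE", le_open), re = one_side("RE", re_open))
}

#' Call element completeness from its boundary calls
#'
#' An element is `full` iff both LE and RE boundaries are present with
#' identifiable cleavage tetramers; otherwise `truncated_LE`,
#' `truncated_RE` or `truncated_both`.  When `known_tetramers` is supplied,
#' "identifiable" requires either a tetramer matching a known cleavage
#' motif or a structurally strong repeat (palindrome stem of at least
#' `strong_arm` nt, or a multi-copy direct repeat), which suppresses chance
#' repeats in truncated flanks while tolerating substitutions that shift
#' the detected repeat edge of genuine ends.
#'
#' @param le,re boundary calls from [detect_boundaries()] (or `NULL`).
#' @param known_tetramers optional character vector of accepted cleavage
#'   tetramers.
#' @param strong_arm palindrome stem length accepted as identifiable on its
#'   own.
#' @return one of `"full"`, `"truncated_LE"`, `"truncated_RE"`,
#'   `"truncated_both"`.
#' @export
call_completeness <- function(le, re, known_tetramers = NULL,
                              strong_arm = 12L) {
  ok <- function(b) {
    if (is.null(b) || is.na(b$tetramer)) return(FALSE)
    if (is.null(known_tetramers)) return(TRUE)
    if (b$tetramer %in% known_tetramers) return(TRUE)
    if (identical(b$repeat_kind, "direct")) return(isTRUE(b$n_occ >= 3))
    isTRUE(b$stem_len >= strong_arm) && isTRUE(b$mismatches <= 1)
  }
  le_ok <- ok(le)
  re_ok <- ok(re)
  if (le_ok && re_ok) "full"
  else if (!le_ok && re_ok) "truncated_LE"
  else if (le_ok && !re_ok) "truncated_RE"
  else "truncated_both"
}

#' Classify the structural subgroup from role-assigned ORFs
#'
#' (Y1, TnpB) on the same strand with coding overlap of at least 1 nt is
#' IS605a; same strand disjoint is IS605b; opposite strands IS605c.
#' (SR, TnpB) same strand overlapping is IS607a, same strand disjoint
#' IS607b.  TnpB alone is IS1341.  Anything else is `unclassified`.
#'
#' @param orfs tibble with columns `start`, `end`, `strand`, `role` for the
#'   element's ORFs (roles among TnpB/Y1/SR; `unknown` rows are ignored).
#' @return subgroup label.
#' @export
classify_subgroup <- function(orfs) {
  orfs <- orfs[orfs$role %in% c("TnpB", "Y1", "SR"), ]
  tnpb <- orfs[orfs$role == "TnpB", ]
  if (nrow(tnpb) == 0) stop("no TnpB ORF: not a TCME", call. = FALSE)
  partners <- orfs[orfs$role %in% c("Y1", "SR"), ]
  if (nrow(tnpb) > 1) return("unclassified")
  if (nrow(partners) == 0) return("IS1341")
  if (nrow(partners) > 1) return("unclassified")
  p <- partners[1, ]
  tb <- tnpb[1, ]
  overlap <- min(p$end, tb$end) - max(p$start, tb$start) >= 1
  same <- p$strand == tb$strand
  if (p$role == "Y1") {
    if (!same) return("IS605c")
    if (overlap) "IS605a" else "IS605b"
  } else {
    if (!same) return("unclassified")
    if (overlap) "IS607a" else "IS607b"
  }
}

#' IS1341 decay filter
#'
#' Flags an IS1341 candidate as a decayed IS605/IS607 copy if the regions
#' upstream or downstream of its TnpB CDS contain a local alignment to any
#' reference Y1/SR CDS (forward or reverse complement) spanning strictly
#' more than `min_match` nt at `min_identity` identity or better.
#'
#' @param upstream,downstream flanking nucleotide sequences (may be empty).
#' @param references character vector of Y1/SR CDS nucleotide sequences.
#' @param min_match matched-length threshold in nt (strict `>`).
#' @param min_identity identity threshold of the matched span.
#' @return `TRUE` if the candidate is a decay copy.
#' @export
decay_filter <- function(upstream, downstream, references,
                         min_match = 20L, min_identity = 0.8) {
  if (length(references) == 0) stop("empty reference set", call. = FALSE)
  flanks <- c(upstream, downstream)
  flanks <- flanks[!is.na(flanks) & nchar(flanks) > min_match]
  for (fl in flanks) {
    fi <- dna_to_int(fl)
    for (ref in references) {
      for (rs in c(ref, revcomp(ref))) {
        st <- cpp_local_stats(fi, dna_to_int(rs), 1, -1, 2, 1)
        if (st[["columns"]] > min_match &&
            st[["matches"]] / st[["columns"]] >= min_identity) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

#' Assign known or new family names to element consensus sequences
#'
#' A consensus keeps a reference (known) name iff it matches a reference
#' element at more than 90% nucleotide identity, its LE and RE cleavage
#' tetramers equal the reference's, and both boundary repeats were
#' detected.  Otherwise it receives a new name `IS<Abbrev><n>`, where
#' `Abbrev` is one genus letter plus two species-epithet letters and `n`
#' increments per species in consensus-id order.
#'
#' @param consensus_tbl tibble with columns `family_id`, `sequence`,
#'   `le_tetramer`, `re_tetramer`, `boundaries_ok`, `species`.
#' @param reference optional tibble with columns `name`, `sequence`,
#'   `le_tetramer`, `re_tetramer` of known elements.
#' @param identity known-name identity threshold (strict `>`).
#' @return `consensus_tbl` with added columns `family_name` and `known`.
#' @export
assign_family <- function(consensus_tbl, reference = NULL, identity = 0.90) {
  if (is.null(reference) || nrow(reference) == 0) {
    if (is.null(reference)) {
      warning("no reference library: all families named as new elements")
    }
    reference <- tibble::tibble(name = character(0), sequence = character(0),
                                le_tetramer = character(0),
                                re_tetramer = character(0))
  }
  consensus_tbl <- dplyr::arrange(consensus_tbl, .data$species, .data$family_id)
  counters <- list()
  name <- character(nrow(consensus_tbl))
  known <- logical(nrow(consensus_tbl))
  for (i in seq_len(nrow(consensus_tbl))) {
    row <- consensus_tbl[i, ]
    hit <- NA_character_
    if (isTRUE(row$boundaries_ok) && nrow(reference) > 0) {
      for (j in seq_len(nrow(reference))) {
        idn <- pairwise_identity(row$sequence, reference$sequence[j],
                                 band = 200L)
        if (idn > identity &&
            identical(row$le_tetramer, reference$le_tetramer[j]) &&
            identical(row$re_tetramer, reference$re_tetramer[j])) {
          hit <- reference$name[j]
          break
        }
      }
    }
    if (!is.na(hit)) {
      name[i] <- hit
      known[i] <- TRUE
    } else {
      ab <- species_abbrev(row$species)
      counters[[ab]] <- (counters[[ab]] %||% 0L) + 1L
      name[i] <- sprintf("IS%s%d", ab, counters[[ab]])
      known[i] <- FALSE
    }
  }
  consensus_tbl$family_name <- name
  consensus_tbl$known <- known
  consensus_tbl
}

# "Escherichia coli" -> "Eco"
species_abbrev <- function(species) {
  parts <- strsplit(trimws(species), "\\s+")[[1]]
  genus <- toupper(substr(parts[1], 1, 1))
  epithet <- if (length(parts) > 1) tolower(substr(parts[2], 1, 2)) else "sp"
  paste0(genus, epithet)
}
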