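# Position-specific scoring model of the TnpB RuvC nuclease domain and the
# six-frame genome scan that seeds locus discovery.

#' Seed-set curation thresholds
#'
#' Thresholds applied while building the RuvC scoring model: proteins
#' shorter than 200 aa or longer than 600 aa are discarded (strict `<`/`>`),
#' the seed set is pre-clustered at 80% identity, alignment rows with more
#' than 20% gaps across the domain region are dropped, and scan hits whose
#' matched segment is shorter than 50 aa are discarded.
#'
#' @param min_protein_len,max_protein_len length filter bounds in aa.
#' @param build_cluster_identity identity for seed pre-clustering.
#' @param max_gap_fraction maximum tolerated gap fraction per row.
#' @param min_hit_len minimum matched length of a reported hit, in aa.
#' @return a list of class `curation_thresholds`.
#' @export
curation_thresholds <- function(min_protein_len = 200L,
                                max_protein_len = 600L,
                                build_cluster_identity = 0.80,
                                max_gap_fraction = 0.20,
                                min_hit_len = 50L) {
  stopifnot(min_protein_len < max_protein_len,
            build_cluster_identity > 0, build_cluster_identity <= 1,
            max_gap_fraction >= 0, max_gap_fraction <= 1)
  structure(list(min_protein_len = as.integer(min_protein_len),
                 max_protein_len = as.integer(max_protein_len),
                 build_cluster_identity = build_cluster_identity,
                 max_gap_fraction = max_gap_fraction,
                 min_hit_len = as.integer(min_hit_len)),
            class = "curation_thresholds")
}

#' Length-filter a seed protein set
#'
#' Keeps exactly the sequences with
#' `min_protein_len <= length <= max_protein_len`; the filter is strict on
#' both sides (a 200-aa and a 600-aa protein are both kept under the
#' defaults).  Input order is preserved.
#'
#' @param proteins tibble with columns `id`, `sequence`.
#' @param thresholds a [curation_thresholds()] object.
#' @return the filtered tibble; warns (does not fail) if nothing survives.
#' @export
curate_seed <- function(proteins, thresholds = curation_thresholds()) {
  proteins <- check_seqset(proteins, "proteins")
  if (nrow(proteins) == 0) stop("empty seed set", call. = FALSE)
  len <- nchar(proteins$sequence)
  out <- proteins[len >= thresholds$min_protein_len &
                    len <= thresholds$max_protein_len, ]
  if (nrow(out) == 0) warning("no seed sequences survived the length filter")
  out
}

# per-row gap fraction over a set of alignment columns
row_gap_fraction <- function(mat, cols) {
  rowMeans(mat[, cols, drop = FALSE] == "-")
}

#' Drop alignment rows with gappy domain regions
#'
#' A row is retained iff its gap fraction across `region` is
#' `<= max_gap_fraction` (strictly more than the threshold is discarded,
#' so a row with exactly 20.0% gaps survives the default).
#'
#' @param aln tibble with columns `id`, `sequence` (equal-length rows).
#' @param region integer vector of column indices to assess; `NULL` uses the
#'   match columns (gap fraction < 0.5).
#' @param max_gap_fraction tolerated gap fraction.
#' @return the retained rows of `aln`.
#' @export
gap_filter <- function(aln, region = NULL, max_gap_fraction = 0.20) {
  aln <- check_seqset(aln, "aln")
  w <- unique(nchar(aln$sequence))
  if (length(w) != 1) stop("alignment rows differ in length", call. = FALSE)
  mat <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
  if (is.null(region)) region <- which(colMeans(mat == "-") < 0.5)
  if (length(region) == 0) stop("empty column region", call. = FALSE)
  if (any(region < 1 | region > w)) stop("region outside alignment", call. = FALSE)
  aln[row_gap_fraction(mat, region) <= max_gap_fraction, ]
}

#' Build a log-odds scoring profile from a curated alignment
#'
#' Match columns are the alignment columns with gap fraction < 0.5.  The
#' score of residue `a` in column `c` is
#' `log2(((count_c(a) + pseudocount * background(a)) / (n_c + pseudocount)) / background(a))`
#' with `n_c` the number of residues (non-gaps) in the column.  Scores are in
#' bits; gap penalties follow the half-bit convention (open 11, extend 1 in
#' half-bits) used by the scanner.
#'
#' @param aln tibble with columns `id`, `sequence` (equal-length protein rows).
#' @param pseudocount positive pseudocount mass.
#' @param background named numeric vector of residue frequencies over
#'   [AA_ALPHABET]; `NULL` means uniform 1/20.
#' @param gap_open,gap_extend affine gap penalties in half-bits.
#' @return an object of class `ruvc_profile`.
#' @export
build_profile <- function(aln, pseudocount = 1, background = NULL,
                          gap_open = 11, gap_extend = 1) {
  aln <- check_seqset(aln, "aln")
  stopifnot(pseudocount > 0)
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  background <- background[AA_ALPHABET]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-6) {
    stop("background must be frequencies over the 20 residues", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
  match_cols <- which(colMeans(mat == "-") < 0.5)
  if (length(match_cols) == 0) stop("alignment has no match columns", call. = FALSE)
  scores <- matrix(0, nrow = 20, ncol = length(match_cols),
                   dimnames = list(AA_ALPHABET, NULL))
  for (k in seq_along(match_cols)) {
    col <- mat[, match_cols[k]]
    col <- col[col != "-"]
    n_c <- length(col)
    cnt <- table(factor(col, levels = AA_ALPHABET))
    p <- (as.numeric(cnt) + pseudocount * background) / (n_c + pseudocount)
    scores[, k] <- log2(p / background)
  }
  structure(list(scores = scores, n_columns = ncol(scores),
                 gap_open = gap_open, gap_extend = gap_extend,
                 background = background, pseudocount = pseudocount,
                 match_cols = match_cols),
            class = "ruvc_profile")
}

#' @export
print.ruvc_profile <- function(x, ...) {
  cat("<ruvc_profile> ", x$n_columns, " match columns, gap open/extend ",
      x$gap_open, "/", x$gap_extend, " (half-bits)\n", sep = "")
  invisible(x)
}

#' @rdname build_profile
#' @param x a `ruvc_profile` object.
#' @param ... unused.
#' @method tidy ruvc_profile
#' @export
tidy.ruvc_profile <- function(x, ...) {
  tibble::tibble(
    column = rep(seq_len(x$n_columns), each = 20),
    residue = rep(AA_ALPHABET, times = x$n_columns),
    score = as.vector(x$scores)
  )
}

#' @rdname build_profile
#' @method glance ruvc_profile
#' @export
glance.ruvc_profile <- function(x, ...) {
  tibble::tibble(n_columns = x$n_columns,
                 max_score = sum(apply(x$scores, 2, max)),
                 gap_open = x$gap_open, gap_extend = x$gap_extend)
}

#' Build the RuvC profile from raw seed proteins
#'
#' Runs the full seed-curation cascade: length filter, greedy pre-clustering
#' at 80% identity (cluster representatives carried forward), extraction of
#' each representative's conserved RuvC-like region by local alignment to
#' the anchor representative (full-length TnpBs differ widely outside the
#' nuclease domain, so only the domain region is aligned), center-star
#' alignment of the extracted regions, gap filter over the match columns,
#' and profile construction.  Representatives whose local alignment to the
#' anchor falls below `min_anchor_score` are discarded as domain-free.
#'
#' @param proteins tibble with columns `id`, `sequence` of candidate TnpB
#'   seed proteins.
#' @param thresholds a [curation_thresholds()] object.
#' @param pseudocount,background passed to [build_profile()].
#' @param min_anchor_score minimum local alignment score (match 2,
#'   mismatch -1, gap 11/1) to the anchor representative.
#' @return a `ruvc_profile` object.
#' @export
build_ruvc_profile <- function(proteins, thresholds = curation_thresholds(),
                               pseudocount = 1, background = NULL,
                               min_anchor_score = 40) {
  cur <- curate_seed(proteins, thresholds)
  if (nrow(cur) < 2) stop("need at least 2 curated seed proteins", call. = FALSE)
  cl <- greedy_cluster(cur, thresholds$build_cluster_identity)
  reps <- cur[cur$id %in% unique(cl$representative_id), ]
  reps <- reps[order(-nchar(reps$sequence), reps$id), ]
  if (nrow(reps) >= 2) {
    anchor <- aa_to_int(reps$sequence[1])
    doms <- purrr::pmap_dfr(reps, function(id, sequence, ...) {
      st <- cpp_local_stats(anchor, aa_to_int(sequence), 2, -1, 11, 1)
      if (st[["score"]] < min_anchor_score) return(NULL)
      tibble::tibble(id = id,
                     sequence = substr(sequence, st[["b_start"]] + 1,
                                       st[["b_end"]]))
    })
    if (nrow(doms) < 2) {
      stop("seed representatives share no conserved region", call. = FALSE)
    }
    aln <- center_star_msa(doms)
  } else {
    aln <- reps
  }
  aln <- gap_filter(aln, NULL, thresholds$max_gap_fraction)
  build_profile(aln, pseudocount, background)
}

# ---------------------------------------------------------------------------
# Synthetic seed material.  The canonical domain below is a synthetic
# RuvC-like sequence (not taken from any database): 120 residues carrying
# the catalytic D / E / D residues in RuvC I / II / III order.
CANONICAL_RUVC <- paste0(
  "KRVVGIDPGLKSAGYGVVEV",
  "NHQGRLVDFGVIKTSAHESW",
  "AQRRALIDELVTIAGRYGRA",
  "TIVMEELDFSQRKGSGRTNA",
  "VHQWVARFNAGLVDIPTAKV",
  "NPAYTSQRCSHCGHIGKRED"
)

# mutate a protein at an expected per-site substitution rate
mutate_protein <- function(x, rate) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1)
  }
  paste0(chars, collapse = "")
}

#' Generate a synthetic RuvC seed protein set
#'
#' Produces full-length TnpB-like proteins sharing a mutated copy of the
#' package's synthetic canonical RuvC domain, embedded between random
#' N-/C-terminal regions of varying length, for profile building and tests.
#'
#' @param n number of seed proteins.
#' @param divergence expected per-residue substitution rate applied to the
#'   domain copy of each protein.
#' @param seed integer RNG seed.
#' @return tibble with columns `id`, `sequence`, `domain_start`,
#'   `domain_end` (0-based half-open coordinates of the embedded domain).
#' @export
synthetic_ruvc_seed <- function(n = 24, divergence = 0.15, seed = 1L) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n), function(i) {
      nlen <- sample(120:200, 1)
      clen <- sample(60:140, 1)
      dom <- mutate_protein(CANONICAL_RUVC, divergence)
      tibble::tibble(
        id = sprintf("seed%03d", i),
        sequence = paste0(random_protein(nlen), dom, random_protein(clen)),
        domain_start = nlen,
        domain_end = nlen + nchar(CANONICAL_RUVC)
      )
    })
  })
}

# ---------------------------------------------------------------------------

#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles a DNA sequence while exactly preserving its dinucleotide (and
#' hence mononucleotide) composition, via a random Eulerian path on the
#' doublet graph (Altschul-Erickson).  Uses R's RNG, so results are
#' reproducible under `set.seed()`.
#'
#' @param x a DNA string.
#' @return a shuffled DNA string with identical dinucleotide counts.
#' @export
dinuc_shuffle <- function(x) {
  s <- dna_to_int(x)
  n <- length(s)
  if (n < 3) return(x)
  verts <- sort(unique(s))
  last <- s[n]
  # outgoing edge targets per vertex, in original order
  edges <- lapply(verts, function(v) s[which(s[-n] == v) + 1L])
  names(edges) <- as.character(verts)
  nonfinal <- setdiff(verts, last)
  # choose last-edge targets forming an arborescence into the final vertex
  repeat {
    last_edge <- vapply(as.character(verts), function(v) {
      e <- edges[[v]]
      if (length(e) == 0) return(NA_integer_)
      e[sample.int(length(e), 1)]
    }, integer(1))
    ok <- TRUE
    for (v in nonfinal) {
      cur <- v
      steps <- 0
      while (cur != last && steps <= length(verts)) {
        cur <- last_edge[[as.character(cur)]]
        if (is.na(cur)) break
        steps <- steps + 1
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  # permute the remaining edges, appending the chosen last edge
  pools <- lapply(as.character(verts), function(v) {
    e <- edges[[v]]
    if (v == as.character(last) || length(e) == 0) {
      # final vertex keeps all edges shuffled (no forced last edge)
      if (length(e) > 1) e[sample.int(length(e))] else e
    } else {
      le <- last_edge[[v]]
      i <- which(e == le)[1]
      rest <- e[-i]
      if (length(rest) > 1) rest <- rest[sample.int(length(rest))]
      c(rest, le)
    }
  })
  names(pools) <- as.character(verts)
  ptr <- setNames(rep(1L, length(verts)), as.character(verts))
  out <- integer(n)
  out[1] <- s[1]
  cur <- s[1]
  for (i in 2:n) {
    k <- as.character(cur)
    nxt <- pools[[k]][ptr[[k]]]
    ptr[[k]] <- ptr[[k]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  int_to_dna(out)
}

# best local profile score (half-bits) over the six frames of a DNA string
best_frame_score <- function(profile, dna) {
  fr <- six_frame_translate(dna)
  best <- 0
  for (p in fr$protein) {
    if (!nzchar(p)) next
    h <- cpp_pssm_scan(aa_to_int(p), profile$scores * 2,
                       profile$gap_open, profile$gap_extend,
                       -Inf, 1L)
    if (nrow(h) > 0) best <- max(best, max(h[, "score"]))
  }
  best
}

#' Calibrate the scan score threshold on shuffled decoys
#'
#' Samples windows from the input genomes, applies a dinucleotide-preserving
#' shuffle to each, records the best local profile score across the six
#' frames of every decoy, and returns the `q`-th empirical percentile (in
#' bits).  With the default `q = 0.999` the expected false-hit rate is below
#' 1e-2 per decoy.
#'
#' @param profile a `ruvc_profile`.
#' @param genomes tibble with columns `genome_id`, `contig_id`, `sequence`.
#' @param n_decoys number of shuffled decoy windows.
#' @param decoy_length window length in nt.
#' @param q percentile of the decoy score distribution.
#' @param seed integer RNG seed.
#' @return threshold in bits, with attribute `decoy_scores`.
#' @export
calibrate_threshold <- function(profile, genomes, n_decoys = 200,
                                decoy_length = 1500, q = 0.999, seed = 1L) {
  stopifnot(inherits(profile, "ruvc_profile"), n_decoys >= 1)
  withr::with_seed(seed, {
    lens <- nchar(genomes$sequence)
    pick <- sample.int(nrow(genomes), n_decoys,
                       replace = TRUE, prob = pmax(lens, 1))
    scores <- vapply(pick, function(i) {
      L <- lens[i]
      w <- min(decoy_length, L)
      st <- if (L > w) sample.int(L - w + 1, 1) else 1L
      dna <- substring(genomes$sequence[i], st, st + w - 1)
      best_frame_score(profile, dinuc_shuffle(dna)) / 2
    }, numeric(1))
  })
  scores <- sort(scores)
  thr <- scores[ceiling(q * length(scores))]
  attr(thr, "decoy_scores") <- scores
  thr
}

#' Scan genomes for TnpB-homolog hits
#'
#' Translates every contig in all six frames, aligns the RuvC profile
#' locally (affine-gap dynamic programming) against each translation, and
#' reports hits with score `>= threshold` and matched length `>= min_hit_len`
#' amino acids.  Overlapping hits within one frame are merged keeping the
#' best score; hits from different frames are all reported (they coalesce
#' into a single locus downstream if close).  Local alignments never span
#' stop codons, so a hit is always contained in one ORF's translation.
#'
#' @param genomes tibble with columns `genome_id`, `contig_id`, `sequence`.
#' @param profile a `ruvc_profile`.
#' @param threshold score threshold in bits (e.g. from
#'   [calibrate_threshold()]).
#' @param min_hit_len minimum matched segment length in aa.
#' @return tibble with columns `genome_id`, `contig_id`, `frame`, `strand`,
#'   `protein_start`, `protein_end` (aa, 0-based half-open within the
#'   frame's translation), `genomic_start`, `genomic_end` (nt, 0-based
#'   half-open, forward strand), `score` (bits), `matched_len` (aa), sorted
#'   by genome, contig and genomic start.
#' @export
scan_genomes <- function(genomes, profile, threshold, min_hit_len = 50L) {
  stopifnot(inherits(profile, "ruvc_profile"))
  pssm2 <- profile$scores * 2
  rows <- purrr::pmap_dfr(
    list(genomes$genome_id, genomes$contig_id, genomes$sequence),
    function(gid, cid, seqc) {
      L <- nchar(seqc)
      fr <- six_frame_translate(seqc)
      purrr::pmap_dfr(list(fr$frame, fr$strand, fr$protein),
                      function(f, strand, prot) {
        if (!nzchar(prot)) return(NULL)
        h <- cpp_pssm_scan(aa_to_int(prot), pssm2,
                           profile$gap_open, profile$gap_extend,
                           threshold * 2, as.integer(min_hit_len))
        if (nrow(h) == 0) return(NULL)
        g <- t(apply(h, 1, function(r) {
          frame_to_genomic(f, r[["start"]], r[["end"]], L)
        }))
        tibble::tibble(
          genome_id = gid, contig_id = cid, frame = f, strand = strand,
          protein_start = as.integer(h[, "start"]),
          protein_end = as.integer(h[, "end"]),
          genomic_start = as.integer(g[, 1]),
          genomic_end = as.integer(g[, 2]),
          score = h[, "score"] / 2,
          matched_len = as.integer(h[, "end"] - h[, "start"])
        )
      })
    })
  if (nrow(rows) == 0) {
    return(tibble::tibble(genome_id = character(0), contig_id = character(0),
                          frame = integer(0), strand = character(0),
                          protein_start = integer(0), protein_end = integer(0),
                          genomic_start = integer(0), genomic_end = integer(0),
                          score = numeric(0), matched_len = integer(0)))
  }
  dplyr::arrange(rows, .data$genome_id, .data$contig_id, .data$genomic_start)
}
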