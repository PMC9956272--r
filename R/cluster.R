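# Greedy identity clustering, center-star multiple alignment and consensus
# calling: the machinery behind the 80% seed-protein, 70% locus and 90%
# family clustering stages.

#' Scoring parameters for pairwise identity alignments
#'
#' Identity is computed from a semi-global alignment (free terminal gaps)
#' with affine gap costs; a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`.  Identity is the number of identical
#' columns divided by the number of aligned columns excluding terminal-gap
#' columns, which matches common usage when comparing fragments against
#' full-length sequences.
#'
#' @param match match score (> mismatch).
#' @param mismatch mismatch score.
#' @param gap_open opening cost of a gap (applied to its first column).
#' @param gap_extend per-column extension cost.
#' @return a list of class `identity_params`.
#' @export
identity_params <- function(match = 1, mismatch = -1, gap_open = 2,
                            gap_extend = 1) {
  stopifnot(match > mismatch, gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "identity_params")
}

seq_to_int <- function(x, alphabet) {
  if (alphabet == "nt") dna_to_int(x) else aa_to_int(x)
}

#' Pairwise sequence identity
#'
#' Aligns two sequences semi-globally (affine gaps, free terminal gaps) and
#' returns the fraction of identical columns among aligned columns,
#' terminal gaps excluded.  Symmetric in its arguments.
#'
#' @param a,b sequences (both nucleotide or both amino acid).
#' @param params an [identity_params()] object.
#' @param band if > 0, restrict the alignment to a band of this half-width
#'   around the diagonal (widened by the length difference); 0 means exact
#'   full dynamic programming.
#' @return identity fraction in `[0, 1]`.
#' @export
#' @examples
#' pairwise_identity("ACDE", "ACDF")  # 0.75
pairwise_identity <- function(a, b, params = identity_params(), band = 0L) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  al_a <- guess_alphabet(a)
  al_b <- guess_alphabet(b)
  if (al_a != al_b) {
    stop("cannot compare nucleotide and amino-acid sequences", call. = FALSE)
  }
  # glocal: the shorter sequence is consumed entirely, terminal gaps are
  # free only around it (inside the longer one); canonical ordering keeps
  # the result symmetric
  if (nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    tmp <- a; a <- b; b <- tmp
  }
  st <- cpp_align_stats(seq_to_int(a, al_a), seq_to_int(b, al_a),
                        params$match, params$mismatch,
                        params$gap_open, params$gap_extend,
                        FALSE, TRUE, as.integer(band))
  if (st[["columns"]] == 0) return(0)
  st[["matches"]] / st[["columns"]]
}

#' Greedy incremental identity clustering
#'
#' cd-hit/USEARCH-style clustering: sequences are processed in decreasing
#' length order (ties broken by id); each sequence joins the first existing
#' cluster whose representative it matches at `>= threshold` identity,
#' otherwise it founds a new cluster.  Representatives are therefore the
#' longest member of each cluster (ties: lexicographically smallest id).
#'
#' @param seqs tibble with columns `id`, `sequence`.
#' @param threshold identity threshold in (0, 1].
#' @param params an [identity_params()] object.
#' @param band band half-width passed to [pairwise_identity()].
#' @return tibble with columns `cluster_id`, `representative_id`,
#'   `member_id`, `identity_to_rep`.
#' @export
greedy_cluster <- function(seqs, threshold, params = identity_params(),
                           band = 0L) {
  seqs <- check_seqset(seqs)
  stopifnot(threshold > 0, threshold <= 1)
  ord <- order(-nchar(seqs$sequence), seqs$id)
  seqs <- seqs[ord, ]
  reps <- character(0)
  rep_seq <- character(0)
  out <- vector("list", nrow(seqs))
  for (k in seq_len(nrow(seqs))) {
    id <- seqs$id[k]
    sq <- seqs$sequence[k]
    assigned <- FALSE
    for (ci in seq_along(reps)) {
      idn <- pairwise_identity(sq, rep_seq[ci], params, band)
      if (idn >= threshold) {
        out[[k]] <- tibble::tibble(cluster_id = ci, representative_id = reps[ci],
                                   member_id = id, identity_to_rep = idn)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, id)
      rep_seq <- c(rep_seq, sq)
      out[[k]] <- tibble::tibble(cluster_id = length(reps),
                                 representative_id = id,
                                 member_id = id, identity_to_rep = 1)
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$cluster_id, .data$member_id)
}

# merge a pairwise alignment of (center, other) into the running master
# gap pattern: "once a gap, always a gap"
merge_into_msa <- function(master_map, pair_center, pair_other) {
  # master_map: integer vector over current MSA columns, 1-based index into
  # center residues, 0 for gap.  pair_center/pair_other likewise over the
  # new pairwise alignment columns.
  nM <- length(master_map)
  nP <- length(pair_center)
  out_master <- integer(nM + nP)
  out_other <- integer(nM + nP)
  i <- 1L  # over master columns
  j <- 1L  # over pairwise columns
  k <- 0L
  while (i <= nM || j <= nP) {
    k <- k + 1L
    mi <- if (i <= nM) master_map[i] else NA_integer_
    pj <- if (j <= nP) pair_center[j] else NA_integer_
    if (!is.na(mi) && mi == 0L) {           # master has a gap column
      out_master[k] <- i; out_other[k] <- 0L; i <- i + 1L
    } else if (!is.na(pj) && pj == 0L) {    # pairwise inserts a gap in center
      out_master[k] <- 0L; out_other[k] <- j; j <- j + 1L
    } else if (!is.na(mi) && !is.na(pj)) {  # both consume the same residue
      out_master[k] <- i; out_other[k] <- j
      i <- i + 1L; j <- j + 1L
    } else if (is.na(pj)) {
      out_master[k] <- i; out_other[k] <- 0L; i <- i + 1L
    } else {
      out_master[k] <- 0L; out_other[k] <- j; j <- j + 1L
    }
  }
  list(master = out_master[seq_len(k)], other = out_other[seq_len(k)])
}

#' Center-star multiple sequence alignment
#'
#' Builds a multiple alignment by choosing the center sequence (the one
#' maximising summed pairwise identity to all others; ties broken by id),
#' aligning every other sequence to it pairwise, and merging gaps under the
#' "once a gap, always a gap" rule.  Removing gaps from any row reproduces
#' the corresponding input exactly.
#'
#' @param seqs tibble with columns `id`, `sequence` (all the same alphabet).
#' @param params an [identity_params()] object.
#' @return tibble with columns `id`, `sequence` (gapped rows of equal
#'   length), in the input order.
#' @export
center_star_msa <- function(seqs, params = identity_params()) {
  seqs <- check_seqset(seqs)
  n <- nrow(seqs)
  if (n == 0) stop("no sequences", call. = FALSE)
  if (n == 1) return(seqs)
  idm <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      idm[i, j] <- idm[j, i] <-
        pairwise_identity(seqs$sequence[i], seqs$sequence[j], params)
    }
  }
  sums <- rowSums(idm)
  center <- order(-sums, seqs$id)[1]
  alph <- guess_alphabet(seqs$sequence[center])
  cseq <- seqs$sequence[center]
  cint <- seq_to_int(cseq, alph)

  # master alignment state: columns map to center residues (0 = gap)
  master <- seq_len(nchar(cseq))
  rows <- vector("list", n)  # per sequence: map MSA column -> residue index
  rows[[center]] <- master
  others <- setdiff(seq_len(n), center)
  pair_aln <- vector("list", n)
  for (k in others) {
    oint <- seq_to_int(seqs$sequence[k], alph)
    # free terminal gaps only around the shorter of the pair
    longer_other <- length(oint) >= length(cint)
    al <- cpp_align_pair(cint, oint, params$match, params$mismatch,
                         params$gap_open, params$gap_extend,
                         !longer_other, longer_other)
    pair_aln[[k]] <- al
  }
  # merge sequentially; re-expand earlier rows as the master grows
  col_origin <- master  # center residue index per master column (0 = gap)
  maps <- list()        # per other id: map master columns -> other residue
  for (k in others) {
    al <- pair_aln[[k]]
    m <- merge_into_msa(col_origin, al$a, al$b)
    # m$master: index into old master columns (0 = new gap column)
    new_origin <- ifelse(m$master == 0L, 0L,
                         col_origin[pmax(m$master, 1L)])
    # re-expand previously merged rows
    for (id in names(maps)) {
      old <- maps[[id]]
      maps[[id]] <- ifelse(m$master == 0L, 0L, old[pmax(m$master, 1L)])
    }
    maps[[as.character(seqs$id[k])]] <-
      ifelse(m$other == 0L, 0L, al$b[pmax(m$other, 1L)])
    col_origin <- new_origin
  }
  width <- length(col_origin)
  render <- function(seq_chr, map) {
    chars <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
    paste0(ifelse(map == 0L, "-", chars[pmax(map, 1L)]), collapse = "")
  }
  out <- character(n)
  out[center] <- render(cseq, col_origin)
  for (k in others) {
    out[k] <- render(seqs$sequence[k], maps[[as.character(seqs$id[k])]])
  }
  tibble::tibble(id = seqs$id, sequence = out)
}

#' Majority-rule consensus of an alignment
#'
#' Retains the columns with gap fraction < 0.5 and emits the most frequent
#' non-gap symbol per column (ties broken alphabetically).
#'
#' @param aln tibble with columns `id`, `sequence` (equal-length gapped rows).
#' @return a list with `sequence` (the consensus string) and `majority`
#'   (per retained column, the majority fraction among non-gap symbols).
#' @export
consensus <- function(aln) {
  aln <- check_seqset(aln, "aln")
  w <- unique(nchar(aln$sequence))
  if (length(w) != 1) stop("alignment rows differ in length", call. = FALSE)
  mat <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
  n <- nrow(mat)
  gap_frac <- colMeans(mat == "-")
  keep <- which(gap_frac < 0.5)
  cons <- character(length(keep))
  frac <- numeric(length(keep))
  for (k in seq_along(keep)) {
    col <- mat[, keep[k]]
    col <- col[col != "-"]
    tab <- table(col)
    top <- sort(names(tab)[tab == max(tab)])[1]
    cons[k] <- top
    frac[k] <- max(tab) / length(col)
  }
  list(sequence = paste0(cons, collapse = ""), majority = frac)
}
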