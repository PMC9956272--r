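test_that("seed curation keeps exactly the 200-600 aa range, boundaries inclusive", {
  mk <- function(lens) tibble::tibble(
    id = paste0("p", seq_along(lens)),
    sequence = vapply(lens, tcmescan:::random_protein, character(1)))
  set.seed(12)
  out <- curate_seed(mk(c(150, 250, 601)))
  expect_equal(out$id, "p2")
  out2 <- curate_seed(mk(c(200, 600)))
  expect_equal(nrow(out2), 2)          # filter is strict <200 / >600
  same <- mk(rep(400, 4))
  expect_identical(curate_seed(same), same)
  expect_warning(curate_seed(mk(c(10, 700))), "survived")
})

test_that("gap filter discards rows with strictly more than 20% gaps", {
  aln <- tibble::tibble(
    id = c("clean", "exact20", "gappy25"),
    sequence = c("MKVLMKVLMKVLMKVLMKVL",
                 paste0(strrep("M", 16), strrep("-", 4)),
                 paste0(strrep("K", 15), strrep("-", 5))))
  kept <- gap_filter(aln, region = 1:20)
  expect_setequal(kept$id, c("clean", "exact20"))
  expect_error(gap_filter(aln, region = integer(0)), "empty")
  expect_error(gap_filter(aln, region = 1:30), "outside")
})

test_that("profile scores follow the pseudocount log-odds formula", {
  # N identical copies: the observed residue maximises every column
  aln <- tibble::tibble(id = paste0("s", 1:4), sequence = rep("MKVD", 4))
  prof <- build_profile(aln)
  picks <- tcmescan:::AA_ALPHABET[apply(prof$scores, 2, which.max)]
  expect_equal(picks, c("M", "K", "V", "D"))
  # single column of A with vanishing pseudocount: score -> log2(1/bg)
  one <- build_profile(tibble::tibble(id = paste0("s", 1:4),
                                      sequence = rep("A", 4)),
                       pseudocount = 1e-9)
  expect_equal(unname(one$scores["A", 1]), log2(20), tolerance = 1e-6)
  # random alignment vs an independently coded count-based oracle
  set.seed(13)
  r <- random_alignment(5, 30, gap_frac = 0.05)
  p <- build_profile(r, pseudocount = 0.7)
  mat <- do.call(rbind, strsplit(r$sequence, ""))
  cols <- which(colMeans(mat == "-") < 0.5)
  for (k in seq_along(cols)) {
    col <- mat[, cols[k]]
    col <- col[col != "-"]
    for (a in c("A", "W", "K")) {
      cnt <- sum(col == a)
      expected <- log2(((cnt + 0.7 * 0.05) / (length(col) + 0.7)) / 0.05)
      expect_equal(unname(p$scores[a, k]), expected, tolerance = 1e-9)
    }
  }
  expect_error(build_profile(tibble::tibble(id = "a", sequence = "----")),
               "match columns")
})

test_that("local profile alignment equals exhaustive enumeration on tiny instances", {
  # oracle: best over all (sequence substring, profile column interval)
  # pairs of the brute-force global alignment against the sub-profile
  set.seed(14)
  for (case in 1:25) {
    C <- sample(3:5, 1)
    aln <- random_alignment(3, C, gap_frac = 0)
    prof <- build_profile(aln)
    seqc <- tcmescan:::random_protein(sample(6:9, 1))
    h <- tcmescan:::cpp_pssm_scan(tcmescan:::aa_to_int(seqc), prof$scores,
                                  2, 1, -Inf, 1L)
    got <- if (nrow(h) > 0) max(h[, "score"]) else 0
    # brute force: enumerate substrings and column ranges; score each cell
    # path by plain recursion over gapped alignments
    best <- 0
    n <- nchar(seqc)
    score_pair <- function(sub, c1, c2) {
      sv <- tcmescan:::aa_to_int(sub) + 1L
      cols <- c1:c2
      memo <- new.env()
      rec <- function(i, j, st) {
        key <- paste(i, j, st)
        if (!is.null(memo[[key]])) return(memo[[key]])
        v <- -Inf
        if (st == "M") {
          if (i > 0 && j > 0) {
            sc <- prof$scores[sv[i], cols[j]]
            prev <- if (i == 1 && j == 1) 0 else
              max(rec(i - 1, j - 1, "M"), rec(i - 1, j - 1, "E"),
                  rec(i - 1, j - 1, "F"))
            v <- sc + prev
          }
        } else if (st == "E") {
          if (j > 0) {
            v <- max(rec(i, j - 1, "M") - 2, rec(i, j - 1, "F") - 2,
                     rec(i, j - 1, "E") - 1)
            if (i == 0 && j == 1) v <- max(v, -2)
          }
        } else {
          if (i > 0) {
            v <- max(rec(i - 1, j, "M") - 2, rec(i - 1, j, "E") - 2,
                     rec(i - 1, j, "F") - 1)
            if (j == 0 && i == 1) v <- max(v, -2)
          }
        }
        memo[[key]] <- v
        v
      }
      nn <- nchar(sub)
      mm <- length(cols)
      max(rec(nn, mm, "M"), rec(nn, mm, "E"), rec(nn, mm, "F"))
    }
    for (i in 1:n) for (j in i:n) {
      for (c1 in 1:C) for (c2 in c1:C) {
        best <- max(best, score_pair(substr(seqc, i, j), c1, c2))
      }
    }
    expect_equal(got, best, tolerance = 1e-9, info = paste("case", case))
  }
})

test_that("genome scan recovers planted domains and rejects shuffles and short hits", {
  set.seed(15)
  # plant one unmutated RuvC-domain CDS inside a random genome
  dom_cds <- paste0(tcmescan:::reverse_translate(
    paste0("M", tcmescan:::CANONICAL_RUVC)), "TAA")
  g <- paste0(tcmescan:::random_dna(4000), dom_cds, tcmescan:::random_dna(4000))
  genomes <- tibble::tibble(genome_id = "g1", contig_id = "c01",
                            species = "test", sequence = g)
  hits <- scan_genomes(genomes, PROF, THR)
  expect_equal(nrow(hits), 1)
  # the hit covers the planted domain (up to a few trimmed residues)
  expect_lte(hits$genomic_start, 4000 + 30)
  expect_gte(hits$genomic_end, 4000 + nchar(dom_cds) - 30)
  expect_gte(hits$matched_len, 100)
  # shuffled genome of the same composition: no hits
  set.seed(16)
  shuf <- dinuc_shuffle(g)
  hits0 <- scan_genomes(tibble::tibble(genome_id = "g1", contig_id = "c01",
                                       species = "t", sequence = shuf),
                        PROF, THR)
  expect_equal(nrow(hits0), 0)
  # a 40-aa domain fragment scores well but fails the 50-aa length rule
  frag_cds <- paste0(tcmescan:::reverse_translate(
    paste0("M", substr(tcmescan:::CANONICAL_RUVC, 1, 40))), "TAA")
  # insulate with all-frame stops so the local alignment cannot pad its
  # matched length with flanking residues
  g2 <- paste0(tcmescan:::random_dna(3000), "TTAATTAATTAA", frag_cds,
               "TTAATTAATTAA", tcmescan:::random_dna(3000))
  tb2 <- tibble::tibble(genome_id = "g1", contig_id = "c01",
                        species = "t", sequence = g2)
  expect_equal(nrow(scan_genomes(tb2, PROF, THR, min_hit_len = 50L)), 0)
  expect_equal(nrow(scan_genomes(tb2, PROF, THR, min_hit_len = 30L)), 1)
})

test_that("reverse-frame hits map back to coordinates that reproduce the peptide", {
  set.seed(17)
  dom_cds <- paste0(tcmescan:::reverse_translate(
    paste0("M", tcmescan:::CANONICAL_RUVC)), "TAA")
  fwd <- paste0(tcmescan:::random_dna(2001), dom_cds,
                tcmescan:::random_dna(2000))
  g <- revcomp(fwd)    # put the domain on the minus strand
  hits <- scan_genomes(tibble::tibble(genome_id = "g", contig_id = "c",
                                      species = "t", sequence = g),
                       PROF, THR)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "-")
  sub <- substr(g, hits$genomic_start + 1, hits$genomic_end)
  pep <- translate_dna(revcomp(sub))
  fr <- six_frame_translate(g)
  prot <- fr$protein[fr$frame == hits$frame]
  expect_equal(pep, substr(prot, hits$protein_start + 1, hits$protein_end))
})

test_that("local score never decreases when unrelated flanks are appended", {
  set.seed(18)
  core <- tcmescan:::mutate_protein(tcmescan:::CANONICAL_RUVC, 0.1)
  s0 <- tcmescan:::protein_profile_score(core, PROF)
  for (k in 1:10) {
    ext <- paste0(tcmescan:::random_protein(sample(5:60, 1)), core,
                  tcmescan:::random_protein(sample(5:60, 1)))
    expect_gte(tcmescan:::protein_profile_score(ext, PROF), s0)
  }
})

test_that("dinucleotide shuffling preserves doublet composition exactly", {
  set.seed(19)
  for (k in 1:10) {
    x <- tcmescan:::random_dna(sample(100:400, 1), gc = runif(1, 0.3, 0.7))
    y <- dinuc_shuffle(x)
    expect_equal(nchar(y), nchar(x))
    count2 <- function(s) {
      table(substring(s, 1:(nchar(s) - 1), 2:nchar(s)))
    }
    expect_identical(as.list(count2(y))[order(names(count2(y)))],
                     as.list(count2(x))[order(names(count2(x)))])
  }
})

test_that("calibration bounds the decoy false-hit rate", {
  set.seed(20)
  genomes <- tibble::tibble(
    genome_id = "g1", contig_id = "c01", species = "t",
    sequence = tcmescan:::random_dna(150000))
  thr <- calibrate_threshold(PROF, genomes, n_decoys = 1000,
                             decoy_length = 600, seed = 99)
  scores <- attr(thr, "decoy_scores")
  expect_equal(length(scores), 1000)
  expect_lt(mean(scores > thr), 1e-2)
  # same seed, same threshold
  thr2 <- calibrate_threshold(PROF, genomes, n_decoys = 1000,
                              decoy_length = 600, seed = 99)
  expect_equal(as.numeric(thr), as.numeric(thr2))
})
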