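test_that("locus extraction applies the 1.7 kb flank rule with clipping", {
  set.seed(22)
  contig <- tcmescan:::random_dna(100000)
  genomes <- tibble::tibble(genome_id = "g", contig_id = "c", species = "t",
                            sequence = contig)
  hits <- tibble::tibble(genome_id = "g", contig_id = "c", frame = 1L,
                         strand = "+", protein_start = 0L, protein_end = 10L,
                         genomic_start = 5000L, genomic_end = 6200L,
                         score = 50, matched_len = 400L)
  loc <- extract_loci(hits, genomes)
  expect_equal(c(loc$start, loc$end), c(3300L, 7900L))
  expect_equal(loc$sequence, substr(contig, 3301, 7900))
  hits$genomic_start <- 100L
  hits$genomic_end <- 1300L
  loc2 <- extract_loci(hits, genomes)
  expect_equal(loc2$start, 0L)
  expect_true(loc2$clipped_start)
})

test_that("ORF prediction matches an exhaustive six-frame scanner", {
  # planted construct: ATG + 60 sense codons + TAA, recovered exactly
  set.seed(23)
  body60 <- tcmescan:::reverse_translate(
    paste0("M", tcmescan:::random_protein(59)))
  orf <- paste0(body60, "TAA")
  flank1 <- paste0(tcmescan:::random_dna(101), "TTAATTAATTAA")
  flank2 <- paste0("TTAATTAATTAA", tcmescan:::random_dna(100))
  seqc <- paste0(flank1, orf, flank2)
  got <- find_orfs(seqc, min_len = 50L)
  st <- nchar(flank1)
  expect_true(any(got$start == st & got$end == st + nchar(orf) &
                    got$strand == "+"))
  # same construct on the reverse strand
  got2 <- find_orfs(revcomp(seqc), min_len = 50L)
  L <- nchar(seqc)
  expect_true(any(got2$start == L - (st + nchar(orf)) &
                    got2$end == L - st & got2$strand == "-"))
  # random sequences against the brute-force oracle
  for (k in 1:20) {
    rnd <- tcmescan:::random_dna(800)
    a <- find_orfs(rnd, min_len = 20L)
    b <- oracle_orfs(rnd, min_len = 20L)
    expect_equal(nrow(a), nrow(b), info = paste("case", k))
    key <- function(d) sort(paste(d$start, d$end, d$strand))
    expect_equal(key(a), key(b), info = paste("case", k))
  }
})

test_that("role assignment follows motif rules and shuffle controls", {
  y1 <- TPL$orfA_protein[TPL$subgroup == "IS605b"]
  r <- assign_role(y1, PROF, THR)
  expect_equal(r$role, "Y1")
  expect_match(r$evidence, "HuH")
  tb <- assign_role(TPL$tnpb_protein[1], PROF, THR)
  expect_equal(tb$role, "TnpB")
  # shuffled Y1: motifs destroyed, no role
  set.seed(24)
  shuffled <- paste0(sample(strsplit(y1, "")[[1]]), collapse = "")
  # re-shuffle until the chance motif is absent, then expect no Y1 call
  while (grepl("H.H.*Y.*Q", shuffled)) {
    shuffled <- paste0(sample(strsplit(y1, "")[[1]]), collapse = "")
  }
  expect_false(assign_role(shuffled, PROF, THR)$role == "Y1")
  # with a reference library, junk in the SR length range is not SR
  set.seed(25)
  junk <- tcmescan:::random_protein(180)
  expect_equal(assign_role(junk, PROF, THR, REF$orfA)$role, "unknown")
})

test_that("boundary detection finds planted repeats and honors IS607 semantics", {
  set.seed(26)
  # planted perfect 10-nt-stem / 4-nt-loop palindrome in the LE window
  arm <- "GATTCCAGTC"
  pal <- paste0(arm, "TTTT", revcomp(arm))
  orf_block <- paste0("TTAATTAATTAA",
                      tcmescan:::reverse_translate(
                        paste0("M", tcmescan:::random_protein(99))), "TAA")
  # CCCCC after the palindrome cannot pair with the TTAT before it, so the
  # planted stem cannot extend by chance
  seqc <- paste0(tcmescan:::random_dna(60), "TTAT", pal, "CCCCC",
                 tcmescan:::random_dna(15), orf_block,
                 tcmescan:::random_dna(260))
  orf_lo <- 60 + 4 + nchar(pal) + 20 + 12
  orf_hi <- orf_lo + 303
  bd <- detect_boundaries(seqc, orf_lo, orf_hi, "inverted")
  expect_false(is.null(bd$le))
  expect_equal(bd$le$stem_len, 10L)
  expect_equal(bd$le$start, 64L)
  expect_equal(bd$le$tetramer, "TTAT")

  # IS607-mode template ends: no inverted repeat call, direct repeats found
  t607 <- TPL[TPL$subgroup == "IS607b", ]
  f <- t607$features[[1]]
  lo <- min(f$start[f$feature %in% c("orfA", "tnpB")])
  hi <- max(f$end[f$feature %in% c("orfA", "tnpB")])
  # the subterminal windows proper carry no inverted repeat
  inv <- detect_boundaries(t607$sequence, lo, hi, "inverted",
                           boundary_params(overhang = 0L))
  expect_true(is.null(inv$le) && is.null(inv$re))
  dir <- detect_boundaries(t607$sequence, lo, hi, "direct",
                           prefer_tetramers = c("TTAT", "TCAA", "TTCA"))
  expect_false(is.null(dir$le) || is.null(dir$re))
  expect_equal(dir$le$tetramer, t607$le_tetramer)
  expect_equal(dir$re$tetramer, t607$re_tetramer)
})

test_that("inverted-repeat search equals the exhaustive enumeration oracle", {
  set.seed(27)
  bp <- boundary_params()
  for (k in 1:30) {
    w <- tcmescan:::random_dna(120)
    got <- tcmescan:::filter_palindromes(
      tcmescan:::cpp_find_palindromes(tcmescan:::dna_to_int(w), bp$min_arm,
                                      bp$loop_range[1], bp$loop_range[2],
                                      bp$strong_max_mismatch), bp)
    ora <- oracle_palindromes(w)
    key <- function(m) {
      if (nrow(m) == 0) return(character(0))
      sort(paste(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5]))
    }
    expect_equal(key(got),
                 key(as.matrix(ora[, c("start", "end", "arm", "loop", "mm")])),
                 info = paste("case", k))
  }
})

test_that("completeness calls reduce to the LE/RE presence rule", {
  le <- list(side = "LE", repeat_kind = "inverted", stem_len = 10L,
             mismatches = 0L, n_occ = NA_integer_, tetramer = "TTAT")
  re <- list(side = "RE", repeat_kind = "inverted", stem_len = 10L,
             mismatches = 0L, n_occ = NA_integer_, tetramer = "TCAA")
  expect_equal(call_completeness(le, re), "full")
  expect_equal(call_completeness(le, NULL), "truncated_RE")
  expect_equal(call_completeness(NULL, re), "truncated_LE")
  expect_equal(call_completeness(NULL, NULL), "truncated_both")
  # with a known-motif set, an unidentifiable weak repeat does not count
  weak <- modifyList(le, list(tetramer = "GGGG", stem_len = 8L))
  expect_equal(call_completeness(weak, re, known_tetramers = c("TTAT", "TCAA")),
               "truncated_LE")
})

test_that("subgroup classification implements the orientation/overlap rules", {
  mk <- function(...) tibble::tibble(...)
  orfs <- mk(start = c(0L, 386L), end = c(400L, 1600L), strand = c("+", "+"),
             role = c("Y1", "TnpB"))
  expect_equal(classify_subgroup(orfs), "IS605a")     # 14-nt overlap
  orfs$end[1] <- 360L
  expect_equal(classify_subgroup(orfs), "IS605b")     # disjoint
  orfs$strand[1] <- "-"
  expect_equal(classify_subgroup(orfs), "IS605c")     # reverse direction
  sr <- mk(start = c(0L, 525L), end = c(500L, 1700L), strand = c("+", "+"),
           role = c("SR", "TnpB"))
  expect_equal(classify_subgroup(sr), "IS607b")       # 25-nt gap
  sr$start[2] <- 480L
  expect_equal(classify_subgroup(sr), "IS607a")       # overlapping
  only <- mk(start = 0L, end = 1200L, strand = "+", role = "TnpB")
  expect_equal(classify_subgroup(only), "IS1341")
  two <- mk(start = c(0L, 1500L), end = c(1200L, 2700L),
            strand = c("+", "+"), role = c("TnpB", "TnpB"))
  expect_equal(classify_subgroup(two), "unclassified")
  expect_error(classify_subgroup(mk(start = 0L, end = 10L, strand = "+",
                                    role = "Y1")), "TnpB")
})

test_that("the decay filter applies the strict >20 bp at >=80% identity rule", {
  set.seed(28)
  y1_cds <- REF$orfA_cds[1]
  # the flank IS the remnant, so the matched span cannot extend beyond it
  expect_true(decay_filter(substr(y1_cds, 50, 74), NA, y1_cds))    # 25 nt
  expect_false(decay_filter(substr(y1_cds, 50, 69), NA, y1_cds))   # 20 nt
  # clean random flanks never trip the filter (oracle cross-check)
  for (k in 1:20) {
    fl <- tcmescan:::random_dna(60)
    got <- decay_filter(fl, NA, y1_cds)
    if (got) {
      expect_true(oracle_decay(fl, y1_cds), info = paste("case", k))
    } else {
      expect_false(got)
    }
  }
  expect_error(decay_filter("ACGT", NA, character(0)), "empty")
})

test_that("family naming combines identity, cleavage sites and boundaries", {
  set.seed(29)
  base <- TPL$sequence[TPL$subgroup == "IS605b"]
  mutate95 <- function(s) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), round(0.05 * length(ch)))
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste0(ch, collapse = "")
  }
  refs <- tibble::tibble(name = "ISKno1", sequence = base,
                         le_tetramer = "TTAT", re_tetramer = "TCAA")
  cons <- tibble::tibble(
    family_id = c("f1", "f2", "f3"),
    sequence = c(mutate95(base), mutate95(base), tcmescan:::random_dna(1800)),
    le_tetramer = c("TTAT", "TTAT", "TTAT"),
    re_tetramer = c("TCAA", "TTCA", "TCAA"),   # f2: RE tetramer differs
    boundaries_ok = TRUE,
    species = "Escherichia coli")
  out <- assign_family(cons, refs)
  expect_equal(out$family_name[out$family_id == "f1"], "ISKno1")
  expect_true(out$known[out$family_id == "f1"])
  # >90% identical but mismatching RE tetramer: new name
  expect_false(out$known[out$family_id == "f2"])
  # deterministic new names per species
  expect_setequal(out$family_name[!out$known], c("ISEco1", "ISEco2"))
  expect_warning(assign_family(cons, NULL), "reference")
})
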