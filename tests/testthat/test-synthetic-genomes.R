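test_that("templates respect the structural conventions of every subgroup", {
  expect_setequal(TPL$subgroup, c("IS605a", "IS605b", "IS605c",
                                  "IS607a", "IS607b", "IS1341"))
  pr <- group_priors()
  for (i in seq_len(nrow(TPL))) {
    t <- TPL[i, ]
    f <- t$features[[1]]
    orfA <- f[f$feature == "orfA", ]
    tnpb <- f[f$feature == "tnpB", ]
    # TnpB CDS translates back to the stored protein
    cds <- substr(t$sequence, tnpb$start + 1, tnpb$end)
    expect_equal(translate_dna(cds), paste0(t$tnpb_protein, "*"))
    if (t$subgroup == "IS1341") {
      expect_equal(nrow(orfA), 0)
      expect_true(t$length >= pr$is1341_short_range[1] &&
                    t$length <= pr$is1341_long_range[2])
    } else {
      acds <- substr(t$sequence, orfA$start + 1, orfA$end)
      if (orfA$strand == "-") acds <- revcomp(acds)
      expect_equal(substr(translate_dna(acds), 1, nchar(t$orfA_protein)),
                   t$orfA_protein)
      overlap <- min(orfA$end, tnpb$end) - max(orfA$start, tnpb$start)
      if (t$subgroup %in% c("IS605a", "IS607a")) {
        expect_true(orfA$strand == "+" && overlap >= 1)
      } else if (t$subgroup %in% c("IS605b", "IS607b")) {
        expect_true(orfA$strand == "+" && overlap <= 0)
      } else {                      # IS605c: opposite strands
        expect_equal(orfA$strand, "-")
      }
    }
    if (t$group == "IS605") {
      expect_true(t$length >= pr$is605_length_range[1] &&
                    t$length <= pr$is605_length_range[2])
    }
    if (t$group == "IS607") {
      expect_true(t$length >= pr$is607_length_range[1] &&
                    t$length <= pr$is607_length_range[2])
      # direct repeats at both ends, unit present >= 2 times
      le <- f[f$feature == "le_repeat", ]
      block <- substr(t$sequence, le$start + 1, le$end)
      expect_gte(stringi::stri_count_fixed(block, t$le_stem), 2)
    } else {
      # palindromic ends: arm and reverse-complement arm flank the loop
      le <- f[f$feature == "le_repeat", ]
      block <- substr(t$sequence, le$start + 1, le$end)
      arm <- t$le_stem
      expect_equal(substr(block, 1, nchar(arm)), arm)
      expect_equal(substring(block, nchar(block) - nchar(arm) + 1),
                   revcomp(arm))
    }
    # Y1 motif structure
    if (t$subgroup %in% c("IS605a", "IS605b", "IS605c")) {
      expect_true(grepl("H.H.*Y.*Q", t$orfA_protein))
    }
    if (t$subgroup %in% c("IS607a", "IS607b")) {
      len <- nchar(t$orfA_protein)
      third <- substr(t$orfA_protein, floor(len / 3) + 1, ceiling(2 * len / 3))
      expect_true(grepl("S", third))
    }
    # TnpB catalytic D/E/D present
    expect_true(grepl("D.*E.*D", t$tnpb_protein))
  }
})

test_that("template generation is deterministic and priors are enforced", {
  expect_identical(TPL$sequence, tcme_templates(seed = 7)$sequence)
  expect_error(group_priors(is605_length_range = c(100, 50)), "range")
  tight <- group_priors(is605_length_range = c(600L, 650L))
  expect_error(tcme_templates(priors = tight, seed = 1), "length range")
})

test_that("simulation is deterministic, conservative and plants exact copies", {
  sim <- tcme_simulate(TPL, n_genomes = 2, genome_length = 60000,
                       divergence = 0, truncation_fraction = 0,
                       decay_fraction = 0, copy_number = setNames(
                         rep(0.5, 6), tcmescan:::SUBGROUPS), seed = 3)
  sim2 <- tcme_simulate(TPL, n_genomes = 2, genome_length = 60000,
                        divergence = 0, truncation_fraction = 0,
                        decay_fraction = 0, copy_number = setNames(
                          rep(0.5, 6), tcmescan:::SUBGROUPS), seed = 3)
  expect_identical(sim$genomes, sim2$genomes)
  expect_identical(sim$ledger, sim2$ledger)
  expect_equal(nchar(sim$genomes$sequence),
               rep(60000, nrow(sim$genomes)))
  # plant-ability: ledger coordinates recover the stored copy exactly
  for (i in seq_len(nrow(sim$ledger))) {
    r <- sim$ledger[i, ]
    ctg <- sim$genomes$sequence[sim$genomes$genome_id == r$genome_id &
                                  sim$genomes$contig_id == r$contig_id]
    expect_identical(substr(ctg, r$start + 1, r$end), r$sequence)
    # zero noise: the planted copy is an exact substring of its template
    tplseq <- TPL$sequence[TPL$template_id == r$template_id]
    planted <- if (r$strand == "-") revcomp(r$sequence) else r$sequence
    expect_true(grepl(planted, tplseq, fixed = TRUE))
  }
})

test_that("requested copy numbers are booked exactly and errors are explicit", {
  sim <- tcme_simulate(TPL, n_genomes = 1, genome_length = 80000,
                       divergence = 0, truncation_fraction = 0,
                       copy_number = c(IS605b = 3),
                       exact_copy_number = TRUE, seed = 11)
  expect_true(all(sim$ledger$subgroup == "IS605b"))
  expect_equal(nrow(sim$ledger), 3L)
  expect_error(
    tcme_simulate(TPL, n_genomes = 1, genome_length = 8000,
                  copy_number = c(IS605b = 10), seed = 1),
    "too short")
  expect_error(
    tcme_simulate(TPL, n_genomes = 1, genome_length = 50000,
                  copy_number = c(IS605b = -1), seed = 1),
    "negative")
  expect_error(
    tcme_simulate(TPL, n_genomes = 1, genome_length = 50000,
                  divergence = 1.5, seed = 1),
    "fraction")
})

test_that("truncated copies lose the corresponding end and tetramer", {
  sim <- tcme_simulate(TPL, n_genomes = 4, genome_length = 80000,
                       divergence = 0, truncation_fraction = 0.9,
                       decay_fraction = 0, seed = 21)
  tr <- sim$ledger[sim$ledger$completeness != "full", ]
  expect_gt(nrow(tr), 0)
  for (i in seq_len(nrow(tr))) {
    r <- tr[i, ]
    tpl <- TPL[TPL$template_id == r$template_id, ]
    oriented <- if (r$strand == "-") revcomp(r$sequence) else r$sequence
    if (r$completeness %in% c("truncated_LE", "truncated_both")) {
      expect_false(substr(oriented, 1, 4) == tpl$le_tetramer)
    } else {
      expect_equal(substr(oriented, 1, 4), tpl$le_tetramer)
    }
    if (r$completeness %in% c("truncated_RE", "truncated_both")) {
      expect_false(substring(oriented, nchar(oriented) - 3) == tpl$re_tetramer)
    } else {
      expect_equal(substring(oriented, nchar(oriented) - 3), tpl$re_tetramer)
    }
  }
})

test_that("decay copies carry an ORFA-derived remnant of the configured length", {
  sim <- tcme_simulate(TPL, n_genomes = 6, genome_length = 60000,
                       divergence = 0, truncation_fraction = 0,
                       decay_fraction = 1,
                       copy_number = c(IS1341 = 1.5),
                       decay_remnant_len = 30L, seed = 31)
  dec <- sim$ledger[sim$ledger$completeness == "decay", ]
  expect_gt(nrow(dec), 0)
  orfA_cds <- REF$orfA_cds
  for (i in seq_len(nrow(dec))) {
    oriented <- if (dec$strand[i] == "-") revcomp(dec$sequence[i]) else
      dec$sequence[i]
    # brute-force substring scan: a 30-nt exact window of some ORFA CDS
    found <- any(vapply(orfA_cds, function(cds) {
      any(vapply(seq_len(nchar(cds) - 29), function(j) {
        grepl(substr(cds, j, j + 29), oriented, fixed = TRUE)
      }, logical(1)))
    }, logical(1)))
    expect_true(found)
  }
})
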