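mk_census <- function(n, species = "Testus exemplaris", prefix = "g") {
  tibble::tibble(genome_id = sprintf("%s%04d", prefix, seq_len(n)),
                 species = species)
}

mk_elements <- function(genome_ids, subgroups,
                        completeness = "full", decay = FALSE) {
  tibble::tibble(genome_id = genome_ids, subgroup = subgroups,
                 group = sub("[abc]$", "", subgroups),
                 completeness = completeness, decay_flag = decay)
}

test_that("species summary reproduces the survey-table arithmetic", {
  # 12 genomes, 44 elements, all genomes positive
  census <- mk_census(12)
  set.seed(35)
  gids <- c(census$genome_id, sample(census$genome_id, 32, replace = TRUE))
  el <- mk_elements(gids, "IS605a")
  s <- species_summary(el, census)
  expect_equal(s$pct_genomes_with_tcme, 100)
  expect_equal(s$mean_copies, 3.67)
  expect_equal(s$n_full, 44)
  expect_equal(s$pct_full, 100)
  # 152 genomes, 126 positive -> 83%
  census2 <- mk_census(152)
  el2 <- mk_elements(census2$genome_id[1:126], "IS605b")
  expect_equal(species_summary(el2, census2)$pct_genomes_with_tcme, 83)
  # zero elements: NA mean, zero percent
  s0 <- species_summary(el2[0, ], census2)
  expect_equal(s0$pct_genomes_with_tcme, 0)
  expect_true(is.na(s0$mean_copies))
  expect_error(species_summary(mk_elements("nope", "IS605a"), census2),
               "absent")
})

test_that("summary cells equal a brute-force recount on random ledgers", {
  set.seed(36)
  for (k in 1:20) {
    census <- mk_census(sample(5:15, 1))
    n_el <- sample(0:40, 1)
    el <- mk_elements(
      sample(census$genome_id, n_el, replace = TRUE),
      sample(tcmescan:::SUBGROUPS, n_el, replace = TRUE),
      completeness = sample(c("full", "truncated_LE", "truncated_both"),
                            n_el, replace = TRUE),
      decay = runif(n_el) < 0.1)
    s <- species_summary(el, census)
    pos <- unique(el$genome_id)
    expect_equal(s$n_genomes_with_tcme, length(pos))
    expect_equal(s$n_tcmes, nrow(el))
    expect_equal(s$pct_genomes_with_tcme,
                 round_half_up(100 * length(pos) / nrow(census)))
    if (length(pos) > 0) {
      expect_equal(s$mean_copies, round_half_up(nrow(el) / length(pos), 2))
    }
    expect_equal(s$n_full, sum(el$completeness == "full" & !el$decay_flag))
    g <- group_summary(el, census)
    for (sg in tcmescan:::SUBGROUPS) {
      cnt <- length(unique(el$genome_id[el$subgroup == sg & !el$decay_flag]))
      expect_equal(g$n_genomes_containing[g$label == sg], cnt)
      expect_equal(g$pct[g$label == sg],
                   round_half_up(100 * cnt / nrow(census), 2))
    }
    is605 <- length(unique(el$genome_id[grepl("^IS605", el$subgroup) &
                                          !el$decay_flag]))
    expect_equal(g$n_genomes_containing[g$label == "IS605_total"], is605)
  }
})

test_that("group totals use set semantics over subgroups", {
  census <- mk_census(10)
  el <- mk_elements(c("g0001", "g0001", "g0002"),
                    c("IS605a", "IS605b", "IS1341"))
  g <- group_summary(el, census)
  expect_equal(g$n_genomes_containing[g$label == "IS605_total"], 1)
  expect_equal(g$pct[g$label == "IS605_total"], 10)
})

test_that("co-invasion counts are exact set intersections", {
  census <- mk_census(4)
  el <- mk_elements(c("g0001", "g0002", "g0002"),
                    c("IS605a", "IS605b", "IS1341"))
  co <- coinvasion_counts(el, census, c("IS605", "IS1341"))
  expect_equal(co$n_coinvaded, 1)
  one <- coinvasion_counts(el, census, "IS605")
  expect_equal(one$n_coinvaded, 2)   # degenerate case equals the group total
  expect_error(coinvasion_counts(el, census, "IS999"), "unknown")
  expect_error(coinvasion_counts(el, census, character(0)), "nonempty")
  # brute force on random ledgers
  set.seed(37)
  for (k in 1:20) {
    census <- mk_census(8)
    n_el <- sample(1:30, 1)
    el <- mk_elements(sample(census$genome_id, n_el, replace = TRUE),
                      sample(tcmescan:::SUBGROUPS, n_el, replace = TRUE))
    co <- coinvasion_counts(el, census, c("IS605", "IS607"))
    manual <- sum(vapply(census$genome_id, function(g) {
      sub <- el$group[el$genome_id == g]
      all(c("IS605", "IS607") %in% sub)
    }, logical(1)))
    expect_equal(co$n_coinvaded, manual)
  }
})

test_that("identity statistics report mean, population sd, min and max", {
  set.seed(38)
  p <- tcmescan:::random_protein(80)
  two <- tibble::tibble(class = "TnpB", id = c("a", "b"), sequence = c(p, p))
  s <- identity_stats(two)
  expect_equal(c(s$mean, s$min, s$max), c(100, 100, 100))
  expect_equal(s$sd, 0)
  one <- identity_stats(tibble::tibble(class = "Y1", id = "a", sequence = p))
  expect_true(is.na(one$mean))
  # hand-computable case: identities 1.0, 0.5, 0.5 -> mean 66.67
  core <- tcmescan:::random_protein(40)
  pa <- paste0(core, strrep("A", 40))
  pc <- paste0(core, strrep("C", 40))
  stopifnot(pairwise_identity(pa, pc) == 0.5)
  three <- tibble::tibble(class = "SR", id = c("a", "b", "c"),
                          sequence = c(pa, pa, pc))
  s3 <- identity_stats(three)
  expect_equal(round_half_up(s3$mean, 2), 66.67)
})

test_that("half-up rounding matches printed-table conventions", {
  expect_equal(round_half_up(82.89), 83)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.5), 3)     # base round() would give 2
  expect_equal(round_half_up(53.945, 2), 53.95)
  expect_equal(round_half_up(-2.5), -3)
})
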