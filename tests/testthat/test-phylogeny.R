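aln_from_rows <- function(rows) {
  tibble::tibble(id = names(rows), sequence = unname(rows))
}

test_that("protein distances are p-distances over comparable columns", {
  aln <- aln_from_rows(c(a = "MKVLMKVL", b = "MKVLMKVL", c = "MKVLMKVA"))
  d <- protein_distance(aln)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1 / 8)
  # rows differing at 3 of 100 ungapped columns
  set.seed(30)
  base <- strsplit(tcmescan:::random_protein(100), "")[[1]]
  mut <- base
  for (i in c(5, 50, 95)) mut[i] <- setdiff(tcmescan:::AA_ALPHABET, mut[i])[1]
  d2 <- protein_distance(aln_from_rows(c(
    x = paste0(base, collapse = ""), y = paste0(mut, collapse = ""),
    z = paste0(base, collapse = ""))))
  expect_equal(d2["x", "y"], 0.03)
  # counting oracle on random gapped alignments
  for (k in 1:20) {
    r <- random_alignment(5, 60, gap_frac = 0.1)
    d3 <- protein_distance(r)
    mat <- do.call(rbind, strsplit(r$sequence, ""))
    for (i in 1:4) for (j in (i + 1):5) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      expect_equal(d3[i, j], sum(mat[i, ok] != mat[j, ok]) / sum(ok))
    }
  }
  gappy <- aln_from_rows(c(a = "MK--", b = "--VL", c = "MKVL"))
  expect_error(protein_distance(gappy), "comparable")
})

test_that("neighbor joining realizes additive distances exactly", {
  # 3 taxa: closed-form branch lengths
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd[rownames(d), colnames(d)], d, tolerance = 1e-12)
  expect_error(neighbor_joining(matrix(c(0, 1, 1, 0), 2, 2)), "3 taxa")
  dns <- d
  dns[1, 2] <- 7
  expect_error(neighbor_joining(dns), "symmetric")
  # random additive matrices: topology recovered, path lengths reproduced
  set.seed(31)
  for (k in 1:30) {
    n <- sample(4:6, 1)
    true <- ape::rtree(n, br = function(x) runif(x, 0.1, 2))
    D <- ape::cophenetic.phylo(true)
    D <- D[sort(rownames(D)), sort(colnames(D))]
    tr <- neighbor_joining(D)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9, info = paste("case", k))
    # independent implementation agrees on the topology
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ape::nj(D))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are deterministic and saturate on clean signal", {
  # two clades, half the columns discriminating, no within-clade variation
  set.seed(32)
  pa <- tcmescan:::random_protein(60)
  pb <- local({
    ch <- strsplit(pa, "")[[1]]
    for (i in seq(1, 60, by = 2)) ch[i] <- setdiff(tcmescan:::AA_ALPHABET, ch[i])[1]
    paste0(ch, collapse = "")
  })
  aln <- aln_from_rows(c(a1 = pa, a2 = pa, b1 = pb, b2 = pb))
  tr <- bootstrap_support(aln, B = 100, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_equal(max(sup, na.rm = TRUE), 100)
  tr2 <- bootstrap_support(aln, B = 100, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
  expect_true(all(sup >= 0 & sup <= 100, na.rm = TRUE))
  expect_error(bootstrap_support(aln, B = 0, seed = 1), "B")
})

test_that("a planted two-clade split receives strong support", {
  set.seed(33)
  p1 <- tcmescan:::random_protein(120)
  p2 <- tcmescan:::random_protein(120)
  rows <- c(
    setNames(vapply(1:3, function(i) tcmescan:::mutate_protein(p1, 0.05),
                    character(1)), paste0("c1_", 1:3)),
    setNames(vapply(1:3, function(i) tcmescan:::mutate_protein(p2, 0.05),
                    character(1)), paste0("c2_", 1:3)))
  tr <- bootstrap_support(aln_from_rows(rows), B = 200, seed = 9)
  # locate the support of the c1 | c2 bipartition
  parts <- ape::prop.part(tr)
  n <- length(tr$tip.label)
  found <- NA
  for (pi in seq_along(parts)) {
    tips <- tr$tip.label[parts[[pi]]]
    if (length(tips) %in% c(3) &&
        (all(grepl("^c1_", tips)) || all(grepl("^c2_", tips)))) {
      found <- suppressWarnings(as.numeric(tr$node.label[pi]))
      if (!is.na(found)) break
    }
  }
  expect_gte(found, 90)
})

test_that("branch labelling roots on the outgroup and reports supported clades", {
  set.seed(34)
  bases <- replicate(4, tcmescan:::random_protein(150))
  out_base <- tcmescan:::random_protein(150)
  rows <- c(unlist(lapply(1:4, function(cl) {
    setNames(vapply(1:3, function(i) tcmescan:::mutate_protein(bases[cl], 0.04),
                    character(1)), paste0("cl", cl, "_", 1:3))
  })), setNames(vapply(1:2, function(i) tcmescan:::mutate_protein(out_base, 0.04),
                       character(1)), paste0("og", 1:2)))
  tr <- bootstrap_support(aln_from_rows(rows), B = 100, seed = 3)
  lab <- label_branches(tr, c("og1", "og2"))
  expect_setequal(lab$branch_group[grepl("^og", lab$taxon)], "outgroup")
  ingroups <- lab[!grepl("^og", lab$taxon), ]
  expect_equal(dplyr::n_distinct(ingroups$branch_group), 4)
  # every labelled group coincides with a planted clade
  for (g in unique(ingroups$branch_group)) {
    members <- ingroups$taxon[ingroups$branch_group == g]
    expect_equal(dplyr::n_distinct(sub("_[0-9]$", "", members)), 1)
  }
  expect_error(label_branches(tr, "missing_taxon"), "outgroup")
  # single ingroup clade is labelled A
  rows2 <- c(setNames(vapply(1:4, function(i)
    tcmescan:::mutate_protein(bases[1], 0.03), character(1)),
    paste0("m", 1:4)),
    setNames(vapply(1:2, function(i) tcmescan:::mutate_protein(out_base, 0.03),
                    character(1)), paste0("og", 1:2)))
  tr2 <- bootstrap_support(aln_from_rows(rows2), B = 50, seed = 4)
  lab2 <- label_branches(tr2, c("og1", "og2"))
  expect_setequal(lab2$branch_group[grepl("^m", lab2$taxon)], "A")
})
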