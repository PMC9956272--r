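# Synthetic genomes with planted TnpB-containing mobile elements and a
# machine-readable ground-truth ledger.  The generator is the test bed for
# every downstream stage: templates follow the structural conventions of the
# six TCME subgroups, planted copies can be diverged, truncated or decayed,
# and a fixed seed reproduces the dataset byte for byte.

SUBGROUPS <- c("IS605a", "IS605b", "IS605c", "IS607a", "IS607b", "IS1341")

# stop codons in all six frames; equal to its own reverse complement, so it
# insulates ORFs on either strand
STOP_CASSETTE <- "TTAATTAATTAA"

#' Structural length priors of the TCME groups
#'
#' Total-length and protein-length ranges used when drawing element
#' templates: IS605 elements span 1740-1950 nt with a Y1 transposase of
#' 102-164 aa; IS607 elements span 1620-2400 nt with a serine recombinase of
#' 150-217 aa; IS1341 elements fall in a short (1252-1393 nt) or long
#' (1512-2382 nt) class and encode TnpBs of 362-489 aa.
#'
#' @param is605_length_range,is607_length_range,is1341_short_range,is1341_long_range
#'   total element length ranges in nt.
#' @param y1_len_range,sr_len_range,tnpb_len_range,is1341_tnpb_len_range
#'   protein length ranges in aa.
#' @return a list of class `group_priors`.
#' @export
group_priors <- function(is605_length_range = c(1740L, 1950L),
                         is607_length_range = c(1620L, 2400L),
                         is1341_short_range = c(1252L, 1393L),
                         is1341_long_range = c(1512L, 2382L),
                         y1_len_range = c(102L, 164L),
                         sr_len_range = c(150L, 217L),
                         tnpb_len_range = c(340L, 489L),
                         is1341_tnpb_len_range = c(362L, 489L)) {
  pr <- list(is605_length_range = is605_length_range,
             is607_length_range = is607_length_range,
             is1341_short_range = is1341_short_range,
             is1341_long_range = is1341_long_range,
             y1_len_range = y1_len_range,
             sr_len_range = sr_len_range,
             tnpb_len_range = tnpb_len_range,
             is1341_tnpb_len_range = is1341_tnpb_len_range)
  for (nm in names(pr)) {
    r <- pr[[nm]]
    if (length(r) != 2 || r[1] > r[2]) {
      stop(sprintf("prior `%s` must be a nonempty range", nm), call. = FALSE)
    }
  }
  structure(pr, class = "group_priors")
}

# positions of the catalytic D / E / D in CANONICAL_RUVC (RuvC I/II/III)
RUVC_CATALYTIC <- c(7L, 65L, 94L)

# --- protein generators -----------------------------------------------------

# Y1 transposase: HuH triad near the N terminus, catalytic Y then Q in the
# C-terminal region
make_protein_y1 <- function(len) {
  p <- strsplit(random_protein(len), "", fixed = TRUE)[[1]]
  p[1] <- "M"
  tri <- 10L
  p[tri] <- "H"; p[tri + 2L] <- "H"
  ypos <- max(tri + 5L, floor(len * 0.75))
  qpos <- min(len - 2L, ypos + 6L)
  p[ypos] <- "Y"; p[qpos] <- "Q"
  paste0(p, collapse = "")
}

# serine recombinase: catalytic S inside the central third
make_protein_sr <- function(len) {
  p <- strsplit(random_protein(len), "", fixed = TRUE)[[1]]
  p[1] <- "M"
  p[floor(len / 2)] <- "S"
  paste0(p, collapse = "")
}

# TnpB: a mutated copy of the synthetic canonical RuvC domain embedded
# between random N-/C-terminal regions; catalytic D/E/D restored
make_protein_tnpb <- function(len, domain_divergence = 0.05) {
  stopifnot(len >= nchar(CANONICAL_RUVC) + 40)
  ctail <- 40L
  nhead <- len - nchar(CANONICAL_RUVC) - ctail
  dom <- strsplit(mutate_protein(CANONICAL_RUVC, domain_divergence),
                  "", fixed = TRUE)[[1]]
  can <- strsplit(CANONICAL_RUVC, "", fixed = TRUE)[[1]]
  dom[RUVC_CATALYTIC] <- can[RUVC_CATALYTIC]
  p <- paste0(random_protein(nhead), paste0(dom, collapse = ""),
              random_protein(ctail))
  p <- strsplit(p, "", fixed = TRUE)[[1]]
  p[1] <- "M"
  paste0(p, collapse = "")
}

# reverse-translate a protein to a CDS (no stop appended).  `force` is a
# named list position -> codon for positions needing a fixed codon.
CODONS_BY_AA <- split(names(GENETIC_CODE_11), GENETIC_CODE_11)

reverse_translate <- function(protein, force = list()) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  cods <- vapply(seq_along(aa), function(i) {
    if (!is.null(force[[as.character(i)]])) return(force[[as.character(i)]])
    opts <- CODONS_BY_AA[[aa[i]]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  cods[1] <- "ATG"
  paste0(cods, collapse = "")
}

# --- template assembly ------------------------------------------------------

PALIN_ARM <- 14L
PALIN_LOOP <- 5L
DR_UNIT <- 8L
DR_COPIES <- 3L

make_palindrome_block <- function(gc = 0.5) {
  arm <- random_dna(PALIN_ARM, gc)
  loop <- random_dna(PALIN_LOOP, gc)
  list(block = paste0(arm, loop, revcomp(arm)), arm = arm)
}

make_dr_block <- function(gc = 0.5) {
  unit <- random_dna(DR_UNIT, gc)
  seps <- replicate(DR_COPIES - 1, random_dna(2, gc))
  parts <- character(0)
  for (i in seq_len(DR_COPIES)) {
    parts <- c(parts, unit)
    if (i < DR_COPIES) parts <- c(parts, seps[i])
  }
  list(block = paste0(parts, collapse = ""), unit = unit)
}

# sample protein lengths so the assembled element lands inside the group's
# total-length prior; errors if the priors are contradictory
sample_lengths <- function(subgroup, priors) {
  ov <- 114L  # ends + spacers, see assemble_template
  if (subgroup %in% c("IS605a", "IS605b", "IS605c")) {
    tot <- priors$is605_length_range
    extra <- switch(subgroup, IS605a = -4L, IS605b = 20L, IS605c = 40L)
    # total = ov + extra + (3*y1+3) + (3*tnpb+3)
    lo <- tot[1] - ov - extra - 6L
    hi <- tot[2] - ov - extra - 6L
    y1r <- priors$y1_len_range
    tbr <- priors$tnpb_len_range
    for (try in 1:200) {
      y1 <- sample(y1r[1]:y1r[2], 1)
      lo_t <- max(tbr[1], ceiling(lo / 3) - y1)
      hi_t <- min(tbr[2], floor(hi / 3) - y1)
      if (lo_t <= hi_t) {
        return(list(orfA = y1, tnpb = sample(lo_t:hi_t, 1)))
      }
    }
    stop(sprintf("priors cannot fit Y1 and TnpB ORFs inside the IS605 length range (%d-%d nt)",
                 tot[1], tot[2]), call. = FALSE)
  }
  if (subgroup %in% c("IS607a", "IS607b")) {
    tot <- priors$is607_length_range
    ov607 <- 104L
    extra <- switch(subgroup, IS607a = -4L, IS607b = 20L)
    lo <- tot[1] - ov607 - extra - 6L
    hi <- tot[2] - ov607 - extra - 6L
    srr <- priors$sr_len_range
    tbr <- c(max(priors$tnpb_len_range[1], 361L),
             min(priors$tnpb_len_range[2], 447L))
    for (try in 1:200) {
      sr <- sample(srr[1]:srr[2], 1)
      lo_t <- max(tbr[1], ceiling(lo / 3) - sr)
      hi_t <- min(tbr[2], floor(hi / 3) - sr)
      if (lo_t <= hi_t) {
        return(list(orfA = sr, tnpb = sample(lo_t:hi_t, 1)))
      }
    }
    stop(sprintf("priors cannot fit SR and TnpB ORFs inside the IS607 length range (%d-%d nt)",
                 tot[1], tot[2]), call. = FALSE)
  }
  # IS1341: draw from the short or the long class
  tbr <- priors$is1341_tnpb_len_range
  cls <- sample(c("short", "long"), 1)
  tot <- if (cls == "short") priors$is1341_short_range else priors$is1341_long_range
  lo_t <- max(tbr[1], ceiling((tot[1] - 114L - 6L) / 3))
  hi_t <- min(tbr[2], floor((tot[2] - 114L - 6L) / 3))
  if (lo_t > hi_t) {
    stop(sprintf("priors cannot fit a TnpB ORF inside the IS1341 %s length range",
                 cls), call. = FALSE)
  }
  list(orfA = NA_integer_, tnpb = sample(lo_t:hi_t, 1))
}

# assemble one template; returns NULL if a structural check fails (caller
# retries with fresh random parts)
assemble_template <- function(subgroup, priors, gc, le_tet, re_tet) {
  lens <- sample_lengths(subgroup, priors)
  is607 <- subgroup %in% c("IS607a", "IS607b")
  le <- if (is607) make_dr_block(gc) else make_palindrome_block(gc)
  re <- if (is607) make_dr_block(gc) else make_palindrome_block(gc)

  tnpb_prot <- make_protein_tnpb(lens$tnpb)
  orfA_prot <- NA_character_
  orfA_cds <- NULL
  force_tnpb <- list()
  if (subgroup %in% c("IS605a", "IS607a")) {
    # 4-nt coding overlap via an ATGA junction: orfA's last sense codon is
    # GCA (Ala) followed by TGA; TnpB's second codon must begin with A
    p <- strsplit(tnpb_prot, "", fixed = TRUE)[[1]]
    p[2] <- "K"
    tnpb_prot <- paste0(p, collapse = "")
    force_tnpb[["2"]] <- "AAA"
  }
  tnpb_cds <- paste0(reverse_translate(tnpb_prot, force_tnpb), "TAA")

  orf_parts <- NULL
  if (subgroup != "IS1341") {
    alen <- lens$orfA
    orfA_prot <- if (is607) make_protein_sr(alen) else make_protein_y1(alen)
    if (subgroup %in% c("IS605a", "IS607a")) {
      pa <- strsplit(orfA_prot, "", fixed = TRUE)[[1]]
      pa[alen] <- "A"
      orfA_prot <- paste0(pa, collapse = "")
      forceA <- list()
      forceA[[as.character(alen)]] <- "GCA"
      orfA_cds <- paste0(reverse_translate(orfA_prot, forceA), "TGA")
    } else {
      orfA_cds <- paste0(reverse_translate(orfA_prot), "TAA")
    }
  }

  spacer_le <- paste0(random_dna(8, gc), STOP_CASSETTE)   # abuts first CDS
  spacer_re <- paste0(STOP_CASSETTE, random_dna(8, gc))   # follows last stop
  mid <- paste0(STOP_CASSETTE, random_dna(8, gc))         # between ORFs

  # element-relative feature assembly
  feats <- list()
  push <- function(feats, name, start, len, strand = "+") {
    feats[[length(feats) + 1]] <- tibble::tibble(
      feature = name, start = start, end = start + len, strand = strand)
    feats
  }
  pos <- 0L
  seqparts <- character(0)
  add <- function(x) {
    seqparts <<- c(seqparts, x)
    old <- pos
    pos <<- pos + nchar(x)
    old
  }
  feats <- push(feats, "le_tetramer", add(le_tet), 4L)
  feats <- push(feats, "le_repeat", add(le$block), nchar(le$block))
  add(spacer_le)
  aL <- nchar(orfA_cds %||% "")
  tL <- nchar(tnpb_cds)
  if (subgroup %in% c("IS605a", "IS607a")) {
    s <- add(substr(orfA_cds, 1, aL - 4L))
    feats <- push(feats, "orfA", s, aL)  # reconstituted by the ATGA junction
    s2 <- add(tnpb_cds)                  # tnpB ATG at s2; 4-nt coding overlap
    feats <- push(feats, "tnpB", s2, tL)
  } else if (subgroup %in% c("IS605b", "IS607b")) {
    s <- add(orfA_cds)
    feats <- push(feats, "orfA", s, aL)
    add(mid)
    s2 <- add(tnpb_cds)
    feats <- push(feats, "tnpB", s2, tL)
  } else if (subgroup == "IS605c") {
    s <- add(revcomp(orfA_cds))
    feats <- push(feats, "orfA", s, aL, strand = "-")
    add(mid)
    s2 <- add(tnpb_cds)
    feats <- push(feats, "tnpB", s2, tL)
  } else {
    s2 <- add(tnpb_cds)
    feats <- push(feats, "tnpB", s2, tL)
  }
  add(spacer_re)
  feats <- push(feats, "re_repeat", add(re$block), nchar(re$block))
  feats <- push(feats, "re_tetramer", add(re_tet), 4L)
  sequence <- paste0(seqparts, collapse = "")
  features <- dplyr::bind_rows(feats)

  # structural checks ------------------------------------------------------
  orf_lo <- min(features$start[features$feature %in% c("orfA", "tnpB")])
  orf_hi <- max(features$end[features$feature %in% c("orfA", "tnpB")])
  # a template is acceptable only if the boundary detector, run on the bare
  # template with its own cleavage motifs as anchors, recovers both ends at
  # their exact positions; this guarantees exact boundary recovery of
  # undiverged planted copies
  bp <- boundary_params()
  bd <- detect_boundaries(sequence, orf_lo, orf_hi,
                          mode = if (is607) "direct" else "inverted",
                          params = bp,
                          prefer_tetramers = c(le_tet, re_tet))
  if (is.null(bd$le) || is.null(bd$re)) return(NULL)
  if (bd$le$tetramer_start != 0L || bd$le$tetramer != le_tet) return(NULL)
  if (bd$re$tetramer_start != nchar(sequence) - 4L ||
      bd$re$tetramer != re_tet) return(NULL)
  if (is607) {
    # IS607 ends must carry no inverted repeat at or above the detection
    # minimum
    svec <- dna_to_int(sequence)
    for (win in list(svec[seq_len(orf_lo)],
                     svec[(orf_hi + 1):length(svec)])) {
      pal <- filter_palindromes(
        cpp_find_palindromes(win, bp$min_arm, bp$loop_range[1],
                             bp$loop_range[2], bp$strong_max_mismatch), bp)
      if (nrow(pal) > 0) return(NULL)
    }
  }

  # translation sanity
  tb <- features[features$feature == "tnpB", ]
  cds <- substr(sequence, tb$start + 1, tb$end)
  if (translate_dna(cds) != paste0(tnpb_prot, "*")) return(NULL)

  list(sequence = sequence, features = features,
       orfA_protein = orfA_prot, tnpb_protein = tnpb_prot,
       le_stem = if (is607) le$unit else le$arm,
       re_stem = if (is607) re$unit else re$arm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw TCME element templates
#'
#' Generates sequence templates for the six structural subgroups: IS605a
#' (Y1 and TnpB on the same strand, coding regions overlapping), IS605b
#' (same strand, separated), IS605c (opposite strands), IS607a/IS607b
#' (serine recombinase instead of Y1), and IS1341 (TnpB only).  IS605 and
#' IS1341 templates end in perfect subterminal palindromes; IS607 templates
#' carry short direct repeats and no detectable inverted repeat.  Cleavage
#' tetramers (default TTAT left, TCAA/TTCA right) sit immediately outside
#' the repeats at both ends.
#'
#' @param priors a [group_priors()] object.
#' @param n_per_subgroup number of templates per subgroup.
#' @param gc GC content of spacer and random protein-coding draws.
#' @param seed integer RNG seed; the same seed reproduces templates exactly.
#' @return tibble with one row per template: `template_id`, `subgroup`,
#'   `group`, `sequence`, `length`, `orfA_protein`, `tnpb_protein`,
#'   `le_stem`, `re_stem`, `le_tetramer`, `re_tetramer` and a `features`
#'   list-column of 0-based half-open feature intervals.
#' @export
tcme_templates <- function(priors = group_priors(), n_per_subgroup = 1L,
                           gc = 0.5, seed = 1L) {
  stopifnot(inherits(priors, "group_priors"), n_per_subgroup >= 1)
  withr::with_seed(seed, {
    rows <- list()
    for (sg in SUBGROUPS) {
      for (k in seq_len(n_per_subgroup)) {
        le_tet <- "TTAT"
        re_tet <- if (k %% 2 == 1) "TCAA" else "TTCA"
        tpl <- NULL
        for (try in 1:100) {
          tpl <- assemble_template(sg, priors, gc, le_tet, re_tet)
          if (!is.null(tpl)) break
        }
        if (is.null(tpl)) {
          stop(sprintf("failed to assemble a structurally valid %s template", sg),
               call. = FALSE)
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          template_id = sprintf("%s_t%d", sg, k),
          subgroup = sg,
          group = substr(sg, 1, nchar(sg) - ifelse(sg == "IS1341", 0, 1)),
          sequence = tpl$sequence,
          length = nchar(tpl$sequence),
          orfA_protein = tpl$orfA_protein,
          tnpb_protein = tpl$tnpb_protein,
          le_stem = tpl$le_stem,
          re_stem = tpl$re_stem,
          le_tetramer = le_tet,
          re_tetramer = re_tet,
          features = list(tpl$features)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

# --- planting ---------------------------------------------------------------

# shift/cut features after modifying the element sequence
shift_features <- function(features, at, delta) {
  dplyr::mutate(features,
    start = ifelse(.data$start >= at, .data$start + delta, .data$start),
    end = ifelse(.data$end > at, .data$end + delta, .data$end))
}

# constrained substitution mutation: expected per-site rate `rate`;
# positions inside cleavage tetramers are left untouched and substitutions
# that create a premature stop (or destroy a start codon) inside a CDS
# feature are redrawn or skipped, emulating purifying selection on active
# copies
mutate_element <- function(sequence, features, rate) {
  if (rate <= 0) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  protected <- rep(FALSE, L)
  tets <- features[features$feature %in% c("le_tetramer", "re_tetramer"), ]
  for (i in seq_len(nrow(tets))) {
    protected[(tets$start[i] + 1):tets$end[i]] <- TRUE
  }
  cds <- features[features$feature %in% c("orfA", "tnpB"), ]
  pos <- which(runif(L) < rate)
  for (p in pos) {
    if (protected[p]) next
    alts <- sample(setdiff(c("A", "C", "G", "T"), chars[p]))
    placed <- FALSE
    for (alt in alts) {
      bad <- FALSE
      for (i in seq_len(nrow(cds))) {
        if (p <= cds$start[i] || p > cds$end[i]) next
        # codon containing p within this CDS (1-based p)
        if (cds$strand[i] == "+") {
          off <- (p - 1 - cds$start[i]) %% 3
          c0 <- p - off
          codon <- chars[c0:(c0 + 2)]
          codon[off + 1] <- alt
          cod <- paste0(codon, collapse = "")
          if (c0 == cds$start[i] + 1 && cod != "ATG") bad <- TRUE
          if (c0 < cds$end[i] - 2 && GENETIC_CODE_11[[cod]] == "*") bad <- TRUE
        } else {
          off <- (cds$end[i] - p) %% 3
          c0 <- p + off           # last base of the codon on forward strand
          codon <- chars[(c0 - 2):c0]
          codon[3 - off] <- alt
          cod <- revcomp(paste0(codon, collapse = ""))
          if (c0 == cds$end[i] && cod != "ATG") bad <- TRUE
          if (c0 > cds$start[i] + 3 && GENETIC_CODE_11[[cod]] == "*") bad <- TRUE
        }
        if (bad) break
      }
      if (!bad) {
        chars[p] <- alt
        placed <- TRUE
        break
      }
    }
    # if every alternative is disruptive the site is skipped
  }
  paste0(chars, collapse = "")
}

# build one planted copy from a template row; returns list(sequence,
# completeness)
realize_copy <- function(tpl, completeness, divergence, decay_remnant,
                         decay_remnant_len) {
  sequence <- tpl$sequence
  features <- tpl$features[[1]]
  if (completeness == "decay") {
    # insert an orfA-derived remnant upstream of the TnpB CDS, insulated by
    # a stop cassette so it can never be absorbed into the predicted ORF
    at <- features$start[features$feature == "tnpB"]
    ins <- paste0(decay_remnant, STOP_CASSETTE)
    sequence <- paste0(substr(sequence, 1, at), ins, substring(sequence, at + 1))
    features <- shift_features(features, at, nchar(ins))
  }
  if (completeness %in% c("truncated_LE", "truncated_both")) {
    cut <- features$end[features$feature == "le_repeat"]
    sequence <- substring(sequence, cut + 1)
    features <- features[!features$feature %in% c("le_tetramer", "le_repeat"), ]
    features <- shift_features(features, 0L, -cut)
  }
  if (completeness %in% c("truncated_RE", "truncated_both")) {
    cut <- features$start[features$feature == "re_repeat"]
    sequence <- substr(sequence, 1, cut)
    features <- features[!features$feature %in% c("re_tetramer", "re_repeat"), ]
  }
  sequence <- mutate_element(sequence, features, divergence)
  sequence
}

#' Simulate genomes with planted TCME copies
#'
#' Builds `n_genomes` multi-contig genomes of i.i.d. background nucleotides
#' at the configured GC content, plants element copies drawn per subgroup
#' from Poisson counts, and returns the genomes together with a ground-truth
#' ledger.  Planted copies are diverged by a substitution-only model that
#' emulates purifying selection (no premature stops in CDS features, intact
#' cleavage tetramers); a configurable fraction is truncated (LE, RE or
#' both; the repeat and its tetramer are removed) and a fraction of IS1341
#' copies carries a short Y1/SR-derived remnant and is recorded as `decay`.
#' Elements are placed on one strand at random, never across contig ends,
#' and never closer than `min_gap` nt.
#'
#' @param templates template tibble from [tcme_templates()].
#' @param n_genomes number of genomes.
#' @param genome_length total genome length in nt (split over contigs).
#' @param n_contigs contigs per genome.
#' @param gc background GC fraction.
#' @param copy_number named vector of per-subgroup Poisson means.
#' @param exact_copy_number if `TRUE`, plant exactly `round(copy_number)`
#'   copies per genome instead of Poisson draws.
#' @param divergence expected per-site substitution rate of planted copies.
#' @param truncation_fraction fraction of copies with an end deleted.
#' @param decay_fraction fraction of IS1341 copies converted to decays.
#' @param decay_remnant_len remnant length in nt for decay copies.
#' @param min_gap minimum spacing between planted copies in nt.
#' @param species species label recorded for all genomes.
#' @param seed integer RNG seed; fully determines the output.
#' @return list of class `tcme_sim` with `genomes` (tibble: `genome_id`,
#'   `contig_id`, `species`, `sequence`), `ledger` (tibble: `genome_id`,
#'   `contig_id`, `start`, `end`, `strand`, `subgroup`, `completeness`,
#'   `template_id`, `sequence`; coordinates 0-based half-open) and
#'   `templates`.
#' @export
tcme_simulate <- function(templates, n_genomes = 20L, genome_length = 500000L,
                          n_contigs = 1L, gc = 0.5,
                          copy_number = NULL, exact_copy_number = FALSE,
                          divergence = 0.02, truncation_fraction = 0.15,
                          decay_fraction = 0.15, decay_remnant_len = 30L,
                          min_gap = 2500L,
                          species = "Synthetica primaria", seed = 1L) {
  stopifnot(nrow(templates) > 0, n_genomes >= 1, n_contigs >= 1)
  if (divergence < 0 || divergence > 1 || truncation_fraction < 0 ||
      truncation_fraction > 1 || decay_fraction < 0 || decay_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(copy_number)) {
    copy_number <- setNames(rep(0.8, length(SUBGROUPS)), SUBGROUPS)
  }
  if (any(copy_number < 0)) stop("negative copy numbers", call. = FALSE)
  copy_number <- copy_number[intersect(names(copy_number), unique(templates$subgroup))]

  # remnant source: a central slice of an orfA CDS from the template set
  orfA_tpl <- templates[!is.na(templates$orfA_protein), ]

  withr::with_seed(seed, {
    genome_rows <- list()
    ledger_rows <- list()
    contig_len <- rep(genome_length %/% n_contigs, n_contigs)
    contig_len[1] <- contig_len[1] + genome_length %% n_contigs
    for (g in seq_len(n_genomes)) {
      gid <- sprintf("g%03d", g)
      # draw copies for this genome
      copies <- list()
      for (sg in names(copy_number)) {
        n <- if (exact_copy_number) {
          as.integer(round(copy_number[[sg]]))
        } else {
          rpois(1, copy_number[[sg]])
        }
        if (n == 0) next
        tpls <- which(templates$subgroup == sg)
        for (k in seq_len(n)) {
          ti <- tpls[sample.int(length(tpls), 1)]
          tpl <- templates[ti, ]
          completeness <- "full"
          if (sg == "IS1341" && runif(1) < decay_fraction) {
            completeness <- "decay"
          } else if (runif(1) < truncation_fraction) {
            completeness <- sample(c("truncated_LE", "truncated_RE",
                                     "truncated_both"), 1,
                                   prob = c(0.4, 0.4, 0.2))
          }
          remnant <- NA_character_
          if (completeness == "decay") {
            if (nrow(orfA_tpl) == 0) {
              completeness <- "full"
            } else {
              src <- orfA_tpl[sample.int(nrow(orfA_tpl), 1), ]
              f <- src$features[[1]]
              a <- f[f$feature == "orfA", ]
              cds <- substr(src$sequence, a$start + 1, a$end)
              if (a$strand == "-") cds <- revcomp(cds)
              st <- sample.int(nchar(cds) - decay_remnant_len, 1)
              remnant <- substr(cds, st, st + decay_remnant_len - 1)
            }
          }
          seqc <- realize_copy(tpl, completeness, divergence, remnant,
                               decay_remnant_len)
          strand <- sample(c("+", "-"), 1)
          copies[[length(copies) + 1]] <- list(
            subgroup = sg, template_id = tpl$template_id,
            completeness = completeness, strand = strand,
            sequence = if (strand == "+") seqc else revcomp(seqc))
        }
      }
      # assign copies to contigs and positions
      if (length(copies) > 0) {
        ci <- sample.int(n_contigs, length(copies), replace = TRUE)
      } else {
        ci <- integer(0)
      }
      for (cc in seq_len(n_contigs)) {
        cid <- sprintf("c%02d", cc)
        idx <- which(ci == cc)
        elems <- copies[idx]
        elen <- vapply(elems, function(e) nchar(e$sequence), integer(1))
        bg_total <- contig_len[cc] - sum(elen)
        need <- (length(elems) + 1) * min_gap
        if (bg_total < need) {
          stop(sprintf("genome %s contig %s too short for %d planted copies",
                       gid, cid, length(elems)), call. = FALSE)
        }
        # background split into length(elems)+1 gaps, each >= min_gap
        ngap <- length(elems) + 1
        freearea <- bg_total - ngap * min_gap
        cuts <- sort(sample.int(freearea + 1, ngap - 1, replace = TRUE) - 1L)
        gaps <- diff(c(0L, cuts, freearea)) + min_gap
        parts <- character(0)
        posn <- 0L
        for (k in seq_len(ngap)) {
          parts <- c(parts, random_dna(gaps[k], gc))
          posn <- posn + gaps[k]
          if (k <= length(elems)) {
            e <- elems[[k]]
            ledger_rows[[length(ledger_rows) + 1]] <- tibble::tibble(
              genome_id = gid, contig_id = cid,
              start = posn, end = posn + nchar(e$sequence),
              strand = e$strand, subgroup = e$subgroup,
              completeness = e$completeness, template_id = e$template_id,
              sequence = e$sequence)
            parts <- c(parts, e$sequence)
            posn <- posn + nchar(e$sequence)
          }
        }
        genome_rows[[length(genome_rows) + 1]] <- tibble::tibble(
          genome_id = gid, contig_id = cid, species = species,
          sequence = paste0(parts, collapse = ""))
      }
    }
    structure(list(genomes = dplyr::bind_rows(genome_rows),
                   ledger = if (length(ledger_rows) > 0) {
                     dplyr::bind_rows(ledger_rows)
                   } else {
                     tibble::tibble(genome_id = character(0),
                                    contig_id = character(0),
                                    start = integer(0), end = integer(0),
                                    strand = character(0),
                                    subgroup = character(0),
                                    completeness = character(0),
                                    template_id = character(0),
                                    sequence = character(0))
                   },
                   templates = templates,
                   config = list(n_genomes = n_genomes,
                                 genome_length = genome_length,
                                 n_contigs = n_contigs, gc = gc,
                                 copy_number = copy_number,
                                 divergence = divergence,
                                 truncation_fraction = truncation_fraction,
                                 decay_fraction = decay_fraction,
                                 decay_remnant_len = decay_remnant_len,
                                 min_gap = min_gap, species = species,
                                 seed = seed)),
              class = "tcme_sim")
  })
}

#' @export
print.tcme_sim <- function(x, ...) {
  cat("<tcme_sim> ", length(unique(x$genomes$genome_id)), " genomes, ",
      nrow(x$ledger), " planted copies\n", sep = "")
  invisible(x)
}
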