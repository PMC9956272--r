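# Independent brute-force implementations used as oracles.  These are
# written directly from the definitions (plain recursion / exhaustive
# enumeration / naive counting) and share no code with the package
# internals they check.

# best global alignment score of a vs b with affine gaps
# (gap of length L costs gap_open + (L-1)*gap_extend), by plain recursion
oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                gap_open = 2, gap_extend = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  memo <- new.env()
  # best score of aligning prefixes a[1..i], b[1..j] with the last column
  # being `state` (M = aligned pair, E = gap in a, F = gap in b)
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- -Inf
    if (state == "M") {
      if (i > 0 && j > 0) {
        sc <- if (av[i] == bv[j]) match else mismatch
        prev <- if (i == 1 && j == 1) 0 else
          max(rec(i - 1, j - 1, "M"), rec(i - 1, j - 1, "E"),
              rec(i - 1, j - 1, "F"))
        val <- sc + prev
      }
    } else if (state == "E") {  # gap in a, consumes b[j]
      if (j > 0) {
        val <- max(rec(i, j - 1, "M") - gap_open,
                   rec(i, j - 1, "F") - gap_open,
                   rec(i, j - 1, "E") - gap_extend)
        if (i == 0 && j == 1) val <- max(val, -gap_open)
      }
    } else {  # F: gap in b, consumes a[i]
      if (i > 0) {
        val <- max(rec(i - 1, j, "M") - gap_open,
                   rec(i - 1, j, "E") - gap_open,
                   rec(i - 1, j, "F") - gap_extend)
        if (j == 0 && i == 1) val <- max(val, -gap_open)
      }
    }
    memo[[key]] <- val
    val
  }
  n <- length(av)
  m <- length(bv)
  max(rec(n, m, "M"), rec(n, m, "E"), rec(n, m, "F"))
}

# glocal score: a aligned globally against the best contiguous substring of
# b (terminal gaps around a's alignment are free)
oracle_glocal_score <- function(a, b, ...) {
  m <- nchar(b)
  best <- -Inf
  for (p in 1:m) {
    for (q in p:m) {
      best <- max(best, oracle_global_score(a, substr(b, p, q), ...))
    }
  }
  best
}

# all maximal ORFs by exhaustive start-codon walking
oracle_orfs <- function(sequence, min_len = 50L) {
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") toupper(sequence) else revcomp(sequence)
    L <- nchar(s)
    for (st in seq_len(max(0, L - 2))) {
      if (!substr(s, st, st + 2) %in% c("ATG", "GTG", "TTG")) next
      j <- st
      repeat {
        j <- j + 3
        if (j + 2 > L) break
        cj <- substr(s, j, j + 2)
        if (cj %in% c("TAA", "TAG", "TGA")) {
          if ((j - st) / 3 >= min_len) {
            a0 <- st - 1          # 0-based on this strand
            b0 <- j + 2           # stop included
            if (strand == "-") {
              tmp <- a0
              a0 <- L - b0
              b0 <- L - tmp
            }
            out[[length(out) + 1]] <- data.frame(
              start = a0, end = b0, strand = strand,
              stop_key = paste(strand, if (strand == "+") b0 else a0))
          }
          break
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  df <- do.call(rbind, out)
  # longest ORF per stop (earliest start on the coding strand)
  keep <- do.call(rbind, lapply(split(df, df$stop_key), function(g) {
    g[which.max(g$end - g$start), ]
  }))
  keep <- keep[order(keep$start, keep$strand), c("start", "end", "strand")]
  rownames(keep) <- NULL
  keep
}

# maximal trimmed inverted repeats, re-derived from the definition
oracle_palindromes <- function(sequence, min_arm = 8L, loop_min = 3L,
                               loop_max = 15L, mm_short = 1L,
                               strong_arm = 12L, mm_long = 2L) {
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(s)
  rows <- list()
  for (L in loop_min:loop_max) {
    for (i in seq_len(n)) {     # i = last base of left arm (1-based)
      r1 <- i + L + 1
      if (r1 > n) next
      pairs <- logical(0)
      k <- 0
      while (i - k >= 1 && r1 + k <= n) {
        k <- k + 1
        lc <- s[i - k + 1]
        rc <- s[r1 + k - 1]
        pairs[k] <- !is.na(comp[lc]) && identical(unname(comp[lc]), rc)
      }
      if (length(pairs) == 0 || !pairs[1]) next
      best <- function(budget) {
        arm <- 0
        mm <- 0
        bestarm <- 0
        bestmm <- 0
        for (k in seq_along(pairs)) {
          if (!pairs[k]) {
            mm <- mm + 1
            if (mm > budget) break
          }
          arm <- k
          if (pairs[k]) { bestarm <- k; bestmm <- mm }
        }
        c(bestarm, bestmm)
      }
      b1 <- best(mm_long)  # scan with the widest budget, then restrict
      # maximal arm with <= mm_short mismatches
      a_s <- 0; m_s <- 0; mm <- 0
      for (k in seq_along(pairs)) {
        if (!pairs[k]) { mm <- mm + 1; if (mm > mm_short) break }
        if (pairs[k]) { a_s <- k; m_s <- mm }
      }
      add <- function(arm, mm) {
        ok <- (arm >= min_arm && mm <= mm_short) ||
          (arm >= strong_arm && mm <= mm_long)
        if (ok) {
          rows[[length(rows) + 1]] <<- data.frame(
            start = i - arm, end = i + L + arm, arm = arm, loop = L, mm = mm)
        }
      }
      add(a_s, m_s)
      if (b1[1] > a_s) add(b1[1], b1[2])
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), end = integer(0), arm = integer(0),
                      loop = integer(0), mm = integer(0)))
  }
  df <- unique(do.call(rbind, rows))
  df[order(df$start, df$loop, df$arm), ]
}

# longest exact-substring style decay check: does any window of >= (min+1)
# nt of `flank` match some equally long window of a reference at >= 80%?
oracle_decay <- function(flank, references, min_match = 20L,
                         min_identity = 0.8) {
  w <- min_match + 1L
  for (ref in references) {
    for (rs in c(ref, revcomp(ref))) {
      nf <- nchar(flank)
      nr <- nchar(rs)
      if (nf < w || nr < w) next
      for (len in w:min(nf, nr)) {
        for (i in seq_len(nf - len + 1)) {
          fa <- strsplit(substr(flank, i, i + len - 1), "")[[1]]
          for (j in seq_len(nr - len + 1)) {
            rb <- strsplit(substr(rs, j, j + len - 1), "")[[1]]
            if (mean(fa == rb) >= min_identity) return(TRUE)
          }
        }
        break  # windows of w suffice: longer matches contain one
      }
    }
  }
  FALSE
}

# naive per-column consensus
oracle_consensus <- function(aln) {
  mat <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
  keep <- which(colMeans(mat == "-") < 0.5)
  paste0(vapply(keep, function(k) {
    col <- mat[, k]
    col <- col[col != "-"]
    tb <- sort(table(col), decreasing = TRUE)
    sort(names(tb)[tb == max(tb)])[1]
  }, character(1)), collapse = "")
}

# random protein alignment (gap-free rows of equal length, then gaps poked)
random_alignment <- function(nrow, ncol, gap_frac = 0.1) {
  rows <- vapply(seq_len(nrow), function(i) {
    chars <- sample(tcmescan:::AA_ALPHABET, ncol, replace = TRUE)
    gaps <- runif(ncol) < gap_frac
    chars[gaps] <- "-"
    paste0(chars, collapse = "")
  }, character(1))
  tibble::tibble(id = paste0("r", seq_len(nrow)), sequence = rows)
}
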