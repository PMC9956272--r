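#' Round half away from zero at a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; printed summary tables in the IS
#' annotation literature use conventional half-up rounding, so table outputs
#' go through this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(82.895, 2)  # 82.9
#' round_half_up(0.5)        # 1
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# uppercase and validate a DNA string
clean_dna <- function(x) {
  x <- toupper(x)
  if (stringi::stri_detect_regex(x, "[^ACGTN]")) {
    stop("sequence contains characters outside ACGTN", call. = FALSE)
  }
  x
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtN", "TGCAtgcaN", x))
}

# DNA string -> integer codes A=0 C=1 G=2 T=3, others 8
.dna_lut <- local({
  lut <- rep(8L, 256)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  lut[utf8ToInt("a") + 1L] <- 0L
  lut[utf8ToInt("c") + 1L] <- 1L
  lut[utf8ToInt("g") + 1L] <- 2L
  lut[utf8ToInt("t") + 1L] <- 3L
  lut
})

dna_to_int <- function(x) {
  .dna_lut[as.integer(charToRaw(x)) + 1L]
}

int_to_dna <- function(v) {
  rawToChar(as.raw(utf8ToInt("ACGTNNNNN")[v + 1L]))
}

# amino-acid alphabet used throughout (alphabetical one-letter codes)
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.aa_lut <- local({
  lut <- rep(25L, 256)
  for (i in seq_along(AA_ALPHABET)) {
    lut[utf8ToInt(AA_ALPHABET[i]) + 1L] <- i - 1L
    lut[utf8ToInt(tolower(AA_ALPHABET[i])) + 1L] <- i - 1L
  }
  lut
})

aa_to_int <- function(x) {
  .aa_lut[as.integer(charToRaw(x)) + 1L]
}

# classify sequence alphabet; used to refuse mixed nt/aa comparisons
guess_alphabet <- function(x) {
  if (!stringi::stri_detect_regex(x, "[^ACGTUN-]")) "nt" else "aa"
}

# random DNA of length n at a given GC content (order-0 background)
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# random protein of length n, uniform over the 20 residues
random_protein <- function(n) {
  paste0(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# deterministic integer sub-seed derived from a base seed and a tag,
# kept below 2^31
derive_seed <- function(seed, tag) {
  s <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  (as.integer(seed) %% 1000003L) * 1009L + (s %% 99991L)
}

# tibble(id, sequence) input checker used across the sequence-set API
check_seqset <- function(x, arg = "seqs") {
  if (!is.data.frame(x) || !all(c("id", "sequence") %in% names(x))) {
    stop(sprintf("`%s` must be a data frame with columns `id` and `sequence`", arg),
         call. = FALSE)
  }
  if (anyDuplicated(x$id)) stop(sprintf("duplicated ids in `%s`", arg), call. = FALSE)
  tibble::as_tibble(x)
}
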