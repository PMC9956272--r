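# Bacterial genetic code (translation table 11).  The codon-to-residue map is
# identical to the standard code; table 11 differs only in its wider set of
# initiation codons (ATG/GTG/TTG are accepted as starts by the ORF finder).

GENETIC_CODE_11 <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

START_CODONS <- c("ATG", "GTG", "TTG")

#' Translate a DNA sequence under the bacterial genetic code
#'
#' Translates frame +1 of `x` using translation table 11.  Stop codons are
#' rendered `*`; codons containing N (or a trailing partial codon) become `X`.
#'
#' @param x a DNA string (ACGTN).
#' @return an amino-acid string of length `floor(nchar(x) / 3)`.
#' @export
#' @examples
#' translate_dna("ATGAAATAA")  # "MK*"
translate_dna <- function(x) {
  x <- toupper(x)
  n <- nchar(x) %/% 3
  if (n == 0) return("")
  codons <- substring(x, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- unname(GENETIC_CODE_11[codons])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

#' Six-frame translation with coordinate maps
#'
#' Translates a contig in all six reading frames (+1..+3 on the forward
#' strand, -1..-3 on the reverse complement) under the bacterial code.
#'
#' @param sequence a DNA string.
#' @return a tibble with columns `frame` (+1,+2,+3,-1,-2,-3), `strand`,
#'   `offset` (0-based nt offset of the frame's first codon on its own
#'   strand) and `protein`.  Use [frame_to_genomic()] to map amino-acid
#'   intervals back to forward-strand nucleotide coordinates.
#' @export
six_frame_translate <- function(sequence) {
  sequence <- toupper(sequence)
  rc <- revcomp(sequence)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  tibble::tibble(
    frame = frames,
    strand = ifelse(frames > 0, "+", "-"),
    offset = abs(frames) - 1L,
    protein = purrr::map_chr(frames, function(f) {
      s <- if (f > 0) sequence else rc
      translate_dna(substring(s, abs(f)))
    })
  )
}

#' Map an amino-acid interval in a reading frame to genomic coordinates
#'
#' @param frame reading frame, one of +1,+2,+3,-1,-2,-3.
#' @param aa_start,aa_end 0-based half-open amino-acid interval within the
#'   frame's translation.
#' @param contig_len length of the contig in nt.
#' @return integer vector `c(start, end)`: the 0-based half-open
#'   forward-strand nucleotide interval covering those codons.
#' @export
frame_to_genomic <- function(frame, aa_start, aa_end, contig_len) {
  off <- abs(frame) - 1L
  nt_start <- off + 3L * aa_start      # on the frame's own strand
  nt_end <- off + 3L * aa_end
  if (frame > 0) {
    c(nt_start, nt_end)
  } else {
    c(contig_len - nt_end, contig_len - nt_start)
  }
}
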