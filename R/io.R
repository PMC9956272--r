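# Standard-format readers and writers: FASTA genomes, TSV tables, GFF3,
# BED6, Newick and PHYLIP, plus a result writer with a checksum manifest.

#' Read genomes from multi-FASTA files
#'
#' Headers are expected as `<genome_id>|<contig_id>`; a header without
#' `|` becomes a single-contig genome with contig id `c01`.
#'
#' @param paths FASTA file paths.
#' @param species species label applied to all genomes (recycled).
#' @return genome tibble (`genome_id`, `contig_id`, `species`, `sequence`).
#' @export
read_genomes <- function(paths, species = "unknown") {
  purrr::map2_dfr(paths, rep_len(species, length(paths)), function(p, sp) {
    x <- Biostrings::readDNAStringSet(p)
    if (length(x) == 0) stop(sprintf("no records in %s", p), call. = FALSE)
    nm <- names(x)
    has_bar <- grepl("|", nm, fixed = TRUE)
    gid <- ifelse(has_bar, sub("\\|.*$", "", nm),
                  sub("\\.(fa|fasta|fna)$", "", basename(p)))
    cid <- ifelse(has_bar, sub("^[^|]*\\|", "", nm), "c01")
    tibble::tibble(genome_id = unname(gid), contig_id = unname(cid),
                   species = sp, sequence = unname(as.character(x)))
  })
}

#' Write genomes as multi-FASTA, one file per genome
#'
#' @param genomes genome tibble.
#' @param dir output directory (created if needed).
#' @return written paths, invisibly.
#' @export
write_genomes <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(sort(unique(genomes$genome_id)), function(g) {
    sub <- genomes[genomes$genome_id == g, ]
    x <- Biostrings::DNAStringSet(sub$sequence)
    names(x) <- paste(sub$genome_id, sub$contig_id, sep = "|")
    p <- file.path(dir, paste0(g, ".fasta"))
    Biostrings::writeXStringSet(x, p)
    p
  }, character(1))
  invisible(paths)
}

#' Write sequences as FASTA
#'
#' @param seqs tibble with `id`, `sequence` (DNA or protein; gapped rows
#'   allowed).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  lines <- as.vector(rbind(paste0(">", seqs$id), seqs$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file into a sequence tibble
#'
#' @param path FASTA file (plain text, DNA or protein, gaps allowed).
#' @return tibble with `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop(sprintf("no FASTA records in %s", path),
                             call. = FALSE)
  ends <- c(hdr[-1] - 1, length(lines))
  tibble::tibble(
    id = sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr])),
    sequence = vapply(seq_along(hdr), function(i) {
      paste0(lines[(hdr[i] + 1):ends[i]], collapse = "")
    }, character(1)))
}

#' Write the truth ledger (or any element table) as TSV
#'
#' @param x a data frame.
#' @param path output file.
#' @param columns columns to keep (default: all).
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path, columns = NULL) {
  if (!is.null(columns)) x <- x[, columns]
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write elements as GFF3
#'
#' Emits one `mobile_genetic_element` feature per element (1-based
#' inclusive coordinates) with `subgroup`, `completeness`, `family` and
#' cleavage-site attributes.
#'
#' @param elements element tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(elements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(elements) > 0) {
    attrs <- sprintf(
      "ID=%s;subgroup=%s;completeness=%s;family=%s;cleavage_LE=%s;cleavage_RE=%s",
      elements$element_id, elements$subgroup, elements$completeness,
      ifelse(is.na(elements$family_name %||% NA), ".", elements$family_name),
      ifelse(is.na(elements$le_tetramer), ".", elements$le_tetramer),
      ifelse(is.na(elements$re_tetramer), ".", elements$re_tetramer))
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t%.1f\t%s\t.\t%s",
                       paste(elements$genome_id, elements$contig_id, sep = "|"),
                       "tcmescan", "mobile_genetic_element",
                       elements$start + 1L, elements$end,
                       elements$score, elements$strand, attrs), con)
  }
  invisible(path)
}

#' Write hits as BED6
#'
#' 0-based half-open intervals with the bit score rescaled to 0-1000.
#'
#' @param hits hit tibble from [scan_genomes()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(hits, path) {
  if (nrow(hits) > 0) {
    smax <- max(hits$score)
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                     paste(hits$genome_id, hits$contig_id, sep = "|"),
                     hits$genomic_start, hits$genomic_end,
                     sprintf("hit%04d", seq_len(nrow(hits))),
                     as.integer(round(1000 * hits$score / max(smax, 1e-9))),
                     hits$strand)
  } else {
    lines <- character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d symmetric matrix with dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Write a pipeline result directory with manifest
#'
#' Writes the element table (TSV + GFF3), hits (TSV + BED6), families,
#' summary tables, trees (Newick), the resolved configuration, and a
#' manifest of md5 checksums; reruns under the same seed produce identical
#' files.
#'
#' @param result a `tcme_result`.
#' @param dir output directory.
#' @return the manifest tibble, invisibly.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tsv_table(result$hits, p("hits.tsv"))
  write_bed6(result$hits, p("hits.bed"))
  write_tsv_table(result$loci, p("loci.tsv"))
  write_tsv_table(result$elements[, setdiff(names(result$elements),
                                            c("tnpb_protein", "orfA_protein",
                                              "sequence"))],
                  p("elements.tsv"))
  write_gff3(result$elements, p("elements.gff3"))
  if (!is.null(result$locus_clusters)) {
    write_tsv_table(result$locus_clusters, p("locus_clusters.tsv"))
  }
  if (nrow(result$families) > 0) {
    write_fasta(tibble::tibble(id = result$families$family_name,
                               sequence = result$families$sequence),
                p("family_consensus.fasta"))
    write_tsv_table(result$families[, setdiff(names(result$families),
                                              c("sequence", "member_ids"))],
                    p("families.tsv"))
  }
  write_tsv_table(result$species_table, p("species_summary.tsv"))
  write_tsv_table(result$group_table, p("group_summary.tsv"))
  if (!is.null(result$trees$tnpb)) {
    ape::write.tree(result$trees$tnpb, p("tnpb_tree.nwk"))
  }
  cfg <- result$config
  cfg_lines <- vapply(names(cfg), function(nm) {
    v <- cfg[[nm]]
    if (is.list(v)) v <- paste(names(unlist(v)), unlist(v), sep = "=",
                               collapse = ",")
    sprintf("%s: %s", nm, paste(format(v), collapse = " "))
  }, character(1))
  writeLines(cfg_lines, p("config.txt"))
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!basename(files) %in% "manifest.tsv"]
  manifest <- tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  write_tsv_table(manifest, p("manifest.tsv"))
  invisible(manifest)
}
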