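# File I/O: FASTA/FASTQ via Biostrings, GFF3/BED/TSV writers, and helpers
# for the wide genotype-table layout used across the package.

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ file (Phred+33).
#' @return Tibble read_id, sequence, quality.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(read_id = names(x),
         sequence = as.character(x),
         quality = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a read tibble to FASTQ
#'
#' @param reads Tibble with read_id, sequence, quality.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write all reference artefacts of a simulated reference to a directory
#'
#' Emits `reference.fa`, `te_library.fa`, `genes.gff3`,
#' `ref_te_copies.bed` (BED6, 0-based half-open), `genetic_map.tsv` and
#' `pericentromere.tsv` (1-based inclusive).
#'
#' @param reference A [simulate_reference()] object.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(reference$genome, file.path(dir, "reference.fa"))
  te <- setNames(reference$te_library$sequence,
                 paste0(reference$te_library$te_id, " class=",
                        reference$te_library$class))
  write_fasta(te, file.path(dir, "te_library.fa"))
  write_gff3(reference$genes, reference$features,
             file.path(dir, "genes.gff3"))
  bed <- reference$ref_te_copies %>%
    mutate(start0 = .data$start - 1L, score = 0L) %>%
    select("chromosome", "start0", "end", "te_id", "score", "strand")
  readr::write_tsv(bed, file.path(dir, "ref_te_copies.bed"),
                   col_names = FALSE)
  readr::write_tsv(reference$genetic_map, file.path(dir, "genetic_map.tsv"))
  readr::write_tsv(reference$pericentromere,
                   file.path(dir, "pericentromere.tsv"))
  invisible(dir)
}

write_gff3 <- function(genes, features, path) {
  gff_row <- function(chrom, src, type, start, end, strand, attrs) {
    paste(chrom, src, type, start, end, ".", strand, ".", attrs, sep = "\t")
  }
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines,
               gff_row(g$chromosome, "nrte_sim", "gene", g$start, g$end,
                       g$strand, paste0("ID=", g$gene_id)))
    f <- features[features$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(f)) {
      lines <- c(lines,
                 gff_row(f$chromosome, "nrte_sim", f$feature, f$start,
                         f$end, f$strand,
                         paste0("Parent=", f$gene_id)))
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write truth-set tables to TSV
#'
#' @param truth A [simulate_panel()] truth set.
#' @param dir Output directory.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(truth$panel, file.path(dir, "panel.tsv"))
  readr::write_tsv(truth$loci, file.path(dir, "truth_loci.tsv"))
  readr::write_tsv(truth$genotypes, file.path(dir, "truth_genotypes.tsv"))
  readr::write_tsv(truth$causal_effects,
                   file.path(dir, "truth_causal_effects.tsv"))
  readr::write_tsv(truth$expression_effects,
                   file.path(dir, "truth_expression_effects.tsv"))
  invisible(dir)
}

#' Write called loci as BED6 (+class) and a VCF-like genotype TSV
#'
#' @param loci Locus table from [cluster_hits()].
#' @param genotypes Wide genotype tibble (locus_id + one column per line).
#' @param dir Output directory.
#' @export
write_loci <- function(loci, genotypes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- loci %>%
    mutate(start0 = .data$position - 1L, score = 0L, strand = ".") %>%
    select("chromosome", "start0", "position", "locus_id", "score",
           "strand", "class")
  readr::write_tsv(bed, file.path(dir, "nrte_loci.bed"), col_names = FALSE)
  tab <- loci %>%
    transmute(CHROM = .data$chromosome, POS = .data$position,
              ID = .data$locus_id, TE_FAMILY = .data$te_family,
              CLASS = .data$class) %>%
    dplyr::bind_cols(genotypes[match(loci$locus_id, genotypes$locus_id),
                               setdiff(names(genotypes), "locus_id")])
  readr::write_tsv(tab, file.path(dir, "nrte_genotypes.tsv"))
  invisible(dir)
}

# ---- genotype-table helpers -------------------------------------------

#' Line columns of a wide genotype tibble
#' @param genotypes Tibble with a locus_id column plus one column per line.
#' @return Character vector of line ids.
#' @export
genotype_lines <- function(genotypes) {
  setdiff(names(genotypes), c("locus_id", "chromosome", "position",
                              "te_family", "class"))
}

#' Convert a wide genotype tibble to a lines-by-loci 0/1 matrix
#' @inheritParams genotype_lines
#' @return Numeric matrix, rows = lines, columns = loci; NA for missing.
#' @export
genotype_matrix <- function(genotypes) {
  lines <- genotype_lines(genotypes)
  M <- t(as.matrix(genotypes[, lines]))
  colnames(M) <- genotypes$locus_id
  storage.mode(M) <- "double"
  M
}
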