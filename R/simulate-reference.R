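# Synthetic reference genome, TE library, annotation and genetic map.

# Maize-style three-letter superfamily codes used for simulated family names.
TE_CODES <- list(
  DNA = c("DTA", "DTC", "DTH", "DTM", "DTT", "DHH"),
  `LTR/Gypsy` = "RLG",
  `LTR/Copia` = "RLC",
  other = c("RLX", "RIL", "RST")
)

#' Simulate a reference genome with embedded TE copies, genes and a map
#'
#' Builds the fixed inputs of the detection pipeline: chromosomes of uniform
#' i.i.d. base composition, a TE library whose members carry
#' superfamily-coded family names, full-length TE copies embedded in the
#' reference (these are the decoys the reference filter of the junction scan
#' must reject), non-overlapping gene models with UTR/exon/intron structure,
#' and a genetic map whose middle third has suppressed recombination
#' (a pericentromere-like low-slope segment of the Marey curve).
#'
#' @param config A [sim_config()].
#' @return A list of class `nrte_reference` with elements `genome` (named
#'   character vector, one string per chromosome), `te_library` (tibble:
#'   te_id, family, class, length, sequence), `ref_te_copies` (tibble:
#'   te_id, chromosome, start, end, strand; 1-based inclusive), `genes`
#'   (tibble of gene bounds), `features` (tibble of per-gene
#'   five_prime_UTR/exon/intron/three_prime_UTR intervals), `genetic_map`
#'   (tibble: marker, chromosome, position, cm) and `pericentromere`
#'   (tibble: chromosome, start, end).
#' @export
#' @examples
#' ref <- simulate_reference(sim_config(seed = 1, chrom_length = 1e5,
#'                                      n_genes = 4, reference_te_copies = 1,
#'                                      te_library_size = 3))
simulate_reference <- function(config) {
  config <- validate_sim_config(config)
  with_seed(derive_seed(config$seed, 1L), {
    te_library <- simulate_te_library(config$te_library_size)
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    genome <- setNames(
      vapply(chroms, function(.) random_dna(config$chrom_length), ""),
      chroms)

    # Place reference TE copies and genes jointly without overlap.
    copies <- if (config$reference_te_copies > 0) {
      idx <- sample.int(nrow(te_library), config$reference_te_copies,
                        replace = TRUE)
      tibble(te_id = te_library$te_id[idx],
             length = te_library$length[idx])
    } else {
      tibble(te_id = character(), length = integer())
    }
    gene_models <- simulate_gene_models(config$n_genes)
    widths <- c(copies$length,
                if (nrow(gene_models$genes)) gene_models$genes$length else
                  integer())
    kind <- rep(c("te", "gene"), c(nrow(copies), nrow(gene_models$genes)))
    placed <- place_intervals(widths, chroms, config$chrom_length)
    placed$kind <- kind

    te_placed <- placed[placed$kind == "te", , drop = FALSE]
    ref_te_copies <- tibble(
      te_id = copies$te_id,
      chromosome = te_placed$chromosome,
      start = te_placed$start,
      end = te_placed$end,
      strand = if (nrow(te_placed)) sample(c("+", "-"), nrow(te_placed),
                                           replace = TRUE) else character())
    # Overwrite reference sequence with the TE copy sequence.
    if (nrow(ref_te_copies)) {
      seqs <- te_library$sequence[match(ref_te_copies$te_id,
                                        te_library$te_id)]
      for (i in seq_len(nrow(ref_te_copies))) {
        s <- if (ref_te_copies$strand[i] == "+") seqs[i] else revcomp(seqs[i])
        substr(genome[[ref_te_copies$chromosome[i]]],
               ref_te_copies$start[i], ref_te_copies$end[i]) <- s
      }
    }

    gene_placed <- placed[placed$kind == "gene", , drop = FALSE]
    ann <- layout_gene_features(gene_models, gene_placed)

    map <- simulate_genetic_map(config, chroms)

    structure(list(genome = genome,
                   te_library = te_library,
                   ref_te_copies = ref_te_copies,
                   genes = ann$genes,
                   features = ann$features,
                   genetic_map = map$map,
                   pericentromere = map$pericentromere,
                   config = config),
              class = "nrte_reference")
  })
}

simulate_te_library <- function(n) {
  if (n == 0) {
    return(tibble(te_id = character(), family = character(),
                  class = character(), length = integer(),
                  sequence = character()))
  }
  # Class mix loosely follows the observed superfamily proportions of
  # non-reference insertions in maize panels (roughly 31% DNA, 40% Gypsy,
  # 26% Copia, 3% other).
  cls <- sample(c("DNA", "LTR/Gypsy", "LTR/Copia", "other"), n,
                replace = TRUE, prob = c(0.31, 0.40, 0.26, 0.03))
  code <- vapply(cls, function(k) sample(TE_CODES[[k]], 1), "")
  family <- sprintf("%s_fam%02d", code, seq_len(n))
  len <- sample(200:5000, n, replace = TRUE)
  tibble(te_id = family, family = family, class = cls, length = len,
         sequence = vapply(len, random_dna, ""))
}

# Draw gene internal structure; coordinates are laid out later once a start
# is chosen.
simulate_gene_models <- function(n_genes) {
  if (n_genes == 0) {
    return(list(genes = tibble(length = integer()), parts = list()))
  }
  parts <- lapply(seq_len(n_genes), function(i) {
    n_exon <- sample(2:4, 1)
    widths <- c(sample(100:300, 1),                       # 5' UTR
                rbind(sample(150:400, n_exon, replace = TRUE),
                      c(sample(100:400, n_exon - 1, replace = TRUE), NA)),
                sample(100:300, 1))
    widths <- widths[!is.na(widths)]
    labels <- c("five_prime_UTR",
                head(rep(c("exon", "intron"), n_exon), 2 * n_exon - 1),
                "three_prime_UTR")
    tibble(feature = labels, width = widths)
  })
  list(genes = tibble(length = vapply(parts, function(p) sum(p$width), 0)),
       parts = parts)
}

# Greedy non-overlapping placement of widths across chromosomes; errors out
# when placement fails, per the generator contract.
place_intervals <- function(widths, chroms, chrom_length, max_tries = 200) {
  n <- length(widths)
  out <- tibble(chromosome = character(n), start = integer(n),
                end = integer(n))
  occupied <- setNames(vector("list", length(chroms)), chroms)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      chr <- sample(chroms, 1)
      if (widths[i] + 2 > chrom_length) break
      s <- sample.int(chrom_length - widths[i] - 1, 1) + 1
      e <- s + widths[i] - 1
      occ <- occupied[[chr]]
      clash <- !is.null(occ) && any(s <= occ$end & e >= occ$start)
      if (!clash) {
        occupied[[chr]] <- bind_rows(occ, tibble(start = s, end = e))
        out$chromosome[i] <- chr
        out$start[i] <- s
        out$end[i] <- e
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort("could not place genes and reference TE copies without overlap; reduce their number or lengths")
    }
  }
  out
}

layout_gene_features <- function(gene_models, gene_placed) {
  n <- nrow(gene_placed)
  if (n == 0) {
    return(list(
      genes = tibble(gene_id = character(), chromosome = character(),
                     start = integer(), end = integer(), strand = character()),
      features = tibble(gene_id = character(), chromosome = character(),
                        feature = character(), start = integer(),
                        end = integer(), strand = character())))
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  genes <- tibble(gene_id = sprintf("gene%03d", seq_len(n)),
                  chromosome = gene_placed$chromosome,
                  start = gene_placed$start, end = gene_placed$end,
                  strand = strand)
  features <- purrr::map_dfr(seq_len(n), function(i) {
    p <- gene_models$parts[[i]]
    ends <- gene_placed$start[i] - 1 + cumsum(p$width)
    starts <- ends - p$width + 1
    lab <- p$feature
    if (strand[i] == "-") {
      # Leftmost interval is the 3' end on the minus strand.
      lab <- rev(lab)
    }
    tibble(gene_id = genes$gene_id[i], chromosome = genes$chromosome[i],
           feature = lab, start = starts, end = ends, strand = strand[i])
  })
  list(genes = genes, features = features)
}

simulate_genetic_map <- function(config, chroms) {
  L <- config$chrom_length
  b1 <- floor(L / 3)
  b2 <- floor(2 * L / 3)
  marey <- function(x) {
    # piecewise-linear cM: arm / pericentromere / arm
    a <- config$arm_cm_per_mb / 1e6
    p <- config$pericentromere_cm_per_mb / 1e6
    ifelse(x <= b1, a * x,
           ifelse(x <= b2, a * b1 + p * (x - b1),
                  a * b1 + p * (b2 - b1) + a * (x - b2)))
  }
  pos <- unique(c(seq(1, L, by = config$map_spacing), L))
  map <- purrr::map_dfr(chroms, function(chr) {
    tibble(marker = sprintf("%s_m%04d", chr, seq_along(pos)),
           chromosome = chr, position = pos, cm = marey(pos))
  })
  peri <- tibble(chromosome = chroms, start = b1 + 1L, end = b2)
  list(map = map, pericentromere = peri)
}

#' @export
print.nrte_reference <- function(x, ...) {
  cat("<nrte_reference> ", length(x$genome), " chromosome(s), ",
      nrow(x$te_library), " TE families, ", nrow(x$ref_te_copies),
      " embedded copies, ", nrow(x$genes), " genes\n", sep = "")
  invisible(x)
}
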