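# Synthetic panel: planted insertion loci, per-line genotypes, reads,
# phenotypes and expression, with the generating truth recorded.

#' Simulate a two-population panel of inbred lines with planted insertions
#'
#' Plants `n_insertion_loci` non-reference TE insertions in a reference from
#' [simulate_reference()], draws per-locus carrier frequencies from the
#' per-class Beta models, realises presence/absence genotypes for every line
#' (lines are fully inbred, so one haploid donor genome per line), and
#' records everything in a truth set. Insertion positions keep a buffer of
#' one read length away from embedded reference TE copies and chromosome
#' ends, and at least one read length from each other, so clustering of
#' junction hits is unambiguous. Recorded frequencies are the realised
#' carrier fractions, not the Beta draws.
#'
#' Reads are not generated here: use [reads_for_line()] (deterministic per
#' line) or [write_panel_fastq()].
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()] under the same config.
#' @return A list of class `nrte_truth`: `panel` (tibble line_id,
#'   population), `loci` (tibble locus_id, chromosome, position, te_id,
#'   family, class, locus_class, freq_temperate, freq_tropical; `position`
#'   is the last reference base before the insertion, 1-based),
#'   `genotypes` (tibble: locus_id plus one 0/1 column per line),
#'   `causal_effects` (locus_id, effect), `expression_effects` (gene_id,
#'   locus_id, multiplier), and `gene_ids`.
#' @export
simulate_panel <- function(config, reference) {
  config <- validate_sim_config(config)
  stopifnot(inherits(reference, "nrte_reference"))
  with_seed(derive_seed(config$seed, 2L), {
    panel <- panel_tibble(config)
    loci <- place_insertion_loci(config, reference)
    geno <- realise_genotypes(config, loci, panel)
    loci <- geno$loci
    causal <- draw_causal_effects(config, loci)
    expr_eff <- draw_expression_effects(config, loci, reference)
    structure(list(panel = panel,
                   loci = loci,
                   genotypes = geno$genotypes,
                   causal_effects = causal,
                   expression_effects = expr_eff,
                   gene_ids = reference$genes$gene_id,
                   config = config),
              class = "nrte_truth")
  })
}

panel_tibble <- function(config) {
  np <- config$n_lines_per_pop
  tibble(
    line_id = c(sprintf("TEM%03d", seq_len(np[["temperate"]])),
                sprintf("TRO%03d", seq_len(np[["tropical"]]))),
    population = rep(c("temperate", "tropical"), np))
}

place_insertion_loci <- function(config, reference, max_tries = 500) {
  n <- config$n_insertion_loci
  if (n == 0) {
    return(tibble(locus_id = character(), chromosome = character(),
                  position = integer(), te_id = character(),
                  family = character(), class = character(),
                  locus_class = character()))
  }
  if (nrow(reference$te_library) == 0) {
    abort("cannot plant insertions from an empty TE library")
  }
  buffer <- config$read_length
  chroms <- names(reference$genome)
  L <- config$chrom_length
  chosen <- tibble(chromosome = character(), position = integer())
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      chr <- sample(chroms, 1)
      p <- sample.int(L - 2L * buffer, 1) + buffer
      copies <- reference$ref_te_copies
      copies <- copies[copies$chromosome == chr, , drop = FALSE]
      near_copy <- nrow(copies) > 0 &&
        any(p >= copies$start - buffer & p <= copies$end + buffer)
      prev <- chosen[chosen$chromosome == chr, , drop = FALSE]
      near_prev <- nrow(prev) > 0 && any(abs(p - prev$position) < buffer)
      if (!near_copy && !near_prev) {
        chosen <- bind_rows(chosen, tibble(chromosome = chr, position = p))
        ok <- TRUE
        break
      }
    }
    if (!ok) abort("could not place insertion loci with the required spacing; reduce n_insertion_loci")
  }
  te_idx <- sample.int(nrow(reference$te_library), n, replace = TRUE)
  locus_class <- sample(names(config$class_mix), n, replace = TRUE,
                        prob = config$class_mix)
  chosen %>%
    mutate(te_id = reference$te_library$te_id[te_idx],
           family = reference$te_library$family[te_idx],
           class = reference$te_library$class[te_idx],
           locus_class = locus_class) %>%
    arrange(.data$chromosome, .data$position) %>%
    mutate(locus_id = sprintf("L%04d", row_number()), .before = 1)
}

# Draw Beta frequencies per segregating population, realise Bernoulli
# genotypes, and record the realised carrier fractions as the truth
# frequencies. A locus carried by nobody is redrawn (an insertion absent
# from every line is not an insertion event in the panel at all).
realise_genotypes <- function(config, loci, panel) {
  n <- nrow(loci)
  lines <- panel$line_id
  is_tem <- panel$population == "temperate"
  G <- matrix(0L, nrow = n, ncol = length(lines),
              dimnames = list(loci$locus_id, lines))
  f_tem <- f_tro <- numeric(n)
  for (i in seq_len(n)) {
    cl <- loci$locus_class[i]
    ab <- config$freq_model[[cl]]
    for (try in 1:100) {
      pt_ <- if (cl %in% c("private_temperate", "shared"))
        rbeta(1, ab[1], ab[2]) else 0
      pp_ <- if (cl %in% c("private_tropical", "shared"))
        rbeta(1, ab[1], ab[2]) else 0
      g <- integer(length(lines))
      g[is_tem] <- rbinom(sum(is_tem), 1, pt_)
      g[!is_tem] <- rbinom(sum(!is_tem), 1, pp_)
      if (sum(g) > 0) break
    }
    if (sum(g) == 0) g[sample(which(if (cl == "private_tropical") !is_tem
                                    else is_tem), 1)] <- 1L
    G[i, ] <- g
    f_tem[i] <- mean(g[is_tem])
    f_tro[i] <- mean(g[!is_tem])
  }
  loci$freq_temperate <- f_tem
  loci$freq_tropical <- f_tro
  genotypes <- dplyr::bind_cols(tibble(locus_id = loci$locus_id),
                                as_tibble(G))
  list(loci = loci, genotypes = genotypes)
}

draw_causal_effects <- function(config, loci) {
  k <- min(config$n_causal_loci, nrow(loci))
  if (k == 0) return(tibble(locus_id = character(), effect = numeric()))
  idx <- sample.int(nrow(loci), k)
  tibble(locus_id = loci$locus_id[idx],
         effect = rep_len(config$effect_sizes, k))
}

draw_expression_effects <- function(config, loci, reference) {
  k <- min(config$n_expression_effects, nrow(loci))
  if (k == 0 || nrow(reference$genes) == 0) {
    return(tibble(gene_id = character(), locus_id = character(),
                  multiplier = numeric()))
  }
  idx <- sample.int(nrow(loci), k)
  gene_id <- vapply(idx, function(i) {
    g <- reference$genes[reference$genes$chromosome ==
                           loci$chromosome[i], , drop = FALSE]
    if (nrow(g) == 0) g <- reference$genes
    g$gene_id[which.min(abs((g$start + g$end) / 2 - loci$position[i]))]
  }, "")
  tibble(gene_id = gene_id, locus_id = loci$locus_id[idx],
         multiplier = config$expression_multiplier)
}

#' Donor genome of one line (reference plus its carried insertions)
#'
#' @param truth A [simulate_panel()] truth set.
#' @param reference The matching reference.
#' @param line_id One line identifier from `truth$panel`.
#' @return Named character vector of chromosome sequences.
#' @export
donor_genome <- function(truth, reference, line_id) {
  g <- truth$genotypes[[line_id]]
  if (is.null(g)) abort(paste0("unknown line_id: ", line_id))
  carried <- truth$loci[g == 1L, , drop = FALSE]
  te_seq <- reference$te_library$sequence[
    match(carried$te_id, reference$te_library$te_id)]
  out <- reference$genome
  for (chr in names(out)) {
    rows <- which(carried$chromosome == chr)
    if (!length(rows)) next
    rows <- rows[order(carried$position[rows])]
    pos <- carried$position[rows]
    ref <- out[[chr]]
    bounds <- c(0L, pos, nchar(ref))
    segs <- substring(ref, bounds[-length(bounds)] + 1L, bounds[-1L])
    pieces <- character(2L * length(rows) + 1L)
    pieces[seq(1, by = 2, length.out = length(segs))] <- segs
    pieces[seq(2, by = 2, length.out = length(rows))] <- te_seq[rows]
    out[[chr]] <- paste(pieces, collapse = "")
  }
  out
}

#' Simulated reads for one line
#'
#' Uniformly samples single-end reads of `read_length` from the line's
#' donor genome at the configured coverage, on both strands, with i.i.d.
#' substitution errors at `error_rate`. Deterministic per (config seed,
#' line): the same line always yields the same reads, so FASTQ export and
#' in-memory scanning see identical data.
#'
#' @inheritParams donor_genome
#' @return Tibble with columns read_id, sequence, quality (Phred+33, Q30).
#' @export
reads_for_line <- function(truth, reference, line_id) {
  config <- truth$config
  line_index <- match(line_id, truth$panel$line_id)
  if (is.na(line_index)) abort(paste0("unknown line_id: ", line_id))
  donor <- donor_genome(truth, reference, line_id)
  rl <- config$read_length
  with_seed(derive_seed(config$seed, 100L + line_index), {
    out <- purrr::map_dfr(names(donor), function(chr) {
      dlen <- nchar(donor[[chr]])
      n_reads <- round(config$coverage * dlen / rl)
      if (n_reads == 0) {
        return(tibble(read_id = character(), sequence = character()))
      }
      starts <- sample.int(dlen - rl + 1L, n_reads, replace = TRUE)
      seqs <- as.character(Biostrings::extractAt(
        Biostrings::DNAString(donor[[chr]]),
        IRanges::IRanges(start = starts, width = rl)))
      minus <- sample(c(TRUE, FALSE), n_reads, replace = TRUE)
      seqs[minus] <- revcomp(seqs[minus])
      tibble(read_id = sprintf("%s_%s_%06d", line_id, chr,
                               seq_len(n_reads)),
             sequence = seqs)
    })
    out$sequence <- add_substitution_errors(out$sequence, rl,
                                            config$error_rate)
    out$quality <- strrep("?", rl)  # Q30, Phred+33
    out
  })
}

# Exact i.i.d. substitution model: the number of erroneous base slots is
# Binomial(n*rl, rate) and the slots are a uniform draw without
# replacement; substituted bases are drawn from the three other bases.
add_substitution_errors <- function(seqs, rl, rate) {
  n <- length(seqs)
  if (n == 0 || rate <= 0) return(seqs)
  total <- rbinom(1, n * rl, rate)
  if (total == 0) return(seqs)
  slots <- sample(n * rl, total)
  read_i <- (slots - 1L) %/% rl + 1L
  pos <- (slots - 1L) %% rl + 1L
  orig <- substring(seqs[read_i], pos, pos)
  others <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
  pick <- sample.int(3, total, replace = TRUE)
  new <- vapply(seq_len(total),
                function(i) others[[orig[i]]][pick[i]], "")
  # Apply in rounds so several errors in one read all land.
  ord <- order(read_i, pos)
  read_i <- read_i[ord]; pos <- pos[ord]; new <- new[ord]
  rank_in_read <- stats::ave(pos, read_i, FUN = seq_along)
  for (r in seq_len(max(rank_in_read))) {
    sel <- rank_in_read == r
    idx <- read_i[sel]
    s <- seqs[idx]
    substr(s, pos[sel], pos[sel]) <- new[sel]
    seqs[idx] <- s
  }
  seqs
}

#' Write per-line FASTQ files for a simulated panel
#'
#' @inheritParams donor_genome
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_panel_fastq <- function(truth, reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(truth$panel$line_id, function(id) {
    reads <- reads_for_line(truth, reference, id)
    path <- file.path(dir, paste0(id, ".fastq"))
    write_fastq(reads, path)
    path
  }, "")
  invisible(paths)
}

#' Simulate replicated phenotypes for the panel
#'
#' One polygenic trait:
#' `y = shift * [tropical] + sum_j effect_j g_j + N(0, line_sd^2) + N(0, residual_sd^2)`
#' with the line-level genetic deviate shared across replicates. The
#' realised among-population variance component implied by the fixed shift
#' (`d^2 n1 n2 / (N n0 (k-1))` with `n0 = (N - sum(ni^2)/N)/(k-1)`) and the
#' generating within-population component are recorded in the
#' `"components"` attribute so variance-component recovery can be tested.
#'
#' @param truth A [simulate_panel()] truth set.
#' @param config A [sim_config()] (defaults to the truth's own).
#' @return Tibble line_id, population, replicate, trait, value with a
#'   `"components"` attribute.
#' @export
simulate_phenotypes <- function(truth, config = truth$config) {
  panel <- truth$panel
  with_seed(derive_seed(config$seed, 3L), {
    gmat <- genotype_matrix(truth$genotypes)      # lines x loci
    eff <- setNames(truth$causal_effects$effect,
                    truth$causal_effects$locus_id)
    genetic <- if (length(eff))
      as.numeric(gmat[, names(eff), drop = FALSE] %*% eff) else
      numeric(nrow(panel))
    shift <- config$pop_mean_shift * (panel$population == "tropical")
    line_dev <- rnorm(nrow(panel), 0, config$line_sd)
    out <- tidyr::crossing(panel, replicate = seq_len(config$n_replicates)) %>%
      arrange(match(.data$line_id, panel$line_id), .data$replicate)
    i <- match(out$line_id, panel$line_id)
    out$trait <- "trait1"
    out$value <- shift[i] + genetic[i] + line_dev[i] +
      rnorm(nrow(out), 0, config$residual_sd)
    ni <- table(panel$population)
    N <- sum(ni); k <- length(ni)
    n0 <- (N - sum(ni^2) / N) / (k - 1)
    s2gb_shift <- config$pop_mean_shift^2 * prod(ni) / (N * n0 * (k - 1))
    attr(out, "components") <- list(
      sigma2_GB_shift = s2gb_shift,
      sigma2_GW = config$line_sd^2,
      sigma2_E = config$residual_sd^2)
    out
  })
}

#' Simulate an FPKM-like expression matrix
#'
#' Log-normal baseline per gene; carriers of a perturbing insertion have
#' that gene's mean multiplied by the recorded fold-change.
#'
#' @inheritParams simulate_phenotypes
#' @return Tibble gene_id plus one numeric column per line.
#' @export
simulate_expression <- function(truth, config = truth$config) {
  genes <- truth$gene_ids
  panel <- truth$panel
  with_seed(derive_seed(config$seed, 4L), {
    meanlog <- rnorm(length(genes), mean = 3, sd = 1)
    M <- exp(matrix(rnorm(length(genes) * nrow(panel), meanlog,
                          config$expr_sdlog),
                    nrow = length(genes)))
    dimnames(M) <- list(genes, panel$line_id)
    if (nrow(truth$expression_effects)) {
      gmat <- genotype_matrix(truth$genotypes)
      for (i in seq_len(nrow(truth$expression_effects))) {
        e <- truth$expression_effects[i, ]
        carriers <- gmat[, e$locus_id] == 1
        M[e$gene_id, carriers] <- M[e$gene_id, carriers] * e$multiplier
      }
    }
    dplyr::bind_cols(tibble(gene_id = genes), as_tibble(M))
  })
}

#' @export
print.nrte_truth <- function(x, ...) {
  cat("<nrte_truth> ", nrow(x$loci), " planted loci over ",
      nrow(x$panel), " lines (",
      paste(names(table(x$panel$population)),
            table(x$panel$population), collapse = " + "),
      "); ", nrow(x$causal_effects), " causal\n", sep = "")
  invisible(x)
}
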