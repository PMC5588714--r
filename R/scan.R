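# Junction-scan pipeline: QC, TE-edge matching, reference-resident-copy
# filtering, unique flank placement, clustering into loci, genotyping.
#
# Detection logic: a 75-bp read contains a junction when k in [20, 55]
# terminal bases perfectly match the extremity of a TE edge (the prefix of
# a 5' edge or the suffix of a 3' edge, on either strand) and the
# complementary 75-k bases (the flank) perfectly match the reference at
# exactly one location. Reads with >= 65 bp matching the reference at
# >= 95% identity are TE copies already present in the reference and are
# excluded.

K_MIN <- 20L
K_MAX <- 55L
READ_LEN <- 75L
SEED_LEN <- 20L

#' Probability that two random flanks agree over a fixed stretch
#'
#' Under uniform i.i.d. base composition, the chance that two independent
#' flanking sequences are identical over `overlap_bp` consecutive bases at
#' a fixed junction is `(1/4)^overlap_bp`. With the junction rule's 20-bp
#' floor, sharing a stretch longer than 20 bp has probability
#' `flank_collision_prob(21)`, below `4^-20` -- the uniqueness argument
#' behind requiring at least 20 bp of perfect flank match.
#'
#' @param overlap_bp Length of the shared stretch in bp.
#' @return The collision probability.
#' @export
#' @examples
#' flank_collision_prob(21) <= 4^-20
flank_collision_prob <- function(overlap_bp) {
  stopifnot(overlap_bp >= 1)
  0.25^overlap_bp
}

#' Quality-control and truncate reads to 75 bp
#'
#' Trims trailing (3') bases whose Phred quality falls below
#' `quality_threshold`, drops reads shorter than `min_length` after
#' trimming, and hard-truncates survivors to exactly 75 bp (the fixed read
#' length of the junction rule; post-trim reads shorter than 75 bp are
#' dropped too).
#'
#' @param reads Tibble (read_id, sequence, quality; Phred+33) or a FASTQ
#'   path.
#' @param quality_threshold Minimum Phred score retained at the 3' end.
#' @param min_length Minimum post-trim length.
#' @return Tibble of 75-bp reads.
#' @export
qc_reads <- function(reads, quality_threshold = 20, min_length = 75) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  bad <- which(nchar(reads$sequence) != nchar(reads$quality))
  if (length(bad)) {
    abort(paste0("malformed FASTQ record(s) at index: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (nrow(reads) == 0) return(reads)
  # Characters below the threshold form a contiguous low end of the
  # Phred+33 alphabet; strip any trailing run of them with one regex.
  hi <- rawToChar(as.raw(33L + as.integer(quality_threshold) - 1L))
  pat <- paste0("[\\x21-", sub("(\\W)", "\\\\\\1", hi), "]+$")
  len <- nchar(reads$quality)
  # only reads whose final base is low-quality can have a trailing run
  low_chars <- strsplit(rawToChar(as.raw(33:(32L + max(1L,
    as.integer(quality_threshold))))), "")[[1]]
  last <- substr(reads$quality, len, len)
  needs_trim <- len > 0 & last %in% low_chars
  if (any(needs_trim)) {
    len[needs_trim] <- nchar(
      stringr::str_replace(reads$quality[needs_trim], pat, ""))
  }
  len <- pmin(len, nchar(reads$sequence))
  keep <- len >= max(min_length, READ_LEN)
  out <- reads[keep, , drop = FALSE]
  out$sequence <- substr(out$sequence, 1L, READ_LEN)
  out$quality <- substr(out$quality, 1L, READ_LEN)
  out
}

# ---- edge index --------------------------------------------------------

# Expand an edge database into two lookup tables keyed by a 20-bp anchor:
# `prefix` rows expect the anchor at read positions [1,20] (TE part is the
# read prefix), `suffix` rows at [56,75] (TE part is the read suffix).
# Both strands are folded in by also indexing reverse-complemented edges.
edge_index <- function(edge_db) {
  rows <- purrr::map_dfr(seq_len(nrow(edge_db)), function(i) {
    e <- edge_db[i, ]
    len <- nchar(e$sequence)
    ks <- K_MIN:min(K_MAX, len)
    if (!length(ks) || len < SEED_LEN) return(NULL)
    if (e$end == "five_prime") {
      term <- substr(rep(e$sequence, length(ks)), 1L, ks)  # TE start
      # forward: read suffix == term  -> TE right of flank
      fwd <- tibble(side = "suffix", k = ks, expected = term,
                    strand = "+")
      # reverse strand: read prefix == revcomp(term) -> TE left of flank
      rev <- tibble(side = "prefix", k = ks, expected = revcomp(term),
                    strand = "-")
    } else {
      term <- substr(rep(e$sequence, length(ks)), len - ks + 1L, len)
      fwd <- tibble(side = "prefix", k = ks, expected = term,
                    strand = "+")
      rev <- tibble(side = "suffix", k = ks, expected = revcomp(term),
                    strand = "-")
    }
    out <- bind_rows(fwd, rev)
    out$edge_id <- e$edge_id
    out
  })
  if (is.null(rows) || nrow(rows) == 0) {
    abort("edge database yields no indexable terminal segments")
  }
  # Anchor: the 20 bases of the expected segment nearest the read boundary
  # it sits against (read start for prefix rows, read end for suffix rows).
  rows$anchor <- ifelse(rows$side == "prefix",
                        substr(rows$expected, 1L, SEED_LEN),
                        substr(rows$expected, rows$k - SEED_LEN + 1L,
                               rows$k))
  list(prefix = rows[rows$side == "prefix", , drop = FALSE],
       suffix = rows[rows$side == "suffix", , drop = FALSE],
       edge_db = edge_db)
}

#' Match reads against the TE edge database
#'
#' Emits a junction-hit stub for every read whose prefix or suffix of
#' length k in \[20, 55\] exactly equals the terminal k bases of a TE edge
#' on either strand; the complementary 75-k bases become the candidate
#' flank. When several k match the same edge, the maximal k is kept.
#'
#' @param reads Tibble of 75-bp reads (from [qc_reads()]).
#' @param edge_db An [build_edge_db()] database or a prebuilt
#'   [edge_index()] (the index is rebuilt per call otherwise).
#' @param line_id Line identifier stored with the stubs.
#' @return Tibble of stubs: read_id, line_id, edge_id, te_match_len,
#'   te_side (`"left"`/`"right"`: side of the flank the TE sits on, in read
#'   orientation), strand, flank_sequence, read_sequence.
#' @export
match_te_edge <- function(reads, edge_db, line_id = NA_character_) {
  idx <- if (is.list(edge_db) && !is.data.frame(edge_db) &&
             all(c("prefix", "suffix") %in% names(edge_db))) edge_db else
    edge_index(edge_db)
  empty <- tibble(read_id = character(), line_id = character(),
                  edge_id = character(), class = character(),
                  te_match_len = integer(), te_side = character(),
                  strand = character(), flank_sequence = character(),
                  read_sequence = character())
  if (nrow(reads) == 0) return(empty)
  stopifnot(all(nchar(reads$sequence) == READ_LEN))

  scan_side <- function(tab, anchor_of_read, side) {
    hit <- which(anchor_of_read %in% tab$anchor)
    if (!length(hit)) return(NULL)
    cand <- tibble(row = hit, anchor = anchor_of_read[hit]) %>%
      dplyr::inner_join(tab, by = "anchor", relationship = "many-to-many")
    seg <- if (side == "prefix") {
      substr(reads$sequence[cand$row], 1L, cand$k)
    } else {
      substr(reads$sequence[cand$row], READ_LEN - cand$k + 1L, READ_LEN)
    }
    cand <- cand[seg == cand$expected, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    cand %>%
      group_by(.data$row) %>%
      filter(.data$k == max(.data$k)) %>%
      distinct(.data$row, .data$edge_id, .keep_all = TRUE) %>%
      ungroup() %>%
      mutate(side = side)
  }

  p <- scan_side(idx$prefix, substr(reads$sequence, 1L, SEED_LEN), "prefix")
  s <- scan_side(idx$suffix,
                 substr(reads$sequence, READ_LEN - SEED_LEN + 1L, READ_LEN),
                 "suffix")
  cand <- bind_rows(p, s)
  if (is.null(cand) || nrow(cand) == 0) return(empty)
  class_of_edge <- setNames(idx$edge_db$class, idx$edge_db$edge_id)
  tibble(
    read_id = reads$read_id[cand$row],
    line_id = line_id,
    edge_id = cand$edge_id,
    class = unname(class_of_edge[cand$edge_id]),
    te_match_len = as.integer(cand$k),
    te_side = ifelse(cand$side == "prefix", "left", "right"),
    strand = cand$strand,
    flank_sequence = ifelse(
      cand$side == "prefix",
      substr(reads$sequence[cand$row], cand$k + 1L, READ_LEN),
      substr(reads$sequence[cand$row], 1L, READ_LEN - cand$k)),
    read_sequence = reads$sequence[cand$row])
}

# ---- reference index ---------------------------------------------------

#' Precompute the reference structures used by the scan
#'
#' @param reference A [simulate_reference()] object, a named character
#'   vector of chromosome sequences, or a FASTA path.
#' @return A list used by [reference_te_filter()] and [map_flank()].
#' @export
build_scan_index <- function(reference) {
  genome <- if (inherits(reference, "nrte_reference")) reference$genome
            else if (is.character(reference) && is.null(names(reference)) &&
                     length(reference) == 1 && file.exists(reference))
              read_fasta(reference)
            else reference
  stopifnot(is.character(genome), !is.null(names(genome)))
  list(genome = genome,
       dna = lapply(genome, Biostrings::DNAString))
}

# Locate every occurrence of each unique 20-bp seed in the reference
# (forward strand); returns tibble(seed, chromosome, start).
locate_seeds <- function(seeds, index) {
  useq <- unique(seeds)
  pd <- Biostrings::PDict(useq)
  purrr::map_dfr(names(index$dna), function(chr) {
    m <- Biostrings::matchPDict(pd, index$dna[[chr]])
    starts <- S4Vectors::elementNROWS(m)
    hit <- which(starts > 0)
    if (!length(hit)) return(NULL)
    tibble(seed = rep(useq[hit], starts[hit]),
           chromosome = chr,
           start = unlist(lapply(hit, function(i)
             IRanges::start(m[[i]])), use.names = FALSE))
  })
}

#' Filter reads matching the reference over >= 65 bp at >= 95% identity
#'
#' A read whose best (substitution-only) alignment to the reference covers
#' at least `min_span` read bases with at least `min_identity`
#' matches/span, on either strand, derives from sequence already present
#' in the reference -- typically a TE copy resident in the assembly -- and
#' is discarded so that reference-resident copies are not called as
#' non-reference insertions.
#'
#' @param sequences Character vector of 75-bp read sequences.
#' @param index A [build_scan_index()].
#' @param min_span Minimum aligned span in read bases.
#' @param min_identity Minimum identity over the span.
#' @return Logical vector: `TRUE` = keep (not reference-resident).
#' @export
reference_te_filter <- function(sequences, index, min_span = 65,
                                min_identity = 0.95) {
  n <- length(sequences)
  if (n == 0) return(logical(0))
  useq <- unique(sequences)
  discard_u <- logical(length(useq))
  # Seeds tiled across the read; a qualifying span of >= 65 bp holds >= 5
  # of these tiles entirely, so with <= 3 substitutions at least one tile
  # is error-free and seeds the diagonal.
  offsets <- seq(1L, READ_LEN - SEED_LEN + 1L, by = 9L)
  both <- c(useq, revcomp(useq))
  seed_tbl <- tibble(
    u = rep(rep(seq_along(useq), 2), each = length(offsets)),
    orient = rep(c("F", "R"), each = length(useq) * length(offsets)),
    offset = rep(offsets, 2 * length(useq)),
    seed = substr(rep(both, each = length(offsets)),
                  rep(offsets, 2 * length(useq)),
                  rep(offsets, 2 * length(useq)) + SEED_LEN - 1L))
  loc <- locate_seeds(seed_tbl$seed, index)
  if (nrow(loc) > 0) {
    cand <- seed_tbl %>%
      dplyr::inner_join(loc, by = "seed", relationship = "many-to-many") %>%
      mutate(ref_start = .data$start - .data$offset + 1L) %>%
      distinct(.data$u, .data$orient, .data$chromosome, .data$ref_start)
    # Fast path: a full-length exact match discards immediately.
    chr_len <- vapply(index$genome, nchar, 0L)[cand$chromosome]
    full <- cand$ref_start >= 1L &
      cand$ref_start + READ_LEN - 1L <= chr_len
    q_all <- ifelse(cand$orient == "F", useq[cand$u],
                    revcomp(useq[cand$u]))
    exact <- rep(FALSE, nrow(cand))
    if (any(full)) {
      ref_full <- substr_multi(index$genome, cand$chromosome[full],
                               cand$ref_start[full],
                               cand$ref_start[full] + READ_LEN - 1L)
      exact[full] <- ref_full == q_all[full]
    }
    discard_u[unique(cand$u[exact])] <- TRUE
    for (i in which(!exact)) {
      ui <- cand$u[i]
      if (discard_u[ui]) next
      chr_seq <- index$genome[[cand$chromosome[i]]]
      s <- cand$ref_start[i]
      lo <- max(1L, s)
      hi <- min(nchar(chr_seq), s + READ_LEN - 1L)
      if (hi - lo + 1L < min_span) next
      ref_part <- substr(chr_seq, lo, hi)
      q_part <- substr(q_all[i], lo - s + 1L, hi - s + 1L)
      if (spans_identity(q_part, ref_part, min_span, min_identity)) {
        discard_u[ui] <- TRUE
      }
    }
  }
  !discard_u[match(sequences, useq)]
}

# Is there any contiguous window of length >= min_span whose identity
# (matches / window length) reaches min_identity? Substitution-only.
spans_identity <- function(a, b, min_span, min_identity) {
  n <- nchar(a)
  if (n < min_span) return(FALSE)
  mm <- cumsum(c(0L, as.integer(charToRaw(a) != charToRaw(b))))
  for (w in n:min_span) {
    allowed <- floor((1 - min_identity) * w)
    d <- mm[(w + 1L):(n + 1L)] - mm[1L:(n - w + 1L)]
    if (any(d <= allowed)) return(TRUE)
  }
  FALSE
}

# ---- flank placement ---------------------------------------------------

#' Place candidate flanks on the reference and emit junction hits
#'
#' A stub becomes a hit only when its flank matches the reference exactly
#' (100% identity) at exactly one location, counting both strands. The
#' breakpoint is the reference coordinate of the last base before the
#' insertion point (1-based), so left- and right-junction reads of the
#' same insertion agree exactly.
#'
#' @param stubs Tibble from [match_te_edge()] (after
#'   [reference_te_filter()]).
#' @param index A [build_scan_index()].
#' @return Tibble of junction hits: stub columns plus chromosome,
#'   breakpoint, ref_strand.
#' @export
map_flank <- function(stubs, index) {
  empty <- dplyr::mutate(stubs[0, ], chromosome = character(),
                         breakpoint = integer(), ref_strand = character())
  if (nrow(stubs) == 0) return(empty)
  uf <- unique(stubs$flank_sequence)
  ufr <- revcomp(uf)
  seed_tbl <- tibble(
    u = rep(seq_along(uf), 2),
    orient = rep(c("F", "R"), each = length(uf)),
    full = c(uf, ufr),
    seed = substr(c(uf, ufr), 1L, SEED_LEN))
  loc <- locate_seeds(seed_tbl$seed, index)
  if (nrow(loc) == 0) return(empty)
  occ <- seed_tbl %>%
    dplyr::inner_join(loc, by = "seed", relationship = "many-to-many")
  # verify the full flank at the seeded position
  flank_len <- nchar(occ$full)
  chr_len <- vapply(index$genome, nchar, 0L)[occ$chromosome]
  inside <- occ$start + flank_len - 1L <= chr_len
  occ <- occ[inside, , drop = FALSE]
  ref_seg <- substr_multi(index$genome, occ$chromosome, occ$start,
                          occ$start + nchar(occ$full) - 1L)
  occ <- occ[ref_seg == occ$full, , drop = FALSE]
  if (nrow(occ) == 0) return(empty)
  counts <- occ %>% count(.data$u, name = "n_occ")
  occ1 <- occ %>%
    dplyr::inner_join(dplyr::filter(counts, .data$n_occ == 1L), by = "u")
  if (nrow(occ1) == 0) return(empty)
  placed <- tibble(flank_sequence = uf[occ1$u],
                   chromosome = occ1$chromosome,
                   flank_start = occ1$start,
                   flank_end = occ1$start + nchar(occ1$full) - 1L,
                   orient = occ1$orient)
  out <- stubs %>% dplyr::inner_join(placed, by = "flank_sequence")
  if (nrow(out) == 0) return(empty)
  te_right_in_ref <- (out$te_side == "right") == (out$orient == "F")
  out$breakpoint <- ifelse(te_right_in_ref, out$flank_end,
                           out$flank_start - 1L)
  out$ref_strand <- ifelse(out$orient == "F", "+", "-")
  out$flank_start <- NULL
  out$flank_end <- NULL
  out$orient <- NULL
  out
}

# Vectorised substring across a named vector of chromosome strings.
substr_multi <- function(genome, chrom, start, end) {
  out <- character(length(chrom))
  for (chr in unique(chrom)) {
    i <- chrom == chr
    out[i] <- substring(genome[[chr]], start[i], end[i])
  }
  out
}

# ---- clustering & genotyping ------------------------------------------

#' Cluster junction hits into insertion loci and genotype the panel
#'
#' Single-linkage clustering of breakpoints within `tolerance_bp`, within
#' chromosome and superfamily class. A cluster spanning more than
#' `10 * tolerance_bp` is split at its largest internal gap (with a
#' warning). Locus position is the median member breakpoint; a line is
#' called a carrier when it contributes at least `min_support` hits.
#'
#' @param hits Tibble from [map_flank()].
#' @param tolerance_bp Single-linkage distance.
#' @param min_support Minimum supporting hits per line per locus.
#' @param lines Line ids to genotype (defaults to lines seen in `hits`;
#'   pass the full panel so non-carrier lines appear as 0).
#' @param edge_db Edge database, used to attribute a family when an edge
#'   collapses several TEs.
#' @return List with `loci` (tibble: locus_id, chromosome, position,
#'   te_family, class, n_hits) and `genotypes` (wide tibble: locus_id plus
#'   one 0/1 column per line).
#' @export
cluster_hits <- function(hits, tolerance_bp = 10, min_support = 1,
                         lines = NULL, edge_db = NULL) {
  if (is.null(lines)) lines <- sort(unique(hits$line_id))
  if (nrow(hits) == 0) {
    geno <- dplyr::bind_cols(
      tibble(locus_id = character()),
      as_tibble(matrix(integer(), 0, length(lines),
                       dimnames = list(NULL, lines))))
    return(list(loci = tibble(locus_id = character(),
                              chromosome = character(), position = integer(),
                              te_family = character(), class = character(),
                              n_hits = integer()),
                genotypes = geno))
  }
  family_of_edge <- NULL
  if (!is.null(edge_db)) {
    family_of_edge <- setNames(edge_db$family, edge_db$edge_id)
  }
  h <- hits %>%
    arrange(.data$chromosome, .data$class, .data$breakpoint)
  grp <- paste(h$chromosome, h$class, sep = "\r")
  cl <- integer(nrow(h))
  next_id <- 0L
  n_split <- 0L
  for (g in unique(grp)) {
    i <- which(grp == g)
    bp <- h$breakpoint[i]
    newc <- c(TRUE, diff(bp) > tolerance_bp)
    ids <- cumsum(newc)
    # split over-wide clusters at their largest gap
    repeat {
      spans <- tapply(bp, ids, function(x) max(x) - min(x))
      wide <- names(spans)[spans > 10 * tolerance_bp]
      if (!length(wide)) break
      n_split <- n_split + length(wide)
      for (w in wide) {
        j <- which(ids == as.integer(w))
        gaps <- diff(bp[j])
        cut <- which.max(gaps)
        ids[j[(cut + 1):length(j)]] <- max(ids) + 1L
      }
    }
    cl[i] <- next_id + ids
    next_id <- max(cl[i])
  }
  if (n_split > 0) {
    warn(paste0(n_split, " cluster(s) wider than 10x tolerance split at ",
                "their largest gap"))
  }
  h$cluster <- cl
  loci <- h %>%
    group_by(.data$cluster) %>%
    summarise(chromosome = .data$chromosome[1],
              position = as.integer(floor(median(.data$breakpoint))),
              class = .data$class[1],
              te_family = {
                fams <- if (!is.null(family_of_edge))
                  family_of_edge[.data$edge_id] else NA_character_
                fams <- fams[!is.na(fams)]
                if (length(unique(fams)) == 1) fams[1] else .data$class[1]
              },
              n_hits = dplyr::n(),
              .groups = "drop") %>%
    arrange(.data$chromosome, .data$position) %>%
    mutate(locus_id = sprintf("N%05d", row_number()))
  id_of_cluster <- setNames(loci$locus_id, loci$cluster)
  support <- h %>%
    mutate(locus_id = id_of_cluster[as.character(.data$cluster)]) %>%
    count(.data$locus_id, .data$line_id, name = "n_support") %>%
    filter(.data$n_support >= min_support)
  G <- matrix(0L, nrow(loci), length(lines),
              dimnames = list(loci$locus_id, lines))
  ok <- support$line_id %in% lines
  G[cbind(match(support$locus_id[ok], loci$locus_id),
          match(support$line_id[ok], lines))] <- 1L
  carried <- rowSums(G) >= 1
  loci <- loci[carried, , drop = FALSE] %>%
    select("locus_id", "chromosome", "position", "te_family", "class",
           "n_hits")
  genotypes <- dplyr::bind_cols(tibble(locus_id = loci$locus_id),
                                as_tibble(G[carried, , drop = FALSE]))
  list(loci = loci, genotypes = genotypes)
}

#' Sharing spectrum of a genotype table
#'
#' Counts loci present in exactly one line, exactly two lines, and three
#' or more lines.
#'
#' @param genotypes Wide genotype tibble.
#' @return Tibble sharing (`"1"`, `"2"`, `">=3"`), n, proportion.
#' @export
sharing_spectrum <- function(genotypes) {
  lines <- genotype_lines(genotypes)
  carriers <- rowSums(genotypes[, lines, drop = FALSE] == 1L,
                      na.rm = TRUE)
  n <- c(sum(carriers == 1), sum(carriers == 2), sum(carriers >= 3))
  tibble(sharing = c("1", "2", ">=3"), n = n,
         proportion = if (sum(n) > 0) n / sum(n) else rep(NA_real_, 3))
}

#' Per-population carrier frequencies
#'
#' Carrier fraction per locus per population over genotyped (non-missing)
#' lines; a population with zero genotyped lines at a locus yields
#' `NA` with `defined = FALSE`, not 0.
#'
#' @param genotypes Wide genotype tibble (0/1/NA).
#' @param panel Tibble line_id, population.
#' @return Tibble locus_id, population, n_carriers, n_genotyped,
#'   frequency, defined.
#' @export
population_frequencies <- function(genotypes, panel) {
  lines <- genotype_lines(genotypes)
  missing_panel <- setdiff(lines, panel$line_id)
  if (length(missing_panel)) {
    abort(paste0("panel labels missing for line(s): ",
                 paste(head(missing_panel, 5), collapse = ", ")))
  }
  purrr::map_dfr(unique(panel$population), function(pop) {
    ids <- intersect(panel$line_id[panel$population == pop], lines)
    M <- as.matrix(genotypes[, ids, drop = FALSE])
    n_gen <- rowSums(!is.na(M))
    n_car <- rowSums(M == 1L, na.rm = TRUE)
    tibble(locus_id = genotypes$locus_id, population = pop,
           n_carriers = n_car, n_genotyped = n_gen,
           frequency = ifelse(n_gen > 0, n_car / n_gen, NA_real_),
           defined = n_gen > 0)
  })
}

# ---- per-line and panel drivers ---------------------------------------

#' Scan one line's reads for junction hits
#'
#' Runs [qc_reads()], [match_te_edge()], [reference_te_filter()] and
#' [map_flank()] in order.
#'
#' @param reads Read tibble or FASTQ path.
#' @param edge_idx An [edge_index()] (or edge database).
#' @param index A [build_scan_index()].
#' @param line_id Line identifier.
#' @param quality_threshold,min_length Passed to [qc_reads()].
#' @return Tibble of junction hits for the line.
#' @export
scan_line <- function(reads, edge_idx, index, line_id,
                      quality_threshold = 20, min_length = 75) {
  reads <- qc_reads(reads, quality_threshold, min_length)
  stubs <- match_te_edge(reads, edge_idx, line_id = line_id)
  if (nrow(stubs) == 0) return(map_flank(stubs, index))
  keep <- reference_te_filter(stubs$read_sequence, index)
  map_flank(stubs[keep, , drop = FALSE], index)
}

#' Scan a simulated panel end-to-end
#'
#' Generates each line's reads with [reads_for_line()], scans them, and
#' clusters all junction hits into genotyped loci. Memory stays flat: one
#' line's reads exist at a time.
#'
#' @param truth A [simulate_panel()] truth set.
#' @param reference The matching reference.
#' @param edge_db Edge database (defaults to one built from the
#'   reference's TE library).
#' @param tolerance_bp,min_support Passed to [cluster_hits()].
#' @param verbose Print per-line progress.
#' @return List: `hits`, `loci`, `genotypes` (all panel lines as columns).
#' @export
scan_simulated_panel <- function(truth, reference,
                                 edge_db = build_edge_db(reference$te_library),
                                 tolerance_bp = 10, min_support = 1,
                                 verbose = FALSE) {
  idx <- build_scan_index(reference)
  eidx <- edge_index(edge_db)
  stubs <- purrr::map_dfr(truth$panel$line_id, function(id) {
    if (verbose) message("matching ", id)
    match_te_edge(qc_reads(reads_for_line(truth, reference, id)),
                  eidx, line_id = id)
  })
  hits <- finish_scan(stubs, idx)
  res <- cluster_hits(hits, tolerance_bp = tolerance_bp,
                      min_support = min_support,
                      lines = truth$panel$line_id, edge_db = edge_db)
  c(list(hits = hits), res)
}

# Pooled tail of the scan: reference filtering and flank placement over
# the stubs of the whole panel at once (one seed index pass instead of
# one per line).
finish_scan <- function(stubs, index) {
  if (nrow(stubs) == 0) return(map_flank(stubs, index))
  keep <- reference_te_filter(stubs$read_sequence, index)
  map_flank(stubs[keep, , drop = FALSE], index)
}

#' Scan a directory of per-line FASTQ files
#'
#' Files must be named `<line_id>.fastq`.
#'
#' @param dir Directory of FASTQ files.
#' @param reference Reference (any form accepted by [build_scan_index()]).
#' @param edge_db An edge database.
#' @param panel Optional tibble line_id, population; genotype columns then
#'   cover all panel lines.
#' @inheritParams scan_simulated_panel
#' @return As [scan_simulated_panel()].
#' @export
scan_fastq_dir <- function(dir, reference, edge_db, panel = NULL,
                           tolerance_bp = 10, min_support = 1,
                           verbose = FALSE) {
  files <- list.files(dir, pattern = "\\.fastq$", full.names = TRUE)
  if (!length(files)) abort(paste0("no .fastq files under ", dir))
  idx <- build_scan_index(reference)
  eidx <- edge_index(edge_db)
  stubs <- purrr::map_dfr(files, function(f) {
    id <- sub("\\.fastq$", "", basename(f))
    if (verbose) message("matching ", id)
    match_te_edge(qc_reads(read_fastq(f)), eidx, line_id = id)
  })
  hits <- finish_scan(stubs, idx)
  lines <- if (!is.null(panel)) panel$line_id else NULL
  res <- cluster_hits(hits, tolerance_bp = tolerance_bp,
                      min_support = min_support, lines = lines,
                      edge_db = edge_db)
  c(list(hits = hits), res)
}
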