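# The junction-scan pipeline: QC, edge matching, reference filtering,
# flank placement, clustering, genotyping, frequencies.

ref_idx <- build_scan_index(tiny_ref)

test_that("qc_reads applies the trim/drop/truncate rule", {
  r <- tibble::tibble(
    read_id = c("a", "b", "c"),
    sequence = c(strrep("A", 100), strrep("C", 70),
                 paste0(strrep("G", 75), strrep("T", 30))),
    quality = c(strrep("I", 100), strrep("I", 70),
                paste0(strrep("I", 75), strrep("#", 30))))
  out <- qc_reads(r, quality_threshold = 20, min_length = 75)
  # 100 bp all-Q40 -> 75 bp; 70 bp dropped; trailing Q2 run removed first
  expect_equal(out$read_id, c("a", "c"))
  expect_true(all(nchar(out$sequence) == 75))
  expect_identical(out$sequence[2], strrep("G", 75))
  # malformed record aborts with its index
  bad <- tibble::tibble(read_id = "x", sequence = "ACGT", quality = "II")
  expect_error(qc_reads(bad), "index: 1")
})

test_that("match_te_edge honours the 20-55 bp terminal rule on both strands", {
  set.seed(1)
  te <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
              collapse = "")
  lib <- tibble::tibble(te_id = "RLG_t", class = "LTR/Gypsy",
                        sequence = te)
  db <- build_edge_db(lib)
  flank <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
  mk <- function(seq) tibble::tibble(read_id = "r", sequence = seq,
                                     quality = strrep("I", 75))
  # read = last 30 bp of the TE (3' edge suffix) + 45 bp flank
  r1 <- mk(paste0(substr(te, 371, 400), substr(flank, 1, 45)))
  s1 <- match_te_edge(r1, db)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$te_match_len, 30L)
  expect_equal(nchar(s1$flank_sequence), 45L)
  expect_equal(s1$te_side, "left")
  expect_equal(s1$strand, "+")
  # same read reverse-complemented: found on the minus strand
  s1rc <- match_te_edge(mk(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(r1$sequence)))), db)
  expect_equal(nrow(s1rc), 1)
  expect_equal(s1rc$te_match_len, 30L)
  expect_equal(s1rc$strand, "-")
  # 19-bp terminal match is below the floor
  r2 <- mk(paste0(substr(te, 382, 400), substr(flank, 1, 56)))
  expect_equal(nrow(match_te_edge(r2, db)), 0)
  # read entirely inside the TE: no >= 20-bp non-TE segment
  r3 <- mk(substr(te, 101, 175))
  expect_equal(nrow(match_te_edge(r3, db)), 0)
  # 5' junction: 40 bp flank + first 35 bp of TE; maximal k kept
  r4 <- mk(paste0(substr(flank, 1, 40), substr(te, 1, 35)))
  s4 <- match_te_edge(r4, db)
  expect_equal(nrow(s4), 1)
  expect_equal(s4$te_match_len, 35L)
  expect_equal(s4$te_side, "right")
  # hard invariant: te_match_len + flank length = 75
  for (s in list(s1, s1rc, s4)) {
    expect_equal(s$te_match_len + nchar(s$flank_sequence), 75L)
  }
})

test_that("reference filter discards >=65 bp / >=95% identity matches only", {
  chrom <- tiny_ref$genome[[1]]
  exact <- substr(chrom, 5001, 5075)
  two_err <- exact
  substr(two_err, 10, 10) <- if (substr(two_err, 10, 10) == "A") "C" else "A"
  substr(two_err, 40, 40) <- if (substr(two_err, 40, 40) == "G") "T" else "G"
  # 45-bp reference flank + 30 bp foreign sequence: max span 45 < 65
  set.seed(2)
  foreign <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                   collapse = "")
  junction <- paste0(substr(chrom, 5001, 5045), foreign)
  keep <- reference_te_filter(c(exact, two_err, junction), ref_idx)
  expect_identical(keep, c(FALSE, FALSE, TRUE))
  # reverse-complemented exact read is caught on the minus strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(exact)))
  expect_false(reference_te_filter(rc, ref_idx))
  # 4 errors inside every >= 65-bp window push identity below 95%
  four_err <- exact
  for (p in c(20, 30, 40, 50)) {
    substr(four_err, p, p) <-
      if (substr(four_err, p, p) == "A") "C" else "A"
  }
  expect_true(reference_te_filter(four_err, ref_idx))
})

test_that("map_flank enforces perfect unique placement and breakpoints", {
  chrom <- tiny_ref$genome[[1]]
  stub <- function(flank, side) tibble::tibble(
    read_id = "r", line_id = "L1", edge_id = "edge0001",
    class = "DNA", te_match_len = 75L - nchar(flank),
    te_side = side, strand = "+", flank_sequence = flank,
    read_sequence = strrep("A", 75))
  # unique 45-bp flank, TE to its right: breakpoint = flank end
  fl <- substr(chrom, 9001, 9045)
  h <- map_flank(stub(fl, "right"), ref_idx)
  expect_equal(h$breakpoint, 9045L)
  expect_equal(h$chromosome, names(tiny_ref$genome)[1])
  # TE to the left: breakpoint = base before the flank start
  h2 <- map_flank(stub(fl, "left"), ref_idx)
  expect_equal(h2$breakpoint, 9000L)
  # one mismatch: no hit
  fl_mm <- fl
  substr(fl_mm, 20, 20) <- if (substr(fl_mm, 20, 20) == "A") "C" else "A"
  expect_equal(nrow(map_flank(stub(fl_mm, "right"), ref_idx)), 0)
  # duplicated flank (two genomic locations): no hit
  dup <- paste0(substr(chrom, 1, 2000),
                substr(chrom, 1001, 1030),  # re-embed a 30-mer
                substr(chrom, 2031, nchar(chrom)))
  idx2 <- build_scan_index(c(chrA = dup))
  expect_equal(nrow(map_flank(stub(substr(chrom, 1001, 1030), "right"),
                              idx2)), 0)
})

test_that("clustering merges within tolerance, splits across, genotypes lines", {
  hit <- function(bp, line, class = "DNA") tibble::tibble(
    read_id = paste0("r", bp, line), line_id = line, edge_id = "e",
    class = class, te_match_len = 30L, te_side = "right", strand = "+",
    flank_sequence = "F", read_sequence = "R", chromosome = "chr1",
    breakpoint = bp, ref_strand = "+")
  h <- dplyr::bind_rows(hit(100, "A"), hit(103, "B"), hit(603, "A"))
  res <- cluster_hits(h, tolerance_bp = 10, lines = c("A", "B", "C"))
  expect_equal(nrow(res$loci), 2)
  expect_equal(res$loci$position[1], 101L)  # floor(median(100,103))
  expect_equal(as.numeric(res$genotypes[1, c("A", "B", "C")]),
               c(1, 1, 0))
  expect_equal(as.numeric(res$genotypes[2, c("A", "B", "C")]),
               c(1, 0, 0))
  # same position, different class: two loci
  h2 <- dplyr::bind_rows(hit(100, "A", "DNA"), hit(100, "A", "LTR/Gypsy"))
  expect_equal(nrow(cluster_hits(h2, 10)$loci), 2)
  # min_support: singleton hit suppressed at min_support = 2
  res2 <- cluster_hits(h, tolerance_bp = 10, min_support = 2,
                       lines = c("A", "B"))
  expect_equal(nrow(res2$loci), 0)
  # chain wider than 10x tolerance is split at the largest gap
  chain <- dplyr::bind_rows(lapply(seq(0, 120, by = 8), function(o)
    hit(1000 + o, "A")))
  expect_warning(res3 <- cluster_hits(chain, tolerance_bp = 10),
                 "split")
  expect_gt(nrow(res3$loci), 1)
})

test_that("sharing spectrum and population frequencies follow definitions", {
  g <- geno_tbl(c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, 1, 1, 1))
  sp <- sharing_spectrum(g)
  expect_equal(sp$n, c(1, 1, 1))
  expect_equal(sum(sp$n), nrow(g))
  panel <- tibble::tibble(line_id = paste0("L", 1:4),
                          population = c("temperate", "temperate",
                                         "tropical", "tropical"))
  fr <- population_frequencies(g, panel)
  expect_equal(fr$frequency[fr$locus_id == "M001" &
                              fr$population == "temperate"], 0.5)
  expect_equal(fr$frequency[fr$locus_id == "M001" &
                              fr$population == "tropical"], 0)
  # missing genotypes leave the denominator
  g2 <- g
  g2$L1[1] <- NA
  fr2 <- population_frequencies(g2, panel)
  expect_equal(fr2$frequency[fr2$locus_id == "M001" &
                               fr2$population == "temperate"], 0)
  expect_equal(fr2$n_genotyped[fr2$locus_id == "M001" &
                                 fr2$population == "temperate"], 1)
  # unlabeled line aborts
  expect_error(population_frequencies(g, panel[-1, ]), "panel labels")
})

test_that("panel scan recovers the truth set exactly on error-free reads", {
  scan <- tiny_scan
  truth <- tiny_truth
  m <- match_loci_to_truth(scan$loci, truth)
  expect_equal(sort(unique(m$locus_id.truth)), sort(truth$loci$locus_id))
  expect_equal(nrow(scan$loci), nrow(truth$loci))
  lines <- truth$panel$line_id
  called <- as.matrix(scan$genotypes[
    match(m$locus_id.call, scan$genotypes$locus_id), lines])
  planted <- as.matrix(truth$genotypes[
    match(m$locus_id.truth, truth$genotypes$locus_id), lines])
  expect_equal(unname(called), unname(planted))
  # no call at or near an embedded reference TE copy
  for (i in seq_len(nrow(tiny_ref$ref_te_copies))) {
    cp <- tiny_ref$ref_te_copies[i, ]
    near <- scan$loci$chromosome == cp$chromosome &
      scan$loci$position >= cp$start - 100 &
      scan$loci$position <= cp$end + 100
    expect_equal(sum(near), 0)
  }
  # hard invariant on every hit
  expect_true(all(scan$hits$te_match_len +
                    nchar(scan$hits$flank_sequence) == 75L))
  expect_true(all(scan$hits$te_match_len >= 20 &
                    scan$hits$te_match_len <= 55))
})

test_that("genotypes are invariant to read order and line order", {
  reads <- reads_for_line(tiny_truth, tiny_ref, "TEM002")
  eidx <- nrte:::edge_index(tiny_edges)
  h1 <- scan_line(reads, eidx, ref_idx, "TEM002")
  set.seed(9)
  h2 <- scan_line(reads[sample(nrow(reads)), ], eidx, ref_idx, "TEM002")
  expect_equal(dplyr::arrange(h1, read_id, edge_id),
               dplyr::arrange(h2, read_id, edge_id))
  fr1 <- population_frequencies(tiny_scan$genotypes, tiny_truth$panel)
  fr2 <- population_frequencies(
    tiny_scan$genotypes,
    tiny_truth$panel[rev(seq_len(nrow(tiny_truth$panel))), ])
  expect_equal(dplyr::arrange(fr1, locus_id, population),
               dplyr::arrange(fr2, locus_id, population))
})

test_that("FASTQ-directory scanning matches the in-memory scan", {
  cfg <- tiny_config(n_lines_per_pop = c(temperate = 2, tropical = 1),
                     n_insertion_loci = 6, coverage = 5)
  ref <- simulate_reference(cfg)
  truth <- simulate_panel(cfg, ref)
  dir <- withr::local_tempdir()
  write_panel_fastq(truth, ref, dir)
  edb <- build_edge_db(ref$te_library)
  from_files <- scan_fastq_dir(dir, ref, edb, panel = truth$panel)
  in_mem <- scan_simulated_panel(truth, ref, edb)
  expect_equal(from_files$loci, in_mem$loci)
  expect_equal(from_files$genotypes, in_mem$genotypes)
})
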