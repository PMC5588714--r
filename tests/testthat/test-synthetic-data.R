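# The synthetic-data generator: validation, determinism, truth-set
# consistency, and the enumerated junction-read example.

test_that("sim_config rejects out-of-range parameters", {
  expect_error(sim_config(error_rate = 0.2), "error_rate")
  expect_error(sim_config(read_length = 50), "read_length")
  expect_error(sim_config(chrom_length = 500, read_length = 75),
               "chrom_length")
  expect_error(sim_config(n_replicates = 0), ">= 1")
  expect_error(sim_config(class_mix = c(a = 0.5, b = 0.1, c = 0.1)),
               "sum to 1")
})

test_that("reference generator handles empty-feature configs", {
  cfg <- tiny_config()
  cfg$n_genes <- 0
  cfg$reference_te_copies <- 0
  ref <- simulate_reference(cfg)
  expect_equal(nrow(ref$genes), 0)
  expect_equal(nrow(ref$ref_te_copies), 0)
  expect_equal(nchar(ref$genome[[1]]), cfg$chrom_length)
  expect_true(all(diff(ref$genetic_map$cm) >= 0))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- tiny_config()
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$te_library, r2$te_library)
  t1 <- simulate_panel(cfg, r1)
  t2 <- simulate_panel(cfg, r2)
  expect_identical(t1$loci, t2$loci)
  expect_identical(t1$genotypes, t2$genotypes)
  expect_identical(reads_for_line(t1, r1, "TEM001"),
                   reads_for_line(t2, r2, "TEM001"))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_reference(r1, d1)
  write_reference(r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("embedded reference TE copies match their library sequence", {
  ref <- tiny_ref
  for (i in seq_len(nrow(ref$ref_te_copies))) {
    cp <- ref$ref_te_copies[i, ]
    seg <- substr(ref$genome[[cp$chromosome]], cp$start, cp$end)
    lib <- ref$te_library$sequence[ref$te_library$te_id == cp$te_id]
    expect_identical(seg, if (cp$strand == "+") lib else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(lib))))
  }
})

test_that("gene features tile genes and genes avoid TE copies", {
  ref <- tiny_ref
  for (g in ref$genes$gene_id) {
    f <- dplyr::arrange(ref$features[ref$features$gene_id == g, ], start)
    gene <- ref$genes[ref$genes$gene_id == g, ]
    expect_equal(f$start[1], gene$start)
    expect_equal(f$end[nrow(f)], gene$end)
    expect_true(all(f$start[-1] == f$end[-nrow(f)] + 1))
    expect_true("exon" %in% f$feature)
  }
  # no overlap between genes and embedded copies
  for (i in seq_len(nrow(ref$ref_te_copies))) {
    cp <- ref$ref_te_copies[i, ]
    same <- ref$genes[ref$genes$chromosome == cp$chromosome, ]
    expect_false(any(same$start <= cp$end & same$end >= cp$start))
  }
})

test_that("truth frequencies are the realised carrier fractions", {
  truth <- tiny_truth
  tem <- truth$panel$line_id[truth$panel$population == "temperate"]
  tro <- truth$panel$line_id[truth$panel$population == "tropical"]
  for (i in seq_len(nrow(truth$loci))) {
    g <- truth$genotypes[i, ]
    expect_identical(g$locus_id, truth$loci$locus_id[i])
    expect_equal(mean(as.numeric(g[tem])), truth$loci$freq_temperate[i])
    expect_equal(mean(as.numeric(g[tro])), truth$loci$freq_tropical[i])
  }
  # positions respect bounds and spacing
  expect_true(all(truth$loci$position > 100 &
                    truth$loci$position < 2e5 - 100))
  d <- diff(sort(truth$loci$position))
  expect_true(all(d >= 100))
})

test_that("read count conserves coverage and zero coverage gives no reads", {
  cfg <- tiny_config()
  reads <- reads_for_line(tiny_truth, tiny_ref, "TRO001")
  donor <- donor_genome(tiny_truth, tiny_ref, "TRO001")
  dlen <- nchar(donor[[1]])
  expect_lt(abs(nrow(reads) * cfg$read_length - cfg$coverage * dlen),
            cfg$read_length)
  expect_true(all(nchar(reads$sequence) == cfg$read_length))
  cfg0 <- tiny_config(coverage = 0)
  t0 <- simulate_panel(cfg0, simulate_reference(cfg0))
  r0 <- reads_for_line(t0, simulate_reference(cfg0), "TEM001")
  expect_equal(nrow(r0), 0)
})

test_that("every error-free read spanning a breakpoint by >=20 bp on both sides is detectable", {
  # enumerate donor-coordinate read starts around one planted junction
  cfg <- tiny_config()
  truth <- tiny_truth
  ref <- tiny_ref
  line <- truth$panel$line_id[which(
    as.numeric(truth$genotypes[1, truth$panel$line_id]) == 1)][1]
  locus <- truth$loci[1, ]
  donor <- donor_genome(truth, ref, line)[[locus$chromosome]]
  carried <- truth$genotypes[[line]] == 1
  # donor position of the breakpoint: truth position plus lengths of
  # TEs inserted before it
  before <- truth$loci$position < locus$position &
    truth$loci$chromosome == locus$chromosome & carried
  te_len <- nchar(ref$te_library$sequence[
    match(truth$loci$te_id, ref$te_library$te_id)])
  P <- locus$position + sum(te_len[before])
  this_len <- te_len[match(locus$locus_id, truth$loci$locus_id)]
  starts <- (P - 80):(P + 5)
  reads <- tibble::tibble(
    read_id = paste0("r", seq_along(starts)),
    sequence = substring(donor, starts, starts + 74),
    quality = strrep("I", 75))
  stubs <- match_te_edge(reads, tiny_edges, line_id = line)
  te_overlap <- pmin(starts + 74, P + this_len) - P
  flank_overlap <- P - starts + 1
  detectable <- te_overlap >= 20 & flank_overlap >= 20 &
    te_overlap <= 55  # 75-bp read: flank >= 20 iff TE part <= 55
  expect_setequal(unique(stubs$read_id), reads$read_id[detectable])
  # and they place at exactly the truth breakpoint
  hits <- map_flank(stubs, build_scan_index(ref))
  expect_true(all(hits$breakpoint == locus$position))
})

test_that("phenotype generator matches its stated model and components", {
  cfg <- tiny_config()
  cfg$residual_sd <- 0
  cfg$line_sd <- 0
  cfg$pop_mean_shift <- 0
  cfg$n_causal_loci <- 0
  truth <- simulate_panel(cfg, tiny_ref)
  ph <- simulate_phenotypes(truth, cfg)
  expect_true(all(ph$value == 0))  # all effects off -> constant trait
  cfg2 <- tiny_config()
  truth2 <- simulate_panel(cfg2, tiny_ref)
  ph2 <- simulate_phenotypes(truth2, cfg2)
  expect_identical(ph2, simulate_phenotypes(truth2, cfg2))
  comp <- attr(ph2, "components")
  ni <- table(truth2$panel$population)
  n0 <- (sum(ni) - sum(ni^2) / sum(ni))
  expect_equal(comp$sigma2_GB_shift,
               cfg2$pop_mean_shift^2 * prod(ni) / (sum(ni) * n0))
  expect_equal(nrow(ph2), nrow(truth2$panel) * cfg2$n_replicates)
})

test_that("expression generator applies multipliers to carriers only", {
  cfg <- tiny_config(expression_multiplier = 1.0)
  truth <- simulate_panel(cfg, tiny_ref)
  e1 <- simulate_expression(truth, cfg)
  cfg2 <- tiny_config(expression_multiplier = 0.5)
  truth2 <- simulate_panel(cfg2, tiny_ref)
  e2 <- simulate_expression(truth2, cfg2)
  # same seed: identical draws; only perturbed genes of carriers differ
  eff <- truth2$expression_effects[1, ]
  carriers <- truth$panel$line_id[
    as.numeric(truth2$genotypes[
      truth2$genotypes$locus_id == eff$locus_id,
      truth$panel$line_id]) == 1]
  noncar <- setdiff(truth$panel$line_id, carriers)
  g1 <- e1[e1$gene_id == eff$gene_id, ]
  g2 <- e2[e2$gene_id == eff$gene_id, ]
  expect_equal(as.numeric(g2[carriers]), 0.5 * as.numeric(g1[carriers]))
  expect_equal(as.numeric(g2[noncar]), as.numeric(g1[noncar]))
})
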