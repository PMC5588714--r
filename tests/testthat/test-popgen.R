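# Frequency spectra, Hudson Fst + resampling CI, Qst, selection calls,
# LD statistics and blocks.

test_that("frequency spectrum bins and densities follow the conventions", {
  fr <- tibble::tibble(
    locus_id = paste0("M", 1:3), population = "temperate",
    n_carriers = c(1, 3, 9), n_genotyped = 10,
    frequency = c(0.05, 0.3, 0.9), defined = TRUE)
  sp <- freq_spectrum(fr, genome_size = 2e6)
  expect_equal(c(sp$n_low, sp$n_intermediate, sp$n_high), c(1, 1, 1))
  expect_equal(sp$n_low + sp$n_intermediate + sp$n_high, sp$n_defined)
  expect_equal(sp$density_per_mb, 3 / 2)
  # boundary convention: 0.1 and 0.5 are intermediate
  fr2 <- fr; fr2$frequency <- c(0.1, 0.5, 0.0999)
  sp2 <- freq_spectrum(fr2, 1e6)
  expect_equal(sp2$n_intermediate, 2)
  # all-zero frequencies: density 0
  fr3 <- fr; fr3$frequency <- 0
  expect_equal(freq_spectrum(fr3, 1e6)$density_per_mb, 0)
  # Beta(0.5, 5) bin proportions match the Beta CDF within 2 SE
  set.seed(7)
  n <- 4000
  f <- rbeta(n, 0.5, 5)
  fr4 <- tibble::tibble(locus_id = as.character(seq_len(n)),
                        population = "tropical", n_carriers = 0,
                        n_genotyped = 10, frequency = f, defined = TRUE)
  sp4 <- freq_spectrum(fr4, 1e6)
  p_low <- pbeta(0.1, 0.5, 5)
  expect_lt(abs(sp4$n_low / n - p_low),
            2 * sqrt(p_low * (1 - p_low) / n))
})

test_that("fst_locus matches an independent hand evaluation of Hudson's formula", {
  # independent route: write out Hw and Hb directly
  p1 <- 0.8; n1 <- 31; p2 <- 0.1; n2 <- 52
  hw <- (p1 * (1 - p1) * n1 / (n1 - 1) + p2 * (1 - p2) * n2 / (n2 - 1)) / 2
  hb <- (p1 * (1 - p2) + p2 * (1 - p1)) / 2
  expect_equal(fst_locus(p1, n1, p2, n2)$fst, 1 - hw / hb)
  # no differentiation -> ~0 at large n; fixed difference -> 1
  expect_lt(abs(fst_locus(0.5, 1e6, 0.5, 1e6)$fst), 1e-5)
  expect_equal(fst_locus(1, 31, 0, 52)$fst, 1)
  # monomorphic in both -> undefined
  expect_true(is.na(fst_locus(0, 31, 0, 52)$fst))
  # symmetry in populations and allele-relabeling invariance
  expect_equal(fst_locus(p1, n1, p2, n2)$fst,
               fst_locus(p2, n2, p1, n1)$fst)
  expect_equal(fst_locus(p1, n1, p2, n2)$fst,
               fst_locus(1 - p1, n1, 1 - p2, n2)$fst)
})

test_that("resampled Fst CI is seed-deterministic and behaves at edge cases", {
  set.seed(8)
  tbl <- tibble::tibble(locus_id = as.character(1:300),
                        num = runif(300, 0, 0.2),
                        den = runif(300, 0.2, 0.5))
  tbl$fst <- tbl$num / tbl$den
  r1 <- resample_fst(tbl, B = 200, L = 100, seed = 5)
  r2 <- resample_fst(tbl, B = 200, L = 100, seed = 5)
  expect_identical(r1$ci99, r2$ci99)
  expect_true(all(r1$resample_means >= min(tbl$fst) &
                    r1$resample_means <= max(tbl$fst)))
  # degenerate: all loci identical -> point CI
  tbl2 <- tibble::tibble(locus_id = as.character(1:50), num = 0.1,
                         den = 0.4, fst = 0.25)
  r3 <- resample_fst(tbl2, B = 10, L = 20, seed = 1)
  expect_equal(unname(r3$ci99), c(0.25, 0.25))
  # B = 1: the CI collapses onto the single replicate mean
  expect_warning(r4 <- resample_fst(tbl[1:40, ], B = 1, L = 100, seed = 2),
                 "reducing L")
  expect_equal(unname(r4$ci99[1]), unname(r4$ci99[2]))
  expect_equal(unname(r4$ci99[1]), r4$resample_means[1])
  # full-data ratio-of-sums mean inside the support
  expect_equal(r1$mean_fst, sum(tbl$num) / sum(tbl$den))
  # broom-style accessors
  expect_equal(nrow(tidy(r1)), 200)
  expect_equal(glance(r1)$ci99_lower, r1$ci99[["lower"]])
})

test_that("trait_qst agrees with an aov-based oracle and obeys identities", {
  set.seed(9)
  panel <- tibble::tibble(line_id = sprintf("L%02d", 1:20),
                          population = rep(c("a", "b"), each = 10))
  ph <- tidyr::crossing(panel, replicate = 1:3)
  ph$value <- 2 * (ph$population == "b") +
    rnorm(20, 0, 1)[match(ph$line_id, panel$line_id)] +
    rnorm(nrow(ph), 0, 0.5)
  q <- trait_qst(ph, panel)
  # independent route: line-mean ANOVA via aov + replicate-level error MS
  lm_means <- aggregate(value ~ line_id + population, ph, mean)
  a <- anova(lm(value ~ population, lm_means))
  expect_equal(q$MSB, a$`Mean Sq`[1])
  expect_equal(q$MSL, a$`Mean Sq`[2])
  err <- anova(lm(value ~ line_id, ph))$`Mean Sq`[2]
  expect_equal(q$MS_error, err)
  s2gw <- max(0, q$MSL - err / 3)
  s2gb <- max(0, (q$MSB - q$MSL) / 10)   # balanced: n0 = 10
  expect_equal(q$qst, s2gb / (s2gb + 2 * s2gw))
  # sigma2_GB = 0 -> qst = 0
  ph0 <- ph
  ph0$value <- rnorm(20)[match(ph0$line_id, panel$line_id)]
  expect_equal(trait_qst(ph0, panel)$sigma2_GB, 0)
  expect_equal(trait_qst(ph0, panel)$qst, 0)
  # plug-in identity: equal components give qst = 1/3
  expect_equal(0.5 / (0.5 + 2 * 0.5), 1 / 3)
  # qst is monotone in the population separation
  qs <- vapply(c(0, 1, 2, 4), function(d) {
    p <- ph
    p$value <- d * (p$population == "b") +
      rnorm(20, 0, 1)[match(p$line_id, panel$line_id)]
    trait_qst(p, panel)$qst
  }, 0)
  expect_true(all(diff(qs) >= 0))
  # degenerate: zero genetic variance flagged
  phc <- ph; phc$value <- 1
  expect_warning(qc <- trait_qst(phc, panel), "undefined")
  expect_true(is.na(qc$qst))
  expect_error(trait_qst(ph[ph$population == "a", ], panel),
               ">= 2 populations")
})

test_that("selection regime is called from qst against the Fst CI", {
  fake <- structure(list(ci99 = c(lower = 0.1, upper = 0.2)),
                    class = "nrte_fst")
  expect_equal(qst_fst_call(0.9, fake)$regime, "directional")
  expect_equal(qst_fst_call(0.15, fake)$regime, "drift")
  expect_equal(qst_fst_call(0.05, fake)$regime, "stabilizing")
  expect_equal(qst_fst_call(0.2, fake)$regime, "drift")  # boundary
})

test_that("ld_stats computes r2 and |D'| with filters and identities", {
  # identical markers: r2 = 1, |D'| = 1
  g <- geno_tbl(c(1, 1, 0, 0, 1, 0), c(1, 1, 0, 0, 1, 0),
                c(0, 0, 1, 1, 0, 1),
                chromosome = "chr1", position = c(100, 200, 5000))
  expect_warning(ld <- ld_stats(g, hwcutoff = 0.001), "haploid")
  row12 <- ld[ld$locus_a == "M001" & ld$locus_b == "M002", ]
  expect_equal(row12$r2, 1)
  expect_equal(row12$dprime, 1)
  # complementary markers are also in complete LD
  row13 <- ld[ld$locus_a == "M001" & ld$locus_b == "M003", ]
  expect_equal(row13$r2, 1)
  # pairs beyond max_distance are not emitted
  ld2 <- ld_stats(g, max_distance = 1000)
  expect_equal(nrow(ld2), 1)
  # monomorphic and incomplete markers are excluded
  g2 <- geno_tbl(c(1, 1, 1, 1, 1, 1), c(1, NA, NA, NA, 0, 1),
                 c(1, 0, 1, 0, 1, 0),
                 chromosome = "chr1", position = c(10, 20, 30))
  ld3 <- ld_stats(g2, min_geno = 0.8)
  expect_equal(nrow(ld3), 0)
  # algebraic identity: r2 * pa(1-pa)pb(1-pb) = D^2 on random markers
  set.seed(10)
  n <- 40
  gm <- geno_tbl(rbinom(n, 1, 0.4), rbinom(n, 1, 0.6),
                 chromosome = "chr1", position = c(1, 2))
  lds <- ld_stats(gm)
  a <- as.numeric(gm[1, paste0("L", 1:n)])
  b <- as.numeric(gm[2, paste0("L", 1:n)])
  D <- mean(a & b) - mean(a) * mean(b)
  expect_equal(lds$r2 * mean(a) * (1 - mean(a)) * mean(b) * (1 - mean(b)),
               D^2)
  expect_true(all(lds$r2 >= 0 & lds$r2 <= 1))
  expect_true(all(lds$dprime >= 0 & lds$dprime <= 1))
  # independent markers: mean r2 ~ 1/n within 2 SE
  set.seed(11)
  nl <- 200
  cols <- lapply(1:60, function(i) rbinom(nl, 1, 0.5))
  gn <- do.call(geno_tbl, c(cols, list(chromosome = "chr1",
                                       position = seq(1e3, 6e4, 1e3))))
  ldn <- ld_stats(gn)
  expect_lt(abs(mean(ldn$r2) - 1 / nl),
            2 * sd(ldn$r2) / sqrt(nrow(ldn)) + 0.002)
})

test_that("Gabriel-rule blocks: perfect runs form blocks, recombinants split them", {
  set.seed(12)
  n <- 60
  hap <- rbinom(n, 1, 0.5)
  # five markers in perfect LD, a recombinant, then three more in LD
  block1 <- lapply(1:5, function(i) hap)
  rec <- list(rbinom(n, 1, 0.5))
  hap2 <- rbinom(n, 1, 0.5)
  block2 <- lapply(1:3, function(i) hap2)
  g <- do.call(geno_tbl, c(block1, rec, block2, list(
    chromosome = "chr1", position = c(1:5 * 100, 2000, 3:5 * 1000))))
  ld <- ld_stats(g, boot_ci = 60, seed = 3)
  pos <- g[, c("locus_id", "chromosome", "position")]
  bl <- ld_blocks(ld, pos)
  expect_equal(nrow(bl$blocks), 2)
  expect_equal(sort(bl$blocks$n_markers), c(3, 5))
  # all-independent markers: essentially no blocks
  cols <- lapply(1:8, function(i) rbinom(n, 1, 0.5))
  gi <- do.call(geno_tbl, c(cols, list(chromosome = "chr1",
                                       position = 1:8 * 500)))
  ldi <- ld_stats(gi, boot_ci = 60, seed = 4)
  bli <- ld_blocks(ldi, gi[, c("locus_id", "chromosome", "position")])
  expect_lte(nrow(bli$blocks), 1)
  # size classes count blocks >= 5 kb
  expect_equal(sum(bl$size_classes$n), nrow(bl$blocks))
})
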