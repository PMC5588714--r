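# Population genetics on presence/absence insertion markers: frequency
# spectra, Hudson Fst with a resampling confidence interval, Qst from
# nested variance components, the Qst-Fst selection call, and linkage
# disequilibrium statistics and Gabriel-rule blocks.

#' Per-population frequency spectrum of insertion loci
#'
#' Bins per-locus carrier frequencies into low `[0, 0.1)`, intermediate
#' `[0.1, 0.5]` and high `(0.5, 1]` classes, and reports the mean
#' frequency over segregating loci (frequency > 0) and the density of
#' segregating loci per Mb of genome.
#'
#' @param freqs Output of [population_frequencies()].
#' @param genome_size Genome size in bp.
#' @return Tibble per population: n_low, n_intermediate, n_high,
#'   n_defined, mean_frequency, density_per_mb.
#' @export
freq_spectrum <- function(freqs, genome_size) {
  freqs %>%
    filter(.data$defined) %>%
    group_by(.data$population) %>%
    summarise(
      n_low = sum(.data$frequency < 0.1),
      n_intermediate = sum(.data$frequency >= 0.1 & .data$frequency <= 0.5),
      n_high = sum(.data$frequency > 0.5),
      n_defined = dplyr::n(),
      mean_frequency = mean(.data$frequency[.data$frequency > 0]),
      density_per_mb = sum(.data$frequency > 0) / (genome_size / 1e6),
      .groups = "drop")
}

#' Hudson's Fst for one biallelic presence/absence locus
#'
#' With carrier fractions `p1`, `p2` over `n1`, `n2` haploid (inbred)
#' lines: within-population heterozygosity
#' `Hw = (p1 (1-p1) n1/(n1-1) + p2 (1-p2) n2/(n2-1)) / 2` (sample-size
#' corrected), between-population `Hb = (p1 (1-p2) + p2 (1-p1)) / 2`, and
#' `Fst = 1 - Hw/Hb`. Undefined (NA) when `Hb = 0` (monomorphic in both
#' populations).
#'
#' @param p1,p2 Carrier fractions.
#' @param n1,n2 Haploid sample sizes (>= 2).
#' @return Tibble fst, num (`Hb - Hw`), den (`Hb`); `num` and `den`
#'   support ratio-of-sums averaging across loci.
#' @export
fst_locus <- function(p1, n1, p2, n2) {
  stopifnot(all(n1 >= 2), all(n2 >= 2))
  hw <- 0.5 * (p1 * (1 - p1) * n1 / (n1 - 1) +
               p2 * (1 - p2) * n2 / (n2 - 1))
  hb <- 0.5 * (p1 * (1 - p2) + p2 * (1 - p1))
  fst <- ifelse(hb > 0, 1 - hw / hb, NA_real_)
  tibble(fst = fst, num = ifelse(hb > 0, hb - hw, NA_real_),
         den = ifelse(hb > 0, hb, NA_real_))
}

#' Per-locus Fst table for a genotyped panel
#'
#' @param genotypes Wide genotype tibble.
#' @param panel Tibble line_id, population (exactly two populations).
#' @param estimator `"hudson"` (default) or `"wc"` (Weir-Cockerham theta
#'   for haploid samples).
#' @return Tibble locus_id, p1, n1, p2, n2, fst, num, den (informative
#'   loci only; monomorphic-in-both loci are dropped).
#' @export
fst_panel <- function(genotypes, panel, estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  pops <- unique(panel$population)
  if (length(pops) != 2) abort("fst_panel needs exactly two populations")
  fr <- population_frequencies(genotypes, panel) %>%
    tidyr::pivot_wider(id_cols = "locus_id",
                       names_from = "population",
                       values_from = c("frequency", "n_genotyped"))
  p1 <- fr[[paste0("frequency_", pops[1])]]
  p2 <- fr[[paste0("frequency_", pops[2])]]
  n1 <- fr[[paste0("n_genotyped_", pops[1])]]
  n2 <- fr[[paste0("n_genotyped_", pops[2])]]
  est <- if (estimator == "hudson") fst_locus(p1, n1, p2, n2) else
    fst_locus_wc(p1, n1, p2, n2)
  out <- dplyr::bind_cols(tibble(locus_id = fr$locus_id,
                                 p1 = p1, n1 = n1, p2 = p2, n2 = n2), est)
  out[!is.na(out$fst), , drop = FALSE]
}

# Weir-Cockerham theta for two haploid samples (no heterozygotes); offered
# as an alternative estimator behind the `estimator` switch.
fst_locus_wc <- function(p1, n1, p2, n2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2)
  den <- a + b
  tibble(fst = ifelse(den > 0, a / den, NA_real_),
         num = ifelse(den > 0, a, NA_real_),
         den = ifelse(den > 0, den, NA_real_))
}

#' Resampled mean-Fst distribution with a 99% confidence interval
#'
#' Repeatedly (`B` times) draws `L` informative loci without replacement,
#' computes the ratio-of-sums mean Fst of each draw, and reports the
#' empirical 0.5% and 99.5% percentiles of the `B` replicate means. If
#' fewer than `L` informative loci exist, `L` is reduced with a warning.
#'
#' @param fst_tbl From [fst_panel()].
#' @param B Number of resampling replicates.
#' @param L Loci per replicate.
#' @param seed RNG seed (replicates are seed-deterministic).
#' @return Object of class `nrte_fst` : list with `mean_fst` (full-data
#'   ratio of sums), `resample_means`, `ci99`, `B`, `L`, `per_locus`.
#' @export
resample_fst <- function(fst_tbl, B = 1000, L = 1000, seed = 1) {
  ok <- fst_tbl[!is.na(fst_tbl$num) & !is.na(fst_tbl$den), , drop = FALSE]
  if (nrow(ok) == 0) abort("no informative loci for Fst resampling")
  if (nrow(ok) < L) {
    warn(paste0("only ", nrow(ok), " informative loci; reducing L from ",
                L))
    L <- nrow(ok)
  }
  means <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      i <- sample.int(nrow(ok), L)
      sum(ok$num[i]) / sum(ok$den[i])
    }, 0)
  })
  ci <- unname(quantile(means, c(0.005, 0.995), type = 7))
  structure(list(mean_fst = sum(ok$num) / sum(ok$den),
                 resample_means = means,
                 ci99 = c(lower = ci[1], upper = ci[2]),
                 B = B, L = L, per_locus = ok),
            class = "nrte_fst")
}

#' @export
print.nrte_fst <- function(x, ...) {
  cat("<nrte_fst> mean Fst (ratio of sums) = ",
      format(x$mean_fst, digits = 4), "; 99% CI of ", x$B,
      " resampled means of ", x$L, " loci: [",
      format(x$ci99[["lower"]], digits = 4), ", ",
      format(x$ci99[["upper"]], digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Qst from a nested ANOVA of a replicated trait
#'
#' Estimates the among-population (`sigma2_GB`) and among-line-within-
#' population (`sigma2_GW`) genetic variance components by expected mean
#' squares on line means (replicate noise is estimated from the replicate
#' level and removed from the within component, so Qst reflects genetic
#' variance only), then forms
#' `Qst = sigma2_GB / (sigma2_GB + 2 sigma2_GW)`.
#' Negative component estimates are clamped to zero. The unbalanced
#' effective sample size is `n0 = (N - sum(ni^2)/N) / (k - 1)`.
#'
#' @param trait Tibble line_id, replicate, value (one trait; use
#'   [trait_qst_all()] or group beforehand for several), as from
#'   [simulate_phenotypes()].
#' @param panel Tibble line_id, population.
#' @return Object of class `nrte_qst`: tibble row with MSB, MSL, MS_error,
#'   n0, r, sigma2_GB, sigma2_GW, qst.
#' @export
trait_qst <- function(trait, panel) {
  d <- trait[, c("line_id", "value")] %>%
    dplyr::inner_join(panel[, c("line_id", "population")], by = "line_id")
  if (dplyr::n_distinct(d$population) < 2) {
    abort("Qst needs >= 2 populations")
  }
  lines <- d %>%
    group_by(.data$line_id, .data$population) %>%
    summarise(m = mean(.data$value), nrep = dplyr::n(), .groups = "drop")
  if (any(table(lines$population) < 2)) {
    abort("Qst needs >= 2 lines per population")
  }
  r_h <- 1 / mean(1 / lines$nrep)  # harmonic-mean replicates per line
  # replicate-level error mean square
  n_rep_total <- nrow(d)
  N <- nrow(lines)
  ms_error <- if (n_rep_total > N) {
    sse <- d %>%
      group_by(.data$line_id) %>%
      summarise(ss = sum((.data$value - mean(.data$value))^2),
                .groups = "drop")
    sum(sse$ss) / (n_rep_total - N)
  } else 0
  k <- dplyr::n_distinct(lines$population)
  pop_means <- lines %>%
    group_by(.data$population) %>%
    summarise(pm = mean(.data$m), ni = dplyr::n(), .groups = "drop")
  grand <- mean(lines$m)
  msb <- sum(pop_means$ni * (pop_means$pm - grand)^2) / (k - 1)
  msl <- lines %>%
    dplyr::inner_join(pop_means, by = "population") %>%
    summarise(ss = sum((.data$m - .data$pm)^2)) %>%
    pull(.data$ss) / (N - k)
  n0 <- (N - sum(pop_means$ni^2) / N) / (k - 1)
  s2gw <- max(0, msl - ms_error / r_h)
  s2gb <- max(0, (msb - msl) / n0)
  denom <- s2gb + 2 * s2gw
  qst <- if (denom > 0) s2gb / denom else NA_real_
  if (denom <= 0) warn("zero total genetic variance; Qst undefined")
  out <- tibble(MSB = msb, MSL = msl, MS_error = ms_error, n0 = n0,
                r = r_h, sigma2_GB = s2gb, sigma2_GW = s2gw, qst = qst)
  class(out) <- c("nrte_qst", class(out))
  out
}

#' Qst for every trait in a long phenotype table
#'
#' @param phenotypes Tibble line_id, trait, replicate, value.
#' @param panel Tibble line_id, population.
#' @return Tibble with one `nrte_qst` row per trait.
#' @export
trait_qst_all <- function(phenotypes, panel) {
  purrr::map_dfr(unique(phenotypes$trait), function(tr) {
    q <- trait_qst(phenotypes[phenotypes$trait == tr, , drop = FALSE],
                   panel)
    dplyr::bind_cols(tibble(trait = tr), as_tibble(q))
  })
}

#' Selection-regime call from Qst against the resampled Fst distribution
#'
#' Directional selection when Qst lies above the 99% CI of the resampled
#' mean-Fst distribution, stabilizing selection when below, genetic drift
#' within.
#'
#' @param qst_value A Qst value (or `nrte_qst` row).
#' @param fst_result An [resample_fst()] result.
#' @return Tibble regime, qst, fst_ci_lower, fst_ci_upper.
#' @export
qst_fst_call <- function(qst_value, fst_result) {
  if (inherits(qst_value, "nrte_qst")) qst_value <- qst_value$qst
  lo <- fst_result$ci99[["lower"]]
  hi <- fst_result$ci99[["upper"]]
  regime <- dplyr::case_when(qst_value > hi ~ "directional",
                             qst_value < lo ~ "stabilizing",
                             TRUE ~ "drift")
  tibble(regime = regime, qst = qst_value, fst_ci_lower = lo,
         fst_ci_upper = hi)
}

# ---- linkage disequilibrium -------------------------------------------

#' Pairwise LD statistics (r2 and |D'|) for haploid 0/1 markers
#'
#' Markers with completeness below `min_geno` or monomorphic are removed;
#' for every retained pair on the same chromosome within `max_distance`,
#' r2 and |D'| are computed from the 2x2 haplotype table. A
#' Hardy-Weinberg cutoff is accepted for interface compatibility but is
#' inapplicable to haploid inbred data and ignored with a warning.
#' Optionally attaches a nonparametric bootstrap percentile CI for |D'|
#' (resampling lines).
#'
#' @param genotypes Wide genotype tibble with locus_id, chromosome,
#'   position columns plus line columns, or list(loci, genotypes) as from
#'   [cluster_hits()].
#' @param max_distance Maximum pair separation in bp (default 500 kb).
#' @param min_geno Minimum fraction of genotyped lines per marker.
#' @param hwcutoff Ignored (haploid data); a warning is emitted if set.
#' @param boot_ci Number of bootstrap replicates for the |D'| CI (0 = no
#'   CI).
#' @param seed Seed for the bootstrap.
#' @return Tibble locus_a, locus_b, distance, r2, dprime, and (with
#'   `boot_ci > 0`) dprime_lo, dprime_hi.
#' @export
ld_stats <- function(genotypes, max_distance = 5e5, min_geno = 0.5,
                     hwcutoff = NULL, boot_ci = 0, seed = 1) {
  if (!is.null(hwcutoff)) {
    warn("hwcutoff is inapplicable to haploid inbred genotypes; ignored")
  }
  if (is.list(genotypes) && !is.data.frame(genotypes) &&
      all(c("loci", "genotypes") %in% names(genotypes))) {
    genotypes <- dplyr::inner_join(
      genotypes$loci[, c("locus_id", "chromosome", "position")],
      genotypes$genotypes, by = "locus_id")
  }
  stopifnot(all(c("locus_id", "chromosome", "position") %in%
                  names(genotypes)))
  lines <- genotype_lines(genotypes)
  M <- as.matrix(genotypes[, lines])
  completeness <- rowMeans(!is.na(M))
  freq <- rowMeans(M == 1, na.rm = TRUE)
  keep <- completeness >= min_geno & freq > 0 & freq < 1
  g <- genotypes[keep, , drop = FALSE]
  M <- M[keep, , drop = FALSE]
  empty <- tibble(locus_a = character(), locus_b = character(),
                  distance = integer(), r2 = numeric(), dprime = numeric())
  if (nrow(g) < 2) return(empty)
  pairs <- purrr::map_dfr(unique(g$chromosome), function(chr) {
    i <- which(g$chromosome == chr)
    if (length(i) < 2) return(NULL)
    cmb <- utils::combn(i, 2)
    d <- abs(g$position[cmb[2, ]] - g$position[cmb[1, ]])
    ok <- d <= max_distance
    tibble(ia = cmb[1, ok], ib = cmb[2, ok], distance = d[ok])
  })
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)
  stat <- purrr::map_dfr(seq_len(nrow(pairs)), function(j) {
    ld_pair(M[pairs$ia[j], ], M[pairs$ib[j], ])
  })
  out <- tibble(locus_a = g$locus_id[pairs$ia],
                locus_b = g$locus_id[pairs$ib],
                chromosome = g$chromosome[pairs$ia],
                pos_a = g$position[pairs$ia],
                pos_b = g$position[pairs$ib],
                distance = pairs$distance,
                r2 = stat$r2, dprime = stat$dprime)
  if (boot_ci > 0) {
    ci <- with_seed(seed, {
      nl <- ncol(M)
      reps <- vapply(seq_len(boot_ci), function(b) {
        s <- sample.int(nl, nl, replace = TRUE)
        vapply(seq_len(nrow(pairs)), function(j) {
          ld_pair(M[pairs$ia[j], s], M[pairs$ib[j], s])$dprime
        }, 0)
      }, numeric(nrow(pairs)))
      reps <- matrix(reps, nrow = nrow(pairs))
      t(apply(reps, 1, quantile, probs = c(0.05, 0.95), na.rm = TRUE))
    })
    out$dprime_lo <- ci[, 1]
    out$dprime_hi <- ci[, 2]
  }
  out
}

# r2 and |D'| from two haploid 0/1 vectors (complete pairs only).
ld_pair <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    return(tibble(r2 = NA_real_, dprime = NA_real_))
  }
  pab <- mean(a == 1 & b == 1)
  D <- pab - pa * pb
  dmax <- if (D >= 0) min(pa * (1 - pb), pb * (1 - pa)) else
    min(pa * pb, (1 - pa) * (1 - pb))
  tibble(r2 = D^2 / (pa * (1 - pa) * pb * (1 - pb)),
         dprime = if (dmax > 0) abs(D) / dmax else NA_real_)
}

#' Gabriel-rule LD blocks from pairwise |D'| confidence intervals
#'
#' A marker pair is in "strong LD" when its |D'| CI has lower bound >=
#' 0.70 and upper bound >= 0.98, and shows "evidence of recombination"
#' when the upper bound < 0.90. Maximal runs of consecutive markers in
#' which at least 95% of informative pairs are in strong LD become
#' blocks (longest-first, non-overlapping).
#'
#' @param ld Output of [ld_stats()] with bootstrap CIs (`boot_ci > 0`).
#' @param positions Tibble locus_id, chromosome, position for all markers
#'   that entered [ld_stats()].
#' @param strong_lo,strong_hi,recomb_hi,min_strong_frac Gabriel-rule
#'   thresholds.
#' @return List of class `nrte_ld_blocks`: `blocks` (tibble chromosome,
#'   start, end, n_markers, span_bp) and `size_classes` (counts, incl.
#'   blocks >= 5 kb).
#' @export
ld_blocks <- function(ld, positions, strong_lo = 0.70, strong_hi = 0.98,
                      recomb_hi = 0.90, min_strong_frac = 0.95) {
  if (!all(c("dprime_lo", "dprime_hi") %in% names(ld))) {
    abort("ld_blocks needs |D'| bootstrap CIs; run ld_stats(boot_ci > 0)")
  }
  ld <- ld %>%
    mutate(strong = !is.na(.data$dprime_lo) & !is.na(.data$dprime_hi) &
             .data$dprime_lo >= strong_lo & .data$dprime_hi >= strong_hi,
           recomb = !is.na(.data$dprime_hi) & .data$dprime_hi < recomb_hi,
           informative = .data$strong | .data$recomb)
  blocks <- purrr::map_dfr(unique(positions$chromosome), function(chr) {
    mk <- positions %>%
      filter(.data$chromosome == chr) %>%
      arrange(.data$position)
    m <- nrow(mk)
    if (m < 2) return(NULL)
    pos_of <- setNames(seq_len(m), mk$locus_id)
    pl <- ld %>%
      filter(.data$locus_a %in% mk$locus_id &
               .data$locus_b %in% mk$locus_id)
    ia <- pos_of[pl$locus_a]; ib <- pos_of[pl$locus_b]
    lo <- pmin(ia, ib); hi <- pmax(ia, ib)
    cand <- purrr::map_dfr(seq(m, 2), function(len) {
      tibble(s = seq_len(m - len + 1), e = seq_len(m - len + 1) + len - 1)
    })
    taken <- rep(FALSE, m)
    keep <- purrr::map_dfr(seq_len(nrow(cand)), function(ci) {
      s <- cand$s[ci]; e <- cand$e[ci]
      if (any(taken[s:e])) return(NULL)
      inpair <- lo >= s & hi <= e
      inf <- inpair & pl$informative
      if (!any(inf)) return(NULL)
      frac <- sum(inpair & pl$strong) / sum(inf)
      if (frac < min_strong_frac) return(NULL)
      taken[s:e] <<- TRUE
      tibble(chromosome = chr, start = mk$position[s],
             end = mk$position[e], n_markers = e - s + 1,
             span_bp = mk$position[e] - mk$position[s] + 1)
    })
    keep
  })
  if (is.null(blocks) || nrow(blocks) == 0) {
    blocks <- tibble(chromosome = character(), start = integer(),
                     end = integer(), n_markers = integer(),
                     span_bp = integer())
  }
  size_classes <- tibble(
    class = c("<1kb", "1-5kb", ">=5kb"),
    n = c(sum(blocks$span_bp < 1e3),
          sum(blocks$span_bp >= 1e3 & blocks$span_bp < 5e3),
          sum(blocks$span_bp >= 5e3)))
  structure(list(blocks = blocks, size_classes = size_classes),
            class = "nrte_ld_blocks")
}

#' @export
print.nrte_ld_blocks <- function(x, ...) {
  cat("<nrte_ld_blocks> ", nrow(x$blocks), " block(s); >=5kb: ",
      x$size_classes$n[x$size_classes$class == ">=5kb"], "\n", sep = "")
  invisible(x)
}
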