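# Window-based genome landscape: densities, Marey-curve recombination
# rates, gene-context classification, and track correlations.

#' Tile chromosomes into contiguous windows
#'
#' @param chrom_lengths Named vector of chromosome lengths, or an
#'   `nrte_reference`.
#' @param window_size Window width in bp (default 1 Mb); the last window
#'   of a chromosome may be short.
#' @param pericentromere Optional tibble (chromosome, start, end); windows
#'   whose midpoint falls inside are labelled `"pericentromere"`, others
#'   `"arm"`.
#' @return Tibble chromosome, start, end (1-based inclusive), width,
#'   region.
#' @export
make_windows <- function(chrom_lengths, window_size = 1e6,
                         pericentromere = NULL) {
  if (inherits(chrom_lengths, "nrte_reference")) {
    if (is.null(pericentromere)) {
      pericentromere <- chrom_lengths$pericentromere
    }
    chrom_lengths <- vapply(chrom_lengths$genome, nchar, 0L)
  }
  w <- purrr::map_dfr(names(chrom_lengths), function(chr) {
    L <- chrom_lengths[[chr]]
    starts <- seq(1L, L, by = window_size)
    tibble(chromosome = chr, start = as.integer(starts),
           end = as.integer(pmin(starts + window_size - 1, L)))
  }) %>%
    mutate(width = .data$end - .data$start + 1L, region = "arm")
  if (!is.null(pericentromere) && nrow(pericentromere) > 0) {
    mid <- (w$start + w$end) / 2
    for (i in seq_len(nrow(pericentromere))) {
      p <- pericentromere[i, ]
      inside <- w$chromosome == p$chromosome & mid >= p$start &
        mid <= p$end
      w$region[inside] <- "pericentromere"
    }
  }
  w
}

#' Per-window feature density (count per Mb)
#'
#' Counts point features per window and normalises by the window's actual
#' width, so short terminal windows are not deflated.
#'
#' @param features Tibble with chromosome and position columns (for
#'   interval features pass e.g. the start or midpoint as `position`).
#' @param windows From [make_windows()].
#' @param value Either `"per_mb"` (default) or `"count"`.
#' @return The windows tibble with a `density` column.
#' @export
window_density <- function(features, windows, value = c("per_mb", "count")) {
  value <- match.arg(value)
  stopifnot(all(c("chromosome", "position") %in% names(features)))
  for (chr in unique(features$chromosome)) {
    L <- max(windows$end[windows$chromosome == chr], -Inf)
    pos <- features$position[features$chromosome == chr]
    if (!is.finite(L) || any(pos < 1 | pos > L)) {
      abort(paste0("feature outside chromosome bounds on ", chr))
    }
  }
  out <- windows
  out$density <- 0
  for (chr in unique(windows$chromosome)) {
    wi <- which(windows$chromosome == chr)
    pos <- features$position[features$chromosome == chr]
    if (!length(pos)) next
    brk <- c(windows$start[wi][1] - 1L, windows$end[wi])
    cnt <- as.integer(table(cut(pos, breaks = brk)))
    out$density[wi] <- cnt
  }
  if (value == "per_mb") out$density <- out$density / (out$width / 1e6)
  out
}

#' Window recombination rates from a genetic map (Marey approach)
#'
#' Linearly interpolates the Marey curve (cM against bp) through the map
#' markers and differentiates it across window boundaries:
#' `rate = (cM(end) - cM(start - 1)) / width_Mb`. Outside the terminal
#' markers the curve is extended with the terminal segment's slope. Summed
#' over a chromosome the window rates integrate back to the interpolated
#' total cM span.
#'
#' @param map Tibble chromosome, position, cm (non-decreasing within
#'   chromosome).
#' @param windows From [make_windows()].
#' @return Windows tibble with a `rate` column (cM/Mb).
#' @export
gr_rate <- function(map, windows) {
  stopifnot(all(c("chromosome", "position", "cm") %in% names(map)))
  out <- windows
  out$rate <- NA_real_
  for (chr in unique(windows$chromosome)) {
    m <- map[map$chromosome == chr, , drop = FALSE] %>%
      arrange(.data$position)
    if (nrow(m) < 2) abort(paste0("need >= 2 map markers on ", chr))
    if (any(diff(m$cm) < 0)) {
      bad <- m$marker[which(diff(m$cm) < 0) + 1]
      abort(paste0("genetic map not monotone on ", chr, " at marker(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    marey <- marey_fun(m$position, m$cm)
    wi <- which(windows$chromosome == chr)
    cm0 <- marey(windows$start[wi] - 1)
    cm1 <- marey(windows$end[wi])
    out$rate[wi] <- (cm1 - cm0) / (windows$width[wi] / 1e6)
  }
  out
}

# Piecewise-linear interpolator with terminal-slope extrapolation.
marey_fun <- function(x, y) {
  n <- length(x)
  s_first <- (y[2] - y[1]) / (x[2] - x[1])
  s_last <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  function(q) {
    inner <- approx(x, y, xout = pmin(pmax(q, x[1]), x[n]),
                    ties = "ordered")$y
    inner +
      pmin(q - x[1], 0) * s_first +
      pmax(q - x[n], 0) * s_last
  }
}

#' Classify insertion loci by gene context
#'
#' Assigns each locus exactly one category with precedence
#' exon > UTR > intron > 1-kb flank > intergenic. Flank categories are
#' strand-aware (`upstream_1kb` is 5' of the gene); when a locus sits in
#' the flank of two genes the nearer gene wins, ties going to upstream.
#'
#' @param loci Tibble chromosome, position (one row per locus).
#' @param features Per-gene feature tibble (gene_id, chromosome, feature,
#'   start, end, strand) as from [simulate_reference()]; features must
#'   include exons (intron-only genes are rejected).
#' @param genes Gene-bounds tibble (gene_id, chromosome, start, end,
#'   strand).
#' @param flank_bp Flank width (default 1000).
#' @return `loci` with a `context` column.
#' @export
classify_context <- function(loci, features, genes, flank_bp = 1000) {
  no_exon <- setdiff(genes$gene_id,
                     features$gene_id[features$feature == "exon"])
  if (length(no_exon)) {
    abort(paste0("gene(s) without exons: ",
                 paste(head(no_exon, 5), collapse = ", ")))
  }
  prec <- c(exon = 1, five_prime_UTR = 2, three_prime_UTR = 2, intron = 3)
  context <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    p <- loci$position[i]
    chr <- loci$chromosome[i]
    f <- features[features$chromosome == chr & features$start <= p &
                    features$end >= p, , drop = FALSE]
    if (nrow(f)) {
      context[i] <- f$feature[which.min(prec[f$feature])]
      next
    }
    g <- genes[genes$chromosome == chr, , drop = FALSE]
    if (nrow(g)) {
      dist <- pmax(g$start - p, p - g$end, 0)
      near <- g[dist > 0 & dist <= flank_bp, , drop = FALSE]
      dnear <- dist[dist > 0 & dist <= flank_bp]
      if (nrow(near)) {
        side <- ifelse(p < near$start,
                       ifelse(near$strand == "+", "upstream_1kb",
                              "downstream_1kb"),
                       ifelse(near$strand == "+", "downstream_1kb",
                              "upstream_1kb"))
        ord <- order(dnear, side != "upstream_1kb")
        context[i] <- side[ord[1]]
        next
      }
    }
    context[i] <- "intergenic"
  }
  loci$context <- context
  loci
}

#' Pearson correlation between two window tracks
#'
#' @param a,b Window tibbles sharing (chromosome, start, end), each with
#'   one value column (the last column, e.g. `density` or `rate`).
#' @param region `"all"` or `"arms"` (drops pericentromeric windows from
#'   both tracks).
#' @return Tibble r, p_value, n, region.
#' @export
correlate_tracks <- function(a, b, region = c("all", "arms")) {
  region <- match.arg(region)
  key <- c("chromosome", "start", "end")
  va <- names(a)[ncol(a)]
  vb <- names(b)[ncol(b)]
  m <- dplyr::inner_join(
    a %>% select(dplyr::all_of(c(key, "region", va))) %>%
      rename(value_a = dplyr::all_of(va)),
    b %>% select(dplyr::all_of(c(key, vb))) %>%
      rename(value_b = dplyr::all_of(vb)),
    by = key)
  if (nrow(m) != nrow(a) || nrow(m) != nrow(b)) {
    abort("tracks are not on identical windows")
  }
  if (region == "arms") m <- m[m$region == "arm", , drop = FALSE]
  if (nrow(m) < 3 || sd(m$value_a) == 0 || sd(m$value_b) == 0) {
    return(tibble(r = NA_real_, p_value = NA_real_, n = nrow(m),
                  region = region, zero_variance = TRUE))
  }
  ct <- cor.test(m$value_a, m$value_b, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(m),
         region = region, zero_variance = FALSE)
}

#' Write a window track as bedGraph
#'
#' @param track Windows tibble whose last column holds the value.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  v <- names(track)[ncol(track)]
  readr::write_tsv(
    tibble(chrom = track$chromosome, start = track$start - 1L,
           end = track$end, value = track[[v]]),
    path, col_names = FALSE)
  invisible(path)
}
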