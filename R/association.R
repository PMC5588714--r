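# Marker-trait association with population-structure correction,
# expression association, Bonferroni thresholds, and assay-vs-in-silico
# concordance arithmetic.

#' Principal-component covariates from a marker matrix
#'
#' Mean-centers marker columns (no variance scaling), optionally
#' subsamples `n_subsample` columns (seeded) in the spirit of computing
#' structure covariates from a random subset of a much larger SNP set,
#' and returns the top-`k` principal-component scores of the lines. The
#' sign of each component is fixed by making its largest-magnitude
#' loading positive.
#'
#' @param markers Lines-by-markers 0/1 matrix (see [genotype_matrix()]),
#'   or a wide genotype tibble.
#' @param k Number of components.
#' @param n_subsample Number of marker columns to subsample (NULL = all).
#' @param seed Seed for the subsample.
#' @return Object of class `nrte_pca`: list with `scores` (lines x k),
#'   `explained` (variance fractions), `k`, `n_markers`.
#' @export
pca_covariates <- function(markers, k = 3, n_subsample = NULL, seed = 1) {
  if (is.data.frame(markers)) markers <- genotype_matrix(markers)
  n <- nrow(markers)
  if (k >= n) abort("k must be smaller than the number of lines")
  if (!is.null(n_subsample) && n_subsample < ncol(markers)) {
    cols <- with_seed(seed, sample.int(ncol(markers), n_subsample))
    markers <- markers[, cols, drop = FALSE]
  }
  X <- scale(markers, center = TRUE, scale = FALSE)
  X[is.na(X)] <- 0
  if (all(abs(X) < 1e-12)) abort("markers carry no variance across lines")
  sv <- svd(X, nu = k, nv = k)
  if (sum(sv$d > 1e-10) < k) {
    abort("fewer non-degenerate components than k")
  }
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  rownames(scores) <- rownames(markers)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 explained = sv$d[seq_len(k)]^2 / sum(svd(X)$d^2),
                 k = k, n_markers = ncol(markers)),
            class = "nrte_pca")
}

#' @export
print.nrte_pca <- function(x, ...) {
  cat("<nrte_pca> ", x$k, " component(s) over ", x$n_markers,
      " markers; explained: ",
      paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Bonferroni-adjusted per-test significance threshold
#'
#' @param m Number of tests (>= 1).
#' @param alpha Family-wise alpha in (0, 1].
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(48296, 1)   # 2.07e-05
#' bonferroni_threshold(28850, 1)   # 3.47e-05
bonferroni_threshold <- function(m, alpha = 1) {
  stopifnot(m >= 1, alpha > 0, alpha <= 1)
  alpha / m
}

#' Filter markers by minor allele frequency
#'
#' MAF of a presence/absence marker is `min(f, 1 - f)` of the carrier
#' frequency over genotyped lines; the floor is inclusive.
#'
#' @param genotypes Wide genotype tibble.
#' @param maf_min MAF floor (default 0.15).
#' @return The genotype tibble restricted to retained markers.
#' @export
maf_filter <- function(genotypes, maf_min = 0.15) {
  lines <- genotype_lines(genotypes)
  M <- as.matrix(genotypes[, lines])
  f <- rowMeans(M == 1, na.rm = TRUE)
  genotypes[pmin(f, 1 - f) >= maf_min, , drop = FALSE]
}

#' General-linear-model association scan with covariates
#'
#' For each marker, least squares of the trait on
#' `[intercept, covariates, marker]`; the marker p-value is the two-sided
#' t test of its coefficient (equivalently the 1-df nested-model F).
#' Implemented by residualising trait and markers on the covariates
#' (partitioned regression), which is exact. Markers below the MAF floor
#' or collinear with the covariates are flagged and get no p-value.
#'
#' @param trait Named numeric vector of line trait values (names = line
#'   ids), or tibble line_id, value.
#' @param genotypes Wide genotype tibble of markers.
#' @param covariates Optional lines-by-q matrix (e.g. `nrte_pca` scores)
#'   with rownames = line ids; NULL for no structure correction.
#' @param maf_min MAF floor applied before testing (0 disables).
#' @param threshold Significance threshold for the `significant` flag
#'   (e.g. [bonferroni_threshold()]); defaults to `alpha = 1` Bonferroni
#'   over the tested markers.
#' @return Object of class `nrte_assoc`: tibble marker_id, chromosome,
#'   position (when available), beta, se, t, p_value, n_used, maf,
#'   significant, flag.
#' @export
glm_assoc <- function(trait, genotypes, covariates = NULL, maf_min = 0.15,
                      threshold = NULL) {
  if (is.data.frame(trait)) {
    trait <- setNames(trait$value, trait$line_id)
  }
  if (inherits(covariates, "nrte_pca")) covariates <- covariates$scores
  if (maf_min > 0) genotypes <- maf_filter(genotypes, maf_min)
  if (nrow(genotypes) == 0) abort("no markers pass the MAF floor")
  lines <- genotype_lines(genotypes)
  lines <- intersect(lines, names(trait)[!is.na(trait)])
  if (!is.null(covariates)) lines <- intersect(lines, rownames(covariates))
  q <- if (is.null(covariates)) 0 else ncol(covariates)
  if (length(lines) < q + 3) abort("too few complete cases")
  y <- trait[lines]
  G <- t(as.matrix(genotypes[, lines]))          # lines x markers
  X0 <- cbind(`(Intercept)` = rep(1, length(lines)),
              if (!is.null(covariates)) covariates[lines, , drop = FALSE])
  qr0 <- qr(X0)
  ry <- qr.resid(qr0, y)
  RG <- qr.resid(qr0, G)
  gss <- colSums(RG^2)
  beta <- colSums(RG * ry) / gss
  df <- length(lines) - ncol(X0) - 1
  sse <- sum(ry^2) - beta^2 * gss
  sse <- pmax(sse, 0)
  se <- sqrt(sse / df / gss)
  tval <- beta / se
  p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  collinear <- gss < 1e-10
  p[collinear] <- NA_real_
  beta[collinear] <- NA_real_
  maf <- pmin(colMeans(G, na.rm = TRUE), 1 - colMeans(G, na.rm = TRUE))
  if (is.null(threshold)) {
    threshold <- bonferroni_threshold(max(1L, sum(!collinear)))
  }
  out <- tibble(marker_id = genotypes$locus_id,
                beta = beta, se = ifelse(collinear, NA_real_, se),
                t = ifelse(collinear, NA_real_, tval), p_value = p,
                n_used = length(lines), maf = maf,
                significant = !is.na(p) & p <= threshold,
                flag = ifelse(collinear, "collinear", "ok"))
  if (all(c("chromosome", "position") %in% names(genotypes))) {
    out <- dplyr::bind_cols(
      out[, 1, drop = FALSE],
      genotypes[, c("chromosome", "position")],
      out[, -1, drop = FALSE])
  }
  attr(out, "threshold") <- threshold
  class(out) <- c("nrte_assoc", class(out))
  out
}

#' Association scan restricted to a coordinate window
#'
#' The same [glm_assoc()] applied only to markers within
#' `[center - half_width, center + half_width]` on one chromosome --
#' the local re-scan used around candidate genes.
#'
#' @inheritParams glm_assoc
#' @param chromosome,center,half_width Window definition (bp).
#' @export
glm_assoc_window <- function(trait, genotypes, chromosome, center,
                             half_width = 1e6, covariates = NULL,
                             maf_min = 0, threshold = 0.001) {
  sel <- genotypes$chromosome == chromosome &
    abs(genotypes$position - center) <= half_width
  glm_assoc(trait, genotypes[sel, , drop = FALSE], covariates = covariates,
            maf_min = maf_min, threshold = threshold)
}

#' Expression association of one marker across genes
#'
#' Welch two-sample t test of each gene's expression between carriers and
#' non-carriers of the marker, thresholded by Bonferroni over the genes
#' tested.
#'
#' @param expression Tibble gene_id plus one numeric column per line.
#' @param marker Named 0/1 vector of carrier status per line.
#' @param alpha Family-wise alpha for the threshold.
#' @return Tibble gene_id, mean_carrier, mean_noncarrier, p_value,
#'   significant; attribute `"threshold"`.
#' @export
expression_assoc <- function(expression, marker, alpha = 1) {
  lines <- intersect(setdiff(names(expression), "gene_id"),
                     names(marker)[!is.na(marker)])
  carrier <- lines[marker[lines] == 1]
  noncar <- lines[marker[lines] == 0]
  if (length(carrier) < 2 || length(noncar) < 2) {
    abort("need >= 2 lines in each carrier class")
  }
  A <- as.matrix(expression[, carrier])
  B <- as.matrix(expression[, noncar])
  res <- purrr::map_dfr(seq_len(nrow(expression)), function(i) {
    a <- A[i, ]; b <- B[i, ]
    if (sd(a) == 0 && sd(b) == 0) {
      return(tibble(p_value = 1, mean_carrier = mean(a),
                    mean_noncarrier = mean(b)))
    }
    tt <- t.test(a, b)   # Welch
    tibble(p_value = tt$p.value, mean_carrier = mean(a),
           mean_noncarrier = mean(b))
  })
  thr <- bonferroni_threshold(nrow(expression), alpha)
  out <- dplyr::bind_cols(tibble(gene_id = expression$gene_id), res) %>%
    mutate(significant = .data$p_value <= thr)
  attr(out, "threshold") <- thr
  out
}

#' Concordance between assay calls and in-silico calls
#'
#' Cross-tabulates presence/absence calls from a validation assay against
#' computational predictions over the same lines: agreements, insertions
#' seen only by the assay, and insertions predicted only in silico.
#' Percentages are exact `n/total*100` rounded to one decimal.
#'
#' @param assay_calls,silico_calls Named 0/1 vectors over the same lines.
#' @return Tibble n_total, n_agree, n_assay_only, n_silico_only,
#'   pct_agree, pct_assay_only, pct_silico_only.
#' @export
#' @examples
#' a <- c(rep(1, 40), rep(0, 35)); names(a) <- paste0("L", 1:75)
#' b <- a; b[1:3] <- 0   # three assay-only carriers
#' concordance(a, b)
concordance <- function(assay_calls, silico_calls) {
  if (is.null(names(assay_calls)) || is.null(names(silico_calls)) ||
      !setequal(names(assay_calls), names(silico_calls))) {
    abort("assay and in-silico calls must cover the same named line set")
  }
  s <- silico_calls[names(assay_calls)]
  n_total <- length(assay_calls)
  n_agree <- sum(assay_calls == s)
  n_assay_only <- sum(assay_calls == 1 & s == 0)
  n_silico_only <- sum(assay_calls == 0 & s == 1)
  tibble(n_total = n_total, n_agree = n_agree,
         n_assay_only = n_assay_only, n_silico_only = n_silico_only,
         pct_agree = round(100 * n_agree / n_total, 1),
         pct_assay_only = round(100 * n_assay_only / n_total, 1),
         pct_silico_only = round(100 * n_silico_only / n_total, 1))
}
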