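# ggplot2 graphics for the main result types.

#' Manhattan plot of an association scan
#'
#' @param object An `nrte_assoc` result with chromosome/position columns.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nrte_assoc <- function(object, ...) {
  stopifnot(all(c("chromosome", "position") %in% names(object)))
  d <- as_tibble(object) %>% filter(!is.na(.data$p_value))
  thr <- attr(object, "threshold")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$position / 1e6,
                                       y = -log10(.data$p_value),
                                       colour = .data$chromosome)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)))
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(thr),
                                 linetype = "dashed")
  }
  p
}

#' Distribution of resampled mean Fst with its 99% interval
#'
#' @param object An `nrte_fst` result.
#' @param qst Optional Qst value drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nrte_fst <- function(object, qst = NULL, ...) {
  d <- tibble(mean_fst = object$resample_means)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_fst)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$ci99, linetype = "dashed") +
    ggplot2::labs(x = "resampled mean Fst", y = "replicates")
  if (!is.null(qst)) {
    p <- p + ggplot2::geom_vline(xintercept = qst, colour = "red")
  }
  p
}

#' Plot one or more window tracks along the genome
#'
#' @param ... Named window tibbles (each with a final value column), e.g.
#'   `plot_window_tracks(nrte = dens, genes = gdens, cM_Mb = rate)`.
#' @return A ggplot, faceted by track and chromosome.
#' @export
plot_window_tracks <- function(...) {
  tracks <- list(...)
  stopifnot(length(tracks) > 0, !is.null(names(tracks)))
  d <- purrr::imap_dfr(tracks, function(tr, nm) {
    tibble(track = nm, chromosome = tr$chromosome,
           mid = (tr$start + tr$end) / 2e6, value = tr[[ncol(tr)]])
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$track),
                        cols = ggplot2::vars(.data$chromosome),
                        scales = "free") +
    ggplot2::labs(x = "position (Mb)", y = NULL)
}

#' Per-population frequency histogram of insertion loci
#'
#' @param freqs Output of [population_frequencies()].
#' @return A ggplot.
#' @export
plot_spectrum <- function(freqs) {
  d <- freqs %>% filter(.data$defined, .data$frequency > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency,
                                  fill = .data$population)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.1),
                            position = "dodge") +
    ggplot2::labs(x = "carrier frequency", y = "loci")
}
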