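# broom-style tidiers for fitted result objects.

#' Tidy a Qst result into a component table
#'
#' @param x An `nrte_qst` object.
#' @param ... Unused.
#' @return Tibble term, estimate (variance components and mean squares).
#' @export
tidy.nrte_qst <- function(x, ...) {
  tibble(term = c("sigma2_GB", "sigma2_GW", "MSB", "MSL", "MS_error",
                  "n0"),
         estimate = c(x$sigma2_GB, x$sigma2_GW, x$MSB, x$MSL, x$MS_error,
                      x$n0))
}

#' One-row summary of a Qst result
#'
#' @inheritParams tidy.nrte_qst
#' @return Tibble qst, sigma2_GB, sigma2_GW.
#' @export
glance.nrte_qst <- function(x, ...) {
  tibble(qst = x$qst, sigma2_GB = x$sigma2_GB, sigma2_GW = x$sigma2_GW)
}

#' Tidy a resampled-Fst result
#'
#' @param x An `nrte_fst` object.
#' @param ... Unused.
#' @return Tibble of per-replicate mean Fst values.
#' @export
tidy.nrte_fst <- function(x, ...) {
  tibble(replicate = seq_along(x$resample_means),
         mean_fst = x$resample_means)
}

#' One-row summary of a resampled-Fst result
#'
#' @inheritParams tidy.nrte_fst
#' @return Tibble mean_fst, ci99_lower, ci99_upper, B, L.
#' @export
glance.nrte_fst <- function(x, ...) {
  tibble(mean_fst = x$mean_fst, ci99_lower = x$ci99[["lower"]],
         ci99_upper = x$ci99[["upper"]], B = x$B, L = x$L)
}

#' Tidy an association scan (per-marker table)
#'
#' @param x An `nrte_assoc` object.
#' @param ... Unused.
#' @export
tidy.nrte_assoc <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of an association scan
#'
#' @inheritParams tidy.nrte_assoc
#' @return Tibble n_markers, n_significant, threshold.
#' @export
glance.nrte_assoc <- function(x, ...) {
  tibble(n_markers = nrow(x),
         n_significant = sum(x$significant, na.rm = TRUE),
         threshold = attr(x, "threshold"))
}
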