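#' Simulation configuration for a synthetic inbred maize-like panel
#'
#' Bundles every tunable of the synthetic-data generator: genome geometry,
#' TE library, panel composition, the per-class Beta frequency models for
#' insertion loci, sequencing parameters, and the generative model for a
#' polygenic trait and for expression. Defaults describe a miniature
#' two-population panel of fully inbred (haploid-equivalent) lines modelled
#' on a diversity panel of 31 temperate and 52 tropical lines phenotyped
#' with two replicates.
#'
#' @param seed Master seed; every random stage derives its own seed from it.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_genes Gene models to place (non-overlapping).
#' @param te_library_size Number of TE families in the library.
#' @param reference_te_copies Full-length TE copies embedded in the
#'   reference genome (false-positive bait for the junction scan).
#' @param n_lines_per_pop Named integer vector `c(temperate =, tropical =)`.
#' @param n_insertion_loci Non-reference insertion loci to plant.
#' @param class_mix Proportions of loci in the three sharing classes
#'   `private_temperate`, `private_tropical`, `shared`.
#' @param freq_model Per-class Beta parameters `c(shape1, shape2)` for the
#'   carrier frequency of a locus in the population(s) where it segregates.
#' @param read_length Raw read length in bp (>= 75; reads are later
#'   hard-truncated to 75 bp by [qc_reads()]).
#' @param coverage Fold sequencing coverage per line.
#' @param error_rate Per-base substitution error probability (< 0.1).
#' @param n_causal_loci Insertion loci given a trait effect.
#' @param effect_sizes Trait-unit effect per causal locus (recycled).
#' @param pop_mean_shift Fixed trait offset of the tropical population.
#' @param line_sd SD of the line-level genetic deviate (trait units).
#' @param residual_sd SD of replicate noise (trait units).
#' @param n_replicates Phenotype replicates per line.
#' @param n_expression_effects Loci that perturb the expression of their
#'   nearest gene.
#' @param expression_multiplier Fold-change applied to carriers.
#' @param expr_sdlog SD of log expression around each gene's baseline.
#' @param map_spacing Genetic-map marker spacing in bp.
#' @param arm_cm_per_mb Recombination rate on chromosome arms (cM/Mb).
#' @param pericentromere_cm_per_mb Rate in the middle third of each
#'   chromosome (suppressed pericentromeric recombination).
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, chrom_length = 2e5, coverage = 2)
sim_config <- function(seed = 1,
                       n_chromosomes = 1,
                       chrom_length = 2e6,
                       n_genes = 40,
                       te_library_size = 12,
                       reference_te_copies = 8,
                       n_lines_per_pop = c(temperate = 31, tropical = 52),
                       n_insertion_loci = 100,
                       class_mix = c(private_temperate = 0.16,
                                     private_tropical = 0.41,
                                     shared = 0.43),
                       freq_model = list(
                         private_temperate = c(0.5, 5),
                         private_tropical = c(0.5, 5),
                         shared = c(0.8, 2)),
                       read_length = 100,
                       coverage = 15,
                       error_rate = 0.005,
                       n_causal_loci = 5,
                       effect_sizes = 1,
                       pop_mean_shift = 2,
                       line_sd = 1,
                       residual_sd = 1,
                       n_replicates = 2,
                       n_expression_effects = 3,
                       expression_multiplier = 0.67,
                       expr_sdlog = 0.3,
                       map_spacing = 5e4,
                       arm_cm_per_mb = 1.5,
                       pericentromere_cm_per_mb = 0.1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  counts <- c("n_chromosomes", "chrom_length", "n_genes", "te_library_size",
              "n_insertion_loci", "n_replicates")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0) {
      abort(paste0("sim_config field `", f, "` must be a single number >= 0"))
    }
  }
  if (cfg$n_chromosomes < 1 || cfg$chrom_length < 1 || cfg$n_replicates < 1) {
    abort("n_chromosomes, chrom_length and n_replicates must be >= 1")
  }
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.1) {
    abort("error_rate must lie in [0, 0.1)")
  }
  if (cfg$read_length < 75) abort("read_length must be >= 75")
  if (cfg$chrom_length < 10 * cfg$read_length) {
    abort("chrom_length must be >= 10 * read_length")
  }
  if (length(cfg$n_lines_per_pop) != 2 ||
      any(cfg$n_lines_per_pop < 1)) {
    abort("n_lines_per_pop must give two populations with >= 1 line each")
  }
  if (is.null(names(cfg$n_lines_per_pop))) {
    names(cfg$n_lines_per_pop) <- c("temperate", "tropical")
  }
  if (abs(sum(cfg$class_mix) - 1) > 1e-8) {
    abort("class_mix must sum to 1")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  genome : ", x$n_chromosomes, " chromosome(s) x ",
      format(x$chrom_length, big.mark = ","), " bp\n", sep = "")
  cat("  panel  : ", paste(names(x$n_lines_per_pop), x$n_lines_per_pop,
                           collapse = " + "), " lines\n", sep = "")
  cat("  loci   : ", x$n_insertion_loci, " insertions, ",
      x$te_library_size, " TE families, ", x$reference_te_copies,
      " reference copies\n", sep = "")
  cat("  reads  : ", x$read_length, " bp at ", x$coverage, "x, error rate ",
      x$error_rate, "\n", sep = "")
  invisible(x)
}
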