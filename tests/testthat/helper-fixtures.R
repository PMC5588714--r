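# Shared small fixtures, built in code once per test run.

tiny_config <- function(...) {
  defaults <- list(seed = 42, chrom_length = 2e5, n_genes = 8,
                   te_library_size = 5, reference_te_copies = 2,
                   n_lines_per_pop = c(temperate = 4, tropical = 5),
                   n_insertion_loci = 10, coverage = 12, error_rate = 0,
                   read_length = 100, n_replicates = 2)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

tiny_ref <- simulate_reference(tiny_config())
tiny_truth <- simulate_panel(tiny_config(), tiny_ref)
tiny_edges <- build_edge_db(tiny_ref$te_library)

# One shared scan of the tiny panel (error-free) for scan-dependent tests.
tiny_scan <- scan_simulated_panel(tiny_truth, tiny_ref, tiny_edges)

# Match called loci to truth loci by position (within clustering
# tolerance); returns tibble(locus_id.call, locus_id.truth).
match_loci_to_truth <- function(loci, truth, tol = 10) {
  out <- dplyr::inner_join(
    loci, truth$loci, by = "chromosome", suffix = c(".call", ".truth"),
    relationship = "many-to-many")
  out <- out[abs(out$position.call - out$position.truth) <= tol, ]
  out[, c("locus_id.call", "locus_id.truth")]
}

# A deterministic wide genotype tibble from explicit 0/1 vectors.
geno_tbl <- function(..., chromosome = NULL, position = NULL) {
  vecs <- list(...)
  lines <- paste0("L", seq_along(vecs[[1]]))
  m <- do.call(rbind, vecs)
  out <- tibble::tibble(locus_id = sprintf("M%03d", seq_along(vecs)))
  if (!is.null(chromosome)) out$chromosome <- chromosome
  if (!is.null(position)) out$position <- position
  dplyr::bind_cols(out, tibble::as_tibble(`colnames<-`(m, lines)))
}
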