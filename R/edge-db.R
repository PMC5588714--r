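# TE edge-sequence database: the probe set for junction detection.
# Each library TE contributes its terminal 100 bp at both ends; a junction
# read must run off one of these termini into unique flanking sequence.

EDGE_LEN <- 100L

#' Classify a TE header/family token into a superfamily class
#'
#' Deterministic mapping of maize-style three-letter family codes:
#' `DT*`/`DH*` (TIR and Helitron DNA transposons) to `"DNA"`, `RLG` to
#' `"LTR/Gypsy"`, `RLC` to `"LTR/Copia"`, anything else (unknown tokens
#' included) to `"other"`. Explicit `gypsy`/`copia` words are also
#' recognised.
#'
#' @param header Character vector of FASTA headers or family names.
#' @return Character vector of classes.
#' @export
#' @examples
#' classify_te(c("RLG_xilon", "DTM_pif", "RLC_opie", "weird"))
classify_te <- function(header) {
  h <- tolower(header)
  dplyr::case_when(
    stringr::str_detect(h, "^(dta|dtc|dth|dtm|dtt|dhh)|dna[-_/ ]?(te|transposon)") ~ "DNA",
    stringr::str_detect(h, "^rlg|gypsy") ~ "LTR/Gypsy",
    stringr::str_detect(h, "^rlc|copia") ~ "LTR/Copia",
    TRUE ~ "other"
  )
}

#' Build the TE edge database from a TE library
#'
#' Takes the terminal 100 bp at each end of every TE (the whole sequence
#' when the TE is shorter than 100 bp, so the two edges of a short TE
#' overlap) and collapses duplicate edge sequences, retaining every source
#' te_id, so that one junction read can never be counted once per family
#' member sharing an identical terminus.
#'
#' @param te_library Either a tibble with columns te_id, class, sequence
#'   (family optional; as produced by [simulate_reference()]) or a path to
#'   a FASTA file whose headers carry the family token.
#' @return Tibble of class `nrte_edge_db`: edge_id, end
#'   (`five_prime`/`three_prime`), sequence, te_ids (list column), family
#'   (unique source family or NA), class.
#' @export
build_edge_db <- function(te_library) {
  if (is.character(te_library) && length(te_library) == 1) {
    seqs <- read_fasta(te_library)
    te_library <- tibble(te_id = names(seqs),
                         family = names(seqs),
                         class = classify_te(names(seqs)),
                         sequence = unname(seqs))
  }
  stopifnot(all(c("te_id", "class", "sequence") %in% names(te_library)))
  if (nrow(te_library) == 0) abort("TE library is empty")
  if (!"family" %in% names(te_library)) te_library$family <- te_library$te_id
  known <- c("DNA", "LTR/Gypsy", "LTR/Copia", "other")
  bad <- !te_library$class %in% known
  if (any(bad)) {
    warn(paste0(sum(bad), " TE(s) with unparseable class assigned 'other'"))
    te_library$class[bad] <- "other"
  }
  len <- nchar(te_library$sequence)
  if (any(len < 1)) abort("TE sequences must have length >= 1")
  edges <- bind_rows(
    tibble(te_id = te_library$te_id, family = te_library$family,
           class = te_library$class, end = "five_prime",
           sequence = substr(te_library$sequence, 1L, pmin(len, EDGE_LEN))),
    tibble(te_id = te_library$te_id, family = te_library$family,
           class = te_library$class, end = "three_prime",
           sequence = substr(te_library$sequence,
                             pmax(1L, len - EDGE_LEN + 1L), len)))
  collapsed <- edges %>%
    group_by(.data$end, .data$sequence) %>%
    summarise(te_ids = list(unique(.data$te_id)),
              family = if (dplyr::n_distinct(.data$family) == 1)
                .data$family[1] else NA_character_,
              class = if (dplyr::n_distinct(.data$class) == 1)
                .data$class[1] else "other",
              .groups = "drop") %>%
    arrange(match(.data$end, c("five_prime", "three_prime")),
            .data$sequence) %>%
    mutate(edge_id = sprintf("edge%04d", row_number()), .before = 1)
  class(collapsed) <- c("nrte_edge_db", class(collapsed))
  collapsed
}

#' Write an edge database as FASTA plus a TSV sidecar
#'
#' @param edge_db From [build_edge_db()].
#' @param dir Output directory; writes `te_edges.fa` and `te_edges.tsv`.
#' @export
write_edge_db <- function(edge_db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(setNames(edge_db$sequence, edge_db$edge_id),
              file.path(dir, "te_edges.fa"))
  sidecar <- edge_db %>%
    mutate(te_id = vapply(.data$te_ids, paste, "", collapse = ",")) %>%
    select("edge_id", "te_id", "end", "class")
  readr::write_tsv(sidecar, file.path(dir, "te_edges.tsv"))
  invisible(dir)
}
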