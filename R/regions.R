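#' Define target regions
#'
#' A target region is the unit of analysis: a constant spacer (part of the
#' sequencing adaptor, immediately downstream of the barcode tag) followed by
#' the genomic target sequence. The region length `l` used by the Poisson
#' error model is the length of the target sequence alone.
#'
#' @param target_id Character vector of region names.
#' @param spacer Character vector of spacer sequences (recycled if length 1).
#' @param target_seq Character vector of target sequences.
#' @param excluded_positions List of integer vectors (one per region) of
#'   1-based positions *within the target* to exclude from error-rate and
#'   variant-call tallies, e.g. known common SNP sites such as rs1800372;
#'   `NULL` for none.
#'
#' @return A tibble with columns `target_id`, `spacer`, `target_seq`,
#'   `ref_seq` (spacer + target, the alignment reference), `spacer_len`,
#'   `length_l`, and list-column `excluded_positions`.
#' @export
#' @examples
#' target_regions("toy", "ACGTACGTACGTACGTACGT", "AAACCCGGGTTTAAACCCGGGTTT")
target_regions <- function(target_id, spacer, target_seq,
                           excluded_positions = NULL) {
  stopifnot(length(target_id) == length(target_seq))
  spacer <- rep_len(toupper(spacer), length(target_id))
  target_seq <- toupper(target_seq)
  if (is.null(excluded_positions)) {
    excluded_positions <- rep(list(integer(0)), length(target_id))
  }
  stopifnot(length(excluded_positions) == length(target_id))
  l <- nchar(target_seq)
  bad <- purrr::map2_lgl(excluded_positions, l,
                         ~ length(.x) > 0 && (min(.x) < 1 || max(.x) > .y))
  if (any(bad)) {
    stop("excluded_positions outside [1, length_l] for region(s): ",
         paste(target_id[bad], collapse = ", "))
  }
  tibble(
    target_id = as.character(target_id),
    spacer = spacer,
    target_seq = target_seq,
    ref_seq = paste0(spacer, target_seq),
    spacer_len = nchar(spacer),
    length_l = l,
    excluded_positions = purrr::map(excluded_positions, as.integer)
  )
}

#' Read target regions from a reference FASTA
#'
#' Each FASTA record holds one region's reference (spacer followed by target);
#' the spacer length must be supplied because the boundary is not encoded in
#' the sequence.
#'
#' @param path Path to a FASTA file (one record per region, id = target_id).
#' @param spacer_len Integer spacer length, recycled across records.
#' @inheritParams target_regions
#' @return A region tibble, as [target_regions()].
#' @export
read_regions_fasta <- function(path, spacer_len, excluded_positions = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- unname(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  spacer_len <- rep_len(as.integer(spacer_len), length(seqs))
  target_regions(
    target_id = ids,
    spacer = substr(seqs, 1L, spacer_len),
    target_seq = substr(seqs, spacer_len + 1L, nchar(seqs)),
    excluded_positions = excluded_positions
  )
}

#' Write target regions to a reference FASTA
#'
#' @param regions A region tibble from [target_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_fasta <- function(regions, path) {
  ss <- Biostrings::DNAStringSet(setNames(regions$ref_seq, regions$target_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Bundled example target regions (synthetic)
#'
#' Two fixed, synthetic target regions mimicking the geometry of common
#' ctDNA screening targets: a 73-bp "KRAS-like" and a 63-bp "CTNNB1-like"
#' region, each behind a distinct 20-bp spacer. The sequences are generated,
#' not genomic; only their lengths and structure matter for simulation and
#' testing.
#'
#' @return A region tibble with two rows.
#' @export
#' @examples
#' example_regions()
example_regions <- function() {
  withr::with_seed(20150629, {
    t1 <- paste(sample(BASES, 73, replace = TRUE), collapse = "")
    t2 <- paste(sample(BASES, 63, replace = TRUE), collapse = "")
  })
  target_regions(
    target_id = c("KRAS_like_synthetic", "CTNNB1_like_synthetic"),
    spacer = c("CTGAGTCGGAGACACGCAGG", "GATCCTCTAGAGTCGACCTG"),
    target_seq = c(t1, t2)
  )
}
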