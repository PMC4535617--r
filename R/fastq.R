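#' Read a FASTQ file into a tibble
#'
#' @param path Path to a FASTQ file (plain or gzip).
#' @return A tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    read_id = sub("\\s.*$", "", names(ss)),
    sequence = unname(as.character(ss)),
    quality = unname(as.character(S4Vectors::mcols(ss)$qualities))
  )
}

#' Write a read tibble to FASTQ
#'
#' @param reads A tibble with columns `read_id`, `sequence`, and optionally
#'   `quality` (defaults to constant Q40, character `I`).
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  qual <- if ("quality" %in% names(reads)) reads$quality else
    strrep("I", nchar(reads$sequence))
  ss <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(
    ss, path, format = "fastq",
    qualities = Biostrings::BStringSet(qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}
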