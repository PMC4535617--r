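# Semi-global alignment of read payloads to target references.
#
# Targets are short (~60-160 bp) and known, so a simple scoring scheme
# suffices: match +1, mismatch -5, gap open 2, gap extend 1, with free end
# gaps on the read (Biostrings "overlap" type). The aligned pattern is kept
# in reference coordinates (insertions removed, deletions as "-"), which is
# exactly the representation consensus building and pileups need.

align_subst_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -5,
                                           baseOnly = TRUE)
}

#' Align read payloads to target regions
#'
#' Each payload (spacer + following bases) is aligned semi-globally against
#' every region's reference (spacer + target) and assigned to the
#' best-scoring one. Reads are discarded when the unaligned (clipped) ends
#' exceed `max_unmapped_frac` of the total read length, or when identity over
#' the aligned span falls below `min_identity`.
#'
#' @param tagged Output of [extract_tags()] (optionally after
#'   [filter_payload_length()]); rows whose `status` is not `"ok"` pass
#'   through untouched.
#' @param regions A region tibble ([target_regions()]).
#' @param max_unmapped_frac Maximum fraction of the total read length allowed
#'   to be unaligned at the ends (default 0.10).
#' @param min_identity Minimum matches / aligned reference span (default 0.5).
#' @param min_payload Payloads of `min_payload` bases or fewer are marked
#'   `"short_payload"` (the read-length filter, applied here for callers that
#'   skipped [filter_payload_length()]).
#' @return `tagged` with columns added: `target_id`, `score`, `ref_start`,
#'   `ref_end` (1-based positions on the region reference), `aligned` (read
#'   bases in reference coordinates, deletions as `-`), `n_insertion`,
#'   `n_clip`, `identity`; `status` becomes one of `"aligned"`,
#'   `"short_payload"`, `"unmapped_ends"`, `"low_identity"`, or its previous
#'   rejection value.
#' @export
align_payloads <- function(tagged, regions, max_unmapped_frac = 0.10,
                           min_identity = 0.5, min_payload = 70L) {
  tagged <- filter_payload_length(tagged, min_len = min_payload)
  out <- dplyr::mutate(
    tagged,
    target_id = NA_character_, score = NA_real_,
    ref_start = NA_integer_, ref_end = NA_integer_,
    aligned = NA_character_, n_insertion = NA_integer_,
    n_clip = NA_integer_, identity = NA_real_
  )
  use <- which(out$status == "ok")
  if (length(use) == 0L) return(out)
  payload <- out$payload[use]
  pats <- Biostrings::DNAStringSet(payload)
  mat <- align_subst_matrix()

  scores <- vapply(seq_len(nrow(regions)), function(r) {
    Biostrings::pairwiseAlignment(
      pats, Biostrings::DNAString(regions$ref_seq[r]), type = "overlap",
      substitutionMatrix = mat, gapOpening = 2, gapExtension = 1,
      scoreOnly = TRUE)
  }, numeric(length(use)))
  if (length(use) == 1L) scores <- matrix(scores, nrow = 1L)
  best <- max.col(scores, ties.method = "first")

  read_len <- nchar(out$sequence[use])
  for (r in sort(unique(best))) {
    sel <- which(best == r)
    pa <- Biostrings::pairwiseAlignment(
      pats[sel], Biostrings::DNAString(regions$ref_seq[r]), type = "overlap",
      substitutionMatrix = mat, gapOpening = 2, gapExtension = 1)
    p_start <- Biostrings::start(Biostrings::pattern(pa))
    p_end <- Biostrings::end(Biostrings::pattern(pa))
    s_start <- Biostrings::start(Biostrings::subject(pa))
    s_end <- Biostrings::end(Biostrings::subject(pa))
    al <- as.character(Biostrings::aligned(Biostrings::pattern(pa)))
    # project out insertion columns (subject-row gaps, located by
    # indel(subject)) so that al is indexed by reference position
    ins_cols <- Biostrings::indel(Biostrings::subject(pa))
    has_ins <- S4Vectors::elementNROWS(ins_cols) > 0L
    if (any(has_ins)) {
      ins_start <- as.list(BiocGenerics::start(ins_cols))
      ins_end <- as.list(BiocGenerics::end(ins_cols))
      al[has_ins] <- vapply(which(has_ins), function(j) {
        pc <- strsplit(al[j], "", fixed = TRUE)[[1L]]
        drop <- unlist(mapply(seq.int, ins_start[[j]], ins_end[[j]],
                              SIMPLIFY = FALSE))
        paste(pc[-drop], collapse = "")
      }, character(1))
    }
    # free end-gaps on the subject side come back as "-" padding: trim them
    # (they are unaligned reference, not observed deletions)
    lead <- nchar(al) - nchar(sub("^-+", "", al))
    trail <- nchar(al) - nchar(sub("-+$", "", al))
    s_start <- s_start + lead
    s_end <- s_end - trail
    al <- substr(al, lead + 1L, nchar(al) - trail)
    span <- s_end - s_start + 1L
    nmat <- Biostrings::nmatch(pa)
    clip <- nchar(payload[sel]) - (p_end - p_start + 1L)
    ident <- nmat / span
    i <- use[sel]
    out$target_id[i] <- regions$target_id[r]
    out$score[i] <- BiocGenerics::score(pa)
    out$ref_start[i] <- s_start
    out$ref_end[i] <- s_end
    out$aligned[i] <- al
    out$n_insertion[i] <- (p_end - p_start + 1L) - (span - stringr::str_count(al, "-"))
    out$n_clip[i] <- clip
    out$identity[i] <- ident
    out$status[i] <- dplyr::case_when(
      clip > max_unmapped_frac * read_len[sel] ~ "unmapped_ends",
      ident < min_identity ~ "low_identity",
      TRUE ~ "aligned"
    )
  }
  out
}

#' Tally read dispositions
#'
#' Every input read ends in exactly one disposition (aligned or one rejection
#' reason); the counts sum to the input total.
#'
#' @param df A tibble with a `status` column.
#' @return A tibble `status`, `n`.
#' @export
read_dispositions <- function(df) {
  dplyr::count(df, .data$status, name = "n")
}
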