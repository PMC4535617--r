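# Per-molecule consensus reads (NOIRs) and per-position pileups.

# long form (one row per read x reference position) from aligned strings
alignments_long <- function(aln) {
  keep <- dplyr::filter(aln, .data$status == "aligned")
  if (nrow(keep) == 0L) {
    return(tibble(read_id = character(), target_id = character(),
                  pos = integer(), base = character()))
  }
  chars <- strsplit(keep$aligned, "", fixed = TRUE)
  len <- lengths(chars)
  tibble(
    read_id = rep(keep$read_id, len),
    target_id = rep(keep$target_id, len),
    pos = unlist(lapply(seq_len(nrow(keep)), function(i)
      seq.int(keep$ref_start[i], length.out = len[i]))),
    base = unlist(chars)
  )
}

#' Build one consensus sequence per accepted tag family
#'
#' For each accepted family, the aligned member reads (at most the
#' `max_reads` longest; ties broken by input order) vote per reference
#' position: an alternative base (including a deletion, `-`) is called only
#' when it is carried by more than `alt_frac` of the reads covering that
#' position, otherwise the reference base is called. Positions covered by no
#' kept read are absent from the consensus. Insertions relative to the
#' reference are excluded from the per-position tally.
#'
#' @param families A family tibble with an `accepted` column
#'   ([threshold_families()]).
#' @param aln Aligned reads ([align_payloads()]).
#' @param regions A region tibble.
#' @param max_reads Analyse at most this many longest reads per family
#'   (default 50).
#' @param alt_frac Strict support fraction required to call an alternative
#'   base (default 0.8).
#' @return An object of class `noir_consensus`: a tibble with one row per
#'   family and reference position: `canonical_tag`, `target_id`, `pos`,
#'   `ref`, `call`, `support`, `depth`, `is_variant`.
#' @export
build_consensus <- function(families, aln, regions, max_reads = 50L,
                            alt_frac = 0.8) {
  acc <- dplyr::filter(families, .data$accepted)
  membership <- tibble(
    canonical_tag = rep(acc$canonical_tag, lengths(acc$read_ids)),
    read_id = unlist(c(acc$read_ids, character(0)))
  )
  keep <- dplyr::filter(aln, .data$status == "aligned") |>
    dplyr::inner_join(membership, by = "read_id") |>
    dplyr::mutate(aln_len = .data$ref_end - .data$ref_start + 1L,
                  .order = dplyr::row_number()) |>
    dplyr::group_by(.data$canonical_tag) |>
    dplyr::arrange(dplyr::desc(.data$aln_len), .data$.order,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = max_reads) |>
    dplyr::ungroup()
  if (nrow(keep) == 0L) {
    out <- tibble(canonical_tag = character(), target_id = character(),
                  pos = integer(), ref = character(), call = character(),
                  support = integer(), depth = integer(),
                  is_variant = logical())
    class(out) <- c("noir_consensus", class(out))
    return(out)
  }
  long <- alignments_long(keep) |>
    dplyr::left_join(dplyr::select(keep, "read_id", "canonical_tag"),
                     by = "read_id")
  tallies <- long |>
    dplyr::count(.data$canonical_tag, .data$target_id, .data$pos,
                 .data$base, name = "support") |>
    dplyr::mutate(depth = sum(.data$support),
                  .by = c("canonical_tag", "target_id", "pos")) |>
    dplyr::left_join(region_ref_table(regions), by = c("target_id", "pos"))
  # strict >alt_frac rule: at most one alternative can exceed that share of
  # the covering reads, so no tie-break is needed
  sites <- dplyr::distinct(tallies, .data$canonical_tag, .data$target_id,
                           .data$pos, .data$ref, .data$depth)
  ref_rows <- tallies |>
    dplyr::filter(.data$base == .data$ref) |>
    dplyr::select("canonical_tag", "target_id", "pos",
                  ref_support = "support")
  var_rows <- tallies |>
    dplyr::filter(.data$base != .data$ref,
                  .data$support > alt_frac * .data$depth) |>
    dplyr::select("canonical_tag", "target_id", "pos",
                  alt_call = "base", alt_support = "support")
  calls <- sites |>
    dplyr::left_join(ref_rows, by = c("canonical_tag", "target_id", "pos")) |>
    dplyr::left_join(var_rows, by = c("canonical_tag", "target_id", "pos")) |>
    dplyr::mutate(
      is_variant = !is.na(.data$alt_call),
      call = ifelse(.data$is_variant, .data$alt_call, .data$ref),
      support = as.integer(ifelse(.data$is_variant, .data$alt_support,
                                  dplyr::coalesce(.data$ref_support, 0L)))
    ) |>
    dplyr::select("canonical_tag", "target_id", "pos", "ref", "call",
                  "support", "depth", "is_variant") |>
    dplyr::arrange(.data$canonical_tag, .data$pos)
  class(calls) <- c("noir_consensus", class(calls))
  calls
}

# long (target_id, pos, ref) lookup across all regions
region_ref_table <- function(regions) {
  chars <- strsplit(regions$ref_seq, "", fixed = TRUE)
  tibble(
    target_id = rep(regions$target_id, lengths(chars)),
    pos = unlist(lapply(lengths(chars), seq_len)),
    ref = unlist(chars)
  )
}

#' Collapse a consensus table to one sequence per family
#'
#' @param consensus A [build_consensus()] table.
#' @return A tibble `canonical_tag`, `target_id`, `ref_start`, `sequence`
#'   (deletion symbols removed), `n_variant`.
#' @export
consensus_sequences <- function(consensus) {
  if (nrow(consensus) == 0L) {
    return(tibble(canonical_tag = character(), target_id = character(),
                  ref_start = integer(), sequence = character(),
                  n_variant = integer()))
  }
  consensus |>
    dplyr::group_by(.data$canonical_tag, .data$target_id) |>
    dplyr::summarise(
      ref_start = min(.data$pos),
      sequence = gsub("-", "", paste(.data$call[order(.data$pos)],
                                     collapse = ""), fixed = TRUE),
      n_variant = sum(.data$is_variant),
      .groups = "drop"
    )
}

#' Write consensus reads to FASTQ at Q57
#'
#' Every base of every consensus read is assigned quality 57 (Phred+33
#' character `Z`), reflecting the post-consensus confidence rather than any
#' input quality.
#'
#' @param consensus A [build_consensus()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus_fastq <- function(consensus, path) {
  seqs <- consensus_sequences(consensus)
  write_fastq(
    tibble(read_id = seqs$canonical_tag, sequence = seqs$sequence,
           quality = strrep(rawToChar(as.raw(57L + 33L)),
                            nchar(seqs$sequence))),
    path
  )
}

pileup_from_long <- function(long, regions) {
  sp <- setNames(regions$spacer_len, regions$target_id)
  long |>
    dplyr::count(.data$target_id, .data$pos, .data$base) |>
    tidyr::pivot_wider(names_from = "base", values_from = "n",
                       values_fill = 0L) |>
    (\(df) {
      for (b in c(BASES, "-")) if (!b %in% names(df)) df[[b]] <- 0L
      df
    })() |>
    dplyr::rename(del = "-") |>
    dplyr::left_join(region_ref_table(regions), by = c("target_id", "pos")) |>
    dplyr::mutate(
      coverage = .data$A + .data$C + .data$G + .data$T + .data$del,
      target_pos = .data$pos - sp[.data$target_id]
    ) |>
    dplyr::select("target_id", "pos", "target_pos", "ref",
                  dplyr::all_of(BASES), "del", "coverage") |>
    dplyr::arrange(.data$target_id, .data$pos)
}

#' Per-position base counts over consensus reads
#'
#' Each accepted molecule contributes exactly once per covered position.
#' `pos` is 1-based on the region reference (spacer + target); `target_pos`
#' is 1-based within the target (non-positive in the spacer).
#'
#' @param consensus A [build_consensus()] table.
#' @param regions A region tibble.
#' @return A pileup tibble: `target_id`, `pos`, `target_pos`, `ref`, `A`,
#'   `C`, `G`, `T`, `del`, `coverage`.
#' @export
pileup_consensus <- function(consensus, regions) {
  long <- dplyr::select(consensus, "target_id", "pos", base = "call")
  pileup_from_long(long, regions)
}

#' Per-position base counts over raw aligned reads
#'
#' The deep-sequencing arm: every read counts, molecules are not collapsed.
#'
#' @param aln Aligned reads ([align_payloads()]).
#' @param regions A region tibble.
#' @return A pileup tibble as [pileup_consensus()].
#' @export
pileup_reads <- function(aln, regions) {
  long <- alignments_long(aln)
  pileup_from_long(dplyr::select(long, "target_id", "pos", "base"), regions)
}
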