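# Tag families, indel-tolerant merging, and the data-driven reads-per-tag
# threshold that separates erroneous tags from real molecules.

length_class_of <- function(len, scheme = "N12") {
  expected <- if (scheme == "BDHV15") 15L else 12L
  dplyr::case_when(
    len < 9L ~ "<9",
    len < expected - 1L ~ sprintf("9-%d", expected - 1L),
    len > expected + 1L ~ sprintf(">=%d", expected + 2L),
    TRUE ~ as.character(len)
  )
}

# all sequences obtainable from x by deleting one base, deduplicated
single_deletions <- function(x) {
  n <- nchar(x)
  unique(vapply(seq_len(n), function(i) {
    paste0(substr(x, 1L, i - 1L), substr(x, i + 1L, n))
  }, character(1)))
}

#' Group reads into barcode tag families
#'
#' Reads sharing an identical tag form a family. Tags shorter than
#' `min_tag_len` (default 9) are discarded. Tags one base shorter or longer
#' than the expected length that can be produced from a canonical
#' expected-length tag by a single deletion (insertion) are then merged into
#' that family — these are overwhelmingly indel read-errors of the true tag.
#' When several canonical tags qualify, the family with more reads wins
#' (ties: lexicographically smaller canonical). Expected-length tags never
#' merge with each other, and 9-10-bp or >=14-bp tags are kept as their own
#' (erroneous) families.
#'
#' @param tagged A tibble with columns `read_id` and `tag` (e.g. from
#'   [extract_tags()]); rows with `NA` tags are ignored.
#' @param scheme `"N12"` (expected length 12) or `"BDHV15"` (expected 15).
#' @param min_tag_len Tags shorter than this are discarded (default 9).
#' @param merge_indels Merge single-indel neighbours into expected-length
#'   families (default `TRUE`).
#' @return A tibble with one row per family: `canonical_tag`, `tag_len`,
#'   `length_class`, `n_reads`, list-columns `read_ids` and `merged_from`.
#' @export
tag_families <- function(tagged, scheme = c("N12", "BDHV15"),
                         min_tag_len = 9L, merge_indels = TRUE) {
  scheme <- match.arg(scheme)
  expected <- if (scheme == "N12") 12L else 15L
  df <- dplyr::filter(tagged, !is.na(.data$tag),
                      nchar(.data$tag) >= min_tag_len)
  if (nrow(df) == 0L) {
    return(tibble(canonical_tag = character(), tag_len = integer(),
                  length_class = character(), n_reads = integer(),
                  read_ids = list(), merged_from = list()))
  }
  fam <- df |>
    dplyr::group_by(canonical_tag = .data$tag) |>
    dplyr::summarise(n_reads = dplyr::n(),
                     read_ids = list(.data$read_id), .groups = "drop") |>
    dplyr::mutate(tag_len = nchar(.data$canonical_tag),
                  merged_from = rep(list(character(0)), dplyr::n()))

  if (merge_indels) {
    canon <- fam$canonical_tag[fam$tag_len == expected]
    if (length(canon) > 0L) {
      # map every single-deletion (expected-1)-mer of each canonical tag to
      # its parent; an (expected-1)-length observed tag merges via lookup,
      # an (expected+1)-length tag merges when one of ITS single deletions
      # is canonical
      dels_of <- lapply(canon, single_deletions)
      del_parent <- tibble(
        key = unlist(dels_of),
        parent = rep(canon, lengths(dels_of))
      )
      reads_of <- setNames(fam$n_reads, fam$canonical_tag)
      # candidate (family index, parent) pairs for both length classes,
      # resolved by most-read parent, ties lexicographic
      short <- which(fam$tag_len == expected - 1L)
      long <- which(fam$tag_len == expected + 1L)
      cand_short <- dplyr::inner_join(
        tibble(idx = short, key = fam$canonical_tag[short]),
        del_parent, by = "key", relationship = "many-to-many")
      long_dels <- lapply(fam$canonical_tag[long], single_deletions)
      cand_long <- tibble(
        idx = rep(long, lengths(long_dels)),
        parent = as.character(unlist(c(long_dels, character(0))))
      ) |> dplyr::filter(.data$parent %in% canon)
      cand <- dplyr::bind_rows(
        dplyr::select(cand_short, "idx", "parent"), cand_long) |>
        dplyr::distinct() |>
        dplyr::mutate(parent_reads = reads_of[.data$parent]) |>
        dplyr::arrange(.data$idx, dplyr::desc(.data$parent_reads),
                       .data$parent) |>
        dplyr::distinct(.data$idx, .keep_all = TRUE)
      target <- rep(NA_character_, nrow(fam))
      target[cand$idx] <- cand$parent
      merge_idx <- which(!is.na(target))
      if (length(merge_idx) > 0L) {
        parent_idx <- match(target[merge_idx], fam$canonical_tag)
        for (j in seq_along(merge_idx)) {
          src <- merge_idx[j]; dst <- parent_idx[j]
          fam$n_reads[dst] <- fam$n_reads[dst] + fam$n_reads[src]
          fam$read_ids[[dst]] <- c(fam$read_ids[[dst]], fam$read_ids[[src]])
          fam$merged_from[[dst]] <- c(fam$merged_from[[dst]],
                                      fam$canonical_tag[src])
        }
        fam <- fam[-merge_idx, ]
      }
    }
  }
  fam |>
    dplyr::mutate(length_class = length_class_of(.data$tag_len, scheme)) |>
    dplyr::select("canonical_tag", "tag_len", "length_class", "n_reads",
                  "read_ids", "merged_from") |>
    dplyr::arrange(dplyr::desc(.data$n_reads), .data$canonical_tag)
}

#' Flag BDHV tags that contain a disallowed base
#'
#' In the `BDHVBDHVBDHVBDH` scheme each position lacks one of the four bases
#' (B: no A, D: no C, H: no G, V: no T). A tag showing the missing base at
#' any position certifies a read error.
#'
#' @param tags Character vector of tags.
#' @return Logical vector: `TRUE` where a disallowed base is present.
#' @export
bdhv_flagged <- function(tags) {
  maxlen <- max(nchar(tags), 15L)
  disallowed <- BDHV_DISALLOWED[bdhv_cycle(maxlen)]
  flag <- logical(length(tags))
  for (j in seq_len(maxlen)) {
    flag <- flag | substr(tags, j, j) == disallowed[[j]]
  }
  flag
}

#' Estimate the total number of erroneous BDHV tags
#'
#' Substitutions hit the one disallowed base of a position in one of three
#' equally likely ways, so the observable flagged tags are one third of all
#' substitution-erroneous tags: the total is estimated as three times the
#' flagged count.
#'
#' @param families A family tibble ([tag_families()]).
#' @return A list with `n_flagged` and `estimated_total`.
#' @export
estimate_bdhv_errors <- function(families) {
  n_flagged <- sum(bdhv_flagged(families$canonical_tag))
  list(n_flagged = n_flagged, estimated_total = 3L * n_flagged)
}

#' Reads-per-tag histogram in 2-read bins
#'
#' Families are assigned to 2-read bins (bin k covers reads-per-tag 2k-1 and
#' 2k) and the per-bin proportion of correct tags is computed. "Correct"
#' means length 12 for the N12 scheme; for BDHV15 it means length 15 with no
#' disallowed base.
#'
#' @param families A family tibble ([tag_families()]).
#' @param scheme `"N12"` or `"BDHV15"`.
#' @param window Smoothing window in bins (default 11: the bin and its five
#'   neighbours on each side).
#' @param smooth_method Smoothing estimator, see [smooth_proportions()].
#' @param min_prop Threshold proportion stored for plotting (default 0.90).
#' @return An object of class `noir_histogram`: a tibble with one row per
#'   bin (`bin`, `reads_lo`, `reads_hi`, `n_total`, `n_correct`, `prop_raw`,
#'   `prop_smooth`), empty bins carried with `n_total = 0` and `NA`
#'   proportions.
#' @export
tag_histogram <- function(families, scheme = c("N12", "BDHV15"),
                          window = 11L, min_prop = 0.90,
                          smooth_method = c("pooled", "mean")) {
  scheme <- match.arg(scheme)
  stopifnot(nrow(families) > 0L)
  expected <- if (scheme == "N12") 12L else 15L
  correct <- families$tag_len == expected
  if (scheme == "BDHV15") {
    correct <- correct & !bdhv_flagged(families$canonical_tag)
  }
  bin <- (families$n_reads + 1L) %/% 2L
  tab <- tibble(bin = bin, correct = correct) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_correct = sum(.data$correct), .groups = "drop")
  full <- tibble(bin = seq_len(max(tab$bin))) |>
    dplyr::left_join(tab, by = "bin") |>
    dplyr::mutate(
      n_total = dplyr::coalesce(.data$n_total, 0L),
      n_correct = dplyr::coalesce(.data$n_correct, 0L),
      reads_lo = 2L * .data$bin - 1L,
      reads_hi = 2L * .data$bin,
      prop_raw = ifelse(.data$n_total > 0L,
                        .data$n_correct / .data$n_total, NA_real_)
    ) |>
    dplyr::select("bin", "reads_lo", "reads_hi", "n_total", "n_correct",
                  "prop_raw")
  out <- smooth_proportions(full, window = window, method = smooth_method)
  attr(out, "scheme") <- scheme
  attr(out, "min_prop") <- min_prop
  class(out) <- c("noir_histogram", class(out))
  out
}

#' Smooth per-bin proportions with a centered moving window
#'
#' Each bin's proportion is smoothed over the `window` bins centered on it
#' (the bin and its `(window-1)/2` neighbours each side). At the edges the
#' window runs over the bins that exist; empty bins contribute nothing (they
#' are excluded, not counted as zero).
#'
#' Two estimators are available. `"pooled"` (the default) divides the summed
#' correct-tag count by the summed family count over the window: each family
#' carries equal weight, so a dense error-dominated bin cannot be outvoted
#' by single-family neighbours. `"mean"` is the unweighted average of the
#' per-bin proportions; the two coincide when the bins in a window are
#' similarly occupied, which is the regime the procedure was designed for,
#' but `"mean"` is unstable when the histogram is sparse.
#'
#' @param hist A histogram tibble with columns `bin`, `prop_raw` and (for
#'   `"pooled"`) `n_total`, `n_correct`.
#' @param window Odd window size in bins (default 11).
#' @param method `"pooled"` or `"mean"`.
#' @return `hist` with a `prop_smooth` column (NA where no bin in the window
#'   is informative).
#' @export
smooth_proportions <- function(hist, window = 11L,
                               method = c("pooled", "mean")) {
  stopifnot(window %% 2L == 1L)
  method <- match.arg(method)
  half <- (window - 1L) %/% 2L
  nb <- nrow(hist)
  p <- hist$prop_raw
  sm <- vapply(seq_len(nb), function(i) {
    w <- max(1L, i - half):min(nb, i + half)
    if (method == "pooled") {
      tot <- sum(hist$n_total[w])
      if (tot == 0L) NA_real_ else sum(hist$n_correct[w]) / tot
    } else {
      v <- p[w][!is.na(p[w])]
      if (length(v) == 0L) NA_real_ else mean(v)
    }
  }, numeric(1))
  dplyr::mutate(hist, prop_smooth = sm)
}

#' Derive the erroneous-tag threshold M
#'
#' M is the lower read-count bound (2k-1) of the lowest bin whose smoothed
#' correct-tag proportion reaches `min_prop`. Families with fewer than M
#' reads are classified erroneous. With `strict = TRUE` the qualifying bin
#' must additionally be followed only by qualifying non-empty bins.
#'
#' @param hist A [tag_histogram()].
#' @param min_prop Minimum smoothed proportion (default 0.90).
#' @param strict Require persistence above `min_prop` beyond the first
#'   qualifying bin (default `FALSE`: the minimum qualifying bin is taken).
#' @return Integer threshold M (in reads).
#' @export
find_threshold <- function(hist, min_prop = 0.90, strict = FALSE) {
  ok <- !is.na(hist$prop_smooth) & hist$prop_smooth >= min_prop
  if (strict) {
    informative <- !is.na(hist$prop_smooth) & hist$n_total > 0L
    ok <- ok & rev(cumprod(rev(ok | !informative))) > 0
  }
  if (!any(ok)) {
    stop("no bin reaches a smoothed proportion of ", min_prop,
         "; sequence deeper to separate erroneous tags")
  }
  hist$reads_lo[which(ok)[1L]]
}

#' Split families into accepted and removed at threshold M
#'
#' Families with at least M reads are accepted; the number of accepted
#' families in a region is the molecule count m.
#'
#' @param families A family tibble.
#' @param M Threshold in reads ([find_threshold()]).
#' @return `families` with a logical `accepted` column.
#' @export
threshold_families <- function(families, M) {
  dplyr::mutate(families, accepted = .data$n_reads >= M)
}

#' Upper bound on error-free tags lost to thresholding
#'
#' The error-free reads-per-tag distribution is unimodal with its peak above
#' M, so the error-free mass below M cannot exceed the mass in \[M, 2M).
#' The count of correct-length tags with M <= reads < 2M is therefore an
#' upper bound on the error-free tags removed.
#'
#' @param families A family tibble.
#' @param M Threshold in reads.
#' @param scheme `"N12"` or `"BDHV15"`.
#' @return A list with `bound` (count) and `fraction_of_accepted`.
#' @export
estimate_removed_error_free <- function(families, M,
                                        scheme = c("N12", "BDHV15")) {
  scheme <- match.arg(scheme)
  expected <- if (scheme == "N12") 12L else 15L
  correct <- families$tag_len == expected
  if (scheme == "BDHV15") {
    correct <- correct & !bdhv_flagged(families$canonical_tag)
  }
  bound <- sum(correct & families$n_reads >= M & families$n_reads < 2 * M)
  n_acc <- sum(families$n_reads >= M)
  list(bound = bound,
       fraction_of_accepted = if (n_acc > 0L) bound / n_acc else NA_real_)
}
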