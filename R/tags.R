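# Demultiplexing and barcode-tag extraction.

#' Assign reads to samples by their 5-bp index
#'
#' Exact match of the first five bases against an index table; anything else
#' goes to `"unassigned"` (a valid outcome, counted in the run log, never an
#' error).
#'
#' @param reads A read tibble (needs `sequence`).
#' @param index_table A data frame with columns `index` (5-mers) and
#'   `sample`, or a named character vector `c(ACGTA = "s1", ...)`.
#' @return `reads` with a `sample` column added.
#' @export
#' @examples
#' demultiplex(tibble::tibble(read_id = "r1", sequence = "ACGTAGGG"),
#'             c(ACGTA = "s1"))
demultiplex <- function(reads, index_table) {
  if (!is.data.frame(index_table)) {
    index_table <- tibble(index = names(index_table),
                          sample = unname(index_table))
  }
  stopifnot(all(c("index", "sample") %in% names(index_table)),
            all(nchar(index_table$index) == 5L))
  idx <- substr(reads$sequence, 1L, 5L)
  pos <- match(idx, index_table$index)
  dplyr::mutate(reads,
                sample = ifelse(is.na(pos), "unassigned",
                                index_table$sample[pos]))
}

# Elementwise Levenshtein distance between equal-length character vectors,
# via utils::adist on the unique pairs (C implementation).
edit_dist_to <- function(x, ref) {
  u <- unique(x)
  d <- as.integer(utils::adist(u, ref))
  d[match(x, u)]
}

#' Extract barcode tags by locating the spacer
#'
#' The tag is everything strictly between the 5-bp index and the start of the
#' spacer. The spacer is located by the lowest-edit-distance match of the
#' full spacer sequence over a window of candidate start positions (tag
#' lengths `scheme length - 3` to `scheme length + 4`, i.e. 9-16 for N12),
#' ties broken leftmost. Reads with no candidate within `max_dist` edits are
#' rejected with reason `"no_spacer"`.
#'
#' @param reads A read tibble (needs `read_id`, `sequence`).
#' @param spacer Spacer sequence(s); with several (e.g. per-region spacers)
#'   the best-matching one wins.
#' @param scheme `"N12"` or `"BDHV15"` (sets the search window).
#' @param max_dist Maximum edit distance for a spacer match (default 2).
#' @return `reads` with columns added: `tag`, `tag_len`, `payload` (spacer
#'   onward), `spacer_dist`, and `status` (`"ok"` or `"no_spacer"`).
#' @export
extract_tags <- function(reads, spacer, scheme = c("N12", "BDHV15"),
                         max_dist = 2L) {
  scheme <- match.arg(scheme)
  expected <- if (scheme == "N12") 12L else 15L
  offsets <- (expected - 3L):(expected + 4L)  # candidate tag lengths
  seqs <- reads$sequence
  n <- length(seqs)
  best_dist <- rep.int(.Machine$integer.max, n)
  best_start <- rep.int(NA_integer_, n)
  for (sp in unique(toupper(spacer))) {
    L <- nchar(sp)
    for (tl in offsets) {
      s <- 6L + tl  # 1-based spacer start for a tag of length tl
      win <- substr(seqs, s, s + L - 1L)
      d <- ifelse(win == sp, 0L, NA_integer_)
      miss <- is.na(d)
      if (any(miss)) d[miss] <- edit_dist_to(win[miss], sp)
      upd <- d < best_dist  # strict: earlier (leftmost) offset wins ties
      best_dist[upd] <- d[upd]
      best_start[upd] <- s
    }
  }
  ok <- best_dist <= max_dist
  dplyr::mutate(
    reads,
    tag = ifelse(ok, substr(seqs, 6L, best_start - 1L), NA_character_),
    tag_len = ifelse(ok, best_start - 6L, NA_integer_),
    payload = ifelse(ok, substr(seqs, best_start, nchar(seqs)), NA_character_),
    spacer_dist = ifelse(ok, best_dist, NA_integer_),
    status = ifelse(ok, "ok", "no_spacer")
  )
}

#' Read-level payload length filter
#'
#' Reads are usable only when the spacer plus the following sequence is
#' longer than `min_len` bases (default 70): shorter payloads cannot be
#' aligned reliably.
#'
#' @param tagged Output of [extract_tags()].
#' @param min_len Minimum exclusive payload length.
#' @return `tagged` with `status` set to `"short_payload"` where the filter
#'   fails.
#' @export
filter_payload_length <- function(tagged, min_len = 70L) {
  dplyr::mutate(
    tagged,
    status = ifelse(.data$status == "ok" & nchar(.data$payload) <= min_len,
                    "short_payload", .data$status)
  )
}
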