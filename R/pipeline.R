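# End-to-end orchestration: extract -> filter -> align -> denoise ->
# consensus -> call, with a conserved per-stage disposition log.

#' Run the full NOIR analysis pipeline
#'
#' Takes raw reads (real or simulated) through tag extraction, alignment,
#' tag-family grouping with indel-tolerant merging, histogram-based
#' erroneous-tag removal, per-molecule consensus building, and region-level
#' Poisson variant calling. Deterministic: no randomness is used anywhere in
#' the pipeline itself.
#'
#' @param reads A read tibble (`read_id`, `sequence`), e.g. from
#'   [read_fastq()] or `simulate_library()$reads`.
#' @param regions A region tibble ([target_regions()]).
#' @param index_table Optional sample index table for [demultiplex()]; reads
#'   demultiplexing to `"unassigned"` are dropped. `NULL` skips the step.
#' @param scheme Barcode scheme, `"N12"` or `"BDHV15"`.
#' @param min_prop Minimum smoothed correct-tag proportion defining the
#'   threshold bin (default 0.90).
#' @param window Histogram smoothing window in bins (default 11).
#' @param min_tag_len Minimum tag length retained (default 9).
#' @param alt_frac Consensus alternative-base fraction (default 0.8,
#'   strict).
#' @param max_reads_per_consensus Longest-reads cap per family (default 50).
#' @param min_payload Minimum exclusive payload length (default 70).
#' @param max_unmapped_frac Maximum clipped-end fraction (default 0.10).
#' @param ER Error-rate constant for calling (default 1e-5, consensus mode).
#' @param alpha Poisson verdict threshold (default 1e-3).
#' @param run_consensus Build consensus reads and call variants
#'   (default `TRUE`); `FALSE` stops after erroneous-tag removal, which is
#'   all molecule counting needs.
#' @param strict_threshold Use the persistent variant of the threshold scan.
#' @return An object of class `noir_run`: a list with elements `log`
#'   (per-stage read dispositions), `tagged`, `aln`, `families`,
#'   `histogram`, `M`, `m` (accepted molecule counts per region),
#'   `removed_error_free` (bound), and when `run_consensus = TRUE` also
#'   `consensus`, `pileup`, `error_rate`, `calls`.
#' @export
#' @examples
#' sim <- simulate_library(
#'   sim_config(60, "KRAS_like_synthetic",
#'              reads_per_tag = list(model = "constant", k = 12), seed = 2))
#' run <- run_noir(sim$reads, example_regions())
#' glance(run)
run_noir <- function(reads, regions, index_table = NULL,
                     scheme = c("N12", "BDHV15"),
                     min_prop = 0.90, window = 11L, min_tag_len = 9L,
                     alt_frac = 0.8, max_reads_per_consensus = 50L,
                     min_payload = 70L, max_unmapped_frac = 0.10,
                     ER = 1e-5, alpha = 1e-3,
                     run_consensus = TRUE, strict_threshold = FALSE) {
  scheme <- match.arg(scheme)
  n_in <- nrow(reads)
  if (!is.null(index_table)) {
    reads <- demultiplex(reads, index_table)
    reads <- dplyr::filter(reads, .data$sample != "unassigned")
  }
  n_demux <- nrow(reads)
  tagged <- extract_tags(reads, spacer = regions$spacer, scheme = scheme)
  aln <- align_payloads(tagged, regions,
                        max_unmapped_frac = max_unmapped_frac,
                        min_payload = min_payload)
  log <- dplyr::bind_rows(
    tibble(status = "input", n = n_in),
    tibble(status = "unassigned_index", n = n_in - n_demux),
    read_dispositions(aln)
  )
  mapped <- dplyr::filter(aln, .data$status == "aligned")
  families <- tag_families(mapped, scheme = scheme,
                           min_tag_len = min_tag_len)
  hist <- tag_histogram(families, scheme = scheme, window = window,
                        min_prop = min_prop)
  M <- find_threshold(hist, min_prop = min_prop, strict = strict_threshold)
  families <- threshold_families(families, M)
  fam_region <- dplyr::select(mapped, "read_id", "target_id")
  fam_target <- families |>
    tidyr::unnest_longer("read_ids", values_to = "read_id") |>
    dplyr::left_join(fam_region, by = "read_id") |>
    dplyr::count(.data$canonical_tag, .data$target_id) |>
    dplyr::slice_max(.data$n, n = 1L, by = "canonical_tag",
                     with_ties = FALSE) |>
    dplyr::select("canonical_tag", "target_id")
  m_per_region <- families |>
    dplyr::filter(.data$accepted) |>
    dplyr::left_join(fam_target, by = "canonical_tag") |>
    dplyr::count(.data$target_id, name = "m")
  out <- list(
    log = log,
    tagged = tagged,
    aln = aln,
    families = families,
    histogram = hist,
    M = M,
    m = m_per_region,
    removed_error_free = estimate_removed_error_free(families, M, scheme),
    scheme = scheme,
    params = list(min_prop = min_prop, window = window,
                  min_tag_len = min_tag_len, alt_frac = alt_frac,
                  max_reads_per_consensus = max_reads_per_consensus,
                  min_payload = min_payload,
                  max_unmapped_frac = max_unmapped_frac,
                  ER = ER, alpha = alpha)
  )
  if (run_consensus) {
    cons <- build_consensus(families, aln, regions,
                            max_reads = max_reads_per_consensus,
                            alt_frac = alt_frac)
    pu <- pileup_consensus(cons, regions)
    mvec <- setNames(m_per_region$m, m_per_region$target_id)
    out$consensus <- cons
    out$pileup <- pu
    out$error_rate <- error_rate(pu, regions)
    out$calls <- call_regions(pu, regions, ER = ER, alpha = alpha, m = mvec)
  }
  structure(out, class = "noir_run")
}

#' @export
print.noir_run <- function(x, ...) {
  cat("<noir_run>\n")
  cat("  threshold M:", x$M, "reads\n")
  cat("  accepted molecules:",
      paste(sprintf("%s = %d", x$m$target_id, x$m$m), collapse = ", "), "\n")
  if (!is.null(x$calls)) {
    pos <- dplyr::filter(x$calls, .data$variant_positive)
    cat("  variant-positive regions:",
        if (nrow(pos)) paste(pos$target_id, collapse = ", ") else "none",
        "\n")
  }
  invisible(x)
}

#' @rdname run_noir
#' @param x A `noir_run`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.noir_run <- function(x, ...) {
  tibble(
    n_input = x$log$n[x$log$status == "input"],
    n_aligned = sum(x$log$n[x$log$status == "aligned"]),
    n_families = nrow(x$families),
    M = x$M,
    n_accepted = sum(x$families$accepted),
    removed_error_free_bound = x$removed_error_free$bound,
    error_rate = if (!is.null(x$error_rate)) x$error_rate$rate else NA_real_
  )
}

#' @rdname run_noir
#' @exportS3Method generics::tidy
tidy.noir_run <- function(x, ...) {
  if (is.null(x$calls)) {
    stop("run_noir() was called with run_consensus = FALSE; no calls to tidy")
  }
  tidy(x$calls)
}

#' @exportS3Method generics::tidy
tidy.noir_calls <- function(x, ...) {
  dplyr::select(as_tibble(x), -"changes")
}

#' @exportS3Method generics::glance
glance.noir_calls <- function(x, ...) {
  tibble(
    n_regions = nrow(x),
    n_positive = sum(x$variant_positive),
    ER = attr(x, "ER"),
    alpha = attr(x, "alpha")
  )
}

#' Subsample reads without replacement
#'
#' For saturation analysis: draw a uniform random subset of reads (by count
#' or by fraction) from a library.
#'
#' @param reads A read tibble.
#' @param n Number of reads to keep (exclusive with `fraction`).
#' @param fraction Fraction of reads to keep.
#' @param seed Optional seed for reproducibility.
#' @return The subsampled read tibble (input order preserved).
#' @export
subsample_reads <- function(reads, n = NULL, fraction = NULL, seed = NULL) {
  stopifnot(xor(is.null(n), is.null(fraction)))
  if (is.null(n)) n <- round(fraction * nrow(reads))
  if (n > nrow(reads)) stop("cannot subsample ", n, " of ", nrow(reads),
                            " reads")
  pick <- if (is.null(seed)) sample.int(nrow(reads), n) else
    withr::with_seed(seed, sample.int(nrow(reads), n))
  reads[sort(pick), ]
}
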