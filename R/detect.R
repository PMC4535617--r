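# Error rates, the region-level Poisson anomaly model, and the
# deep-sequencing comparison arm.

target_pileup <- function(pileup, regions) {
  excl <- setNames(regions$excluded_positions, regions$target_id)
  pileup |>
    dplyr::filter(.data$target_pos >= 1L) |>
    dplyr::filter(!purrr::map2_lgl(.data$target_id, .data$target_pos,
                                   ~ .y %in% excl[[.x]]))
}

#' Sequencing error rate from a pileup
#'
#' The number of non-reference base calls divided by the number of all base
#' calls over the target regions, with excluded positions (known germline
#' SNP sites) contributing to neither count. Deletions are not counted as
#' errors by default (indel calls are reported separately throughout);
#' `count_del = TRUE` includes them in both numerator and denominator.
#'
#' @param pileup A pileup tibble ([pileup_consensus()] or [pileup_reads()]).
#' @param regions A region tibble.
#' @param count_del Count deletion calls as non-reference (default `FALSE`).
#' @return A list: `n_nonref`, `n_total`, `rate`, `conf_low`, `conf_high`
#'   (exact binomial 95% CI).
#' @export
error_rate <- function(pileup, regions, count_del = FALSE) {
  tp <- target_pileup(pileup, regions)
  base_calls <- as.matrix(tp[, BASES])
  ref_idx <- match(tp$ref, BASES)
  total <- sum(base_calls)
  nonref <- sum(base_calls) - sum(base_calls[cbind(seq_len(nrow(tp)), ref_idx)])
  if (count_del) {
    nonref <- nonref + sum(tp$del)
    total <- total + sum(tp$del)
  }
  if (total == 0L) {
    return(list(n_nonref = 0L, n_total = 0L, rate = NA_real_,
                conf_low = NA_real_, conf_high = NA_real_))
  }
  ci <- stats::binom.test(nonref, total)$conf.int
  list(n_nonref = nonref, n_total = total, rate = nonref / total,
       conf_low = ci[1L], conf_high = ci[2L])
}

#' Poisson tail probability of n or more sequencing errors
#'
#' With expected error count `lambda = l * m * ER` (region length in bp
#' times molecules sequenced times per-base error rate), returns
#' `P = 1 - sum_{k=0}^{n-1} lambda^k e^-lambda / k!`, i.e. the upper-tail
#' probability `P(X >= n)`, computed with a numerically stable routine
#' (accurate even when P is far below machine epsilon of 1).
#'
#' @param l Region length in base pairs.
#' @param m Number of molecules sequenced.
#' @param ER Per-base sequencing error rate.
#' @param n Observed number of non-reference base changes.
#' @return The tail probability in \[0, 1\]; `n = 0` gives 1 exactly.
#' @export
#' @examples
#' poisson_p(l = 73, m = 2000, ER = 1e-5, n = 8)
poisson_p <- function(l, m, ER, n) {
  stopifnot(l >= 0, m >= 0, ER >= 0, ER <= 1, n >= 0,
            n == as.integer(n))
  lambda <- l * m * ER
  ifelse(n == 0, 1, ppois(n - 1, lambda, lower.tail = FALSE))
}

#' Classify the positional pattern of base changes
#'
#' Scattered changes (every change at a different position) look like
#' sequencing errors; changes accumulated at a single position look like a
#' real mutation. A region is `"clustered"` when the modal position carries
#' at least `min_modal_fraction` of all changes and there are at least
#' `min_changes` changes; `"scattered"` otherwise; `"indeterminate"` with
#' fewer than `min_changes`. The label annotates, and never overrides, the
#' Poisson verdict.
#'
#' @param position_counts Named or unnamed integer vector of per-position
#'   change counts (zeros allowed), or a two-column data frame
#'   `target_pos`, `n`.
#' @param min_modal_fraction Minimum share of changes at the modal position
#'   (default 0.5).
#' @param min_changes Minimum total changes to attempt classification
#'   (default 2).
#' @return `"clustered"`, `"scattered"`, or `"indeterminate"`.
#' @export
classify_changes <- function(position_counts, min_modal_fraction = 0.5,
                             min_changes = 2L) {
  if (is.data.frame(position_counts)) position_counts <- position_counts$n
  total <- sum(position_counts)
  if (total < min_changes) return("indeterminate")
  if (max(position_counts) >= min_modal_fraction * total) "clustered"
  else "scattered"
}

#' Region-level Poisson variant calls
#'
#' For each region, tallies the non-reference substitution calls n over
#' non-excluded target positions, computes `lambda = l * m * ER` and the
#' Poisson tail probability, and declares the region variant-positive when
#' `P <= alpha`. The criterion evaluates the entire region, not individual
#' positions. ER is a configured constant: 1e-5 for consensus (NOIR)
#' pileups, 5e-4 for raw-read (deep sequencing) pileups.
#'
#' @param pileup A pileup tibble.
#' @param regions A region tibble.
#' @param ER Per-base error-rate constant (default 1e-5, the consensus-mode
#'   value; use 5e-4 for raw-read pileups).
#' @param alpha Verdict threshold on P (default 1e-3: one false positive per
#'   1000 samples).
#' @param m Molecules sequenced per region, as a named vector or single
#'   number; default: the maximum coverage observed in the region.
#' @param count_del Count deletion calls in n (default `FALSE`; indel calls
#'   are reported in the `n_del` column either way).
#' @return An object of class `noir_calls`: a tibble with one row per
#'   region (`target_id`, `l`, `m`, `n`, `n_del`, `lambda`, `p_value`,
#'   `variant_positive`, `clustering`, and list-column `changes` of
#'   per-position change counts).
#' @export
call_regions <- function(pileup, regions, ER = 1e-5, alpha = 1e-3,
                         m = NULL, count_del = FALSE) {
  tp <- target_pileup(pileup, regions)
  m_of <- function(id, fallback) {
    if (is.null(m)) return(fallback)
    v <- unname(if (!is.null(names(m))) m[id] else m[1L])
    if (is.na(v)) fallback else v
  }
  res <- lapply(seq_len(nrow(regions)), function(r) {
    reg <- regions[r, ]
    sub <- dplyr::filter(tp, .data$target_id == reg$target_id)
    if (nrow(sub) == 0L) {
      mm <- m_of(reg$target_id, 0)
      return(tibble(target_id = reg$target_id, l = reg$length_l, m = mm,
                    n = 0L, n_del = 0L, lambda = reg$length_l * mm * ER,
                    p_value = 1, variant_positive = FALSE,
                    clustering = "indeterminate",
                    changes = list(tibble(target_pos = integer(),
                                          n = integer()))))
    }
    base_calls <- as.matrix(sub[, BASES])
    ref_idx <- cbind(seq_len(nrow(sub)), match(sub$ref, BASES))
    nonref_by_pos <- rowSums(base_calls) - base_calls[ref_idx]
    if (count_del) nonref_by_pos <- nonref_by_pos + sub$del
    mm <- m_of(reg$target_id, max(sub$coverage))
    n <- sum(nonref_by_pos)
    lambda <- reg$length_l * mm * ER
    p <- poisson_p(reg$length_l, mm, ER, n)
    changes <- tibble(target_pos = sub$target_pos, n = as.integer(nonref_by_pos)) |>
      dplyr::filter(.data$n > 0L)
    tibble(
      target_id = reg$target_id, l = reg$length_l, m = mm, n = as.integer(n),
      n_del = as.integer(sum(sub$del)), lambda = lambda, p_value = p,
      variant_positive = p <= alpha,
      clustering = classify_changes(changes),
      changes = list(changes)
    )
  })
  out <- dplyr::bind_rows(res)
  attr(out, "ER") <- ER
  attr(out, "alpha") <- alpha
  class(out) <- c("noir_calls", class(out))
  out
}

#' Mutant-molecule fraction at a position (ctDNA %)
#'
#' The fraction of sequenced molecules carrying a given alternative base at
#' a target position, as a percentage — with consensus pileups this is an
#' absolute quantitation of mutant molecules (e.g. the ctDNA level).
#'
#' @param pileup A consensus pileup.
#' @param target One region name.
#' @param target_pos 1-based position within the target.
#' @param alt Alternative base.
#' @param m Total molecules; default: coverage at the position.
#' @return A list: `n_mutant`, `m`, `percent` (`NA` when the position is
#'   uncovered).
#' @export
mutant_fraction <- function(pileup, target, target_pos, alt, m = NULL) {
  row <- dplyr::filter(pileup, .data$target_id == target,
                       .data$target_pos == !!target_pos)
  if (nrow(row) == 0L || row$coverage == 0L) {
    return(list(n_mutant = NA_integer_, m = m %||% NA_integer_,
                percent = NA_real_))
  }
  n_mut <- row[[alt]]
  m <- m %||% row$coverage
  list(n_mutant = n_mut, m = m, percent = 100 * n_mut / m)
}

#' Subsample aligned reads for the deep-sequencing arm
#'
#' Draws `k` aligned raw reads uniformly without replacement (a deep-
#' sequencing comparison arm typically uses a few hundred plasma or a few
#' thousand leucocyte reads), for calling with the deep-sequencing
#' error-rate constant.
#'
#' @param aln Aligned reads ([align_payloads()]).
#' @param k Number of reads to keep (`k = 0` gives an empty set; `k` larger
#'   than available is an error).
#' @param seed Optional seed for reproducible subsampling.
#' @return The subsampled rows of `aln`.
#' @export
subsample_aligned <- function(aln, k, seed = NULL) {
  idx <- which(aln$status == "aligned")
  if (k > length(idx)) stop("k exceeds the ", length(idx),
                            " aligned reads available")
  pick <- if (is.null(seed)) sample(idx, k) else
    withr::with_seed(seed, sample(idx, k))
  aln[sort(pick), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
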