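# Independent oracles used to compute expected values.

# Upper-tail Poisson probability P(X >= n) by direct summation of the pmf in
# log space, terms accumulated smallest-first. Independent of stats::ppois.
poisson_tail_oracle <- function(lambda, n) {
  if (n == 0) return(1)
  if (lambda == 0) return(0)
  kmax <- max(n, ceiling(lambda + 40 * sqrt(lambda) + 60))
  k <- n:kmax
  logterms <- k * log(lambda) - lambda - lgamma(k + 1)
  sum(sort(exp(logterms)))
}

# Expected number of distinct barcodes when n are drawn uniformly with
# replacement from a space of size S (birthday-collision closed form), with
# an approximate sd of the duplicate count for tolerance setting.
expected_distinct <- function(n, S) {
  S * (1 - (1 - 1 / S)^n)
}

# brute-force merge-target oracle: all 12-mers obtainable from an 11-mer by
# inserting one base anywhere, intersected with the canonical set, resolved
# by the most-reads-then-lexicographic rule
merge_target_oracle <- function(tag11, canon, reads_of) {
  cands <- character(0)
  for (i in 0:nchar(tag11)) {
    for (b in c("A", "C", "G", "T")) {
      cands <- c(cands, paste0(substr(tag11, 1, i), b,
                               substr(tag11, i + 1, nchar(tag11))))
    }
  }
  cands <- unique(intersect(cands, canon))
  if (length(cands) == 0) return(NA_character_)
  nr <- reads_of[cands]
  cands <- cands[nr == max(nr)]
  sort(cands)[1]
}

# reads constructed exactly as the library structure prescribes
make_reads <- function(tags, region, index5 = "ACGTA", target = NULL) {
  target <- target %||% region$target_seq
  tibble::tibble(
    read_id = sprintf("t%04d", seq_along(tags)),
    sequence = paste0(index5, tags, region$spacer, target)
  )
}

random_tags <- function(n, len = 12, seed = 1) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
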