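fam_of <- function(tags, reads_each = rep(1L, length(tags)), ...) {
  tg <- tibble::tibble(
    read_id = sprintf("r%05d", seq_len(sum(reads_each))),
    tag = rep(tags, times = reads_each)
  )
  tag_families(tg, ...)
}

test_that("single-indel 11/13-bp tags merge into their 12-bp family", {
  canonical <- "TGCATGATTACG"
  fam <- fam_of(c(rep(canonical, 5), "TGCATGATACG", "TGCATGGATTACG"))
  expect_equal(nrow(fam), 1)
  expect_equal(fam$canonical_tag, canonical)
  expect_equal(fam$n_reads, 7L)
  expect_setequal(fam$merged_from[[1]], c("TGCATGATACG", "TGCATGGATTACG"))
})

test_that("tags shorter than 9 bp are discarded, 9-11 and >=14 retained", {
  fam <- fam_of(c("ACGTACGT",                 # 8 bp, dropped
                  "ACGTACGTA",                # 9 bp
                  "ACGTACGTACGTAC",           # 14 bp
                  "TGCATGATTACG"))            # 12 bp
  expect_equal(sort(fam$tag_len), c(9L, 12L, 14L))
  expect_setequal(fam$length_class, c("9-11", "12", ">=14"))
})

test_that("ambiguous merges resolve by reads then lexicographic order, matching brute force", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      canon <- random_tags(6, len = 12, seed = 100 + rep)
      # derive an 11-mer from a random canonical by single deletion
      src <- sample(canon, 1)
      cut <- sample(12, 1)
      tag11 <- paste0(substr(src, 1, cut - 1), substr(src, cut + 1, 12))
      reads_each <- sample(1:5, 7, replace = TRUE)
      fam <- fam_of(c(canon, tag11), reads_each = reads_each)
      reads_of <- setNames(reads_each[1:6], canon)
      expected <- merge_target_oracle(tag11, canon, reads_of)
      merged_into <- fam$canonical_tag[vapply(fam$merged_from,
                                              function(m) tag11 %in% m,
                                              logical(1))]
      if (is.na(expected)) {
        expect_length(merged_into, 0)
      } else {
        expect_equal(merged_into, expected)
      }
    }
  })
})

test_that("an explicit tie resolves to the lexicographically smaller parent", {
  # deleting the first base of both parents yields the same 11-mer
  p1 <- "AACGTACGTACG"
  p2 <- "CACGTACGTACG"
  tag11 <- "ACGTACGTACG"
  fam <- fam_of(c(p1, p2, tag11), reads_each = c(3L, 3L, 1L))
  expect_equal(fam$n_reads[fam$canonical_tag == p1], 4L)
  expect_equal(fam$n_reads[fam$canonical_tag == p2], 3L)
})

test_that("12-bp tags never merge with each other", {
  a <- "AAAAAAAAAAAA"
  b <- "AAAAAAAAAAAT"
  fam <- fam_of(c(a, b), reads_each = c(10L, 1L))
  expect_equal(nrow(fam), 2)
})

test_that("histogram bins are 2-read with correct proportions", {
  fam <- fam_of(random_tags(4, seed = 42), reads_each = c(1L, 2L, 3L, 4L))
  h <- tag_histogram(fam)
  expect_equal(h$n_total, c(2L, 2L))
  expect_equal(h$reads_lo, c(1L, 3L))
  expect_equal(h$reads_hi, c(2L, 4L))
  expect_equal(h$prop_raw, c(1, 1))
  expect_true(sum(h$n_total) == nrow(fam))

  # constructed mix: one bin with 3 tags of which 2 are 12 bp
  mix <- fam_of(c(random_tags(2, seed = 43), "ACGTACGTACG"))
  hm <- tag_histogram(mix)
  expect_equal(hm$n_total, 3L)
  expect_equal(hm$n_correct, 2L)
  expect_equal(hm$prop_raw, 2 / 3)
})

test_that("smoothing is a centered window honouring edges and empty bins", {
  mk_hist <- function(prop, n_total = rep(1L, length(prop))) {
    tibble::tibble(
      bin = seq_along(prop), reads_lo = 2L * seq_along(prop) - 1L,
      reads_hi = 2L * seq_along(prop),
      n_total = n_total,
      n_correct = as.integer(round(prop * n_total)),
      prop_raw = ifelse(n_total > 0, n_correct / n_total, NA_real_)
    )
  }
  # constant proportion -> unchanged everywhere (both estimators)
  hc <- mk_hist(rep(0.7, 30), n_total = rep(10L, 30))
  expect_equal(smooth_proportions(hc)$prop_smooth, rep(0.7, 30))
  expect_equal(smooth_proportions(hc, method = "mean")$prop_smooth,
               rep(0.7, 30))

  # step 0 -> 1 at bin 50 under equal occupancy: window 45..55 holds six 1s
  hs <- mk_hist(c(rep(0, 49), rep(1, 51)))
  sm <- smooth_proportions(hs)
  expect_equal(sm$prop_smooth[50], 6 / 11)
  expect_equal(smooth_proportions(hs, method = "mean")$prop_smooth[50],
               6 / 11)

  # single nonempty bin -> its own raw proportion, empty bins excluded
  h1 <- mk_hist(c(NA, NA, 0.4, NA, NA), n_total = c(0L, 0L, 5L, 0L, 0L))
  h1$n_correct[is.na(h1$prop_raw)] <- 0L
  expect_equal(smooth_proportions(h1)$prop_smooth, rep(0.4, 5))
})

test_that("the threshold is the lower bound of the first qualifying bin", {
  mk <- function(sm) {
    tibble::tibble(bin = seq_along(sm), reads_lo = 2L * seq_along(sm) - 1L,
                   reads_hi = 2L * seq_along(sm),
                   n_total = 1L, n_correct = 0L, prop_raw = sm,
                   prop_smooth = sm)
  }
  h <- mk(c(rep(0.2, 20), rep(0.95, 20)))
  expect_equal(find_threshold(h), 41L)
  expect_equal(find_threshold(mk(rep(0.95, 10))), 1L)
  expect_error(find_threshold(mk(rep(0.5, 10))), "deeper")
})

test_that("removal at M conserves families and respects the boundary", {
  fam <- fam_of(random_tags(6, seed = 44),
                reads_each = c(1L, 2L, 10L, 11L, 40L, 80L))
  all_in <- threshold_families(fam, 1L)
  expect_true(all(all_in$accepted))
  at11 <- threshold_families(fam, 11L)
  expect_equal(sum(at11$accepted), 3L)
  expect_false(at11$accepted[at11$n_reads == 10L])
  expect_true(at11$accepted[at11$n_reads == 11L])
  expect_equal(sum(at11$accepted) + sum(!at11$accepted), nrow(fam))
})

test_that("the removed-error-free bound counts 12-bp families in [M, 2M)", {
  none <- fam_of(random_tags(3, seed = 45), reads_each = rep(50L, 3))
  expect_equal(estimate_removed_error_free(none, 10L)$bound, 0L)

  seven <- fam_of(random_tags(9, seed = 46),
                  reads_each = c(rep(12L, 7), 9L, 25L))
  est <- estimate_removed_error_free(seven, 10L)
  expect_equal(est$bound, 7L)
  expect_equal(est$fraction_of_accepted, 7 / 8)
})

test_that("BDHV flagging spots disallowed bases and estimates x3", {
  clean <- "GGAAGGAAGGAAGGA"   # B!=A, D!=C, H!=G, V!=T satisfied
  expect_false(bdhv_flagged(clean))
  dirty <- clean
  substr(dirty, 1, 1) <- "A"   # A at a B position
  expect_true(bdhv_flagged(dirty))

  fam <- fam_of(c(clean, dirty))
  expect_equal(estimate_bdhv_errors(fam)$estimated_total, 3L)
  fam_clean <- fam_of(clean)
  expect_equal(estimate_bdhv_errors(fam_clean)$estimated_total, 0L)
})

test_that("uniform single substitutions are flagged one third of the time", {
  n <- 30000
  regions <- example_regions()
  mols <- draw_molecules(
    sim_config(n, "KRAS_like_synthetic", barcode_scheme = "BDHV15",
               seed = 47), regions)
  tags <- mols$barcode
  withr::with_seed(48, {
    pos <- sample.int(15L, n, replace = TRUE)
    cur <- substr(tags, pos, pos)
    alt <- vapply(cur, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                          1), character(1), USE.NAMES = FALSE)
  })
  mutated <- tags
  substr(mutated, pos, pos) <- alt
  flagged <- sum(bdhv_flagged(mutated))
  ratio <- n / flagged
  p <- 1 / 3
  sd_ratio <- sqrt(p * (1 - p) / n) / p^2   # delta method on n/flagged
  expect_lt(abs(ratio - 3), 3 * sd_ratio)
})

test_that("thresholding at scale keeps correct-length, true-barcode families", {
  regions <- example_regions()
  cfg <- sim_config(400, "KRAS_like_synthetic", platform = "ion",
                    per_base_error_rate = 0.005,
                    reads_per_tag = list(model = "lognormal",
                                         meanlog = log(60), sdlog = 0.6),
                    seed = 49)
  sim <- simulate_library(cfg, regions)
  tg <- extract_tags(sim$reads, regions$spacer)
  fam <- tag_families(tg)
  M <- find_threshold(tag_histogram(fam))
  fam <- threshold_families(fam, M)
  acc <- fam[fam$accepted, ]
  rem <- fam[!fam$accepted, ]
  expect_gt(M, 1L)
  # precision improves over the unthresholded pool
  truth <- sim$molecules$barcode
  expect_gt(mean(acc$canonical_tag %in% truth),
            mean(fam$canonical_tag %in% truth))
  expect_gt(mean(acc$canonical_tag %in% truth), 0.99)
  # recall: nearly all true molecules kept
  expect_gt(mean(truth %in% acc$canonical_tag), 0.98)
  expect_equal(nrow(acc) + nrow(rem), nrow(fam))
})
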