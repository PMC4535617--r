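regions <- example_regions()
kras <- regions[1, ]

# fabricate a consensus-style pileup for one region: per-position nonref
# counts on top of uniform coverage m
fab_pileup <- function(m, nonref = integer(0), nonref_pos = integer(0),
                       region = kras) {
  refc <- strsplit(region$ref_seq, "")[[1]]
  sp <- region$spacer_len
  df <- tibble::tibble(
    target_id = region$target_id,
    pos = seq_along(refc),
    target_pos = seq_along(refc) - sp,
    ref = refc, A = 0L, C = 0L, G = 0L, T = 0L, del = 0L,
    coverage = as.integer(m)
  )
  for (b in c("A", "C", "G", "T")) df[[b]][df$ref == b] <- as.integer(m)
  if (length(nonref_pos) > 0) {
    for (i in seq_along(nonref_pos)) {
      p <- which(df$target_pos == nonref_pos[i])
      alt <- setdiff(c("A", "C", "G", "T"), df$ref[p])[1]
      df[[alt]][p] <- df[[alt]][p] + as.integer(nonref[i])
      df[[df$ref[p]]][p] <- df[[df$ref[p]]][p] - as.integer(nonref[i])
    }
  }
  df
}

test_that("error rate is nonref over total with exact binomial CI", {
  # ~1e6 base calls: coverage chosen so that 10 nonref give 1e-5
  m <- ceiling(1e6 / 73)
  pu <- fab_pileup(m, nonref = 10L, nonref_pos = 20L)
  er <- error_rate(pu, regions)
  expect_equal(er$n_nonref, 10L)
  expect_equal(er$n_total, m * 73L)
  expect_equal(er$rate, 10 / (m * 73))
  ci <- stats::binom.test(10L, m * 73L)$conf.int
  expect_equal(c(er$conf_low, er$conf_high), as.numeric(ci))

  # all-reference pileup: rate 0, CI from the exact binomial oracle
  pu0 <- fab_pileup(100)
  er0 <- error_rate(pu0, regions)
  expect_equal(er0$rate, 0)
  ci0 <- stats::binom.test(0L, 7300L)$conf.int
  expect_equal(c(er0$conf_low, er0$conf_high), as.numeric(ci0))
})

test_that("excluded positions contribute to neither error-rate count", {
  reg <- target_regions("x", kras$spacer, kras$target_seq,
                        excluded_positions = list(20L))
  pu <- fab_pileup(1000, nonref = 500L, nonref_pos = 20L, region = reg)
  er <- error_rate(pu, reg)
  expect_equal(er$n_nonref, 0L)
  expect_equal(er$n_total, 1000L * 72L)
})

test_that("poisson_p matches the direct-summation oracle to 1e-12 relative", {
  for (lambda in c(1e-6, 1e-4, 1e-2, 0.73, 1, 7.3, 73, 1e3)) {
    for (n in c(0:10, 20, 35, 50)) {
      p_impl <- poisson_p(l = lambda, m = 1, ER = 1, n = n) # lambda = l
      p_orac <- poisson_tail_oracle(lambda, n)
      if (p_orac > 0) {
        expect_lt(abs(p_impl - p_orac) / p_orac, 1e-12)
      } else {
        expect_equal(p_impl, 0)
      }
    }
  }
})

test_that("poisson_p handles the degenerate and documented cases", {
  expect_equal(poisson_p(73, 1000, 1e-5, 0), 1)
  expect_equal(poisson_p(73, 1000, 0, 5), 0)
  # lambda = 7.3e-4: two or more errors are vanishingly unlikely
  expect_equal(poisson_p(73, 1, 1e-5, 2),
               poisson_tail_oracle(7.3e-4, 2), tolerance = 1e-12)
  expect_lt(abs(poisson_p(73, 1, 1e-5, 2) - 2.66e-7) / 2.66e-7, 2e-3)
  # lambda = 0.73 (l = 73, m = 1000, ER = 1e-5)
  expect_equal(poisson_p(73, 1000, 1e-5, 2),
               poisson_tail_oracle(0.73, 2), tolerance = 1e-12)
  expect_error(poisson_p(-1, 1, 1e-5, 1))
  expect_error(poisson_p(73, 1, 1e-5, -1))
})

test_that("poisson_p is monotone in n and in lambda", {
  for (lambda in c(0, 1e-3, 0.5, 5, 100)) {
    p <- vapply(0:30, function(n) poisson_p(lambda, 1, 1, n), numeric(1))
    expect_true(all(diff(p) <= 0))
  }
  for (n in c(1, 3, 10)) {
    p <- vapply(c(1e-4, 1e-2, 1, 10, 100), function(l)
      poisson_p(l, 1, 1, n), numeric(1))
    expect_true(all(diff(p) >= 0))
  }
})

test_that("region calls follow the P <= alpha criterion over the whole region", {
  pu0 <- fab_pileup(2000)
  calls0 <- call_regions(pu0, regions, ER = 1e-5)
  k0 <- calls0[calls0$target_id == kras$target_id, ]
  expect_equal(k0$n, 0L)
  expect_equal(k0$p_value, 1)
  expect_false(k0$variant_positive)

  # 1% mutant fraction at m = 2000: n = 20 >> lambda = 1.46
  pu <- fab_pileup(2000, nonref = 20L, nonref_pos = 35L)
  calls <- call_regions(pu, regions, ER = 1e-5)
  k <- calls[calls$target_id == kras$target_id, ]
  expect_equal(k$n, 20L)
  expect_equal(k$lambda, 73 * 2000 * 1e-5)
  expect_equal(k$p_value, poisson_tail_oracle(1.46, 20), tolerance = 1e-10)
  expect_true(k$variant_positive)
  expect_equal(k$clustering, "clustered")
})

test_that("positional patterns classify as scattered, clustered or indeterminate", {
  expect_equal(classify_changes(rep(1L, 8)), "scattered")
  expect_equal(classify_changes(c(9L)), "clustered")
  expect_equal(classify_changes(c(1L)), "indeterminate")
  expect_equal(classify_changes(integer(0)), "indeterminate")
  # half the changes at the modal position qualifies
  expect_equal(classify_changes(c(3L, 1L, 1L, 1L)), "clustered")
  expect_equal(classify_changes(c(2L, 1L, 1L, 1L)), "scattered")
})

test_that("mutant fraction quantitates molecules as a percentage", {
  pu <- fab_pileup(1000, nonref = 5L, nonref_pos = 35L)
  alt <- setdiff(c("A", "C", "G", "T"),
                 substr(kras$target_seq, 35, 35))[1]
  mf <- mutant_fraction(pu, kras$target_id, 35L, alt)
  expect_equal(mf$percent, 0.5)
  expect_equal(mf$n_mutant, 5L)

  mf0 <- mutant_fraction(pu, kras$target_id, 36L,
                         setdiff(c("A", "C", "G", "T"),
                                 substr(kras$target_seq, 36, 36))[1])
  expect_equal(mf0$percent, 0)
  # uncovered position -> missing
  mfna <- mutant_fraction(pu[pu$target_pos != 35L, ], kras$target_id, 35L,
                          alt)
  expect_true(is.na(mfna$percent))
})

test_that("type-I error of the Poisson criterion stays near alpha", {
  # 1000 mutation-free consensus-scale datasets at the matching error rate
  ER <- 1e-5
  m <- 1500
  withr::with_seed(52, {
    # per-position independent consensus errors, summed over the region
    n_err <- vapply(1:1000, function(i)
      sum(stats::rbinom(73, m, ER)), integer(1))
  })
  p <- vapply(n_err, function(n) poisson_p(73, m, ER, n), numeric(1))
  fp <- mean(p <= 1e-3)
  # binomial tolerance around the nominal 1e-3
  expect_lte(fp, 1e-3 + 3 * sqrt(1e-3 * 0.999 / 1000))
})

test_that("subsampling aligned reads is seeded and bounded", {
  aln <- tibble::tibble(read_id = sprintf("r%03d", 1:50),
                        status = c(rep("aligned", 40), rep("no_spacer", 10)))
  s1 <- subsample_aligned(aln, 10, seed = 53)
  s2 <- subsample_aligned(aln, 10, seed = 53)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 10)
  expect_true(all(s1$status == "aligned"))
  expect_equal(nrow(subsample_aligned(aln, 0)), 0)
  expect_error(subsample_aligned(aln, 41), "exceeds")
})

test_that("deep sequencing inflates false positives that consensus removes", {
  # substitution-dominant platform, clean BDHV library: raw reads carry the
  # full per-read error load, consensus reads carry almost none
  cfg <- sim_config(100, "KRAS_like_synthetic", platform = "illumina",
                    per_base_error_rate = 0.005,
                    barcode_scheme = "BDHV15",
                    reads_per_tag = list(model = "constant", k = 15),
                    seed = 54)
  sim <- simulate_library(cfg, regions)
  run <- run_noir(sim$reads, regions, scheme = "BDHV15")
  noir_calls <- run$calls[run$calls$target_id == kras$target_id, ]
  expect_false(noir_calls$variant_positive)

  deep_pu <- pileup_reads(subsample_aligned(run$aln, 500, seed = 55),
                          regions)
  deep_calls <- call_regions(deep_pu, regions, ER = 5e-4)
  dk <- deep_calls[deep_calls$target_id == kras$target_id, ]
  expect_true(dk$variant_positive)
  expect_gt(sum(deep_calls$variant_positive),
            sum(run$calls$variant_positive))
})
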