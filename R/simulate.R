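# Synthetic barcoded amplicon libraries with ground truth.
#
# Model: each input molecule receives one barcode drawn from the scheme's
# space (collisions possible, as in reality), is amplified unevenly (k reads
# per molecule from the reads-per-tag model), and every emitted read is then
# corrupted by independent per-base sequencing errors partitioned into
# indels/substitutions according to the platform profile. Erroneous barcode
# tags arise implicitly from read errors inside the barcode region; there is
# no separate tag-error channel. An optional amplification-lineage channel
# adds substitutions shared by all reads descending from an erring PCR
# lineage (off by default).

draw_barcode_strings <- function(n, scheme) {
  if (n == 0L) return(character(0))
  if (scheme == "N12") {
    m <- matrix(sample(BASES, 12L * n, replace = TRUE), nrow = n)
  } else {
    len <- 15L
    pat <- bdhv_cycle(len)
    m <- vapply(seq_len(len), function(j) {
      sample(setdiff(BASES, BDHV_DISALLOWED[[pat[j]]]), n, replace = TRUE)
    }, character(n))
    if (n == 1L) m <- matrix(m, nrow = 1L)
  }
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

draw_molecules_impl <- function(cfg, regions) {
  region <- regions[regions$target_id == cfg$target_id, ]
  if (nrow(region) != 1L) stop("unknown target_id: ", cfg$target_id)
  n <- cfg$n_molecules
  n_mut <- as.integer(round(cfg$mutant_fraction * n))
  hap_ref <- region$target_seq
  hap_mut <- hap_ref
  if (n_mut > 0L) {
    if (cfg$mut_pos < 1L || cfg$mut_pos > region$length_l) {
      stop("mutation position outside target region")
    }
    if (substr(hap_ref, cfg$mut_pos, cfg$mut_pos) == cfg$mut_alt) {
      stop("mut_alt equals the reference base at mut_pos")
    }
    substr(hap_mut, cfg$mut_pos, cfg$mut_pos) <- cfg$mut_alt
  }
  is_mut <- logical(n)
  if (n_mut > 0L) is_mut[sample.int(n, n_mut)] <- TRUE
  tibble(
    molecule_id = sprintf("m%06d", seq_len(n)),
    barcode = draw_barcode_strings(n, cfg$barcode_scheme),
    is_mutant = is_mut,
    haplotype = ifelse(is_mut, hap_mut, hap_ref)
  )
}

#' Draw the input molecules of a simulated library
#'
#' Assigns each molecule a barcode sampled with replacement from the scheme's
#' space (so barcode collisions can occur, exactly as with real random tags)
#' and a haplotype: exactly `round(mutant_fraction * n_molecules)` molecules
#' carry the configured mutation.
#'
#' @param cfg A [sim_config()].
#' @param regions A region tibble ([target_regions()]); defaults to
#'   [example_regions()].
#' @return A tibble with one row per molecule: `molecule_id`, `barcode`,
#'   `is_mutant`, `haplotype`.
#' @export
draw_molecules <- function(cfg, regions = example_regions()) {
  withr::with_seed(cfg$seed, draw_molecules_impl(cfg, regions))
}

# Corrupt sequences with independent per-base errors. Single-base events:
# substitutions uniform over the three alternatives, insertions/deletions
# equiprobable within the indel share, positions uniform. Event positions are
# reported in the coordinates of the uncorrupted sequence.
inject_errors <- function(seqs, rate, indel_fraction) {
  nch <- nchar(seqs)
  n_err <- rbinom(length(seqs), nch, rate)
  total <- sum(n_err)
  ev_idx <- integer(total); ev_pos <- integer(total)
  ev_type <- character(total); ev_ref <- character(total)
  ev_alt <- character(total)
  if (total > 0L) {
    out <- seqs
    at <- 0L
    for (i in which(n_err > 0L)) {
      k <- n_err[i]
      pos <- sort(sample.int(nch[i], k), decreasing = TRUE)
      u <- runif(k)
      type <- ifelse(u < indel_fraction,
                     ifelse(runif(k) < 0.5, "ins", "del"), "sub")
      s <- out[i]
      for (j in seq_len(k)) {
        p <- pos[j]
        refb <- substr(s, p, p)
        if (type[j] == "sub") {
          altb <- sample(BASES[BASES != refb], 1L)
          substr(s, p, p) <- altb
        } else if (type[j] == "del") {
          altb <- ""
          s <- paste0(substr(s, 1L, p - 1L), substr(s, p + 1L, nchar(s)))
        } else {
          altb <- sample(BASES, 1L)
          s <- paste0(substr(s, 1L, p - 1L), altb,
                      substr(s, p, nchar(s)))
        }
        at <- at + 1L
        ev_idx[at] <- i; ev_pos[at] <- p; ev_type[at] <- type[j]
        ev_ref[at] <- refb; ev_alt[at] <- altb
      }
      out[i] <- s
    }
    seqs <- out
  }
  list(
    seqs = seqs,
    events = tibble(seq_index = ev_idx, pos = ev_pos, type = ev_type,
                    ref = ev_ref, alt = ev_alt)
  )
}

#' Simulate a barcoded amplicon sequencing library
#'
#' Generates single-end reads with the 5' structure
#' `[5-bp index][barcode tag][spacer][target]`, together with a ground-truth
#' table linking every read to its source molecule and a log of every
#' injected error event. The same configuration (including its seed) always
#' produces byte-identical output.
#'
#' @inheritParams draw_molecules
#' @return An object of class `noir_sim`: a list with
#'   \describe{
#'     \item{reads}{tibble `read_id`, `sequence`, `quality` (placeholder
#'       Q40), `molecule_id`.}
#'     \item{molecules}{truth tibble: `molecule_id`, `barcode`, `is_mutant`,
#'       `reads` (number emitted).}
#'     \item{events}{per-read error events: `read_id`, `zone`
#'       (index/tag/spacer/target), `pos` (1-based in the uncorrupted read),
#'       `type` (sub/ins/del/pcr_sub), `ref`, `alt`.}
#'     \item{cfg, region}{the configuration and the region row used.}
#'   }
#' @export
#' @examples
#' sim <- simulate_library(sim_config(20, "KRAS_like_synthetic", seed = 7))
#' sim$molecules
simulate_library <- function(cfg, regions = example_regions()) {
  region <- regions[regions$target_id == cfg$target_id, ]
  if (nrow(region) != 1L) stop("unknown target_id: ", cfg$target_id)
  withr::with_seed(cfg$seed, {
    mols <- draw_molecules_impl(cfg, regions)
    n <- nrow(mols)
    if (n == 0L) {
      return(structure(
        list(
          reads = tibble(read_id = character(), sequence = character(),
                         quality = character(), molecule_id = character()),
          molecules = tibble(molecule_id = character(), barcode = character(),
                             is_mutant = logical(), reads = integer()),
          events = tibble(read_id = character(), zone = character(),
                          pos = integer(), type = character(),
                          ref = character(), alt = character()),
          cfg = cfg, region = region
        ),
        class = "noir_sim"
      ))
    }
    rpt <- cfg$reads_per_tag
    k <- switch(rpt$model,
      constant = rep.int(as.integer(rpt$k), n),
      lognormal = pmax(1L, as.integer(round(
        rlnorm(n, meanlog = rpt$meanlog, sdlog = rpt$sdlog))))
    )
    template <- paste0(cfg$index5, mols$barcode, region$spacer, mols$haplotype)
    mol_of_read <- rep.int(seq_len(n), k)
    read_seqs <- template[mol_of_read]
    n_reads <- length(read_seqs)
    read_ids <- sprintf("r%07d", seq_len(n_reads))

    pcr_events <- NULL
    if (cfg$pcr_error_rate > 0) {
      # lineage errors: each occurs at a uniform amplification cycle c and is
      # inherited by a given read with probability 2^-c
      read_ranges <- c(0L, cumsum(k))
      body_len <- nchar(template) - 5L  # errors can hit tag/spacer/target
      n_pcr <- rpois(n, cfg$pcr_error_rate * body_len * cfg$pcr_cycles)
      acc <- vector("list", sum(n_pcr > 0L)); ai <- 0L
      for (i in which(n_pcr > 0L)) {
        idx <- (read_ranges[i] + 1L):read_ranges[i + 1L]
        for (e in seq_len(n_pcr[i])) {
          cyc <- sample.int(cfg$pcr_cycles, 1L)
          pos <- 5L + sample.int(body_len[i], 1L)
          hit <- idx[runif(length(idx)) < 2^(-cyc)]
          if (length(hit) == 0L) next
          refb <- substr(template[i], pos, pos)
          altb <- sample(BASES[BASES != refb], 1L)
          tmp <- read_seqs[hit]
          substr(tmp, pos, pos) <- altb
          read_seqs[hit] <- tmp
          ai <- ai + 1L
          acc[[ai]] <- tibble(seq_index = hit, pos = pos, type = "pcr_sub",
                              ref = refb, alt = altb)
        }
      }
      if (ai > 0L) pcr_events <- dplyr::bind_rows(acc[seq_len(ai)])
    }

    inj <- inject_errors(read_seqs, cfg$per_base_error_rate,
                         cfg$indel_fraction)
    events <- dplyr::bind_rows(pcr_events, inj$events)
    bl <- nchar(mols$barcode[1L])
    sp <- region$spacer_len
    tag_end <- 5L + bl
    spacer_end <- tag_end + sp
    events <- events |>
      dplyr::mutate(
        read_id = read_ids[.data$seq_index],
        zone = dplyr::case_when(
          .data$pos <= 5L ~ "index",
          .data$pos <= tag_end ~ "tag",
          .data$pos <= spacer_end ~ "spacer",
          TRUE ~ "target"
        )
      ) |>
      dplyr::select("read_id", "zone", "pos", "type", "ref", "alt")

    structure(
      list(
        reads = tibble(
          read_id = read_ids,
          sequence = inj$seqs,
          quality = strrep("I", nchar(inj$seqs)),
          molecule_id = mols$molecule_id[mol_of_read]
        ),
        molecules = tibble(
          molecule_id = mols$molecule_id,
          barcode = mols$barcode,
          is_mutant = mols$is_mutant,
          reads = k
        ),
        events = events,
        cfg = cfg,
        region = region
      ),
      class = "noir_sim"
    )
  })
}

#' @export
print.noir_sim <- function(x, ...) {
  cat("<noir_sim>", nrow(x$molecules), "molecules,",
      nrow(x$reads), "reads,", nrow(x$events), "error events\n")
  cat("  target:", x$cfg$target_id, " platform:", x$cfg$platform,
      " scheme:", x$cfg$barcode_scheme, "\n")
  invisible(x)
}

#' Write / read a simulation truth table
#'
#' The truth table is a TSV with one row per molecule
#' (`molecule_id`, `barcode`, `is_mutant`, `reads`); the round trip is
#' lossless.
#'
#' @param truth A `noir_sim` object or its `molecules` tibble.
#' @param path File path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` returns
#'   the truth tibble.
#' @export
write_truth <- function(truth, path) {
  if (inherits(truth, "noir_sim")) truth <- truth$molecules
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    molecule_id = readr::col_character(),
    barcode = readr::col_character(),
    is_mutant = readr::col_logical(),
    reads = readr::col_integer()
  ))
}
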