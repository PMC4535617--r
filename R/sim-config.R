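#' Simulation configuration
#'
#' Describes one synthetic barcoded amplicon library: how many input
#' molecules, which target region they come from, what fraction carry a
#' point mutation, how reads-per-tag are distributed (the amplification
#' unevenness), and the sequencing-error profile of the platform.
#'
#' The two platform presets fix the error-type mix reported for the
#' respective chemistries: Ion Torrent errors are >90% insertions/deletions,
#' Illumina errors are substitution-dominant. `indel_fraction` may be set
#' explicitly to override the preset.
#'
#' @param n_molecules Number of input DNA molecules.
#' @param target_id Region name; must match a row of the region tibble passed
#'   to [simulate_library()].
#' @param mutant_fraction Fraction of molecules carrying the mutation, in
#'   \[0, 1\]. The mutant count is `round(mutant_fraction * n_molecules)`.
#' @param mut_pos 1-based position of the mutation within the target
#'   sequence (required when `mutant_fraction > 0`).
#' @param mut_alt Alternative base at `mut_pos` (must differ from reference).
#' @param reads_per_tag Reads-per-tag model: either
#'   `list(model = "lognormal", meanlog =, sdlog =)` (default
#'   `meanlog = log(60)`, `sdlog = 0.6`, truncated to >= 1: a heavy-tailed
#'   shape with a right peak at tens of reads) or
#'   `list(model = "constant", k =)`.
#' @param platform `"ion"` or `"illumina"`.
#' @param per_base_error_rate Per-base probability of a sequencing error
#'   event (default 0.005).
#' @param indel_fraction Fraction of error events that are single-base
#'   insertions or deletions (insertion/deletion equiprobable); remainder are
#'   substitutions uniform over the three alternatives. Defaults: 0.92 for
#'   `"ion"` (indels occupy over 90% of errors on that chemistry) and 0.08
#'   for `"illumina"` (substitution-dominant).
#' @param index5 5-base sample index prepended to every read.
#' @param barcode_scheme `"N12"` (uniform over the 4^12 12-mers) or
#'   `"BDHV15"` (15 positions, each uniform over its 3 allowed bases; the
#'   pattern `BDHVBDHVBDHVBDH` excludes one base per position, so observing
#'   the excluded base certifies a read error).
#' @param pcr_error_rate Optional pre-sequencing (amplification-lineage)
#'   substitution rate per base per cycle, shared by all reads descending
#'   from the erring lineage; `0` disables the channel (default).
#' @param pcr_cycles Number of amplification doublings used by the lineage
#'   error channel.
#' @param seed Integer seed; the same configuration always yields
#'   byte-identical output.
#'
#' @return An object of class `noir_sim_config` (a validated list).
#' @export
#' @examples
#' sim_config(n_molecules = 100, target_id = "KRAS_like_synthetic", seed = 1)
sim_config <- function(n_molecules,
                       target_id,
                       mutant_fraction = 0,
                       mut_pos = NULL,
                       mut_alt = NULL,
                       reads_per_tag = list(model = "lognormal",
                                            meanlog = log(60), sdlog = 0.6),
                       platform = c("ion", "illumina"),
                       per_base_error_rate = 0.005,
                       indel_fraction = NULL,
                       index5 = "ACGTA",
                       barcode_scheme = c("N12", "BDHV15"),
                       pcr_error_rate = 0,
                       pcr_cycles = 10L,
                       seed = 1L) {
  platform <- match.arg(platform)
  barcode_scheme <- match.arg(barcode_scheme)
  if (is.null(indel_fraction)) {
    indel_fraction <- if (platform == "ion") 0.92 else 0.08
  }
  stopifnot(
    n_molecules >= 0,
    mutant_fraction >= 0, mutant_fraction <= 1,
    per_base_error_rate >= 0, per_base_error_rate < 1,
    indel_fraction >= 0, indel_fraction <= 1,
    nchar(index5) == 5,
    pcr_error_rate >= 0, pcr_cycles >= 1
  )
  if (mutant_fraction > 0 && (is.null(mut_pos) || is.null(mut_alt))) {
    stop("mutant_fraction > 0 requires mut_pos and mut_alt")
  }
  stopifnot(reads_per_tag$model %in% c("lognormal", "constant"))
  structure(
    list(
      n_molecules = as.integer(n_molecules),
      target_id = target_id,
      mutant_fraction = mutant_fraction,
      mut_pos = if (!is.null(mut_pos)) as.integer(mut_pos),
      mut_alt = mut_alt,
      reads_per_tag = reads_per_tag,
      platform = platform,
      per_base_error_rate = per_base_error_rate,
      indel_fraction = indel_fraction,
      index5 = toupper(index5),
      barcode_scheme = barcode_scheme,
      pcr_error_rate = pcr_error_rate,
      pcr_cycles = as.integer(pcr_cycles),
      seed = as.integer(seed)
    ),
    class = "noir_sim_config"
  )
}

#' @export
print.noir_sim_config <- function(x, ...) {
  cat("<noir_sim_config>\n")
  cat("  molecules:", x$n_molecules,
      sprintf("(%.1f%% mutant)", 100 * x$mutant_fraction), "\n")
  cat("  target:", x$target_id, " scheme:", x$barcode_scheme, "\n")
  cat("  platform:", x$platform,
      sprintf("(error %.4g/base, indel fraction %.2f)",
              x$per_base_error_rate, x$indel_fraction), "\n")
  rpt <- x$reads_per_tag
  cat("  reads/tag:", rpt$model,
      if (rpt$model == "lognormal")
        sprintf("(meanlog %.3f, sdlog %.2f)", rpt$meanlog, rpt$sdlog)
      else sprintf("(k = %d)", rpt$k), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
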