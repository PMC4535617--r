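---
title: "Counting molecules and calling variants from barcode-tagged amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting molecules and calling variants from barcode-tagged amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noirseq)
library(dplyr)
```

## The problem

A barcode-tagged amplicon library labels every input DNA molecule with a
random tag — N12 (4¹² ≈ 1.7 × 10⁷ sequences) or the 15-bp degenerate BDHV
pattern — before amplification. All reads descending from one molecule share
its tag, so grouping reads by tag should (i) count molecules absolutely and
(ii) let a per-molecule consensus cancel read errors. The catch is that read
errors also hit the tag region: a corrupted tag looks like a new molecule.
Left untreated, these phantom molecules inflate counts severalfold and leak
raw read errors into "consensus" reads (a family of one read has no
redundancy). `noirseq` implements the tag-denoising, consensus, and
region-level Poisson calling machinery around that problem, plus a
simulator that generates libraries with known ground truth.

## Reads and tag extraction

Reads are single-end with 5′ structure
`[5-bp index][tag][spacer][target]`. Demultiplexing is exact on the 5-bp
index (anything else is `unassigned` — a counted outcome, not an error).
The tag is everything between the index and the spacer; since the tag
length is variable under indel errors, the spacer is located by the
lowest-edit-distance match of the full spacer across candidate tag lengths
(expected ± 3/+4, i.e. 9–16 for N12), ties resolved leftmost, and reads
with no match within 2 edits are rejected. The tolerance of 2 edits accepts
essentially all reads whose spacer carries at most two errors
(probability ≈ 1 at the error rates considered) while making a chance match
of a ~20-bp spacer vanishingly unlikely.

Payloads (spacer onward) longer than 70 bases are aligned semi-globally
(free end gaps on the read) to each region's spacer + target reference with
match +1, mismatch −5, gap open 2, gap extend 1 — the heavy mismatch
penalty suits short, known references where spurious mismatch alignments
are worse than clipping. Reads whose unaligned ends exceed 10% of the read,
or whose identity falls below 50%, are discarded with a reason code; the
per-stage log conserves read counts exactly. Alignments are stored as
read bases projected onto reference coordinates (deletions as `-`,
insertions tallied separately), which makes consensus building and pileups
direct. Coordinates are 1-based inclusive throughout, matching R and
Bioconductor convention.

## Tag families and the erroneous-tag threshold

Reads with identical tags form families. Tags shorter than 9 bp are
discarded. Because indel-dominant chemistry mostly shortens or lengthens a
tag by one base, an 11-bp (13-bp) tag that is a single deletion
(insertion) of an existing 12-bp tag is merged into that family; when
several 12-bp parents qualify, the one with more reads wins, ties going to
the lexicographically smaller sequence (the chance that the *wrong* parent
wins is negligible relative to the tag space). 12-bp tags never merge with
each other — no sequence-similarity clustering of same-length tags is done,
deliberately: at these tag-space densities identical-length near-neighbours
are almost surely distinct molecules.

Families are then binned by reads-per-tag into 2-read bins (bin *k* covers
2*k*−1 and 2*k* reads) and the per-bin proportion of *correct* tags is
computed — length 12 for N12; for BDHV, length 15 **and** no forbidden
base. Erroneous tags concentrate at low read counts, so the proportion
rises with the bin index; the threshold *M* is the lower read-count bound
of the first bin whose smoothed proportion reaches 90%, and families with
fewer than *M* reads are removed. The count of accepted families per
region is the molecule count *m*.

### Smoothing choice

The smoothing window is the bin and its five neighbours each side
(11 bins), truncated at the edges; empty bins contribute nothing rather
than zero. Within that window the default estimator is the **pooled
proportion** — summed correct counts over summed family counts — rather
than the unweighted mean of per-bin proportions. The two are
indistinguishable when neighbouring bins are similarly occupied, which is
the dense-histogram regime the procedure was designed for. But in sparse
histograms (small libraries, or error regimes that pile all erroneous tags
into the 1–2-read bin) the unweighted mean lets a few single-family bins at
proportion 1.0 outvote a thousand-family error bin, and the threshold then
oscillates between "remove nothing" and a sensible value depending on which
sparse bins happen to be occupied. Weighting each family equally removes
that instability without changing the dense-regime behaviour; the
unweighted mean remains available as `smooth_proportions(method = "mean")`.
A `strict` scan variant (threshold bin must be followed only by qualifying
bins) is available but off by default: the minimum qualifying bin is taken.

### What removal costs, and the BDHV estimator

Correct-length tags below *M* cannot be counted directly (multi-indel
errors restore the original length), but because the error-free
reads-per-tag distribution is unimodal with its peak above *M*, its mass
below *M* is bounded by its mass in [*M*, 2*M*):
`estimate_removed_error_free()` reports that count as an upper bound on the
error-free tags lost, and as a fraction of accepted tags (expected in the
5–10% range at deep coverage).

On substitution-dominant chemistry, tag length carries no error signal, so
the BDHV barcode replaces it: each position excludes one base
(B≠A, D≠C, H≠G, V≠T), a uniform substitution lands on the excluded base
with probability 1/3, and the total number of substitution-erroneous tags
is estimated as 3 × the flagged count. The flagged state also defines the
"correct" class for the threshold histogram, so `find_threshold()` works
identically on both schemes.

## Consensus and pileups

Each accepted family yields one consensus read. If a family exceeds 50
reads, only the 50 longest are used (ties by input order) — beyond that
depth additional reads add nothing but runtime. Per reference position, an
alternative base (a substitution or a deletion symbol) is called only when
carried by strictly more than 80% of the reads *covering that position*;
otherwise the reference base is called. The "covering reads" denominator
(rather than family size) is the deliberate reading: a read clipped before
a position carries no evidence about it. Insertions relative to the
reference are recorded but excluded from the per-position vote, and
positions covered by no kept read are absent from the consensus. Consensus
FASTQ output carries a constant quality of 57 (`Z`), reflecting
post-consensus confidence; input qualities are never used anywhere in the
pipeline. Pileups tally per-position base counts either over consensus
reads (one vote per molecule — NOIR mode) or over raw aligned reads
(deep-sequencing mode).

## Error rates and the Poisson criterion

The sequencing error rate is the number of non-reference base calls divided
by all base calls over target positions, with configured excluded positions
(known germline SNP sites, e.g. an rs1800372-like site) contributing to
neither count, and an exact binomial 95% CI attached. Deletion calls are
reported separately and excluded from the substitution error rate by
default.

Variant detection is region-level, not per-position. With *l* the target
length (bp), *m* the molecules sequenced, and ER a configured error-rate
constant, the expected number of error calls is λ = *l*·*m*·ER and the
probability of observing *n* or more is the Poisson upper tail
P = 1 − Σ_{k=0}^{n−1} λ^k e^{−λ}/k!, evaluated through a numerically
stable tail routine (accurate far below machine epsilon of 1; a direct
high-precision summation oracle in the test suite agrees to 10⁻¹² relative
over λ ∈ [10⁻⁶, 10³], n ≤ 50). A region is variant-positive when
P ≤ α = 10⁻³ — one false positive per thousand samples. ER is deliberately
a constant (10⁻⁵ for consensus reads, 5 × 10⁻⁴ for raw reads), not
re-estimated per run: the criterion is a calibrated decision rule, and
re-fitting it to each sample would absorb real mutations into the null.
Substitution calls alone enter *n* by default. No multiple-testing
correction is applied across regions, since α is framed per sample;
multi-region reports carry per-region P.

Two annotations accompany the verdict. The positional profile classifies
changes as `clustered` (the modal position carries ≥ half of ≥ 2 changes —
the signature of a real mutation), `scattered` (the signature of residual
errors), or `indeterminate`; it never overrides the Poisson verdict. And
`mutant_fraction()` converts molecule counts at a position into a
percentage — with consensus pileups this is absolute quantitation of the
mutant molecule fraction (the ctDNA level).

`subsample_aligned()` plus `call_regions(ER = 5e-4)` reproduce the
deep-sequencing comparison arm: calling on a few hundred raw reads without
barcodes. Because the raw per-read substitution rate of
substitution-dominant chemistry exceeds the deep-sequencing ER constant,
this arm generates false positives on mutation-free libraries that the
consensus arm removes — the package's tests demonstrate exactly that
contrast.

## The simulator: what it emulates and what it does not

`simulate_library()` draws `n_molecules` barcodes with replacement from the
scheme's space (collisions possible, as in reality), assigns exactly
`round(mutant_fraction × n_molecules)` molecules the configured point
mutation, draws reads-per-tag from a log-normal (default meanlog = log 60,
sdlog = 0.6, truncated to ≥ 1) — the family of the distribution is a
documented modelling choice; only its qualitative shape (a right peak at
tens-to-hundreds of reads with a long tail) is empirically grounded — and
corrupts every read with independent per-base errors: single-base events,
substitutions uniform over three alternatives, insertion/deletion
equiprobable within the indel share. Platform presets fix the indel share
at 0.92 (Ion: indels are >90% of errors) and 0.08 (Illumina:
substitution-dominant). Erroneous tags arise *only* from these read errors
— there is no separate tag-error channel — and FASTQ qualities are a
constant placeholder (Q40) because the pipeline ignores input qualities.
The same configuration and seed yields byte-identical output.

One optional second channel exists: amplification-lineage substitutions
(`pcr_error_rate`, per base per cycle over `pcr_cycles` doublings), where
an error at cycle *c* is inherited by each read with probability 2^−c.
It is off by default. It matters for one specific family of behaviours:
with read-level errors only, erroneous tags are almost all singletons
(1–2 reads), so *any* cutoff above 2 reads removes them and the difference
between the adaptive threshold and a fixed 1–2-read cutoff disappears.
Real libraries contain multi-read erroneous tags (errors propagated through
amplification), and it is in that regime that the adaptive threshold's
saturation behaviour — molecule counts plateau with sequencing depth while
a fixed cutoff keeps inflating — is distinguishable. Tests of those
behaviours therefore enable the lineage channel; everything else runs with
the default per-read-only error model.

Not emulated at all: restriction digestion, ligation-efficiency
differences between sites (the cause of recovery-rate variation between
regions in real libraries), emulsion PCR, flow-space signal artefacts, and
homopolymer-context error enrichment. Passing tests on this simulator
therefore validate the *analysis logic* under the stated error model, not
the full error structure of any particular instrument.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
statistical claims are testable with comfortable margins: threshold
behaviour and quantitation linearity at ~2,000 molecules × ~100 reads/tag
(~2 × 10⁵ reads), error-profile convergence at ≥ 10⁵ events, BDHV ×3
convergence at 1.2 × 10⁵ tags (3σ by the delta method), the false-positive
rate at 10³ mutation-free datasets, and consensus error suppression at
~10² molecules of 20 reads. Monte Carlo assertions use 3σ tolerances
under fixed seeds. Degenerate inputs are handled explicitly: an empty
molecule set yields empty (typed) tables; a histogram in which no bin
reaches 90% raises an error advising deeper sequencing; `n = 0` gives
P = 1 exactly; ER = 0 with n ≥ 1 gives P = 0; uncovered positions
propagate as missing values, never as zeros.
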