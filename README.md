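# noirseq

Barcode-tagged amplicon sequencing promises two things that ordinary deep
sequencing cannot deliver: **absolute quantitation** (each original DNA
molecule is counted exactly once) and **high-fidelity variant detection**
(read errors vanish in a per-molecule consensus). Both break down when read
errors corrupt the barcode tags themselves, creating phantom "molecules".
`noirseq` implements the full analysis for such libraries — aimed at rare
mutation detection in plasma cell-free DNA (ctDNA), where a handful of
mutant molecules must be found among thousands of normal ones:

1. **Tag extraction** — reads structured as
   `[5-bp sample index][12-bp N12 or 15-bp BDHV barcode][spacer][target]`
   are demultiplexed and their tags recovered by approximate spacer
   matching; payloads are aligned semi-globally to the target references.
2. **Erroneous-tag removal** — reads are grouped into tag families
   (single-indel 11/13-bp variants merged into their 12-bp parent), families
   are binned into 2-read bins, and the per-bin proportion of correct-length
   tags, smoothed over 11 bins, determines a data-driven threshold *M*: the
   lower bound of the first bin whose smoothed proportion reaches 90%.
   Families with fewer than *M* reads are discarded as erroneous. On
   substitution-dominant (Illumina-like) chemistry the correct-length signal
   is replaced by the **BDHV error-detecting barcode** (`BDHVBDHVBDHVBDH`:
   each position forbids one base, so the forbidden base certifies an
   error, and total erroneous tags ≈ 3 × flagged tags).
3. **Consensus (NOIR) construction** — each accepted family (one molecule)
   yields one consensus read: per reference position, an alternative base is
   called only when carried by **> 80%** of covering reads (at most the 50
   longest reads are used); output FASTQ carries Q57.
4. **Poisson variant calling** — with region length *l* (bp), molecule
   count *m*, and error-rate constant ER, the expected error count is
   λ = *l*·*m*·ER and the region is variant-positive when the upper-tail
   probability

   P = 1 − Σ<sub>k=0</sub><sup>n−1</sup> λ<sup>k</sup> e<sup>−λ</sup>/k!

   of the observed non-reference count *n* satisfies P ≤ 10⁻³
   (ER defaults: 10⁻⁵ for consensus reads, 5 × 10⁻⁴ for raw "deep
   sequencing" reads). A positional-clustering label separates true
   mutations (changes piled on one position) from scattered errors.

A built-in simulator generates whole libraries with known ground truth —
finite molecule pools, uneven amplification (log-normal reads per tag),
platform error profiles (Ion Torrent: >90% indels; Illumina:
substitution-dominant), configurable mutant fractions, and an optional
amplification-lineage error channel — so every claim above is testable.

## Worked example

Simulate a 300-molecule library in which 5% of molecules carry a point
mutation, run the whole pipeline, and read off the call:

```r
library(noirseq)

regions <- example_regions()                  # synthetic 73-bp + 63-bp targets
cfg <- sim_config(
  n_molecules = 300, target_id = "KRAS_like_synthetic",
  mutant_fraction = 0.05, mut_pos = 35, mut_alt = "T",
  reads_per_tag = list(model = "constant", k = 20),
  platform = "ion", per_base_error_rate = 0.005, seed = 5
)
sim <- simulate_library(cfg, regions)
run <- run_noir(sim$reads, regions)
run
#> <noir_run>
#>   threshold M: 9 reads
#>   accepted molecules: KRAS_like_synthetic = 300
#>   variant-positive regions: KRAS_like_synthetic
tidy(run)[1, c("target_id", "m", "n", "lambda", "p_value", "clustering")]
#> # A tibble: 1 × 6
#>   target_id               m     n lambda  p_value clustering
#>   <chr>               <dbl> <int>  <dbl>    <dbl> <chr>
#> 1 KRAS_like_synthetic   300    15  0.219 7.96e-23 clustered
mutant_fraction(run$pileup, "KRAS_like_synthetic", 35, "T", m = 300)$percent
#> [1] 5
```

Reading the output: the reads-per-tag histogram placed the erroneous-tag
threshold at *M* = 9 reads; after removal, exactly the 300 input molecules
remain (absolute quantitation). Their consensus reads carry *n* = 15
non-reference calls against an expectation of λ = 73 × 300 × 10⁻⁵ ≈ 0.22
errors, so P ≈ 8 × 10⁻²³ — decisively variant-positive — and all 15
changes sit on one position (`clustered`), quantitating the mutation at
exactly the simulated 5% mutant fraction.

`autoplot(run$histogram, M = run$M)` shows the threshold derivation;
`autoplot(run$calls)` plots P per region against the 10⁻³ criterion.
A thin command-line wrapper lives in `inst/cli/noirseq.R`
(`simulate` and `run` subcommands).

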