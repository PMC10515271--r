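# hlbscreen

Candidate screening for DNA-binding factors at the *Drosophila*
replication-dependent histone gene array.

## What it does and for whom

The *D. melanogaster* histone locus is ~100 tandem, nearly identical ~5 kb
repeat units, each carrying the five canonical histone genes (*H1*, *H2A*,
*H2B*, *H3*, *H4*), two divergent TATA-containing core promoters, a
TATA-less *H1* promoter, and CLAMP-binding GA-repeat elements in the
*H3/H4* promoter. The histone locus body (HLB) forms here, and which
DNA-binding factors target the array is largely unknown. A cheap way to
find candidates is to mine public ChIP-seq data: map a factor's reads to a
**single repeat unit** (collapsing signal from all ~100 copies), normalize
to the matched input, and ask whether a peak emerges over an array element.

`hlbscreen` is that pipeline as a tested R package, for genomicists who
want to screen candidate factors (or audit such screens) without a genome
browser in the loop:

* **collapse mapping** of FASTQ reads onto a circular 5 kb unit
  (internal k-mer seed-and-verify mapper; deterministic leftmost-best
  multimap placement; BAM import supported),
* **1 bp coverage** and **depth-scaled log2(ChIP/input)** tracks
  (bedGraph/SAM export),
* a **rule-based classifier**: a candidate is positive iff a peak emerges
  in the normalized ChIP signal with no corresponding input peak, and none
  of four false-positive rules fires —

  | rule | fires when (defaults) |
  |---|---|
  | gene-body overrepresentation | input gene-body/overall coverage ratio > 1.4 |
  | intergenic depletion | input intergenic/overall coverage ratio < 0.5 |
  | input-identical signal | scaled ChIP–input Pearson r > 0.95, both tracks peaked |
  | GA-repeat short-read pileup | peak over a GA element and read length ≤ 50 bp |

  with peak calling at `mean + 3 SD` of the smoothed ratio (minimum width
  50 bp) and per-peak element localization,
* a **synthetic-data module** that generates the tandem reference and
  seeded ChIP/input read sets with per-read ground truth under six modes
  (no enrichment, true promoter enrichment, gene-body bias, intergenic
  depletion, input-identical, GA-repeat artifact), so every rule is
  exercised against known truth,
* **screen orchestration** over a manifest of many candidates, with a
  JSON/TSV report (`tidy()`/`glance()` accessors, `autoplot()` figures).

## Worked example

Simulate a factor genuinely bound at the *H3/H4* promoter, map, and
classify:

```r
library(hlbscreen)

ann  <- histone_annotation()                       # 5 kb unit, 15 features
ref  <- build_reference(ann, n_copies = 100, flank_length = 10000, seed = 42)
idx  <- build_index(ref$unit_sequence)

cfg  <- sim_config(mode = "TRUE_PROMOTER", target_element = "H3_H4_promoter",
                   enrichment_fold = 8, seed = 7)
pair <- simulate_pair(ref, cfg)                    # chip + input read sets

chip  <- coverage(map_reads(pair$chip,  idx, ref$unit_sequence), 5000, 75)
input <- coverage(map_reads(pair$input, idx, ref$unit_sequence), 5000, 75)

call <- classify_candidate(chip, input, ann)
call
#> <candidate_call> POSITIVE | flags: none | 1 emergent peak(s) | top peak at H3_H4_promoter
tidy(call)
#> # A tibble: 1 × 8
#>   start   end width summit max_ratio mean_ratio ga_artifact elements
#>   <int> <int> <int>  <int>     <dbl>      <dbl> <lgl>       <chr>
#> 1   651   936   285    831      2.63       2.46 FALSE       H3_H4_promoter
```

The emergent peak spans positions 651–936 of the unit — the 300 bp *H3/H4*
promoter (610–910) plus the expected half-read-length smear — with a
smoothed log2(ChIP/input) maximum of 2.6 (8-fold enrichment after depth
scaling and normalization dilution), no artifact flags, and the summit
inside the promoter, so the candidate is called positive and localized to
`H3_H4_promoter`. An input-identical simulation of the same shape instead
yields zero emergent peaks and the `INPUT_IDENTICAL` flag; a 36 bp-read
simulation with 5% injected GA reads yields a negative call carrying
`GA_ARTIFACT`.

Screens over many candidates go through a manifest:

```r
m <- screen_manifest(candidate  = c("factorA", "factorA", "factorB"),
                     chip_fastq = c("a_rep1.fastq", "a_rep2.fastq", "b.fastq"),
                     input_fastq = c("a_in1.fastq", "a_in2.fastq", NA),
                     read_length = c(75L, 75L, 36L))
report <- run_screen(m, unit = "unit.fasta")
tidy(report)    # candidate / label / flags / localization table
glance(report)  # n_candidates, n_positive, n_rejected
write_screen_report(report, "screen.json")
```

## Documentation

The methods vignette (`vignettes/histone-array-screen.Rmd`) describes the
model, every rule and cutoff with its rationale, what the synthetic data
does and does not emulate, and the package's numerical conventions
(0-based half-open coordinates, circular unit, leftmost tie-breaks).
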