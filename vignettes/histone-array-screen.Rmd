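---
title: "Screening ChIP datasets at a tandemly repeated histone gene array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening ChIP datasets at a tandemly repeated histone gene array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlbscreen)
library(dplyr)
```

## The problem

The *Drosophila melanogaster* replication-dependent histone genes sit in a
single locus of roughly 100 tandemly repeated, nearly identical ~5 kb units.
Each unit carries the five canonical histone genes — *H1*, *H2A*, *H2B*,
*H3*, *H4* — two divergent TATA-containing core promoters (one shared by
*H3*/*H4*, one by *H2A*/*H2B*), a TATA-less *H1* promoter, and GA-repeat
cis elements in the *H3/H4* promoter bound by the factor CLAMP. The histone
locus body (HLB) assembles at this locus, and most of its known components do
not bind DNA directly, so finding DNA-binding factors that target the array
is a route to understanding how the locus is specified.

Public ChIP-seq archives hold datasets for hundreds of DNA-binding factors.
A cheap screen is therefore possible: align a candidate factor's ChIP reads
not to the whole genome but to a *single copy* of the repeat unit, summing
("collapsing") signal from all ~100 copies, normalize to the matched input
library, and ask whether a peak emerges over an array element. Because the
reference is one 5 kb sequence, conventional statistical peak callers (which
need a genome-wide background model) are not applicable; the decision is
rule-based instead, and the rules must guard against artifacts that mimic
peaks. `hlbscreen` implements that pipeline end to end, together with a
synthetic-data generator that reproduces — with ground truth attached — each
signal regime and each artifact regime the rules distinguish, so the whole
decision procedure is testable at desk scale without downloading anything.

## The pipeline

For each candidate (a ChIP FASTQ and, normally, a matched input FASTQ):

1. **Collapse mapping** (`build_index()`, `map_reads()`). Reads are mapped
   to the repeat unit with an internal exact-k-mer seed-and-verify mapper
   (default seed k = 16, at most 2 mismatches, both strands). The unit is
   treated as *circular*: interior copies of a tandem array produce
   junction-spanning reads that legitimately belong to the locus, so seeds
   and coverage wrap across the origin. A read from any copy reports the
   same unit coordinate, which is precisely the collapse. Multi-mapping
   reads are placed at the *leftmost best* position. That tie-break is a
   deterministic stand-in for how a single reported alignment concentrates
   repeat-derived reads, and it is what makes the GA-repeat artifact (below)
   reproducible; it is our rule, not something the upstream aligner of a
   conventional pipeline defines.
2. **Coverage** (`coverage()`): per-base (1 bp bin) counts over the unit,
   with the exact conservation invariant
   `sum(counts) == n_mapped * read_length`.
3. **Normalization** (`log2_ratio()`): both tracks are depth-scaled to a
   common total (simple total-count scaling to 1e6 — on a single 5 kb
   reference, signal-extraction scaling methods are undefined and
   unnecessary; the scaling label is recorded in the track for provenance),
   then `log2((chip + 1)/(input + 1))` per base. The pseudocount (default
   1) keeps the track finite.
4. **Classification** (`classify_candidate()`): peak calling on the
   smoothed ratio, the peak-emergence test, four false-positive rules,
   element assignment, and the final positive/negative verdict.
   Replicates are classified independently and combined conservatively
   (`classify_replicates()`: positive only if all replicates are positive;
   flags are unioned; localization is the intersection of top-peak element
   sets, falling back to the union with a disagreement diagnostic).

`run_screen()` drives the whole thing over a manifest of candidates and
produces a tabulated report (JSON/TSV) whose shape mirrors a screen
publication's candidate table; per-entry failures are recorded without
aborting other entries, and entries lacking an input are classified on ChIP
coverage alone and labelled as a no-input comparison.

## The decision rules and their quantification

The positivity criterion is **peak emergence**: a peak in the normalized
ChIP signal with no corresponding peak in the input. In the original,
visual form of this screen the criteria are qualitative; this package
quantifies them, and every cutoff is a named `classifier_config()` field
recorded in the output:

* **Peak calling** (`peak_z = 3`, `min_peak_width = 50`): the smoothed
  ratio track is thresholded at `mean + 3 SD` of its own values; maximal
  circular runs above threshold at least 50 bp wide are peaks. Thresholding
  on the track's own distribution makes the caller scale-free; a constant
  track yields no peaks. There is no multiple-testing control: the unit is
  one 5 kb locus with a handful of candidate windows, and the thresholds
  are effect-size based, matching the qualitative regime of a visual
  screen.
* **Emergence** (`input_peak_z = 2`): a called peak is kept only if the
  depth-scaled input coverage, averaged over the peak interval, does not
  exceed `mean + 2 SD` of the input track. The input has no ratio track,
  so the test applies to input coverage.
* **Gene-body overrepresentation** (`genebody_ratio_max = 1.4`): mean input
  coverage over gene bodies divided by the overall mean. Evaluated on the
  *input* because this artifact is a library/amplification or alignment
  bias that the input makes visible; the ChIP-side score is reported as a
  diagnostic only. The default is 1.4 rather than a rounder 1.5 because
  the score is computed on *coverage*: reads smear coverage about half a
  read length past each feature boundary, so even a 3-fold read-start bias
  on gene bodies dilutes to a coverage score of ~1.49 with 75 bp reads on
  the default annotation. The cutoff sits below that deterministic
  dilution while leaving unbiased inputs (score ≈ 1.0) far from it. A
  consequence we accept: a strongly intergenic-depleted input also scores
  ~1.42 here and raises both flags — the two rules describe the same input
  bias from opposite sides.
* **Intergenic underrepresentation** (`intergenic_ratio_min = 0.5`): mean
  input coverage over intergenic bases divided by the overall mean,
  flagged when below 0.5. With no intergenic bases the rule reports
  not-applicable rather than flagging.
* **Input identity** (`identity_corr_min = 0.95`): Pearson correlation of
  the depth-scaled ChIP and input vectors, flagged only when both tracks
  individually contain a called peak — two flat tracks that trivially
  correlate are not this failure mode.
* **GA-repeat short-read rule** (`ga_read_length_max = 50`, inclusive):
  any called peak overlapping a GA-repeat element in a dataset with reads
  of at most 50 bp is flagged as a multimapping artifact. Reads longer
  than the GA element anchor uniquely in flanking sequence, so the pileup
  cannot form — which is also why the rule needs no signal-strength
  component. The rule is applied to *all* called peaks, not only emergent
  ones: the pileup usually has a (smaller) input counterpart that removes
  it from the emergent set, but the artifact remains worth reporting. We
  apply it to every GA-repeat feature rather than only those in the
  *H3/H4* promoter — a superset of the motivating case.

The verdict is **positive** iff at least one emergent peak carries no GA
flag and none of the three dataset-level rules fired. A dataset can thus be
positive at one element while a GA pileup elsewhere is discounted — the
pattern seen for real factors whose genuine promoter signal coexists with a
short-read GA artifact.

## Numerical choices

* **Smoothing** (`smooth_window = 31`): a circular centered moving average
  is applied before peak calling (the raw 1 bp track is always retained).
  The window interacts geometrically with `min_peak_width`: a GA pileup of
  36 bp reads is 36 bp wide, and its above-threshold run after smoothing
  with window `w` is about `36 + w − 2⌈w·t/H⌉` where `t/H ≈ 0.22` is the
  threshold-to-peak-height ratio the track's own SD induces. At `w = 25`
  that run sits almost exactly at the 50 bp minimum width — a knife edge
  that resolves by seed — while `w = 31` leaves a small deterministic
  margin. We therefore default to 31 bp. Wider windows would blunt the
  ~300 bp promoter peaks' localization without further benefit.
* **Tie-breaks**: summit is the leftmost argmax within a peak; multimap
  placements resolve leftmost-best with the forward strand preferred on an
  exact position tie. Both are stated so results are bit-reproducible.
* **Degenerate inputs**: zero-coverage tracks refuse depth scaling with an
  explicit error; zero-variance tracks give an undefined identity
  correlation (never a flag); constant tracks call no peaks; unmapped is a
  value, not an error.

## The synthetic-data generator

`build_reference()` constructs `n_copies` (default 100, the approximate
copy number of the real locus) identical copies of a random 5 kb unit
between 10 kb random flanks. GA-repeat features are perfect (GA)~n~
dinucleotide runs; all other bases are i.i.d. uniform. `simulate_pair()`
draws read start positions from per-base weight vectors
(`position_weights()`) under six modes:

| mode | ChIP | input | emulates |
|---|---|---|---|
| `NONE` | uniform | uniform | no binding |
| `TRUE_PROMOTER` | fold 8 on the target element | uniform | genuine binding |
| `GENE_BODY_BIAS` | weight 3 on gene bodies | same | amplification/alignment bias |
| `INTERGENIC_DEPLETION` | weight 0.2 on intergenic | same | accessibility bias |
| `INPUT_IDENTICAL` | fold 8 on target | same as ChIP | shared bias, no enrichment |
| `GA_ARTIFACT` | uniform + 5% pure-GA reads | uniform | short-read multimap pileup |

Defaults (50,000 reads per role, 75 bp reads — 36 bp in the GA mode —
fold 8, bias weights 3 and 0.2, artifact fraction 5%) are the package's
fixed study conditions; read depths are typical of what a single ChIP
library contributes over a 5 kb window of a repetitive locus, and fold 8
puts the expected ratio peak (~2.5 log2 units) in the range seen for
clear positives in browser tracks. Each read carries its ground-truth
origin (copy index and unit offset, `flank`, or `ga_synthetic`), which
survives the FASTQ round trip in the read id. A fixed 2% of reads
originate in the background flanks so the mapper's rejection path is
always exercised. Reads whose unit offset spans the copy junction are
assigned to one of the first `n_copies − 1` copies, because only there is
the junction followed by another identical copy. Everything is
deterministic given the config, including its seed.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: inter-copy sequence divergence (the real copies
are only *nearly* identical; ours are exactly identical), fragment-size
distributions (read starts are drawn directly, matching a coverage-level
analysis), paired-end reads, PCR duplicates, base-quality structure, and
sequencing error by default (a uniform substitution rate is available as a
config knob but off by default, because none of the decision rules depend
on error). Positive results on synthetic cohorts demonstrate that the
decision procedure recovers the regimes it was designed to distinguish,
not that those regimes exhaust real-data failure modes.

## A worked example

```{r example, eval = FALSE}
ann <- histone_annotation()
ref <- build_reference(ann, n_copies = 100, flank_length = 10000, seed = 42)
idx <- build_index(ref$unit_sequence)

cfg <- sim_config(mode = "TRUE_PROMOTER", target_element = "H3_H4_promoter",
                  seed = 7)
pair <- simulate_pair(ref, cfg)
chip <- coverage(map_reads(pair$chip, idx, ref$unit_sequence), 5000, 75)
input <- coverage(map_reads(pair$input, idx, ref$unit_sequence), 5000, 75)

call <- classify_candidate(chip, input, ann)
call
#> <candidate_call> POSITIVE | flags: none | 1 emergent peak(s) | top peak at H3_H4_promoter
tidy(call)
glance(call)
autoplot(call, ann)
```

## Design choices that were genuinely open

* **Annotation layout.** The repeat unit's internal coordinates are not
  published at base resolution, so the default layout is an invented,
  fixed stand-in: gene bodies and promoters are all at least 200 bp (so a
  peak at simulated fragment scales assigns unambiguously), the *H3/H4*
  promoter is 300 bp wide with two GA elements (50 bp and 24 bp) and two
  flanking TATA boxes, and the divergent gene pairs flank their shared
  promoters. The 50 bp GA element is deliberately sized so that a 50 bp
  read can lie inside it while a 100 bp read cannot — the geometry behind
  the read-length rule. Users with a real annotation override it via
  `read_annotation_bed()` (BED6, kind encoded as `name|kind`).
* **Internal mapper vs an external aligner.** On a 5 kb circular
  reference, exact seeding plus mismatch counting is sufficient, removes a
  binary dependency, and makes multimap handling deterministic. BAM import
  (`read_bam_alignments()`) remains available for users who prefer their
  own aligner; the collapse and everything downstream are unchanged.
* **Replicate combination.** Browser-style screens overlay replicate
  tracks without stating a combination rule; we combine calls, not tracks,
  and conservatively (all replicates must be positive). Classifying per
  replicate keeps each input normalization honest.
* **Bias rules on the input track.** Spurious normalized peaks caused by
  input structure are diagnosed where they originate. The ChIP-side scores
  are retained as diagnostics so a user can see, e.g., open-chromatin
  enrichment in both roles.

## Problem sizes

The test suite runs the classifier grid at the full study conditions
(6 modes × 20 seeds × 100,000 reads per pair) and the unit tests on a
5-copy reference at reduced depth; the whole suite completes in a few
minutes on one CPU. The acceptance script reruns the grid at 5 seeds per
mode plus the collapse, GA-rule, localization and screen computations —
about 19 million simulated bases mapped per invocation.

## Known limitations

* Identical tandem copies mean the collapse is exact by construction; real
  inter-copy variants would create low-level mismatch structure the
  mapper's 2-mismatch budget absorbs only partially.
* The rule cutoffs quantify visual judgments; they are defaults to be
  examined, not truths. All are overridable per run and embedded in every
  report.
* A no-input candidate can only be screened against its own coverage;
  three of the four false-positive rules need an input and are reported as
  unavailable in that case.
* The screen's verdict is a prioritization signal, not a binding call:
  positives warrant wet-lab follow-up, and negatives may simply reflect
  the tissue, stage, or quality of the available dataset.
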