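---
title: "Estimating mean telomere length from whole-genome sequencing reads"
author: "telometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mean telomere length from whole-genome sequencing reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Telomeres — the tandem-repeat caps of linear chromosomes, `TTAGGG` units in
vertebrates — shorten with cell division, and their mean length per
chromosome end (MTL) is a widely used marker of replicative ageing and
cancer biology. Whole-genome sequencing data contain telomeric reads, but a
reference genome typically truncates or masks chromosome ends, and the
extreme repetitiveness of telomeres makes ordinary read mapping ambiguous.
`telometry` estimates MTL directly from the reads with an alignment-based,
coverage-ratio method: telomeric reads are aligned to a purpose-built
telomeric index, their depth is compared with the genome-wide depth, and the
coverage ratio is converted into a length.

## The model

Let `pattern` be the repeat unit (`pl = nchar(pattern)`), `rl` the read
length, and `min_seed` the minimum number of telomeric bases a read must
contribute. The **telomeric index** is

* a telomeric region: the pattern tiled from phase 0, truncated to
  `rl + pl - 1` bases — long enough that a read starting at any of the `pl`
  cyclic phases of the repeat fits entirely inside it, and short enough that
  a pure-repeat read has a *unique* best placement per phase;
* an N-tail of `rl - min_seed` ambiguous bases appended at the 3' end only.

Every end-to-end placement of a length-`rl` read inside the index overlaps
the telomeric region by at least `min_seed` bases, so the minimum telomeric
content of a "telomeric read" is enforced by construction. Reads from the
telomere/subtelomere junction — telomeric 5' prefix, non-telomeric 3'
tail — are captured with the tail absorbed by the N positions, while reads
from *interstitial* telomeric arrays (repeats flanked on both sides inside
chromosome arms) have no feasible placement, because one flank would always
sit on telomeric positions. Keeping the tail one-sided is what buys this
discrimination.

Given the alignments, the estimator is a coverage ratio:

* `tel.cov` — mean per-base depth over the `rl + pl - 1` telomeric
  positions, counting only the telomeric overlap of each read (the N-tail
  never accumulates depth, so junction reads contribute only their
  telomere-derived bases);
* `base.cov` — genome-wide mean depth, either supplied externally or
  computed as `total_reads * rl / genome_length`;
* `rel.cov = tel.cov / base.cov`, the fold enrichment of telomeric
  sequence;
* `MTL = rel.cov * (rl + pl - 1) / (2 * n_chr)`, where `2 * n_chr` is the
  number of telomere ends in the haploid genome.

The logic: under uniform coverage `c`, a genome carrying total telomeric
length `T = 2 * n_chr * MTL` sends `T * c` read-bases to the telomeric
region, so `tel.cov ~ T * c / (rl + pl - 1)` and `base.cov ~ c`; the ratio
recovers `MTL` independent of depth, and read depth cancels — which is why
the estimate is stable across sequencing conditions.

## The aligner

The published workflow delegates this step to a general-purpose short-read
aligner in end-to-end mode. `telometry` instead ships its own exhaustive
scanner (in C++): the index has only `pl + rl - min_seed` candidate offsets,
so evaluating *every* offset on both strands is exact and fast, and removes
the heuristic, version-dependent behaviour of seed-based alignment. The
contract is:

* mismatches are counted only over telomeric-region positions; N-tail
  positions match any base at zero penalty; an `N` in the read mismatches
  every telomeric position;
* a placement is feasible when
  `mismatches <= floor(max_mismatch_rate * telomeric_overlap)`; the default
  `max_mismatch_rate = 0.10` approximates the default minimum-score
  threshold of end-to-end short-read aligners (about `rl / 10` mismatches)
  and is exposed as a parameter;
* the best feasible placement maximises telomeric overlap, then minimises
  mismatches, then takes the smallest offset on the forward strand.
  Preferring overlap concentrates coverage mass on the telomeric region,
  which is what the `tel.cov` definition assumes;
* no indels, no quality-aware scoring, no multi-mapping: the index is a
  pure tandem repeat, where substitution-only end-to-end placement is the
  appropriate model.
* paired-end mates are aligned independently: the index is far shorter than
  any realistic insert, so proper-pair constraints carry no information
  here. Both mates count toward `total_reads`.

The test suite checks this scanner against an independent brute-force
oracle over random reads and small parameter grids.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pattern` | `TTAGGG` | repeat unit; fixed-pattern telomeres only |
| `rl` | auto | read length (modal length of the first 10,000 reads) |
| `min_seed` | `min(rl, 12)` | minimum telomeric bases per mapped read |
| `max_mismatch_rate` | 0.10 | mismatch budget as a fraction of overlap |
| `n_chr` | — | haploid chromosome count (23 for human) |
| `genome_length` / `base_cov` | — | exactly one must be given |

`min_seed` defaults to two full human repeat units: a 12-base exact-ish
match is unlikely to arise by chance in non-telomeric sequence, and 12 is
below every commonly used read length; for ultra-short reads it clamps to
`rl`, which shrinks the N-tail to zero. Lowering `min_seed` admits shorter
junction overlaps (more capture, more noise); raising it does the reverse.
`n_chr` is deliberately a required argument rather than a human default, so
the estimator is usable for any karyotype.

## The synthetic-data generator

Validation uses genomes with telomeres of *known* length, built as:

* a random, repeat-free backbone (default 200 kb, GC 0.5) standing in for a
  non-telomeric chromosome fragment: any window containing a cyclic
  rotation of the pattern or its reverse complement is locally re-drawn;
* telomere lengths drawn independently per end from Normal(10 kb, 7 kb)
  truncated below at zero and rounded to the nearest half-pattern. The
  untruncated distribution puts roughly 8% of its mass below zero, so some
  truncation rule is unavoidable; truncation at zero only reshapes the
  extreme lower tail.
* repeats attached so that they read 5'-to-3' from each terminus inward
  (forward pattern on the left end, reverse-complement pattern on the
  right). With this orientation a junction-spanning read presents its
  telomeric block as a 5' prefix in one of its two orientations, which is
  the configuration the one-sided N-tail captures; it also makes the
  best-case accuracy arithmetic work out (see below). Sequencing both
  strands still produces G-rich and C-rich reads in equal proportion.
* reads placed uniformly with uniform strands; substitution errors at a
  flat per-base rate (default 0.2%, Illumina-like; no indels, no positional
  error ramp, no quality-profile realism); paired-end inserts normal,
  truncated to at least `rl`, FR orientation; optional exact-duplicate
  fraction; read count `round(coverage * genome_length / rl)`.

What the generator does *not* emulate: real subtelomeric sequence (the
backbone is random, so "junction" reads have random, not repeat-rich,
tails), GC-coverage bias, quality-dependent errors, and real interstitial
repeat density. Passing the recovery tests therefore demonstrates
correctness of the estimator's arithmetic and capture logic under its own
model assumptions, not robustness to every artefact of real libraries.

## Numerical behaviour and edge effects

Three small, systematic coverage losses are inherent to the design and
visible in the validation numbers:

1. *terminus edge*: uniform read placement cannot cover the outermost
   `rl - 1` bases at full depth, costing about `(rl - 1) / 2` read-bases of
   telomeric mass per end;
2. *sub-seed junction reads*: reads with fewer than `min_seed` telomeric
   bases are structurally unmappable, costing about
   `sum(j < min_seed) j / rl` read-bases per junction;
3. *phase effects*: a junction read whose telomeric prefix ends at a cyclic
   phase that does not meet the index boundary exactly may map with a few
   extra or missing overlap bases.

At `rl = 36`, `min_seed = 12`, 10 kb telomeres, (1) + (2) total about 19
read-bases of mass per telomere, i.e. an expected bias near -0.2% — which
is exactly the scale of bias the validation sweeps reproduce. The biases
grow relative to short telomeres (they are absolute, not proportional), so
sub-kilobase telomeres at short read lengths are estimated with a few
percent negative bias. Paired-end reads add an insert-scale edge deficit at
the termini, which is why paired-end accuracy is slightly worse and
degrades with insert size.

Degenerate inputs are handled explicitly: zero telomeric coverage yields
`MTL = 0` (a valid estimate), while `base_cov <= 0`, an empty read set, or
a non-positive genome length are errors; periodic patterns (e.g. `ATAT`)
warn and proceed (offsets become ambiguous modulo the period, coverage mass
does not); reads of the wrong length are rejected with a count, never an
exception.

## The repeat-count comparator

For method comparison the package includes a deliberately minimal
count-based estimator in the style of k-repeat-threshold tools:
`l = (t_k / N_gc) * C / E` with `t_k` the number of reads containing at
least `k` (default 7) non-overlapping repeat occurrences in either
orientation, `N_gc` the reads with GC fraction in [0.48, 0.52], `C` a
GC-matched genome length constant and `E` the number of telomere ends. The
published formula is compressed to the point of dimensional ambiguity; this
reading is the only one that yields length units with `s = N_gc / total`
acting as a normalising fraction, and both constants are exposed as
parameters rather than hard-coded. It is not a faithful clone of any
specific tool (no BAM tags, no multi-bin GC stratification); it exists to
reproduce two comparative behaviours, which the tests check directly:

* *error sensitivity*: one substitution can destroy a repeat occurrence and
  drop a short pure-repeat read below the count threshold, while the
  aligner absorbs it as a single mismatch;
* *interstitial confusion*: an interstitial array of `k` units embedded
  mid-read passes the count threshold but cannot be aligned end-to-end,
  so `classify_discordant()` puts such reads in `counted_only`.

## Validation harness and problem sizes

`summarize_accuracy()` reports the signed mean relative error
`MRE = mean((EL - L) / L)`, its standard error, `RMSE` over `EL - L`, and
the R-squared of the OLS fit of estimated on actual lengths (an
identity-line variant is reported alongside; OLS is the headline number,
since the published figure-of-merit is a goodness of linear fit, not a
forced slope of one). `run_sweep()` drives the full
simulate-estimate-evaluate loop over a grid.

The shipped validation (in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) uses the 200 kb-backbone design with read lengths
{36, 76, 100}, coverages {1, 5, 30} and 3 replicates per cell for the
single- and paired-end sweeps, twenty-five replicates of the best
configuration (36 nt single-end at 30x — enough that the mean relative
error is measured more precisely than the sub-percent bias it reports),
and five replicates each of a scaled-down
30 kb-telomere protocol (1 Mb backbone, 2x coverage, 5% duplicates, 76 and
150 nt reads). These sizes keep a full validation run under a few minutes
on one CPU while preserving every quantity under test: telomeric coverage
is driven by telomere length and depth, not by backbone size, so a longer
backbone only adds non-telomeric reads. Replicate counts per cell follow
the harness default of 3 (the published protocol does not state its
pooling depth).

## Known limitations

* Fixed repeat patterns only: organisms with variable telomeric repeats
  (e.g. budding yeast `C1-3A/TG1-3`) are out of scope.
* One MTL per genome: telomeric reads carry no chromosome identity, so
  per-chromosome telomere lengths are not estimable by this design.
* `base.cov` by closed form (or user-supplied): the package does not
  orchestrate whole-genome alignment of non-telomeric reads; for real data
  compute the genome-wide depth with standard tools and pass `base_cov`.
* The coverage model assumes approximately uniform sequencing depth; GC
  bias or duplication hotspots shift `rel.cov` and are not corrected.
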