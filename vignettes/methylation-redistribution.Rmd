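---
title: "Quantifying methylation and Pol V redistribution between chromatin compartments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying methylation and Pol V redistribution between chromatin compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methredist)
library(dplyr)
```

## The problem this package models

In plants, RNA-directed DNA methylation (RdDM) normally targets short,
euchromatic transposable elements (TEs) and the edges of long TEs, depositing
CHH methylation through Pol V (whose largest subunit is NRPE1). The linker
histone H1 is enriched in heterochromatin, where it compacts nucleosome
linker DNA and restricts access. When H1 is lost, Pol V occupancy
redistributes: it invades the bodies of long, pericentromeric,
heterochromatic TEs, while euchromatic CHH methylation weakens. At the same
time, heterochromatin gains substantial CG and CHG methylation through
RdDM-independent pathways, so the `h1` methylation phenotype is a composite
of RdDM redistribution and RdDM-independent gains.

`methredist` implements the quantitative machinery needed to detect and
measure this redistribution — methylation extraction and filtering, DMR
calling and co-occurrence statistics, interval-overlap enrichment, track
normalization, and feature metaprofiles — together with a synthetic-data
generator that programs the redistribution into simulated genomes, so every
stage can be validated against known truth without any sequencing data.

## The synthetic genome and what it emulates

`sim_config()` defines the study conditions. The defaults describe a genome
of 3 chromosomes x 200 kb with the central 30% of each chromosome as
pericentromere, 60 short TEs (200-800 bp) on the arms and 15 long TEs
(2-6 kb) inside pericentromeres, plus a 20 kb unmethylated control contig
standing in for the chloroplast genome used to estimate bisulfite conversion
rates. These sizes are roughly a 1:1000 miniature of a crucifer genome:
large enough that 10-kb window profiles, 100-bp DMR windows and per-TE
statistics are all well populated, small enough that the whole pipeline runs
in minutes on one core.

Three modelling choices matter most:

* **Occupancy model.** A genotype's expected occupancy is
  `background + edge_amplitude * exp(-d / edge_decay)` inside TEs (with `d`
  the distance to the nearest TE edge) plus, for `h1` only, a flat
  `body_gain` across heterochromatic TE bodies. Realized tracks draw
  per-base Poisson counts around this mean. The defaults are background 1,
  edge amplitude 4 and decay 150 bp (so the canonical pattern — short TEs
  and long-TE edges — dominates the wild type), and a body gain of 8 for
  `h1`. The body gain is deliberately strong: after read-count scaling
  (which down-scales the `h1` library because its total mass is larger) an
  invaded body window still shows roughly a 2.5-fold scaled excess over the
  wild type, comfortably above the differential caller's fold-2 rule while
  remaining in the range of a strong ChIP enrichment. A weak invasion (body
  gain near 2-3) would sit at the detection boundary by construction and
  make parameter recovery a coin flip rather than a property of the method.
* **Methylome model.** Every cytosine is assigned a context (CG/CHG/CHH)
  from the simulated sequence and a compartment (heterochromatic TE body,
  euchromatic TE body, background), and its methylated count is drawn from a
  beta-binomial with the compartment's programmed mean, overdispersion 0.1
  and depth 30. Beta-binomial rather than binomial overdispersion is used so
  that windowed DMR calling faces realistic between-site variance. The
  genotype means encode the published qualitative pattern: `h1` gains CG/CHG
  (0.85→0.95, 0.65→0.85) and CHH (0.12→0.22) in heterochromatin; `nrpe1`
  collapses euchromatic CHH (0.12→0.02); the double mutant keeps the
  heterochromatic CG/CHG gains but loses the CHH gain, and adds a CHG gain
  at euchromatic TEs relative to `nrpe1` alone.
* **Conversion failures.** Bisulfite conversion failure is simulated both at
  the read level (`simulate_reads_with_conversion_failure()`, where a failed
  read has every CHH call methylated) and at the contig level (the control
  contig's apparent methylation equals the failure rate, 0.005 by default,
  matching conversion rates around 99.5%).

One global seed drives everything; each generator derives its own
deterministic substream, so regenerating a single genotype's track never
perturbs the others and identical configurations are byte-identical on disk.

What the generator does **not** emulate: mappability artifacts, copy-number
variation between TE families, sequence-composition biases (the genome is
uniform random), M-bias along reads, and the external euchromatic/
heterochromatic TE classification used in published work, which is replaced
by positional classes (arm vs pericentromere). Passing the parameter-recovery
tests therefore demonstrates that the statistical machinery is correct and
well calibrated under the programmed model — not that any particular
biological dataset will behave as cleanly.

## Methylation arithmetic

Methylation level is `#mC / (#mC + #unmC)`, and a cytosine (or window, or
feature) with zero coverage is *missing*, never 0 — conflating the two
biases every downstream average. Window levels pool counts by depth
(`sum mC / sum (mC + unmC)`); a per-site-mean option exists
(`pool = "site"`) because the two conventions differ where depth varies, and
published pipelines rarely state which they use. Windows tile each
chromosome from coordinate 0 with the final partial window keeping its true
span.

The unconverted-read filter removes reads with three or more *consecutive
methylated* CHH calls, where consecutiveness is in read order ignoring
interleaved CG/CHG calls. Reading the rule as "three adjacent genomic CHH
positions" regardless of methylation state would discard most reads, so the
filter targets runs of methylated CHH calls — the standard incomplete-
conversion heuristic, since genuine CHH methylation this dense is rare while
a conversion failure methylates everything.

Context assignment is strict: positions within 2 bp of the readable 3' end
whose context cannot be resolved are reported `"undetermined"` and excluded,
never guessed.

## DMR calling

Because inherited DMR catalogs do not restate their caller, `call_dmrs()` is
a transparent windowed exact-test caller with documented, overridable
defaults: 100-bp windows, at least 10 total counts per sample per window, a
two-sided exact test on the pooled 2x2 count table, Benjamini-Hochberg
adjustment across tested windows, seeds at `p_adj <= 0.05` with an absolute
level difference of at least 0.2 for CG/CHG and 0.1 for CHH (CHH operates at
lower absolute levels), and merging of same-direction seeds within 100 bp —
the same `-d 100` gap convention as Homer's mergePeaks, which
`merge_interval_sets()` implements for arbitrary set collections with
membership flags. Merged DMR levels and the exact-test p are recomputed on
pooled counts; `p_adj` of a merged region is the smallest member-window
value, since BH adjustment is defined at the tested-window level and every
member already passed it. Direction is relative to the first sample (`hyper`
= A above B).

## Overlap statistics

`count_overlaps()` counts connected components of the overlap graph between
two interval sets (>= 1 bp; half-open touching does not connect; a component
must contain members of both sets). This merged-component convention makes
the count symmetric, so the co-occurrence matrix is symmetric by
construction. The random-placement null (`expected_overlaps_mc()`) re-places
each interval uniformly on its own chromosome with length preserved and
overlaps allowed; "randomly distributed throughout the genome" is
direction-agnostic, so the default expectation averages randomize-A and
randomize-B. Empirical p-values use the +1 correction and never return 0.

`hypergeometric_overlap()` tiles the genome into units (default 1 kb,
configurable — published bin-overlap tests rarely state their universe, so
ours is explicit), marks units touched by each set, and tests the doubly
marked count against the hypergeometric distribution; the expected count is
`n_A * n_B / N` and fold is observed over expected.

`cooccurrence_matrix()` clusters the log2 fold rows with average linkage on
correlation distance (1 − Pearson). Folds are floored at 2^-6 before the
log so that empty-overlap pairs stay finite; labels are sorted
lexicographically before clustering so leaf order is deterministic,
ties included. The linkage and distance are choices, stated here because
heatmap figures rarely state theirs.

`rank_sum_test()` enumerates all label assignments when the pooled sample
has at most 20 observations (exact even under ties, using midranks), and
otherwise uses the normal approximation with tie-corrected variance and
continuity correction. The two-sided exact p is the probability of a rank
sum at least as far from its null mean as observed.

## Track normalization and differential occupancy

`normalize_track()` follows the read-count scaling convention: the
larger-mass track is scaled down to the smaller before `log2 ratio`
(pseudocount 1) or subtraction. `differential_regions()` replaces
likelihood-model differential peak callers with a windowed fold rule —
50-bp windows, gain when the scaled mean is at least the 75th percentile of
the pooled windowed means *and* at least 2-fold over the other sample
(pseudocount 1), loss symmetric, same-direction windows merged within
100 bp. This is a deliberate simplification: it is oracle-testable
(swapping arguments exchanges gain and loss exactly; identical tracks give
empty sets) and recovers the programmed invasion cleanly, but it has no
model of local background and should not be expected to match
likelihood-based callers on real data.

## Metaprofiles and compartment summaries

`metaprofile()` rescales each feature body to a fixed number of bins
(mean within bin, the scale-regions convention) with fixed-width flank bins
(default 1 kb flanks, sized to the synthetic TE scale). Features shorter
than the bin count contribute via linear interpolation instead of being
dropped, so short-TE profiles are not biased toward long members. Profiles
average per-bin over features (each feature weighs equally, regardless of
depth); the alternative — pooling all positions genome-wide — would weight
long features more. Features are unstranded by default, as TE metaplots
conventionally are; `strand_aware = TRUE` reverses minus-strand bin order.
For methylomes the per-bin statistic is the depth-pooled level.

`chromosomal_profile()` labels each 10-kb window arm or pericentromere by
its midpoint under the half-open rule (a midpoint exactly at the
pericentromere start is pericentromeric).

## Numerical and degenerate-input conventions

* All intervals are 0-based half-open everywhere in memory and on disk;
  1-based cytosine reports convert at the reader boundary only.
* Zero-coverage anything (cytosine, window, feature, matrix cell) is `NA`.
* Depth-0 cytosines are legal records (0/0) and propagate as missing.
* Equal-value ties in the differential caller resolve by the `>=`
  comparisons stated above; rank ties use midranks.
* The placement sampler maintains explicit free space with a 1-bp guard gap
  and fails with the achieved count when a request cannot fit.

## Problem sizes used in the checks

The bundled tests run the generator at 2 x 60 kb (with a pericentromere-
dominated 1 x 100 kb variant for pooled-level recovery and a 2 x 80 kb
variant with 30 TEs per class for class comparisons); the end-to-end acceptance checks use the
default 3 x 200 kb conditions. The Monte Carlo null is validated at 20,000
permutations against an exhaustively enumerable 10-bp genome, and its type-I
error over 500 independent-placement replicates at 100 permutations each.
These sizes were chosen so the full suite exercises every stage at
well-powered depth while completing in a few minutes.

## Known limitations

* The DMR caller tests windows independently; it has no smoothing or HMM
  component, so single low-coverage windows inside a long DMR can split
  calls (mitigated, but not eliminated, by gap merging).
* The Monte Carlo null preserves interval lengths and chromosome assignment
  but not inter-interval spacing or GC/annotation matching; strongly
  clustered query sets will show liberal enrichment folds against it, which
  is the standard caveat for random-placement nulls.
* The differential-occupancy caller's min-signal quantile couples its
  behaviour to the signal distribution of the dataset at hand; on tracks
  with very widespread true differences the 75th percentile itself moves.
* Beta-binomial depth is constant per configuration; real coverage
  variation (mappability troughs, PCR jackpots) is not modelled.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "methredist_run")
res$summary
autoplot(res$profiles$h1_long_te)
autoplot(res$cooccurrence)
plot_chromosomal_profile(res$chrom_profile, res$genome)
```

The `summary` tibble reports the headline recovery numbers; the README shows
the values printed by an actual run.
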