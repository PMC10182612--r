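---
title: "Population-aware allele-frequency annotation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-aware allele-frequency annotation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popaf)
```

## The problem

A short-read variant caller sees each candidate site through a local pileup
of reads. Whether a weakly supported candidate is a real variant or an
artifact is easier to judge with population context: an allele segregating
at 30% frequency in a large reference panel deserves more benefit of the
doubt than one never observed before. Making that context available to a
caller requires solving three problems that popaf implements:

1. **Representation-robust allele matching.** The same physical allele can
   be written as different VCF records — an indel shifted within a repeat
   run, a record padded with extra shared bases, an MNP instead of a SNP.
   Position-and-allele string lookup against a panel therefore misses real
   matches. popaf matches candidate alleles to panel alleles by *local
   haplotype identity*: both records are spliced into the same reference
   window and the resulting sequences are compared exactly.
2. **Consistent population frequencies.** Cohort panels contain missing
   genotypes; skipping them gives every site a different denominator.
   popaf fills missing genotypes as homozygous reference so that every
   site in a grouping shares the denominator `ploidy * n_members`, and
   computes frequencies for the whole panel and for each superpopulation
   grouping (AFR, AMR, EAS, EUR, SAS in the usual continental labelling).
3. **Encoding frequencies for a pileup-image classifier.** Matched
   frequencies are painted into an extra image channel, one row per read,
   after a logarithmic intensity transform that spends most of the dynamic
   range on rare alleles.

On top of these, the package provides the downstream analyses used to
study such a model: benchmarking against a truth set with
representation-robust matching, stratification of errors into common
(AF > 0.01) and rare (AF <= 0.01) variants, model-specific
(population-resolved versus population-induced) error sets, and
cohort-level rare-variant quality metrics.

## The allele-matching algorithm

For a candidate `v` with reference span `[v_start, v_end)` (0-based,
half-open; an insertion occupies the single base span of its anchor):

1. query all panel records whose span overlaps `[v_start, v_end)`;
2. extend the window once to `[min(starts), max(ends))` over the candidate
   and the queried records;
3. splice each candidate alt and each cohort alt — one allele at a time,
   no combined multi-variant haplotypes — into the extended window;
4. on exact string equality, record the cohort allele's frequency under
   the candidate alt; unmatched alts get frequency 0.

Two consequences of the windowed query are worth stating plainly:

* Equivalent representations match whenever their reference spans
  intersect. This covers padding changes, MNP/SNP rewrites, and indel
  shifts smaller than the reference-allele length — the rewrites
  left-alignment differences between callers actually produce for
  deletions and MNPs.
* A representation whose span is *disjoint* from every equivalent panel
  record (e.g. a 1 bp insertion anchored several bases away inside a long
  homopolymer) is invisible to the single-pass query. This is inherent to
  querying by candidate span; the synthetic generator's `shift` mode
  therefore only emits rewrites within span overlap, and the optional
  `requery = TRUE` fixed-point mode does not change this because an empty
  initial query never grows the window. We follow the single-pass
  formulation by default because it is the simpler, deterministic
  contract; the fixed-point mode is provided for exploration.

When several panel alleles collapse to one candidate haplotype (duplicate
panel entries for one physical allele), the **maximum** frequency is kept
and the collision logged — summing would double-count one physical
haplotype.

Reads are annotated by the allele they exhibit over the candidate span,
reconstructed from their CIGAR alignment (insertion bases attach to their
anchor base, deletions contribute nothing). A read carrying a matched alt
gets that alt's frequency; a reference-supporting read gets
`1 - sum(matched alt AFs)` floored at zero (the reference read's colour
source is a package choice — the quantity is the panel's implied reference
frequency); any other allele gets 0.

## The intensity transform

`transform_af()` maps a frequency to an integer intensity:

```
intensity = round(max_intensity * max(0, 1 - log10(af) / log10(af_floor)))
```

with `af <= af_floor` (including 0) mapping to 0. Defaults:
`af_floor = 1e-4`, just below one allele out of a ~5,000-haplotype panel,
and `max_intensity = 254`, the usual 8-bit pileup ceiling. The transform
is monotone, hits 0 at the floor and 254 at frequency 1 exactly, and
gives AF 0.01 the midpoint intensity 127. The exact constants of any
production encoder are not public; this parameterisation is the package's
own documented choice and both parameters are exposed.

```{r transform}
transform_af(c(0, 1e-4, 0.01, 0.25, 1))
```

The six companion channels of `render_pileup()` (base identity, base
quality, mapping quality, strand, supports-variant, differs-from-reference)
are deliberately simple linear scalings documented in the function help;
exact production rendering belongs to the upstream caller and is out of
scope. The AF channel itself is exactly `render_af_channel()`, row-constant
per read over the read's aligned span.

## Frequencies from a cohort panel

`compute_frequencies()` tallies alt alleles per grouping with missing
alleles counted as reference, dividing by `2 * n_members` always. This is
the missing-to-ref convention: it equalises denominators across sites at
the cost of biasing frequencies slightly downward at poorly genotyped
sites, which is the accepted trade-off when a panel is used as an
annotation source. Counts are kept as integers and divided once, so the
identity `ref_freq + sum(alt_freqs) = 1` holds on the underlying counts.
Ploidy is fixed at 2 and non-diploid genotypes are rejected; sex
chromosomes with special ploidy are out of scope. `exclude_samples()`
removes samples (or a whole population label) before recomputation, the
operation needed for leave-one-population-out experiments.

## Evaluation procedures

`compare_to_truth()` matches call records to truth records by the same
haplotype-identity machinery (candidates are sought within a 50 bp start
distance), so representation differences never create spurious errors. A
matched site with the wrong genotype counts as one false positive *and*
one false negative — the strict set framing. This is intentionally simpler
than diplotype-path benchmarking engines of the vcfeval/hap.py class,
which additionally search for combinations of records explaining a
genotype jointly; popaf compares record against record. For the synthetic
fixtures this package generates (and for the single-record rewrites real
normalizers emit) the two definitions coincide.

`stratify_by_commonness()` partitions each of TP/FP/FN into common
(AF > 0.01) and rare (AF <= 0.01) strata, separately for SNPs and
indels; multi-allelic records with alleles on both sides of the
threshold are excluded and counted, so common + rare + excluded is an
exact partition. `model_specific_errors()` forms the haplotype-identity
set differences of two models' error sets (errors shared by both models
are excluded), annotates them with panel frequencies, and keeps variant
allele fractions on false positives. Printed percentages
(`rare_fraction()`, `common_fraction()`, `error_reduction()`) round half
away from zero to one decimal, matching how such numbers are reported.

## Cohort metrics

`call_frequency_bins()` stratifies cohort alleles by the number of
*samples* carrying them (a singleton is a call in exactly one sample),
binned 1..K with K = 10 by default; alleles in more than K samples fall
outside the bins. Per-sample homozygote counts, flagged-site counts
(against any annotation callset, matched by haplotype identity), Ti:Tv
ratios split by zygosity, and region-restricted frameshift-indel position
counts (`|len(ref) - len(alt)| mod 3 != 0`) follow. Whether Ti:Tv should
be pooled cohort-wide or averaged over per-sample ratios is ambiguous in
general usage; both are provided and the per-sample mean is the default.
Zero transversions yield `NA`, never infinity.

## The synthetic generator

`sim_config()` fixes the study conditions; all generators are byte-stable
under the seed. Defaults, chosen once as a desk-scale emulation of a
1000Genomes-style resource:

| parameter | default | why |
|---|---|---|
| `n_samples` | 100 | enough for frequencies down to 0.005 |
| `populations` | AFR .26, AMR .14, EAS .20, EUR .20, SAS .20 | continental proportions of the usual panel |
| `af_beta` | Beta(0.3, 1.5) | rare-skewed site-frequency spectrum |
| `pop_shift_sd` | 0.8 (logit scale) | visible between-population differentiation |
| `site_density_per_kb` | 5 | dense enough for overlapping-window cases |
| `indel_fraction` | 0.15 | realistic SNV:indel mix |
| `repeat_density_per_kb` | 1 | guarantees shiftable-indel context |
| `missing_rate` | 0.02 | exercises missing-to-ref filling |
| `depth`, `read_length`, `error_rate` | 30x, 100 bp, 1e-3 | standard short-read WGS |

The generator emits ground-truth ledgers with every fixture: planted
allele counts per grouping, and planted confusion counts with per-record
keys for the truth/callset generator. These ledgers are the oracles for
the package's tests. Heterozygous pileups draw the alt allele per read
with probability 1/2 (expected VAF 0.5).

What the generator does **not** emulate: linkage disequilibrium between
sites, realistic error profiles (errors are uniform base flips), split or
soft-clipped alignments, and structural variation. Passing tests on these
fixtures therefore demonstrate algorithmic correctness — exact frequency
recovery, representation invariance, exact set algebra — not calling
accuracy on real data, which depends on upstream alignment and the
classifier itself and is out of scope here.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere inside the package; only
  VCF read/write converts (VCF is 1-based). BED passes through unchanged.
* Symbolic/breakend ALT alleles are dropped at VCF ingestion with a
  logged count: haplotype splicing requires literal sequence.
* Phasing is ignored (`|` normalized to `/`): allele counting does not
  need it.
* Empty denominators yield `NA` sentinels (`titv_ratio` with no
  transversions, `zero_frequency_recall` with no zero-frequency truth,
  `error_reduction` with a zero baseline, fractions of empty sets) —
  never 1.0, 0.0 or infinity by convention.
* Read rows in pileups are ordered by (alignment start, name) for
  reproducibility.
* Percentage formatting rounds half away from zero to one decimal.

## Problem sizes used by the test-suite and acceptance script

Property suites run on seeded synthetic panels of 20–40 samples over
10–20 kb (about 1,000 perturbation fixtures, 10,000 oracle comparison
pairs) and one 300–500-sample panel for frequency recovery; these sizes
were chosen so the whole suite completes in a couple of minutes while
still exercising every code path, and they are stated here as the
package's own reproducibility contract.
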