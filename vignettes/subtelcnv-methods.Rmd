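---
title: "Methods: simulating and detecting a subtelomeric copy-number cassette"
author: "subtelcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting a subtelomeric copy-number cassette}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and the design choices
behind them. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The system being modeled

A herbicide-resistant genotype carries a subtelomeric amplification of a
fused cassette: Region-A (the segment containing the target gene), Region-B
(a segment natively ~1 Mb downstream of A on the same chromosome), and a
small Region-I insert of unknown origin placed just after a short prefix of
Region-B. The amplified unit is *palindromic*: a forward A+B(I) copy and its
reverse complement joined by a short inverted block of a 451 bp subtelomeric
repeat (12 forward then 31 reverse-complement copies), with much larger
arrays of the same unit separating and flanking the units. The susceptible
genotype has single native copies of A and B and no cassette.

Two observable signatures identify this architecture from reads alone:

1. **Read depth.** Mapped against the susceptible reference, all copies of
   A and B pile onto the single native locus. A carrier with `c` palindromic
   units holds `1 + 2c` copies per haplotype, so depth at A/B runs at
   `1 + 2c` times background in a homozygote and about half that in a
   heterozygote.
2. **Junction spanning reads.** Each palindromic unit contributes two
   copies of every domain junction (`STs-A`, `A-B`, `B-I`, `I-B`, `B-ST`)
   but a single inversion point (`INV`) inside the small inverted array.
   The expected support ratio `INV / other` therefore converges to 0.5 for
   an inverted-tandem array, stays near 1 for a plain tandem array, and the
   absence of support for any required junction falsifies the model.

## The synthetic-data generator

`sim_config()` / `build_genomes()` produce a susceptible/resistant genome
pair plus machine-readable truth (CNV intervals with expected multiplicity,
every junction position, all repeat arrays, and the domain sequences).

**What the defaults are.** The generator defaults are the characterized
architecture constants: Region-A 35,000 bp, Region-B 41,000 bp, Region-I
3,396 bp, an A–B gap of 1,018,000 bp, a 451 bp subtelomeric unit, a
12F/31R small inverted array, and `cassette_palindromic_units = 11`, giving
`1 + 2c = 23` copies — the ~22× depth regime. The large flanking arrays
default to 40F/60R: the real flanks are far larger (hundreds of units) and
unresolvable even in real assemblies, so their desk-scale stand-in only
needs to be big enough to (i) present the `STs-A`/`B-ST` junction context
and (ii) buffer the cassette from the chromosome-end coverage ramp (see
below). One feature of the source text is deliberately surfaced rather than
resolved: the repeat unit length is reported both as 451 bp and as 472 bp
in different places; the default is 451 and the parameter is configurable.

**Divergent per-chromosome units.** A master unit is drawn once; each
chromosome's unit applies independent substitutions at
`st_unit_divergence` (default 2%), reproducing the observed 86–99.6%
identity spread among chromosome-end arrays and making the relatedness tree
non-trivial.

**Heterozygotes.** `het = TRUE` represents the carrier as two explicit
haplotypes (one with the insertion, one without); `simulate_reads()` draws
each haplotype at half the total depth, with per-haplotype base targets
proportional to haplotype length. This reproduces the half-depth
heterozygote signal mechanistically rather than by halving a number.

**Reads.** Long reads draw lengths from a log-normal (median 12 kb by
default) and short reads are 150 bp pairs with a Gaussian insert; both are
error-free by default (junction counting must be testable without an error
model), with an optional uniform substitution rate. Coverage is the target
mean depth over the haploid genome; generation stops at the first read
crossing the base target, so totals land within a read length of it.

**What the generator does not emulate.** Realistic error profiles, chimeric
reads, GC bias, SNP backgrounds beyond the cassette and array divergence,
and assembly-scale chromosome counts. Passing tests therefore demonstrate
the *logic* of the detection chain under known truth, not robustness to
platform noise — real alignments enter through `import_alignments()` and
flow through the identical downstream code.

## The mapper

`maplite` is a deliberately minimal seed-and-extend aligner for error-free
or low-error synthetic reads. Every reference k-mer position is indexed
(default `k = 21`); read seeds vote for diagonals on both strands; each
candidate is verified by ungapped comparison, scoring the longest exact
run. Reads overhanging a reference end (cassette-model alignments) are
scored over the overlap only. Multi-mapping reads — the subtelomeric arrays
are repetitive by design — are assigned uniformly at random among
top-scoring loci under the run seed; candidate lists are capped (default
50) with random subsampling beyond the cap. A read whose prefix and suffix
each anchor ≥ 100 exactly matching bases at discordant loci is reported as
two split rows, which is how junction non-support manifests. There is no
gapped alignment and no quality-aware scoring: with substitution errors a
read's block simply ends at the error run, which is adequate for depth
windows and is the documented scope.

## Depth, segments, copy number

`window_depth()` tiles each reference sequence with fixed windows (default
5 kb, the scale used on real data; desk-scale runs use 500 bp so a 2–3 kb
region spans several windows) and divides aligned bases by window length,
normalizing the trailing partial window by its actual width.
`normalize_depth()` divides by the genome-wide mean window depth; the
baseline is replaceable for cross-sample pooling.

`call_segments()` labels windows by strict fold thresholds (deletion
`< 0.25×`, duplication `> 4×`; equality is neutral — "below"/"above" are
strict), merges same-label runs, and gates non-neutral segments with a
two-sided one-sample t-test of window folds against 1.0 at `alpha = 0.01`.
Single-window (or zero-variance) segments fall back to a normal
approximation using the global window variance. No multiple-testing
correction is applied, matching the upstream practice this mirrors. Note
one consequence of the gate: the *classification* is monotone in the
thresholds (raising the duplication fold can only shrink the duplicated
extent), but the gate can revive a sub-segment of a previously demoted
segment, so monotonicity holds with the gate open and is tested that way.

`estimate_copy_number()` reports mean normalized fold over an interval
divided by a background fold. Two practical choices: windows fully inside
the interval are preferred (boundary windows mix in flanking signal), and
at desk scale the background should be measured from a known-neutral
interval — when the amplification is a large fraction of a small simulated
genome it inflates the global mean, which cancels in the ratio. Zygosity is
called against the cohort's modal copies (taken as the median): `het`
within [0.35, 0.65] of the mode, `hom` within [0.8, 1.25], else `na`.

## Consensus events

`consensus_events()` intersects duplication segments across all resistant
samples and subtracts every base duplicated in any susceptible sample
(per-base semantics, equivalent to a bedtools intersect/subtract chain and
verified against a brute-force per-base oracle in the tests). A
whole-event veto at a configurable minimum-overlap fraction is available as
an alternative exclusion mode. Events are numbered in genomic order and
written with 1-based starts and `length = stop − start` — the convention of
the transcribed catalogue, whose arithmetic (e.g. 1,701,750 − 1,666,751 =
34,999) the fixture tests reproduce exactly. Two fixture rows with
internally inconsistent printed coordinates are flagged and excluded from
length arithmetic rather than silently repaired.

## Junction counting and architecture inference

`count_junction_support()` counts reads whose aligned block covers a
junction with at least `min_anchor` bases on each side (default 100 bp for
long reads; ~30 bp suits short reads), pooling forward and
reverse-complement instances under the canonical names. One filter matters
in repeat-rich context: a read only counts if its block covers at least
90% of its overlap window with the model (`min_block_frac`). Reads that
genuinely derive from the cassette align end-to-end over their overlap;
reads from unrelated subtelomeric arrays — whose orientation flips share
local sequence context with the inversion point — match only over the
array portion and would otherwise inflate `INV`.

`infer_architecture()` calls `palindromic_tandem` when all domain junctions
are supported and `INV / median(other)` lies in [0.35, 0.65];
`simple_tandem` when the ratio is ≥ 0.8 or no inversion junction exists;
`unsupported` when a required junction has zero support — and also for
ratios falling between the bands, as the conservative call for an
architecture matching neither model.

Two ratio-law conditions are worth stating because they are physical, not
numerical. First, junctions within a read length of the chromosome end sit
in the long-read coverage ramp and lose support; the simulation therefore
keeps generator-default (40F/60R) flanks in ratio experiments, playing the
buffering role of the enormous real flanks. Second, reads must be long
enough to anchor *uniquely* across the inverted array: a read that starts
and ends inside the 19.4 kb small array matches every orientation flip in
the model equally and is scattered by the multi-mapping tie-break. The
ratio experiments use 18 kb median reads, the regime in which the real
data could span and assemble across the small array. Both choices are
about matching the data property that makes the measurement meaningful,
not about adjusting a threshold.

`validate_alternatives()` maps the same reads to competing local
assemblies and compares spanning versus truncated counts at the designated
junction, declaring a winner only at a 5× margin.

`self_dotplot()` provides the macrostructure view used to enumerate
candidate layouts: exact k-mer match chains (default `k = 15`) on both
orientations, main diagonal excluded. For random sequence the expected
off-diagonal match count is `L²/4^k`, negligible at the scales used.

## Repeats and relatedness

`detect_unit()` estimates the tandem period as the shift minimizing mean
per-position mismatch. Harmonics of a diverged array fluctuate around the
same mismatch level as the fundamental, so the smallest period within
`0.01 + 0.25 × minimum` of the minimum wins; windows whose best period
still mismatches above 20% return nothing (i.i.d. DNA sits near 75%).
Consensus is per-column majority. `count_orientations()` tiles greedily
left-to-right choosing the higher-identity orientation per tile, ties
forward (a self-reverse-complementary unit counts entirely forward, by
documentation). Greedy tiling is sufficient below ~20% divergence and
matches the scale of the counts it needs to recover (12F/31R).

`pairwise_identity()` is global Needleman–Wunsch (match +1, mismatch −1,
gap −2 linear) with identity = matching columns / all alignment columns —
gap columns count in the denominator; the source material does not define
its denominator, so this one is documented and configurable. Arguments are
ordered canonically before aligning, making the measure exactly symmetric.
`nj_tree()` is standard neighbor joining on `100 − identity` distances
(negative branch lengths clamped to zero; the two-taxon case splits the
distance evenly). NJ deliberately replaces likelihood phylogenetics: the
test surface is topology recovery on well-separated units, for which NJ on
additive matrices is exact.

## Expression summary

Differential-expression statistics are consumed, never fitted. A record is
significant iff `p < 0.01` and `log2FC > 1`, both strict — a gene at
exactly 2-fold is not significant. Records with missing statistics (genes
filtered during upstream DE processing) stay in denominators and are never
significant; that convention is what makes "1 of 4" the right summary when
one of four genes carries no statistics. The generator's DE tables draw
null p-values uniformly with sub-threshold fold-changes and give designed
positives large effects, so per-region counts are exact by construction.

## The pipeline and its study sizes

`run_pipeline()` chains all stages with per-stage seeds derived from the
run seed by a stage-name hash (`derive_seed()`), writes stage TSVs and a
JSON report, and computes truth-recovery metrics: consensus precision and
recall at 50% reciprocal overlap against the truth CNV intervals, the
copy-number estimate and its relative error, the architecture call with
its INV ratio, and the recovered repeat-unit layout.

The default configuration is desk-scale by design, chosen once for a
complete run in minutes on one CPU: 3 chromosomes of 150 kb, Region-A/B/I
of 2,000/2,400/400 bp, a 6 kb gap, the full 451 bp unit with 12F/31R small
arrays, 6F/9R large arrays, `c = 11` units (23 copies), panels of 3
resistant and 3 susceptible samples at 30× short-read coverage, 40×
long reads, and 500 bp windows. Relative to the real study this shrinks
region lengths, flank sizes, and panel counts (the real panels were 8 + 8)
while preserving every architectural relationship the methods measure.
Consensus precision is expectedly below 1 on these runs: the subtelomeric
arrays themselves are genuinely amplified in carriers and surface as extra
consensus events outside the truth set — a faithful artifact, not a bug.

## Numerical and degenerate-input choices

Internal coordinates are 0-based half-open everywhere; 1-based inclusive
coordinates appear only in written catalogues. Equal-score mapping ties
break uniformly at random under the run seed. Fold values exactly at a
threshold are neutral. Zero-coverage requests return empty (valid) read
sets and FASTQ files; `c = 0` produces byte-identical genome pairs, an
empty junction truth, and an `unsupported` architecture end-to-end. All
randomness flows through explicit seeds, and identical seeds give
byte-identical genomes, read sets, and run reports.

## Known limitations

The mapper is exact-extension only and is not intended for real error
profiles; real alignments should be imported from SAM. Window-resolution
CNV boundaries inherit the window size; breakpoint-precise calls are out
of scope. The large flanking arrays are modeled smaller than reality and
the tandem-palindromic-unit arrangement between shared flanks is one of
two layouts consistent with the evidence (the generator exposes both; the
ratio law holds for either). Absolute chromosome-by-chromosome identity
percentages require the real assemblies and are not reproduced, only the
relatedness ordering they induce.
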