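# subtelcnv

Simulation-backed discovery and validation of a subtelomeric copy-number
cassette — the kind of structural variant that drives target-site herbicide
resistance in weeds, where a gene-bearing segment is trans-duplicated to a
chromosome end and amplified to dozens of copies between subtelomeric repeat
arrays.

## The problem and who this is for

In several weed species, resistance to glyphosate arises by copy-number
amplification of the target gene (*EPSPS*). In goosegrass the amplified unit
is a fused cassette: Region-A (~35 kb, carrying the target gene), Region-B
(~41 kb, natively ~1 Mb downstream), and a small insert of unknown origin
(Region-I) placed near the start of Region-B. The cassette sits in a
subtelomere as a tandem array of *palindromic* units — a forward A+B(I) copy
and its reverse complement joined by a short inverted array of a 451 bp
subtelomeric repeat (12 forward / 31 reverse copies), flanked by much larger
arrays of the same unit.

Detecting and validating such a structure from resequencing data takes a
chain of standard-but-fiddly steps. `subtelcnv` implements that chain as
reusable, tested R functions, and — because the real datasets are tens of
gigabases — pairs it with a synthetic-genome generator that emits the same
architecture with machine-readable ground truth, so every stage can be
exercised and benchmarked at desk scale. It is aimed at people building or
evaluating structural-variant workflows: simulation first, the same code
paths on real SAM alignments when you have them.

## The core quantities

* **Windowed read-depth CNV**: per-window depth normalized to the
  genome-wide average; windows below 0.25× are deletion candidates, above
  4× duplication candidates, segments with a two-sided one-sample t-test
  p-value > 0.01 against 1.0 are demoted to neutral; normalized fold is the
  copy-number proxy (a homozygous 23-copy amplification reads ~22×; a
  heterozygote reads about half).
* **Consensus events**: intervals duplicated in *every* resistant sample and
  *no* susceptible sample, catalogued with 1-based coordinates where
  `length = stop − start`.
* **Junction spanning-read support**: a read supports a cassette domain
  junction (`STs-A`, `A-B`, `B-I`, `I-B`, `B-ST`) if its alignment covers
  the boundary with ≥ 100 bp on each side. For a tandem array of `c`
  palindromic units every unit carries **two** copies of each domain
  junction but only **one** inversion point, so the inversion-point junction
  (`INV`) runs at half the support of the rest:
  `E[INV] / E[other] → 0.5` — the diagnostic signature of an
  inverted-tandem architecture.
* **Repeat arrays**: telomere motif runs (`TTTAGGG`), tandem-unit period
  detection by shift-mismatch minimization, greedy forward/reverse
  orientation counts, percent identity by global alignment, and a
  neighbor-joining relatedness tree on `100 − identity` distances.

## Worked example

```r
library(subtelcnv)

# a desk-scale genome pair: 3 palindromic cassette units on chromosome 2
cfg <- sim_config(n_chromosomes = 2, chrom_length = 30000,
                  telomere_copies_per_end = 20, st_unit_length = 451,
                  st_native_fwd = 3, st_native_rev = 4,
                  regionA_length = 1500, regionB_length = 1800,
                  regionI_length = 300, regionAB_gap = 2000,
                  regionB_prefix = 300, region_chrom = 2,
                  cassette_palindromic_units = 3,
                  st_small_fwd = 12, st_small_rev = 31,
                  st_large_fwd = 40, st_large_rev = 60, seed = 101)
g <- build_genomes(cfg)

# validate the cassette junctions with 40x error-free long reads
long  <- simulate_reads(g$resistant, "long", coverage = 40,
                        length_params = list(median = 18000), seed = 102)
model <- build_cassette_model(
  list(A = g$truth$domains$A, B1 = g$truth$domains$B1,
       B2 = g$truth$domains$B2, I = g$truth$domains$I,
       ST_large   = paste0(strrep(g$truth$domains$st_unit, 40),
                           strrep(revcomp(g$truth$domains$st_unit), 60)),
       ST_small_f = strrep(g$truth$domains$st_unit, 12),
       ST_small_r = strrep(g$truth$domains$st_unit, 31)),
  palindromic_cassette_layout())
sup <- count_junction_support(long, model, min_anchor = 100, seed = 103)
sup
#>    junction n_spanning n_instances relative_abundance
#> 1:    STs-A        285           2           2.192308
#> 2:      A-B        285           2           2.192308
#> 3:      B-I        282           2           2.169231
#> 4:      I-B        282           2           2.169231
#> 5:     B-ST        277           2           2.130769
#> 6:      INV        130           1           1.000000
infer_architecture(sup)
#> [1] "palindromic_tandem"
#> attr(,"inv_ratio")
#> [1] 0.4609929
```

All five domain junctions are supported; the inversion-point junction runs
at ~0.46× the median of the others — within the palindromic band around the
theoretical 0.5 — so the architecture is called an inverted (palindromic)
tandem array.

The whole chain (simulate panels → map → depth CNV → consensus → junctions
→ repeats → expression, with truth-recovery metrics) runs as:

```r
report <- run_pipeline(pipeline_config(), seed = 1)
report
#> subtelcnv run report (seed 1 )
#>   consensus events: 4 (recall 1.00, precision 0.50)
#>   Region-A copies: 24.36 (rel. error 0.059, zygosity hom)
#>   architecture: palindromic_tandem (INV ratio 0.531)
#>   ST unit: 451 bp, orientations 12 F / 31 R
```

Both cassette regions are recovered (recall 1.0; the two extra events are
the amplified subtelomeric arrays themselves — real signal, outside the
truth set), the copy estimate is within 6% of the planted 1 + 2·11 = 23
copies, and the 451 bp unit with its 12 forward / 31 reverse small-array
layout is recovered from sequence alone.

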