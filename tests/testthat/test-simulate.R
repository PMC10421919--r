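test_that("zero cassette units give identical genomes and no junctions", {
  g <- build_genomes(small_sim_config(units = 0L))
  expect_identical(g$susceptible$sequences, g$resistant$sequences)
  expect_equal(nrow(g$truth$junctions), 0L)
  expect_equal(g$truth$insertion_length, 0L)
  expect_true(all(g$truth$cnv_intervals$expected_multiplicity == 1L))
})

test_that("insertion length equals the closed-form sum over random configs", {
  set.seed(42)
  for (trial in 1:5) {
    units <- sample(0:4, 1L)
    ul <- sample(60:140, 1L)
    cfg <- sim_config(
      n_chromosomes = 2L, chrom_length = 30000L,
      telomere_copies_per_end = sample(10:25, 1L),
      st_unit_length = ul, st_unit_divergence = runif(1, 0, 0.1),
      st_native_fwd = sample(2:4, 1L), st_native_rev = sample(2:5, 1L),
      regionA_length = sample(800:2000, 1L),
      regionB_length = sample(900:2200, 1L),
      regionI_length = sample(150:400, 1L),
      regionAB_gap = sample(1000:3000, 1L),
      regionB_prefix = 150L, region_chrom = 2L,
      cassette_palindromic_units = units,
      st_small_fwd = sample(2:5, 1L), st_small_rev = sample(2:6, 1L),
      st_large_fwd = sample(2:4, 1L), st_large_rev = sample(2:4, 1L),
      seed = sample.int(1e6, 1L))
    g <- build_genomes(cfg)
    lenF <- cfg$regionA_length + cfg$regionB_length + cfg$regionI_length
    lenS <- ul * (cfg$st_small_fwd + cfg$st_small_rev)
    lenL <- ul * (cfg$st_large_fwd + cfg$st_large_rev)
    expected <- if (units == 0L) 0L else
      units * (lenL + 2L * lenF + lenS) + lenL
    carrier <- g$truth$carrier
    expect_equal(nchar(g$resistant$sequences[[carrier]]) -
                   nchar(g$susceptible$sequences[[carrier]]), expected)
    expect_equal(g$truth$insertion_length, expected)
  }
})

test_that("same config and seed give byte-identical genomes and reads", {
  cfg <- small_sim_config(units = 2L, seed = 123L)
  g1 <- build_genomes(cfg)
  g2 <- build_genomes(cfg)
  expect_identical(g1$susceptible$sequences, g2$susceptible$sequences)
  expect_identical(g1$resistant$sequences, g2$resistant$sequences)
  expect_identical(g1$truth$junctions, g2$truth$junctions)
  r1 <- simulate_reads(g1$susceptible, "long", 3, seed = 9L,
                       length_params = list(median = 2000))
  r2 <- simulate_reads(g2$susceptible, "long", 3, seed = 9L,
                       length_params = list(median = 2000))
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$origins, r2$origins)
})

test_that("every truth junction context contains its flanking domains", {
  g <- build_genomes(small_sim_config(units = 2L, seed = 11L))
  d <- g$truth$domains
  seqs <- g$resistant$sequences
  ctx <- 150L
  # expected (left, right) 150-mers around each junction type, forward sense
  u <- d$st_unit
  expect_gt(nrow(g$truth$junctions), 0L)
  for (r in seq_len(nrow(g$truth$junctions))) {
    jn <- g$truth$junctions[r, ]
    left <- substr(seqs[[jn$chrom]], jn$pos - ctx + 1L, jn$pos)
    right <- substr(seqs[[jn$chrom]], jn$pos + 1L, jn$pos + ctx)
    pair <- switch(jn$name,
      "STs-A" = list(c(substr(strrep(revcomp(u), 3L),
                              nchar(u) * 3L - ctx + 1L, nchar(u) * 3L),
                       substr(d$A, 1L, ctx)),
                     c(revcomp(substr(d$A, 1L, ctx)),
                       substr(strrep(u, 3L), 1L, ctx))),
      "A-B" = list(c(substr(d$A, nchar(d$A) - ctx + 1L, nchar(d$A)),
                     substr(d$B1, 1L, ctx)),
                   c(revcomp(substr(d$B1, 1L, ctx)),
                     revcomp(substr(d$A, nchar(d$A) - ctx + 1L,
                                    nchar(d$A))))),
      "B-I" = list(c(substr(d$B1, nchar(d$B1) - ctx + 1L, nchar(d$B1)),
                     substr(d$I, 1L, ctx)),
                   c(revcomp(substr(d$I, 1L, ctx)),
                     revcomp(substr(d$B1, nchar(d$B1) - ctx + 1L,
                                    nchar(d$B1))))),
      "I-B" = list(c(substr(d$I, nchar(d$I) - ctx + 1L, nchar(d$I)),
                     substr(d$B2, 1L, ctx)),
                   c(revcomp(substr(d$B2, 1L, ctx)),
                     revcomp(substr(d$I, nchar(d$I) - ctx + 1L,
                                    nchar(d$I))))),
      NULL)
    if (is.null(pair)) next   # B-ST and INV flanks are repeat arrays
    ok <- (identical(left, pair[[1]][1]) && identical(right, pair[[1]][2])) ||
      (identical(left, pair[[2]][1]) && identical(right, pair[[2]][2]))
    expect_true(ok, info = sprintf("junction %s at %s:%d", jn$name,
                                   jn$chrom, jn$pos))
  }
})

test_that("summed read bases land within 5% of coverage times genome length", {
  g <- build_genomes(small_sim_config(units = 0L, seed = 5L))
  L <- sum(nchar(g$susceptible$sequences))
  rs <- simulate_reads(g$susceptible, "short_paired", coverage = 30,
                       seed = 2L)
  bases <- sum(nchar(rs$reads$seq)) + sum(nchar(rs$reads$mate_seq))
  expect_lt(abs(bases - 30 * L) / (30 * L), 0.05)
  rl <- simulate_reads(g$susceptible, "long", coverage = 30, seed = 2L,
                       length_params = list(median = 2000))
  bases_l <- sum(nchar(rl$reads$seq))
  expect_lt(abs(bases_l - 30 * L) / (30 * L), 0.05)
})

test_that("coverage zero gives an empty read set; negative coverage errors", {
  g <- build_genomes(small_sim_config(units = 0L))
  rs <- simulate_reads(g$susceptible, "long", coverage = 0)
  expect_equal(nrow(rs$reads), 0L)
  expect_error(simulate_reads(g$susceptible, "long", coverage = -1),
               "coverage")
})

test_that("heterozygous simulation halves carrier-haplotype read share", {
  g <- build_genomes(small_sim_config(units = 2L, het = TRUE, seed = 19L))
  expect_true(paste0(g$truth$carrier, "_hap2") %in%
                names(g$resistant$sequences))
  rs <- simulate_reads(g$resistant, "long", coverage = 10, seed = 3L,
                       length_params = list(median = 1500))
  carrier_reads <- mean(rs$origins$chrom == g$truth$carrier)
  alt_reads <- mean(rs$origins$chrom == paste0(g$truth$carrier, "_hap2"))
  # carrier chromosome is longer (insertion), so expect more bases from it,
  # but the alt haplotype must contribute a comparable share of its length
  expect_gt(alt_reads, 0.1)
  expect_gt(carrier_reads, alt_reads)
})

test_that("invalid configurations are rejected", {
  expect_error(small_sim_config(units = -1L), "cassette_palindromic_units")
  expect_error(sim_config(chrom_length = 0), "chrom_length")
  expect_error(small_sim_config(st_unit_divergence = 0.5), "divergence")
  expect_error(sim_config(n_chromosomes = 1L, chrom_length = 5000L),
               "arm")
})

test_that("write_outputs round-trips genome, reads and truth", {
  g <- build_genomes(small_sim_config(units = 1L, seed = 3L))
  rs <- simulate_reads(g$susceptible, "long", coverage = 2, seed = 4L,
                       length_params = list(median = 1000))
  dir <- withr::local_tempdir()
  files <- write_outputs(g$resistant, rs, g$truth, dir)
  back <- read_genome_fasta(files[["genome"]])
  expect_identical(back, g$resistant$sequences)
  reads_back <- read_fastq(files[["reads"]])
  expect_identical(reads_back$seq, rs$reads$seq)
  # truth BED is 0-based half-open: interval lengths equal stop - start
  bed <- read_bed(files[["truth_cnv"]])
  expect_equal(bed$stop - bed$start,
               g$truth$cnv_intervals$stop - g$truth$cnv_intervals$start)
  expect_equal(bed$start, g$truth$cnv_intervals$start)
  # empty read set still yields a valid (empty) FASTQ
  empty <- simulate_reads(g$susceptible, "long", coverage = 0)
  f2 <- write_outputs(g$susceptible, empty, NULL, file.path(dir, "e"))
  expect_true(file.exists(f2[["reads"]]))
  expect_equal(nrow(read_fastq(f2[["reads"]])), 0L)
})
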