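# shared fixtures, all generated in code

# a small, fast simulation of the full architecture
small_sim_config <- function(units = 2L, seed = 7L, het = FALSE,
                             st_unit_length = 100L, ...) {
  sim_config(n_chromosomes = 2L, chrom_length = 30000L,
             telomere_copies_per_end = 20L,
             st_unit_length = st_unit_length, st_unit_divergence = 0.02,
             st_native_fwd = 3L, st_native_rev = 4L,
             regionA_length = 1500L, regionB_length = 1800L,
             regionI_length = 300L, regionAB_gap = 2000L,
             regionB_prefix = 300L, region_chrom = 2L,
             cassette_palindromic_units = units,
             st_small_fwd = 3L, st_small_rev = 5L,
             st_large_fwd = 2L, st_large_rev = 3L,
             het = het, seed = seed, ...)
}

# a single-chromosome genome pair where a region is repeated `mult` times in
# tandem in the "resistant" genome; returns models plus the region interval
multiplicity_genome <- function(mult, seed, chrom_len = 40000L,
                                reg_len = 3000L, reg0 = 20000L,
                                het = FALSE) {
  set.seed(seed)
  base <- random_dna(chrom_len)
  reg <- substr(base, reg0 + 1L, reg0 + reg_len)
  ins_at <- 35000L
  res_seq <- paste0(substr(base, 1L, ins_at), strrep(reg, mult - 1L),
                    substr(base, ins_at + 1L, chrom_len))
  sus <- genome_model(c(Chr1 = base))
  res <- if (het)
    genome_model(c(Chr1 = res_seq, Chr1_alt = base),
                 haplotypes = list(hap1 = "Chr1", hap2 = "Chr1_alt"))
  else genome_model(c(Chr1 = res_seq))
  list(susceptible = sus, resistant = res,
       region = c(start = reg0, stop = reg0 + reg_len),
       neutral = c(start = 4000L, stop = 16000L),
       chrom_len = chrom_len)
}

# copy-number estimate for a multiplicity genome at 30x short reads
estimate_multiplicity <- function(mg, seed, window = 500L) {
  idx <- build_index(mg$susceptible, k = 21L)
  rs <- simulate_reads(mg$resistant, "short_paired", coverage = 30,
                       seed = seed)
  aln <- map_reads(rs, idx, seed = seed + 1L)
  tr <- normalize_depth(window_depth(aln, window = window,
                                     seq_lengths = c(Chr1 = mg$chrom_len)))
  bg <- estimate_copy_number(tr, "Chr1", mg$neutral["start"],
                             mg$neutral["stop"])$copies
  estimate_copy_number(tr, "Chr1", mg$region["start"], mg$region["stop"],
                       background_fold = bg)$copies
}

# build cnv_segments tables directly (for consensus tests)
make_segments <- function(chrom, starts, stops, states,
                          depths = NULL) {
  n <- length(starts)
  if (is.null(depths))
    depths <- ifelse(states == "duplication", 10, 1)
  out <- data.table::data.table(
    chrom = chrom, start = as.integer(starts), stop = as.integer(stops),
    state = states, mean_norm_depth = depths,
    p_value = ifelse(states == "neutral", NA_real_, 1e-6),
    n_windows = pmax(1L, (stops - starts) %/% 500L))
  data.table::setattr(out, "class", c("cnv_segments", class(out)))
  out
}

# random duplication segment set over [0, L) with ~n intervals
random_dup_segments <- function(n, L, chrom = "Chr1") {
  k <- sample.int(n, 1L)
  s <- sort(sample.int(L - 10L, k))
  e <- pmin(L, s + sample.int(max(4L, L %/% max(1L, k)), k,
                              replace = TRUE))
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  if (length(s) > 1L) {       # enforce disjoint sorted segments
    ok <- c(TRUE, s[-1L] >= cummax(e[-length(e)]))
    s <- s[ok]; e <- e[ok]
  }
  make_segments(chrom, s, e, rep("duplication", length(s)))
}

# per-base brute-force consensus oracle (1-based inclusive intervals out)
brute_consensus <- function(r_list, s_list, L) {
  cover <- function(segs) {
    v <- logical(L)
    d <- segs[segs$state == "duplication", ]
    for (r in seq_len(nrow(d))) {
      if (d$stop[r] > d$start[r])
        v[(d$start[r] + 1L):d$stop[r]] <- TRUE   # 1-based positions
    }
    v
  }
  in_all_r <- Reduce(`&`, lapply(r_list, cover))
  in_any_s <- if (length(s_list)) Reduce(`|`, lapply(s_list, cover))
  else logical(L)
  keep <- in_all_r & !in_any_s
  if (!any(keep)) return(data.frame(start = integer(), stop = integer()))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], stop = ends[r$values])
}

table1_fixture <- function() {
  read_cnv_catalogue(system.file("extdata", "consensus_cnv_catalogue.tsv",
                                 package = "subtelcnv"))
}

table2_fixture <- function() {
  read_de_table(system.file("extdata", "cassette_region_de.tsv",
                            package = "subtelcnv"))
}
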