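#' Simulation configuration for a susceptible/resistant genome pair
#'
#' Collects the architecture constants of the simulated system: chromosome
#' count and length, Arabidopsis-type telomere arrays, per-chromosome divergent
#' subtelomeric (ST) repeat arrays, the native interstitial Region-A (carrying
#' the marker gene standing in for the amplified target gene) and Region-B, and
#' the subtelomeric cassette carried by the resistant haplotype: `c` tandem
#' palindromic units, each a forward A+B(I) fusion and its reverse complement
#' joined by a short inverted ST array, separated and flanked by larger ST
#' arrays.
#'
#' Defaults reproduce the characterized system: Region-A 35 kb, Region-B
#' 41 kb, Region-I 3396 bp inserted near the start of Region-B, an
#' `r format(1018000, big.mark=",")` bp A-B gap, a 451 bp ST unit repeated
#' 12 forward / 31 reverse in the small inverted array, and
#' `cassette_palindromic_units = 11` so the carrier haplotype holds
#' 1 + 2c = 23 copies of Region-A/B. The large flanking arrays default to
#' 40 forward / 60 reverse units, a configurable desk-scale stand-in for the
#' much larger arrays real assemblies cannot resolve.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome, bp.
#' @param telomere_motif telomere repeat motif (forward strand at the right
#'   chromosome end).
#' @param telomere_copies_per_end tandem motif copies per chromosome end.
#' @param st_unit_length subtelomeric repeat unit length, bp.
#' @param st_unit_divergence per-chromosome substitution fraction applied to
#'   the master ST unit, in `[0, 0.15]`.
#' @param st_native_fwd,st_native_rev forward/reverse unit counts of the
#'   native ST array at each chromosome end.
#' @param regionA_length,regionB_length,regionI_length domain lengths, bp.
#' @param regionAB_gap distance between Region-A end and Region-B start, bp.
#' @param regionB_prefix length of the Region-B prefix preceding the Region-I
#'   insertion point, bp.
#' @param region_chrom 1-based index of the chromosome carrying Region-A/B
#'   natively (and the cassette in the resistant genome); clipped to
#'   `n_chromosomes`.
#' @param cassette_palindromic_units number `c` of tandem palindromic cassette
#'   units on the carrier haplotype (0 = no insertion).
#' @param st_small_fwd,st_small_rev forward/reverse unit counts of the small
#'   inverted ST array joining the forward and reverse cassette copies.
#' @param st_large_fwd,st_large_rev forward/reverse unit counts of the large
#'   ST arrays separating/flanking cassette units.
#' @param cassette_layout `"separated"` (a large ST array between consecutive
#'   palindromic units and at both ends; default) or `"shared"` (single
#'   flanking arrays, units abut directly).
#' @param het logical; if `TRUE` the resistant individual is heterozygous
#'   (one carrier haplotype, one susceptible-type haplotype).
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chromosomes = 3L,
                       chrom_length = 3e6,
                       telomere_motif = "TTTAGGG",
                       telomere_copies_per_end = 100L,
                       st_unit_length = 451L,
                       st_unit_divergence = 0.02,
                       st_native_fwd = 8L,
                       st_native_rev = 12L,
                       regionA_length = 35000L,
                       regionB_length = 41000L,
                       regionI_length = 3396L,
                       regionAB_gap = 1018000L,
                       regionB_prefix = 2000L,
                       region_chrom = 3L,
                       cassette_palindromic_units = 11L,
                       st_small_fwd = 12L,
                       st_small_rev = 31L,
                       st_large_fwd = 40L,
                       st_large_rev = 60L,
                       cassette_layout = c("separated", "shared"),
                       het = FALSE,
                       seed = 1L) {
  cassette_layout <- match.arg(cassette_layout)
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    telomere_motif = toupper(telomere_motif),
    telomere_copies_per_end = as.integer(telomere_copies_per_end),
    st_unit_length = as.integer(st_unit_length),
    st_unit_divergence = st_unit_divergence,
    st_native_fwd = as.integer(st_native_fwd),
    st_native_rev = as.integer(st_native_rev),
    regionA_length = as.integer(regionA_length),
    regionB_length = as.integer(regionB_length),
    regionI_length = as.integer(regionI_length),
    regionAB_gap = as.integer(regionAB_gap),
    regionB_prefix = as.integer(regionB_prefix),
    region_chrom = as.integer(region_chrom),
    cassette_palindromic_units = as.integer(cassette_palindromic_units),
    st_small_fwd = as.integer(st_small_fwd),
    st_small_rev = as.integer(st_small_rev),
    st_large_fwd = as.integer(st_large_fwd),
    st_large_rev = as.integer(st_large_rev),
    cassette_layout = cassette_layout,
    het = isTRUE(het),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (f in c("n_chromosomes", "chrom_length", "telomere_copies_per_end",
              "st_unit_length", "regionA_length", "regionB_length",
              "regionI_length", "regionAB_gap", "regionB_prefix"))
    stopifnot_scalar(cfg[[f]], f)
  if (!nzchar(cfg$telomere_motif) ||
      grepl("[^ACGT]", cfg$telomere_motif))
    stop("'telomere_motif' must be a non-empty ACGT string", call. = FALSE)
  if (cfg$cassette_palindromic_units < 0)
    stop("'cassette_palindromic_units' must be >= 0", call. = FALSE)
  if (cfg$st_unit_divergence < 0 || cfg$st_unit_divergence > 0.15)
    stop("'st_unit_divergence' must be in [0, 0.15]", call. = FALSE)
  if (cfg$regionB_prefix >= cfg$regionB_length)
    stop("'regionB_prefix' must be smaller than 'regionB_length'",
         call. = FALSE)
  if (cfg$region_chrom < 1)
    stop("'region_chrom' must be >= 1", call. = FALSE)
  # the native domains and the flanking telomere/subtelomere structure must
  # fit on the host chromosome arm
  tel <- nchar(cfg$telomere_motif) * cfg$telomere_copies_per_end
  stn <- cfg$st_unit_length * (cfg$st_native_fwd + cfg$st_native_rev)
  need <- 2 * (tel + stn) + cfg$regionA_length + cfg$regionAB_gap +
    cfg$regionB_length
  if (need > cfg$chrom_length)
    stop(sprintf(paste0("cassette domains do not fit on the host chromosome ",
                        "arm: need %d bp, chrom_length is %d bp"),
                 need, cfg$chrom_length), call. = FALSE)
  invisible(cfg)
}

#' Construct a genome model
#'
#' A genome model bundles named chromosome sequences, annotated features and
#' the haplotype composition of the (diploid) individual. Internal feature
#' coordinates are 0-based half-open throughout the package.
#'
#' @param sequences named character vector of chromosome sequences
#'   (alphabet `A`,`C`,`G`,`T`).
#' @param features data.frame with columns `name`, `chrom`, `start`, `stop`,
#'   `orientation` (`"+"`/`"-"`), `class` (one of `telomere`, `subtelomere`,
#'   `regionA`, `regionB`, `regionI`, `cassette_unit`).
#' @param haplotypes list of character vectors of sequence names, one per
#'   haplotype; defaults to a homozygous diploid over all sequences.
#' @return an object of class `genome_model`.
#' @export
genome_model <- function(sequences, features = NULL, haplotypes = NULL) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("'sequences' must be a named character vector", call. = FALSE)
  sequences <- vapply(sequences, as.character, "")
  if (any(grepl("[^ACGT]", sequences)))
    stop("sequences must be over the alphabet {A,C,G,T}", call. = FALSE)
  if (is.null(features))
    features <- data.frame(name = character(), chrom = character(),
                           start = integer(), stop = integer(),
                           orientation = character(), class = character(),
                           stringsAsFactors = FALSE)
  lens <- nchar(sequences)
  if (nrow(features)) {
    bad <- !(features$chrom %in% names(sequences)) |
      features$start < 0 | features$stop > lens[features$chrom] |
      features$start > features$stop
    if (any(bad))
      stop("feature intervals must lie within sequence bounds", call. = FALSE)
  }
  if (is.null(haplotypes))
    haplotypes <- list(hap1 = names(sequences), hap2 = names(sequences))
  structure(list(sequences = sequences, features = features,
                 haplotypes = haplotypes,
                 ploidy_labels = names(haplotypes)),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$sequences), "sequence(s),",
      nrow(x$features), "feature(s),",
      length(x$haplotypes), "haplotype(s)\n")
  lens <- nchar(x$sequences)
  for (nm in names(lens)) cat(sprintf("  %s: %d bp\n", nm, lens[[nm]]))
  invisible(x)
}

# assemble one tandem ST array: n_fwd forward units then n_rev
# reverse-complement units
st_array <- function(unit, n_fwd, n_rev) {
  paste0(strrep(unit, n_fwd), strrep(revcomp(unit), n_rev))
}

#' Build a susceptible/resistant genome pair with ground truth
#'
#' Generates the susceptible genome (native Region-A and Region-B separated by
#' `regionAB_gap` on the designated chromosome, telomere and subtelomere
#' arrays on every chromosome end) and the resistant genome, identical except
#' for a subtelomeric insertion of `c` tandem palindromic cassette units on
#' the carrier chromosome's right end. Each unit is
#' `[A+B(I) forward] [small inverted ST array] [A+B(I) reverse-complement]`,
#' with large ST arrays between units and at both ends (layout
#' `"separated"`) or single shared flanks (`"shared"`). Native copies of
#' Region-A/B are retained, so the carrier haplotype holds `1 + 2c` copies of
#' each.
#'
#' The returned truth records every cassette junction (named `STs-A`, `A-B`,
#' `B-I`, `I-B`, `B-ST` and `INV` for the inversion point inside the small ST
#' array), the expected CNV multiplicities of Region-A/B on the susceptible
#' reference coordinates, all repeat arrays, and the domain sequences needed
#' to rebuild the cassette model.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_genomes` with elements `susceptible`,
#'   `resistant` (both [genome_model()]) and `truth` (list with
#'   `cnv_intervals`, `junctions`, `repeat_arrays`, `domains`,
#'   `insertion_length`).
#' @export
build_genomes <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config

  motif <- cfg$telomere_motif
  tel_fwd <- strrep(motif, cfg$telomere_copies_per_end)
  tel_rev <- revcomp(tel_fwd)
  tel_len <- nchar(tel_fwd)

  master_unit <- random_dna(cfg$st_unit_length)
  n <- cfg$n_chromosomes
  chrom_names <- paste0("Chr", seq_len(n))
  region_chrom <- min(cfg$region_chrom, n)
  carrier <- chrom_names[region_chrom]

  st_units <- setNames(vapply(seq_len(n), function(i)
    mutate_dna(master_unit, cfg$st_unit_divergence), ""), chrom_names)
  st_nat_len <- cfg$st_unit_length * (cfg$st_native_fwd + cfg$st_native_rev)

  seqs <- character(n)
  feats <- list()
  regA <- regB <- NULL
  for (i in seq_len(n)) {
    nm <- chrom_names[i]
    nat <- st_array(st_units[i], cfg$st_native_fwd, cfg$st_native_rev)
    interior_len <- cfg$chrom_length - 2 * tel_len - 2 * st_nat_len
    interior <- random_dna(interior_len)
    seqs[i] <- paste0(tel_rev, nat, interior, nat, tel_fwd)
    int_off <- tel_len + st_nat_len
    feats[[length(feats) + 1L]] <- data.frame(
      name = c("telL", "stL", "stR", "telR"),
      chrom = nm,
      start = c(0L, tel_len, int_off + interior_len,
                int_off + interior_len + st_nat_len),
      stop = c(tel_len, int_off, int_off + interior_len + st_nat_len,
               cfg$chrom_length),
      orientation = c("-", "+", "+", "+"),
      class = c("telomere", "subtelomere", "subtelomere", "telomere"),
      stringsAsFactors = FALSE)
    if (i == region_chrom) {
      need <- cfg$regionA_length + cfg$regionAB_gap + cfg$regionB_length
      posA <- int_off + (interior_len - need) %/% 2L      # 0-based on chrom
      posB <- posA + cfg$regionA_length + cfg$regionAB_gap
      regA <- c(posA, posA + cfg$regionA_length)
      regB <- c(posB, posB + cfg$regionB_length)
      feats[[length(feats) + 1L]] <- data.frame(
        name = c("Region-A", "Region-B"), chrom = nm,
        start = c(regA[1], regB[1]), stop = c(regA[2], regB[2]),
        orientation = "+", class = c("regionA", "regionB"),
        stringsAsFactors = FALSE)
    }
  }
  names(seqs) <- chrom_names
  feat_df <- do.call(rbind, feats)

  susceptible <- genome_model(seqs, feat_df)

  # cassette domain sequences (taken from the native susceptible copies)
  A_seq <- substr(seqs[[carrier]], regA[1] + 1L, regA[2])
  B_seq <- substr(seqs[[carrier]], regB[1] + 1L, regB[2])
  B1 <- substr(B_seq, 1L, cfg$regionB_prefix)
  B2 <- substr(B_seq, cfg$regionB_prefix + 1L, nchar(B_seq))
  I_seq <- random_dna(cfg$regionI_length)
  unit_c <- st_units[[carrier]]

  cc <- cfg$cassette_palindromic_units
  F_seq <- paste0(A_seq, B1, I_seq, B2)
  F_rc <- revcomp(F_seq)
  S_seq <- st_array(unit_c, cfg$st_small_fwd, cfg$st_small_rev)
  L_seq <- st_array(unit_c, cfg$st_large_fwd, cfg$st_large_rev)
  lenF <- nchar(F_seq); lenS <- nchar(S_seq); lenL <- nchar(L_seq)
  lenA <- cfg$regionA_length; lenI <- cfg$regionI_length
  pre <- cfg$regionB_prefix; lenB2 <- nchar(B2)

  junctions <- data.frame(name = character(), chrom = character(),
                          pos = integer(), stringsAsFactors = FALSE)
  cassette_feats <- NULL
  insertion <- ""
  if (cc > 0) {
    parts <- character(0)
    jn <- list()
    pos <- 0L   # position within insertion
    add_j <- function(name, p) jn[[length(jn) + 1L]] <<-
      data.frame(name = name, pos = p, stringsAsFactors = FALSE)
    unit_feats <- list()
    for (u in seq_len(cc)) {
      if (cfg$cassette_layout == "separated" || u == 1L) {
        parts <- c(parts, L_seq); pos <- pos + lenL
      }
      f0 <- pos
      add_j("STs-A", f0)
      add_j("A-B", f0 + lenA)
      add_j("B-I", f0 + lenA + pre)
      add_j("I-B", f0 + lenA + pre + lenI)
      add_j("B-ST", f0 + lenF)
      s0 <- f0 + lenF
      add_j("INV", s0 + cfg$st_unit_length * cfg$st_small_fwd)
      r0 <- s0 + lenS
      add_j("B-ST", r0)
      add_j("I-B", r0 + lenB2)
      add_j("B-I", r0 + lenB2 + lenI)
      add_j("A-B", r0 + lenB2 + lenI + pre)
      add_j("STs-A", r0 + lenF)
      parts <- c(parts, F_seq, S_seq, F_rc)
      unit_feats[[u]] <- data.frame(
        name = sprintf("cassette_unit_%d", u), start = f0, stop = r0 + lenF,
        stringsAsFactors = FALSE)
      pos <- r0 + lenF
    }
    parts <- c(parts, L_seq); pos <- pos + lenL
    insertion <- paste(parts, collapse = "")
    stopifnot(nchar(insertion) == pos)
    jdf <- do.call(rbind, jn)
    ip <- cfg$chrom_length - tel_len    # insert just before the right telomere
    junctions <- data.frame(name = jdf$name, chrom = carrier,
                            pos = jdf$pos + ip, stringsAsFactors = FALSE)
    uf <- do.call(rbind, unit_feats)
    cassette_feats <- data.frame(name = uf$name, chrom = carrier,
                                 start = uf$start + ip, stop = uf$stop + ip,
                                 orientation = "+", class = "cassette_unit",
                                 stringsAsFactors = FALSE)
  }

  # resistant genome: susceptible plus the insertion on the carrier chromosome
  res_seqs <- seqs
  ip <- cfg$chrom_length - tel_len
  if (nchar(insertion))
    res_seqs[carrier] <- paste0(substr(seqs[carrier], 1L, ip), insertion,
                                substr(seqs[carrier], ip + 1L,
                                       cfg$chrom_length))
  ins_len <- nchar(insertion)

  res_feats <- feat_df
  shift <- res_feats$chrom == carrier & res_feats$start >= ip
  res_feats$start[shift] <- res_feats$start[shift] + ins_len
  res_feats$stop[shift] <- res_feats$stop[shift] + ins_len
  if (!is.null(cassette_feats)) res_feats <- rbind(res_feats, cassette_feats)

  if (cfg$het && ins_len > 0) {
    alt <- paste0(carrier, "_hap2")
    res_seqs[[alt]] <- seqs[[carrier]]
    haps <- list(hap1 = chrom_names,
                 hap2 = c(setdiff(chrom_names, carrier), alt))
    resistant <- genome_model(res_seqs, res_feats, haplotypes = haps)
  } else {
    resistant <- genome_model(res_seqs, res_feats)
  }

  mult <- 1L + 2L * cc
  truth <- list(
    cnv_intervals = data.frame(
      chrom = carrier, start = c(regA[1], regB[1]), stop = c(regA[2], regB[2]),
      region = c("A", "B"), expected_multiplicity = mult,
      stringsAsFactors = FALSE),
    junctions = junctions,
    repeat_arrays = resistant_repeat_arrays(cfg, chrom_names, carrier, ip,
                                            ins_len, tel_len, st_nat_len),
    domains = list(A = A_seq, B1 = B1, B2 = B2, I = I_seq, B = B_seq,
                   st_unit = unit_c, st_unit_master = master_unit,
                   st_units = st_units, small_fwd = cfg$st_small_fwd,
                   small_rev = cfg$st_small_rev,
                   large_fwd = cfg$st_large_fwd,
                   large_rev = cfg$st_large_rev),
    insertion_length = ins_len,
    carrier = carrier,
    config = cfg)

  structure(list(susceptible = susceptible, resistant = resistant,
                 truth = truth), class = "sim_genomes")
}

# truth table of repeat arrays on resistant-genome coordinates
resistant_repeat_arrays <- function(cfg, chrom_names, carrier, ip, ins_len,
                                    tel_len, st_nat_len) {
  rows <- list()
  ul <- cfg$st_unit_length
  for (nm in chrom_names) {
    clen <- cfg$chrom_length + if (nm == carrier) ins_len else 0L
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = nm,
      start = c(0L, tel_len, clen - tel_len - st_nat_len, clen - tel_len),
      stop = c(tel_len, tel_len + st_nat_len, clen - tel_len, clen),
      unit_length = c(nchar(cfg$telomere_motif), ul, ul,
                      nchar(cfg$telomere_motif)),
      n_fwd = c(0L, cfg$st_native_fwd, cfg$st_native_fwd,
                cfg$telomere_copies_per_end),
      n_rev = c(cfg$telomere_copies_per_end, cfg$st_native_rev,
                cfg$st_native_rev, 0L),
      class = c("telomere", "subtelomere", "subtelomere", "telomere"),
      stringsAsFactors = FALSE)
  }
  cc <- cfg$cassette_palindromic_units
  if (cc > 0) {
    lenF <- cfg$regionA_length + cfg$regionB_length + cfg$regionI_length
    lenS <- ul * (cfg$st_small_fwd + cfg$st_small_rev)
    lenL <- ul * (cfg$st_large_fwd + cfg$st_large_rev)
    pos <- ip
    for (u in seq_len(cc)) {
      if (cfg$cassette_layout == "separated" || u == 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = carrier, start = pos, stop = pos + lenL, unit_length = ul,
          n_fwd = cfg$st_large_fwd, n_rev = cfg$st_large_rev,
          class = "st_large", stringsAsFactors = FALSE)
        pos <- pos + lenL
      }
      s0 <- pos + lenF
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = carrier, start = s0, stop = s0 + lenS, unit_length = ul,
        n_fwd = cfg$st_small_fwd, n_rev = cfg$st_small_rev,
        class = "st_small", stringsAsFactors = FALSE)
      pos <- s0 + lenS + lenF
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = carrier, start = pos, stop = pos + lenL, unit_length = ul,
      n_fwd = cfg$st_large_fwd, n_rev = cfg$st_large_rev,
      class = "st_large", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

default_length_params <- function(mode) {
  if (mode == "long")
    list(median = 12000, sdlog = 0.25)
  else
    list(read_length = 150L, insert_mean = 400, insert_sd = 30)
}

#' Simulate a read set from a genome model
#'
#' Draws reads uniformly from both haplotypes (so a heterozygous carrier
#' contributes cassette reads at half depth). Long mode draws read lengths
#' from a log-normal (default median 12 kb); short mode emits 150 bp pairs
#' with a Gaussian insert size. Reads are error-free by default; an optional
#' uniform substitution rate can be applied. Read origins are recorded for
#' truth comparison.
#'
#' @param genome a [genome_model()].
#' @param mode `"long"` (single-end) or `"short_paired"`.
#' @param coverage target fold coverage of the (mean) haploid genome length;
#'   0 gives an empty read set.
#' @param length_params list overriding mode defaults: `median`, `sdlog`
#'   (long); `read_length`, `insert_mean`, `insert_sd` (short).
#' @param seed integer RNG seed.
#' @param error_rate per-base substitution probability (default 0).
#' @return an object of class `read_set`: list with `reads` (data.table
#'   `id`, `seq` and, for pairs, `mate_seq`), `mode`, `coverage` and
#'   `origins` (data.table `id`, `chrom`, `start`, `strand`, `length`,
#'   0-based starts; paired mates have ids suffixed `/1`, `/2`).
#' @export
simulate_reads <- function(genome, mode = c("long", "short_paired"),
                           coverage, length_params = list(), seed = 1L,
                           error_rate = 0) {
  stopifnot(inherits(genome, "genome_model"))
  mode <- match.arg(mode)
  if (coverage < 0) stop("'coverage' must be >= 0", call. = FALSE)
  lp <- utils::modifyList(default_length_params(mode), length_params)
  set.seed(seed)

  empty <- data.table(id = character(), seq = character(),
                      mate_seq = character())
  empty_o <- data.table(id = character(), chrom = character(),
                        start = integer(), strand = character(),
                        length = integer())
  if (coverage == 0)
    return(structure(list(reads = empty, mode = mode, coverage = 0,
                          origins = empty_o), class = "read_set"))

  hap_lens <- vapply(genome$haplotypes, function(h)
    sum(nchar(genome$sequences[h])), 0)
  n_hap <- length(genome$haplotypes)

  reads <- list(); origins <- list(); ctr <- 0L
  for (h in seq_len(n_hap)) {
    hseqs <- genome$sequences[genome$haplotypes[[h]]]
    hlens <- nchar(hseqs)
    # each haplotype is present at 1/n_hap of the total depth, so its base
    # target scales with its own length (a longer carrier haplotype yields
    # more reads, at the same per-base depth)
    target <- coverage * hap_lens[h] / n_hap
    got <- 0
    while (got < target) {
      if (mode == "long") {
        n_draw <- max(50L, ceiling((target - got) / lp$median))
        lens <- pmax(200L, round(rlnorm(n_draw, log(lp$median), lp$sdlog)))
        ch <- sample(names(hlens), n_draw, replace = TRUE,
                     prob = hlens / sum(hlens))
        lens <- pmin(lens, hlens[ch])
        pos <- floor(runif(n_draw) * (hlens[ch] - lens + 1))
        sq <- substring(hseqs[ch], pos + 1, pos + lens)
        st <- sample(c("+", "-"), n_draw, replace = TRUE)
        sq[st == "-"] <- revcomp(sq[st == "-"])
        if (error_rate > 0)
          sq <- vapply(sq, mutate_dna, "", frac = error_rate)
        ids <- sprintf("sim_long_%07d", ctr + seq_len(n_draw))
        reads[[length(reads) + 1L]] <- data.table(id = ids, seq = sq,
                                                  mate_seq = NA_character_)
        # origin names the source chromosome sequence (not the haplotype)
        origins[[length(origins) + 1L]] <- data.table(
          id = ids, chrom = unname(ch), start = as.integer(pos),
          strand = st, length = as.integer(lens))
        got <- got + sum(lens); ctr <- ctr + n_draw
      } else {
        rl <- lp$read_length
        n_draw <- max(100L, ceiling((target - got) / (2 * rl)))
        fl <- pmax(2L * rl, round(rnorm(n_draw, lp$insert_mean,
                                        lp$insert_sd)))
        ch <- sample(names(hlens), n_draw, replace = TRUE,
                     prob = hlens / sum(hlens))
        fl <- pmin(fl, hlens[ch])
        pos <- floor(runif(n_draw) * (hlens[ch] - fl + 1))
        r1 <- substring(hseqs[ch], pos + 1, pos + rl)
        r2 <- revcomp(substring(hseqs[ch], pos + fl - rl + 1, pos + fl))
        if (error_rate > 0) {
          r1 <- vapply(r1, mutate_dna, "", frac = error_rate)
          r2 <- vapply(r2, mutate_dna, "", frac = error_rate)
        }
        ids <- sprintf("sim_pair_%07d", ctr + seq_len(n_draw))
        reads[[length(reads) + 1L]] <- data.table(id = ids, seq = unname(r1),
                                                  mate_seq = unname(r2))
        origins[[length(origins) + 1L]] <- data.table(
          id = as.vector(rbind(paste0(ids, "/1"), paste0(ids, "/2"))),
          chrom = rep(unname(ch), each = 2L),
          start = as.integer(as.vector(rbind(pos, pos + fl - rl))),
          strand = rep(c("+", "-"), n_draw),
          length = rl)
        got <- got + 2 * rl * n_draw; ctr <- ctr + n_draw
      }
    }
  }
  structure(list(reads = rbindlist(reads), mode = mode, coverage = coverage,
                 origins = rbindlist(origins)), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d %s read(s), target coverage %gx\n",
              nrow(x$reads), x$mode, x$coverage))
  invisible(x)
}

#' Simulate a per-gene differential-expression table
#'
#' Emits a per-gene table of log2 fold-changes and p-values with configured
#' numbers of truly overexpressed genes per cassette region; null genes draw
#' uniform p-values and sub-threshold fold-changes, and optionally some
#' records carry missing statistics (genes filtered during DE processing, as
#' happens in real pipelines). Defaults mirror the characterized system:
#' five Region-A genes of which four are overexpressed, four Region-B genes
#' of which one is overexpressed and one is filtered.
#'
#' @param n_regionA,n_regionB genes per region.
#' @param n_sig_A,n_sig_B truly overexpressed genes per region.
#' @param n_filtered_B Region-B records with missing statistics.
#' @param seed integer RNG seed.
#' @return data.table with columns `gene_id`, `label`, `region`, `log2fc`,
#'   `p_value`.
#' @export
simulate_de_table <- function(n_regionA = 5L, n_regionB = 4L,
                              n_sig_A = 4L, n_sig_B = 1L,
                              n_filtered_B = 1L, seed = 1L) {
  stopifnot(n_sig_A <= n_regionA, n_sig_B + n_filtered_B <= n_regionB)
  set.seed(seed)
  make <- function(region, n, n_sig, n_filt) {
    sig <- c(rep(TRUE, n_sig), rep(FALSE, n - n_sig))
    filt <- c(rep(FALSE, n - n_filt), rep(TRUE, n_filt)) & !sig
    lfc <- ifelse(sig, runif(n, 4, 6), runif(n, -1, 0.9))
    p <- ifelse(sig, 10^runif(n, -14, -9), runif(n))
    lfc[filt] <- NA_real_; p[filt] <- NA_real_
    data.table(gene_id = sprintf("gene_%s%02d", region, seq_len(n)),
               label = sprintf("%s%d00", region, seq_len(n) + 3L),
               region = region, log2fc = round(lfc, 2),
               p_value = signif(p, 3))
  }
  rbindlist(list(make("A", n_regionA, n_sig_A, 0L),
                 make("B", n_regionB, n_sig_B, n_filtered_B)))
}
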