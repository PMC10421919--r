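#' Pipeline configuration
#'
#' Assembles the full-run configuration: a desk-scale simulation (smaller
#' chromosomes and domains than the generator defaults, chosen so a complete
#' run is minutes on one CPU, while keeping the architecture constants — the
#' 451 bp subtelomeric unit, the 12F/31R small inverted array, and 11
#' palindromic cassette units giving 1 + 2c = 23 copies), panel sizes, read
#' coverages, the CNV window, and thresholds.
#'
#' @param sim a [sim_config()]; the default is the desk-scale study
#'   configuration described in the methods vignette.
#' @param n_resistant,n_susceptible panel sizes.
#' @param coverage_short short-read coverage per sample (default 30).
#' @param coverage_long long-read coverage for junction validation
#'   (default 40).
#' @param window CNV window size in bp for this genome scale (default 500).
#' @param min_anchor junction spanning-read anchor (default 100).
#' @param k seed k-mer size (default 21).
#' @param thresholds a [threshold_config()].
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL,
                            n_resistant = 3L, n_susceptible = 3L,
                            coverage_short = 30, coverage_long = 40,
                            window = 500L, min_anchor = 100L, k = 21L,
                            thresholds = threshold_config()) {
  if (is.null(sim))
    sim <- sim_config(n_chromosomes = 3L, chrom_length = 150000L,
                      telomere_copies_per_end = 30L,
                      st_unit_length = 451L, st_unit_divergence = 0.02,
                      st_native_fwd = 8L, st_native_rev = 12L,
                      regionA_length = 2000L, regionB_length = 2400L,
                      regionI_length = 400L, regionAB_gap = 6000L,
                      regionB_prefix = 400L, region_chrom = 3L,
                      cassette_palindromic_units = 11L,
                      st_small_fwd = 12L, st_small_rev = 31L,
                      st_large_fwd = 6L, st_large_rev = 9L)
  structure(list(sim = sim, n_resistant = as.integer(n_resistant),
                 n_susceptible = as.integer(n_susceptible),
                 coverage_short = coverage_short,
                 coverage_long = coverage_long,
                 window = as.integer(window),
                 min_anchor = as.integer(min_anchor), k = as.integer(k),
                 thresholds = thresholds),
            class = "pipeline_config")
}

#' Run the full pipeline on simulated data
#'
#' Executes simulate, map, depth/CNV, consensus, cassette-junction,
#' repeat and expression stages on a simulated susceptible/resistant panel
#' and computes truth-recovery metrics: precision/recall of consensus events
#' against the truth CNV intervals (50% reciprocal overlap), copy-number
#' relative error at the amplified region, the architecture call with its
#' inversion-point ratio, and the detected subtelomeric unit. A fixed seed
#' gives an identical report; the top-level seed fans out to per-stage seeds
#' via [derive_seed()].
#'
#' @param config a [pipeline_config()].
#' @param seed integer run seed.
#' @param outdir output directory for stage TSVs and the report JSON;
#'   `NULL` for a temporary directory.
#' @return a list of class `run_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(outdir)) outdir <- tempfile("subtelcnv_run_")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  log_line <- function(...) message(sprintf(...))

  # -- simulate ------------------------------------------------------------
  sims <- stage("simulate", {
    cfg <- config$sim
    cfg$seed <- derive_seed(seed, "simulate")
    validate_sim_config(cfg)
    build_genomes(cfg)
  })
  truth <- sims$truth
  log_line("stage simulate: %d chromosome(s), insertion %d bp",
           config$sim$n_chromosomes, truth$insertion_length)

  # -- short reads + mapping + depth per sample ----------------------------
  ref <- sims$susceptible
  idx <- stage("index", build_index(ref, k = config$k))
  seq_lens <- setNames(nchar(ref$sequences), names(ref$sequences))

  sample_track <- function(genome, sample_name) {
    rs <- simulate_reads(genome, "short_paired", config$coverage_short,
                         seed = derive_seed(seed, sample_name))
    aln <- map_reads(rs, idx, seed = derive_seed(seed,
                                                 paste0(sample_name, "_map")))
    tr <- window_depth(aln, window = config$window, seq_lengths = seq_lens)
    normalize_depth(tr)
  }
  r_tracks <- stage("depth_resistant", lapply(
    seq_len(config$n_resistant), function(i)
      sample_track(sims$resistant, sprintf("R%02d", i))))
  s_tracks <- stage("depth_susceptible", lapply(
    seq_len(config$n_susceptible), function(i)
      sample_track(sims$susceptible, sprintf("S%02d", i))))
  r_segs <- lapply(r_tracks, call_segments, thresholds = config$thresholds)
  s_segs <- lapply(s_tracks, call_segments, thresholds = config$thresholds)
  log_line("stage depth: %d resistant, %d susceptible track(s)",
           length(r_segs), length(s_segs))

  # -- consensus -----------------------------------------------------------
  events <- stage("consensus",
                  consensus_events(r_segs, s_segs, config$thresholds))
  write_cnv_catalogue(events, file.path(outdir, "consensus_events.tsv"))
  log_line("stage consensus: %d event(s)", nrow(events))

  # -- truth comparison: precision/recall at 50% reciprocal overlap --------
  tr_cnv <- truth$cnv_intervals
  matched_truth <- logical(nrow(tr_cnv))
  matched_event <- logical(nrow(events))
  if (nrow(events)) {
    for (t in seq_len(nrow(tr_cnv))) {
      t0 <- tr_cnv$start[t]; t1 <- tr_cnv$stop[t]
      for (e in seq_len(nrow(events))) {
        if (events$seq_name[e] != tr_cnv$chrom[t]) next
        e0 <- events$start[e] - 1L; e1 <- events$stop[e]
        ov <- min(t1, e1) - max(t0, e0)
        if (ov >= 0.5 * (t1 - t0) && ov >= 0.5 * (e1 - e0)) {
          matched_truth[t] <- TRUE
          matched_event[e] <- TRUE
        }
      }
    }
  }
  recall <- if (nrow(tr_cnv)) mean(matched_truth) else NA_real_
  precision <- if (nrow(events)) mean(matched_event) else NA_real_

  # -- copy number at the amplified region ---------------------------------
  copies <- rel_err <- NA_real_
  zygosity <- NA_character_
  if (length(r_tracks)) {
    a_int <- tr_cnv[tr_cnv$region == "A", ]
    gap0 <- a_int$stop + 500L
    gap1 <- tr_cnv[tr_cnv$region == "B", "start"] - 500L
    est <- vapply(r_tracks, function(tr) {
      bg <- estimate_copy_number(tr, a_int$chrom, gap0, gap1)$copies
      estimate_copy_number(tr, a_int$chrom, a_int$start, a_int$stop,
                           background_fold = bg)$copies
    }, 0)
    copies <- est[1L]
    zygosity <- estimate_copy_number(
      r_tracks[[1L]], a_int$chrom, a_int$start, a_int$stop,
      background_fold = estimate_copy_number(r_tracks[[1L]], a_int$chrom,
                                             gap0, gap1)$copies,
      cohort_copies = est)$zygosity
    truth_mult <- a_int$expected_multiplicity
    rel_err <- abs(copies - truth_mult) / truth_mult
  }

  # -- cassette junction validation ----------------------------------------
  arch <- "unsupported"; inv_ratio <- NA_real_; support <- NULL
  if (config$sim$cassette_palindromic_units > 0) {
    long <- stage("long_reads",
                  simulate_reads(sims$resistant, "long",
                                 config$coverage_long,
                                 seed = derive_seed(seed, "long_reads")))
    model <- cassette_model_from_truth(truth)
    support <- stage("junctions",
                     count_junction_support(long, model,
                                            min_anchor = config$min_anchor,
                                            k = config$k,
                                            seed = derive_seed(seed,
                                                               "junctions")))
    fwrite(support, file.path(outdir, "junction_support.tsv"), sep = "\t")
    arch <- infer_architecture(support)
    inv_ratio <- attr(arch, "inv_ratio")
    log_line("stage cassette: architecture %s (INV ratio %.3f)",
             as.character(arch), inv_ratio)
  } else {
    support <- count_junction_support(
      empty_alignments(),
      cassette_model_from_truth_zero_safe(truth),
      min_anchor = config$min_anchor)
    arch <- "unsupported"
  }

  # -- repeats --------------------------------------------------------------
  rep_res <- stage("repeats", {
    tel <- find_motif_arrays(sims$resistant,
                             motif = config$sim$telomere_motif,
                             min_copies = 10L)
    ra <- truth$repeat_arrays
    st_small <- ra[ra$class == "st_small", ][1, ]
    unit_len <- NA_integer_; ori <- c(n_fwd = NA_integer_,
                                      n_rev = NA_integer_)
    if (!is.na(st_small$chrom)) {
      arr_seq <- substr(sims$resistant$sequences[[st_small$chrom]],
                        st_small$start + 1L, st_small$stop)
      du <- detect_unit(arr_seq, max_period = 1500L)
      if (!is.null(du)) {
        unit_len <- du$unit_length
        ori <- count_orientations(arr_seq, truth$domains$st_unit)
      }
    }
    units <- c(truth$domains$st_units,
               cassette = truth$domains$st_unit)
    dm <- 100 - identity_matrix(units)
    diag(dm) <- 0
    tree <- nj_tree(dm)
    list(n_telomere_arrays = nrow(tel), unit_length = unit_len,
         n_fwd = unname(ori["n_fwd"]), n_rev = unname(ori["n_rev"]),
         newick = ape::write.tree(tree))
  })

  # -- expression -----------------------------------------------------------
  de <- stage("expression", {
    tab <- simulate_de_table(seed = derive_seed(seed, "expression"))
    summarize_de(tab, config$thresholds)
  })

  report <- structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    config = config,
    n_events = nrow(events),
    consensus_recall = recall,
    consensus_precision = precision,
    copies_regionA = copies,
    copy_rel_error = rel_err,
    zygosity = zygosity,
    architecture_call = as.character(arch),
    inv_ratio = inv_ratio,
    junction_support = if (!is.null(support)) as.data.frame(support),
    repeats = rep_res,
    de_summary = as.data.frame(de)), class = "run_report")
  write_run_report(report, file.path(outdir, "run_report.json"))
  report
}

cassette_model_from_truth_zero_safe <- function(truth) {
  d <- truth$domains
  build_cassette_model(
    list(A = d$A, B1 = d$B1, B2 = d$B2, I = d$I,
         ST_large = st_array(d$st_unit, max(1L, d$large_fwd),
                             max(1L, d$large_rev)),
         ST_small_f = strrep(d$st_unit, max(1L, d$small_fwd)),
         ST_small_r = strrep(d$st_unit, max(1L, d$small_rev))),
    palindromic_cassette_layout())
}

#' Write a run report as JSON
#'
#' @param report a `run_report`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_run_report <- function(report, path) {
  out <- report
  out$config <- NULL   # the config echo is serialized flat
  out$config_echo <- list(
    sim = unclass(report$config$sim),
    n_resistant = report$config$n_resistant,
    n_susceptible = report$config$n_susceptible,
    coverage_short = report$config$coverage_short,
    coverage_long = report$config$coverage_long,
    window = report$config$window,
    min_anchor = report$config$min_anchor,
    thresholds = unclass(report$config$thresholds))
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("subtelcnv run report (seed", x$seed, ")\n")
  cat(sprintf("  consensus events: %d (recall %.2f, precision %.2f)\n",
              x$n_events, x$consensus_recall, x$consensus_precision))
  cat(sprintf("  Region-A copies: %.2f (rel. error %.3f, zygosity %s)\n",
              x$copies_regionA, x$copy_rel_error, x$zygosity))
  cat(sprintf("  architecture: %s (INV ratio %.3f)\n",
              x$architecture_call, x$inv_ratio))
  cat(sprintf("  ST unit: %s bp, orientations %s F / %s R\n",
              x$repeats$unit_length, x$repeats$n_fwd, x$repeats$n_rev))
  invisible(x)
}
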