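#' Group-exclusive consensus duplication events
#'
#' Intersects per-sample CNV segments across a resistant and a susceptible
#' panel: an event is a maximal interval where every resistant sample has an
#' overlapping duplication segment and no susceptible sample does. The event
#' interval is the intersection of the resistant samples' overlapping
#' segments; events are numbered `CNV1...` in genomic order. Any overlap of
#' at least one base counts as presence by default; a minimum overlap
#' fraction of the event can be required for the susceptible exclusion.
#'
#' @param r_segments list of `cnv_segments` (one per resistant sample).
#' @param s_segments list of `cnv_segments` (one per susceptible sample).
#' @param thresholds a [threshold_config()] (supplies `dup_fold` context for
#'   validation only; segments carry their states).
#' @param min_overlap_frac minimum fraction of an event that a susceptible
#'   duplication must overlap to veto it (default 0: any overlap vetoes).
#' @param pseudomolecule_pattern regex classifying sequence names as
#'   pseudomolecules; all other sequences are scaffolds.
#' @return a data.table of class `cnv_events` with columns `event_id`,
#'   `seq_name`, `start`, `stop` (1-based, `length = stop - start` as in the
#'   catalogue convention), `length`, `mean_depth` (mean over resistant
#'   samples), per-sample `depth_<i>` columns, `seq_class`, `flagged`.
#' @export
consensus_events <- function(r_segments, s_segments,
                             thresholds = threshold_config(),
                             min_overlap_frac = 0,
                             pseudomolecule_pattern = "^Chr") {
  if (!length(r_segments) || !is.list(r_segments))
    stop("need at least one resistant sample", call. = FALSE)
  if (!is.list(s_segments))
    stop("'s_segments' must be a list (possibly empty)", call. = FALSE)

  dup_of <- function(segs) as.data.table(segs)[state == "duplication"]
  r_dups <- lapply(r_segments, dup_of)
  s_dups <- lapply(s_segments, dup_of)

  chroms <- unique(unlist(lapply(r_dups, function(d) d$chrom)))
  if (!length(chroms)) return(empty_events())
  chroms <- chroms[order_seqnames(chroms)]

  ev <- list()
  for (nm in chroms) {
    ir <- lapply(r_dups, function(d) {
      dd <- d[chrom == nm]
      IRanges::IRanges(dd$start + 1L, dd$stop)
    })
    common <- Reduce(IRanges::intersect, ir)
    if (!length(common)) next
    # susceptible exclusion: by default, any base duplicated in any
    # susceptible sample is subtracted (per-base semantics, matching a
    # bedtools-style intersect/subtract chain); with min_overlap_frac > 0 an
    # event is instead vetoed wholesale when a susceptible duplication covers
    # at least that fraction of it
    if (length(s_dups)) {
      sd_all <- rbindlist(lapply(s_dups, function(d) d[chrom == nm]))
      if (nrow(sd_all)) {
        s_ir <- IRanges::reduce(IRanges::IRanges(sd_all$start + 1L,
                                                 sd_all$stop))
        if (min_overlap_frac == 0) {
          common <- IRanges::setdiff(common, s_ir)
        } else {
          ov <- IRanges::findOverlaps(common, s_ir)
          if (length(ov)) {
            ow <- IRanges::width(IRanges::pintersect(
              common[S4Vectors::queryHits(ov)],
              s_ir[S4Vectors::subjectHits(ov)]))
            frac <- ow / IRanges::width(common[S4Vectors::queryHits(ov)])
            veto <- unique(S4Vectors::queryHits(ov)[frac >=
                                                      min_overlap_frac])
            if (length(veto)) common <- common[-veto]
          }
        }
      }
    }
    if (!length(common)) next
    # per-sample mean depth over each event (overlap-weighted)
    depths <- vapply(seq_along(r_dups), function(si) {
      dd <- r_dups[[si]][chrom == nm]
      d_ir <- IRanges::IRanges(dd$start + 1L, dd$stop)
      vapply(seq_along(common), function(ei) {
        ov <- IRanges::findOverlaps(common[ei], d_ir)
        hits <- S4Vectors::subjectHits(ov)
        ow <- IRanges::width(IRanges::pintersect(
          rep(common[ei], length(hits)), d_ir[hits]))
        sum(dd$mean_norm_depth[hits] * ow) / sum(ow)
      }, 0)
    }, numeric(length(common)))
    depths <- matrix(depths, nrow = length(common))
    ev[[length(ev) + 1L]] <- data.table(
      seq_name = nm,
      start = IRanges::start(common),             # 1-based
      stop = IRanges::end(common),
      mean_depth = rowMeans(depths),
      depth_mat = depths)
  }
  if (!length(ev)) return(empty_events())
  out <- rbindlist(ev)
  dm <- as.matrix(out[, grep("^depth_mat", names(out)), with = FALSE])
  colnames(dm) <- sprintf("depth_%d", seq_len(ncol(dm)))
  out <- out[, .(seq_name, start, stop, mean_depth)]
  out[, `:=`(event_id = sprintf("CNV%d", seq_len(.N)),
             length = stop - start,
             seq_class = ifelse(grepl(pseudomolecule_pattern, seq_name),
                                "pseudomolecule", "scaffold"),
             flagged = FALSE)]
  out <- cbind(out, as.data.table(dm))
  data.table::setcolorder(out, c("event_id", "seq_name", "start", "stop",
                                 "length", "mean_depth", "seq_class",
                                 "flagged"))
  data.table::setattr(out, "class", c("cnv_events", class(out)))
  out
}

empty_events <- function() {
  out <- data.table(event_id = character(), seq_name = character(),
                    start = integer(), stop = integer(), length = integer(),
                    mean_depth = numeric(), seq_class = character(),
                    flagged = logical())
  data.table::setattr(out, "class", c("cnv_events", class(out)))
  out
}

#' Event length under the catalogue convention
#'
#' Catalogue coordinates are written with a 1-based start and a stop such
#' that the printed length equals `stop - start` (not `stop - start + 1`).
#'
#' @param event one or more catalogue rows (data.frame with `start`, `stop`).
#' @return integer vector of lengths.
#' @export
event_length <- function(event) {
  if (any(event$stop < event$start))
    stop("'stop' must be >= 'start'", call. = FALSE)
  as.integer(event$stop - event$start)
}

#' Classify and summarize a consensus event catalogue
#'
#' Reports the total event count, counts by sequence class (pseudomolecule
#' vs scaffold), the high-copy subset (mean depth strictly above
#' `high_copy_fold`), and that subset with designated regions of interest
#' (e.g. the cassette's Region-A/B events) excluded.
#'
#' @param events a `cnv_events` table (or the catalogue fixture from
#'   [read_cnv_catalogue()]).
#' @param thresholds a [threshold_config()].
#' @param region_labels optional named character vector mapping `event_id`
#'   to region labels (e.g. `c(CNV2 = "Region-A")`); a `label` column on
#'   `events` is used if present.
#' @return a list of class `cnv_report`: `n_total`, `n_by_class`,
#'   `high_copy_ids`, `high_copy_excl_labeled`, `labels`.
#' @export
classify_and_summarize <- function(events, thresholds = threshold_config(),
                                   region_labels = NULL) {
  ev <- as.data.table(events)
  if (is.null(region_labels) && "label" %in% names(ev)) {
    lab <- ev$label
    names(lab) <- ev$event_id
    region_labels <- lab[!is.na(lab) & nzchar(lab)]
  }
  if (!nrow(ev))
    return(structure(list(n_total = 0L,
                          n_by_class = c(pseudomolecule = 0L, scaffold = 0L),
                          high_copy_ids = character(),
                          high_copy_excl_labeled = character(),
                          labels = region_labels), class = "cnv_report"))
  by_class <- table(factor(ev$seq_class,
                           levels = c("pseudomolecule", "scaffold")))
  hc <- ev$event_id[ev$mean_depth > thresholds$high_copy_fold]
  hc_excl <- setdiff(hc, names(region_labels))
  structure(list(n_total = nrow(ev),
                 n_by_class = c(by_class),
                 high_copy_ids = hc,
                 high_copy_excl_labeled = hc_excl,
                 labels = region_labels),
            class = "cnv_report")
}

#' @export
print.cnv_report <- function(x, ...) {
  cat(sprintf("consensus CNV report: %d event(s) (%d pseudomolecule, %d scaffold)\n",
              x$n_total, x$n_by_class[["pseudomolecule"]],
              x$n_by_class[["scaffold"]]))
  cat(sprintf("high-copy events: %s\n",
              if (length(x$high_copy_ids))
                paste(x$high_copy_ids, collapse = ", ") else "none"))
  cat(sprintf("high-copy excluding labeled regions: %s\n",
              if (length(x$high_copy_excl_labeled))
                paste(x$high_copy_excl_labeled, collapse = ", ") else "none"))
  invisible(x)
}

#' Write a consensus event catalogue as TSV
#'
#' Columns mirror the catalogue convention: 1-based start, stop with
#' `length = stop - start`, mean depth across resistant samples, sequence
#' class, and optional flags/labels.
#'
#' @param events a `cnv_events` table.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_cnv_catalogue <- function(events, path) {
  cols <- intersect(c("event_id", "seq_name", "start", "stop", "length",
                      "mean_depth", "seq_class", "flagged", "label"),
                    names(events))
  fwrite(as.data.table(events)[, cols, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' Read a consensus event catalogue TSV
#'
#' @param path TSV written by [write_cnv_catalogue()] (or the transcribed
#'   catalogue fixture shipped with the package).
#' @return a `cnv_events` data.table.
#' @export
read_cnv_catalogue <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("event_id", "seq_name", "start", "stop", "length", "mean_depth")
  if (!all(need %in% names(dt)))
    stop("catalogue must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"seq_class" %in% names(dt))
    dt[, seq_class := ifelse(grepl("^Chr", seq_name), "pseudomolecule",
                             "scaffold")]
  if (!"flagged" %in% names(dt)) dt[, flagged := FALSE]
  data.table::setattr(dt, "class", c("cnv_events", class(dt)))
  dt
}
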