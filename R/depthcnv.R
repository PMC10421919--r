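#' Thresholds for CNV calling and expression filtering
#'
#' Bundles the fold and significance thresholds used across the pipeline:
#' windows below `del_fold` of the average read depth are deletion
#' candidates, windows above `dup_fold` duplication candidates, non-neutral
#' segments with p-value above `alpha` are demoted to neutral, events above
#' `high_copy_fold` are the high-copy class, and differential-expression
#' records are significant at `p < de_p` and fold-change `> de_fc`.
#'
#' @param del_fold deletion fold threshold (default 0.25).
#' @param dup_fold duplication fold threshold (default 4).
#' @param alpha segment significance level (default 0.01).
#' @param high_copy_fold high-copy-number fold (default 20).
#' @param de_p differential-expression p-value threshold (default 0.01).
#' @param de_fc differential-expression fold-change threshold (default 2,
#'   i.e. log2 fold-change strictly greater than 1).
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(del_fold = 0.25, dup_fold = 4.0, alpha = 0.01,
                             high_copy_fold = 20.0, de_p = 0.01,
                             de_fc = 2.0) {
  if (!(del_fold > 0 && del_fold < 1 && 1 < dup_fold &&
          dup_fold < high_copy_fold))
    stop("need 0 < del_fold < 1 < dup_fold < high_copy_fold", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0,1)",
                                     call. = FALSE)
  structure(list(del_fold = del_fold, dup_fold = dup_fold, alpha = alpha,
                 high_copy_fold = high_copy_fold, de_p = de_p,
                 de_fc = de_fc), class = "threshold_config")
}

#' Windowed read depth from alignments
#'
#' Tiles each reference sequence with fixed windows (default 5 kb) and
#' reports, per window, the aligned bases overlapping the window divided by
#' the window length; a trailing partial window is normalized by its actual
#' length. All mapped alignment blocks contribute, including both rows of
#' split reads.
#'
#' @param alignments an `alignments` table ([map_reads()] or
#'   [import_alignments()]).
#' @param window window size in bp (default 5000).
#' @param seq_lengths named vector of reference sequence lengths (required:
#'   windows tile the full reference, not just the covered extent).
#' @return a data.table of class `depth_track` with columns `chrom`, `start`,
#'   `end` (0-based half-open), `width`, `bases`, `depth`; attribute
#'   `window`; `norm` is added by [normalize_depth()].
#' @export
window_depth <- function(alignments, window = 5000L, seq_lengths) {
  if (window <= 0) stop("'window' must be > 0", call. = FALSE)
  if (missing(seq_lengths) || is.null(names(seq_lengths)))
    stop("'seq_lengths' must be a named vector", call. = FALSE)
  aln <- as.data.table(alignments)[mapped == TRUE]
  tracks <- lapply(names(seq_lengths), function(nm) {
    len <- as.integer(seq_lengths[[nm]])
    starts <- seq.int(0L, len - 1L, by = window)
    ends <- pmin(starts + as.integer(window), len)
    a <- aln[ref == nm]
    bases <- numeric(length(starts))
    if (nrow(a)) {
      cov <- IRanges::coverage(IRanges::IRanges(a$start + 1L, a$stop),
                               width = len)
      v <- IRanges::Views(cov, starts + 1L, ends)
      bases <- as.numeric(IRanges::viewSums(v))
    }
    data.table(chrom = nm, start = starts, end = ends,
               width = ends - starts, bases = bases,
               depth = bases / (ends - starts))
  })
  tr <- rbindlist(tracks)
  data.table::setattr(tr, "window", as.integer(window))
  data.table::setattr(tr, "normalized", FALSE)
  data.table::setattr(tr, "class", c("depth_track", class(tr)))
  tr
}

#' Normalize a depth track to fold of average read depth
#'
#' Divides window depths by the genome-wide mean window depth (or an
#' externally supplied baseline, e.g. a mean pooled across samples), so the
#' normalized track has mean 1 and fold values read directly as copy-number
#' proxies.
#'
#' @param track a [window_depth()] track.
#' @param baseline average depth to divide by; default is the track's own
#'   mean window depth.
#' @return the track with a `norm` column and attributes `normalized = TRUE`,
#'   `baseline`.
#' @export
normalize_depth <- function(track, baseline = NULL) {
  stopifnot(inherits(track, "depth_track"))
  if (is.null(baseline)) baseline <- mean(track$depth)
  if (!is.finite(baseline) || baseline <= 0)
    stop("cannot normalize an all-zero depth track", call. = FALSE)
  track[, norm := depth / baseline]
  data.table::setattr(track, "normalized", TRUE)
  data.table::setattr(track, "baseline", baseline)
  track
}

#' Call CNV segments from a normalized depth track
#'
#' Labels each window by the fold thresholds (strictly below `del_fold` of
#' the average read depth: deletion; strictly above `dup_fold`: duplication;
#' fold exactly at a threshold is neutral), merges adjacent same-state
#' windows into segments, and tests each non-neutral segment's window folds
#' against 1.0 with a two-sided one-sample t-test (for segments of a single
#' window, a normal approximation using the global window variance).
#' Non-neutral segments with p-value above `alpha` are demoted to neutral.
#' Segments tile the full track extent per chromosome. No multiple-testing
#' correction is applied.
#'
#' @param track a normalized [window_depth()] track.
#' @param thresholds a [threshold_config()].
#' @return a data.table of class `cnv_segments`: `chrom`, `start`, `stop`
#'   (0-based half-open), `state` (`deletion`/`neutral`/`duplication`),
#'   `mean_norm_depth`, `p_value`, `n_windows`.
#' @export
call_segments <- function(track, thresholds = threshold_config()) {
  stopifnot(inherits(track, "depth_track"),
            inherits(thresholds, "threshold_config"))
  if (!isTRUE(attr(track, "normalized")) || is.null(track$norm))
    stop("track must be normalized first (see normalize_depth())",
         call. = FALSE)
  gvar <- var(track$norm)
  if (!is.finite(gvar)) gvar <- 0
  segs <- list()
  for (nm in unique(track$chrom)) {
    tr <- track[chrom == nm]
    lab <- ifelse(tr$norm > thresholds$dup_fold, "duplication",
                  ifelse(tr$norm < thresholds$del_fold, "deletion",
                         "neutral"))
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts_i <- ends - r$lengths + 1L
    for (si in seq_along(r$values)) {
      idx <- starts_i[si]:ends[si]
      x <- tr$norm[idx]
      st <- r$values[si]
      p <- NA_real_
      if (st != "neutral") {
        p <- segment_p_value(x, gvar)
        if (is.na(p) || p > thresholds$alpha) st <- "neutral"
      }
      segs[[length(segs) + 1L]] <- data.table(
        chrom = nm, start = tr$start[idx[1L]], stop = tr$end[idx[length(idx)]],
        state = st, mean_norm_depth = mean(x),
        p_value = if (st == "neutral") NA_real_ else p,
        n_windows = length(idx))
    }
  }
  out <- rbindlist(segs)
  # re-merge neutral runs created by demotion
  out <- merge_same_state(out)
  data.table::setattr(out, "class", c("cnv_segments", class(out)))
  out
}

segment_p_value <- function(x, gvar) {
  n <- length(x)
  if (n >= 2L && var(x) > 0) {
    return(t.test(x, mu = 1)$p.value)
  }
  # single window (or zero-variance segment): normal approximation with the
  # global window variance
  if (gvar <= 0) return(if (all(x == 1)) 1 else 0)
  z <- (mean(x) - 1) / sqrt(gvar / n)
  2 * pnorm(-abs(z))
}

merge_same_state <- function(segs) {
  out <- list()
  for (nm in unique(segs$chrom)) {
    s <- segs[chrom == nm]
    keep_i <- 1L
    acc <- s[1L]
    for (r in seq_len(nrow(s))[-1L]) {
      if (s$state[r] == acc$state && s$start[r] == acc$stop) {
        w_old <- acc$n_windows; w_new <- s$n_windows[r]
        acc$mean_norm_depth <- (acc$mean_norm_depth * w_old +
                                  s$mean_norm_depth[r] * w_new) /
          (w_old + w_new)
        acc$stop <- s$stop[r]
        acc$n_windows <- w_old + w_new
        if (acc$state == "neutral") acc$p_value <- NA_real_
      } else {
        out[[length(out) + 1L]] <- acc
        acc <- s[r]
      }
      keep_i <- keep_i + 1L
    }
    out[[length(out) + 1L]] <- acc
  }
  rbindlist(out)
}

#' Estimate copy number and zygosity over an interval
#'
#' Copy number is the mean normalized depth over the interval divided by
#' `background_fold`. When cohort copy estimates are supplied, zygosity is
#' called `het` if the estimate falls in a band around half the cohort's
#' modal copy number (a heterozygous carrier contributes the amplification on
#' only one haplotype, halving the depth signal), `hom` if near the mode, and
#' `na` otherwise. The mode is taken as the cohort median (robust for the
#' small panels used here).
#'
#' @param track a normalized [window_depth()] track.
#' @param chrom,start,stop target interval (0-based half-open).
#' @param background_fold normalized depth of the neutral background
#'   (default 1; pass e.g. the mean normalized depth of a known-neutral
#'   interval when the amplified mass is a large fraction of the simulated
#'   genome).
#' @param cohort_copies optional numeric vector of the cohort's copy
#'   estimates at the same locus.
#' @param het_band,hom_band bands (fractions of the modal copies) for the
#'   het and hom calls.
#' @return list with `copies` (fold) and `zygosity` (`"hom"`, `"het"`, or
#'   `"na"`).
#' @export
estimate_copy_number <- function(track, chrom, start, stop,
                                 background_fold = 1.0,
                                 cohort_copies = NULL,
                                 het_band = c(0.35, 0.65),
                                 hom_band = c(0.8, 1.25)) {
  stopifnot(inherits(track, "depth_track"))
  if (!isTRUE(attr(track, "normalized")))
    stop("track must be normalized first", call. = FALSE)
  if (stop <= start) stop("empty interval", call. = FALSE)
  ch <- chrom; s0 <- start; e0 <- stop
  win <- track[chrom == ch & end > s0 & start < e0]
  if (!nrow(win)) stop("interval not covered by track", call. = FALSE)
  # windows straddling the interval boundary mix in flanking signal; use
  # fully contained windows when the interval holds at least one
  full <- win[start >= s0 & end <= e0]
  if (nrow(full)) win <- full
  copies <- mean(win$norm) / background_fold
  zyg <- "na"
  if (!is.null(cohort_copies) && length(cohort_copies)) {
    mode_c <- median(cohort_copies)
    ratio <- copies / mode_c
    if (ratio >= het_band[1] && ratio <= het_band[2]) zyg <- "het"
    else if (ratio >= hom_band[1] && ratio <= hom_band[2]) zyg <- "hom"
  }
  list(copies = copies, zygosity = zyg)
}
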