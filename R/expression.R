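#' Significance of differential-expression records
#'
#' A record is significantly overexpressed when its statistics are present,
#' `p_value < de_p`, and `log2fc > log2(de_fc)` — both strictly, so a gene at
#' exactly 2-fold change (log2FC = 1) is not significant. Records with
#' missing statistics (genes filtered during DE processing) are never
#' significant but stay in denominators.
#'
#' @param log2fc numeric vector of log2 fold-changes (NA = missing).
#' @param p_value numeric vector of p-values (NA = missing).
#' @param thresholds a [threshold_config()].
#' @return logical vector.
#' @export
de_significant <- function(log2fc, p_value,
                           thresholds = threshold_config()) {
  !is.na(p_value) & !is.na(log2fc) &
    p_value < thresholds$de_p & log2fc > log2(thresholds$de_fc)
}

#' Summarize differential expression per cassette region
#'
#' Applies the significance filter to a per-gene DE table and counts
#' significant and total genes per region label. Records with unknown region
#' labels are assigned to `"other"` with a warning; records with missing
#' statistics count toward totals but never toward significance.
#'
#' @param records data.frame with columns `gene_id`, `region` (`"A"`,
#'   `"B"`, or `"other"`), `log2fc`, `p_value` (see [read_de_table()] /
#'   [simulate_de_table()]).
#' @param thresholds a [threshold_config()].
#' @return a data.table with one row per region: `region`, `n_significant`,
#'   `n_total`.
#' @export
summarize_de <- function(records, thresholds = threshold_config()) {
  rec <- as.data.table(records)
  need <- c("gene_id", "region", "log2fc", "p_value")
  if (!all(need %in% names(rec)))
    stop("records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  known <- c("A", "B", "other")
  if (any(!rec$region %in% known)) {
    bad <- unique(rec$region[!rec$region %in% known])
    warning("unknown region label(s) assigned to 'other': ",
            paste(bad, collapse = ", "), call. = FALSE)
    rec[!region %in% known, region := "other"]
  }
  rec[, significant := de_significant(log2fc, p_value, thresholds)]
  out <- rec[, .(n_significant = sum(significant), n_total = .N),
             by = region]
  setorder(out, region)
  out[]
}
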