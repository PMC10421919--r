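#' Find tandem motif arrays (telomere scan)
#'
#' Scans sequences for maximal tandem runs of a motif or its reverse
#' complement (default the Arabidopsis-type telomere motif `TTTAGGG`),
#' allowing a configurable number of mismatches per copy. Adjacent runs of
#' opposite orientation are merged into one array with per-orientation copy
#' counts. Arrays within `terminal_dist` of a sequence end are flagged
#' terminal.
#'
#' @param sequences named character vector (or [genome_model()]).
#' @param motif repeat motif (default `"TTTAGGG"`).
#' @param min_copies minimum tandem copies to report (default 10).
#' @param max_mismatch mismatches allowed per copy (default 0).
#' @param terminal_dist distance from a sequence end within which an array
#'   counts as terminal (default 5000 bp).
#' @return data.table with columns `chrom`, `start`, `stop` (0-based
#'   half-open), `unit_length`, `n_fwd`, `n_rev`, `orientation`
#'   (`+`/`-`/`mixed`), `terminal`.
#' @export
find_motif_arrays <- function(sequences, motif = "TTTAGGG",
                              min_copies = 10L, max_mismatch = 0L,
                              terminal_dist = 5000L) {
  if (!nzchar(motif)) stop("empty motif", call. = FALSE)
  if (inherits(sequences, "genome_model")) sequences <- sequences$sequences
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  m <- nchar(motif)
  rows <- list()
  for (nm in names(sequences)) {
    subj <- Biostrings::DNAString(sequences[[nm]])
    len <- length(subj)
    runs <- list()
    for (ori in c("+", "-")) {
      pat <- if (ori == "+") motif else revcomp(motif)
      hits <- Biostrings::matchPattern(pat, subj,
                                       max.mismatch = max_mismatch)
      st <- Biostrings::start(hits) - 1L   # 0-based
      if (!length(st)) next
      st <- sort(st)
      # maximal tandem runs: consecutive starts exactly one unit apart
      grp <- cumsum(c(1L, diff(st) != m))
      for (g in unique(grp)) {
        ss <- st[grp == g]
        # overlapping mismatch hits can produce sub-unit steps; keep exact
        if (length(ss) >= 1L)
          runs[[length(runs) + 1L]] <- data.table(
            start = ss[1L], stop = ss[length(ss)] + m,
            n = length(ss), orientation = ori)
      }
    }
    if (!length(runs)) next
    rr <- rbindlist(runs)
    setorder(rr, start)
    # merge abutting/overlapping runs of either orientation into arrays
    if (nrow(rr) > 1L)
      rr[, grp := cumsum(c(TRUE, rr$start[-1L] > rr$stop[-nrow(rr)]))]
    else rr[, grp := 1L]
    arr <- rr[, .(start = min(start), stop = max(stop),
                  n_fwd = sum(n[orientation == "+"]),
                  n_rev = sum(n[orientation == "-"])), by = grp]
    arr <- arr[n_fwd + n_rev >= min_copies]
    if (!nrow(arr)) next
    arr[, `:=`(chrom = nm, unit_length = m,
               orientation = ifelse(n_fwd > 0 & n_rev > 0, "mixed",
                                    ifelse(n_fwd > 0, "+", "-")),
               terminal = start <= terminal_dist |
                 stop >= len - terminal_dist)]
    rows[[length(rows) + 1L]] <- arr[, .(chrom, start, stop, unit_length,
                                         n_fwd, n_rev, orientation,
                                         terminal)]
  }
  if (!length(rows))
    return(data.table(chrom = character(), start = integer(),
                      stop = integer(), unit_length = integer(),
                      n_fwd = integer(), n_rev = integer(),
                      orientation = character(), terminal = logical()))
  rbindlist(rows)
}

#' Detect the tandem repeat unit of a sequence window
#'
#' Estimates the repeat period as the shift `p` minimizing the mean
#' per-position mismatch between the window and itself shifted by `p`
#' (the smallest period within `tol` of the minimum wins, so harmonics
#' resolve to the fundamental). The consensus unit is the per-column
#' majority over the period tiling. Returns `NULL` when even the best
#' period mismatches more than `max_mismatch_frac` (for i.i.d. random DNA
#' the expected mismatch fraction is 0.75).
#'
#' @param window a DNA string (the candidate array region).
#' @param min_period,max_period period search range (defaults 2 to half the
#'   window).
#' @param max_mismatch_frac reject threshold on the best period's mismatch
#'   fraction (default 0.2).
#' @param tol closeness to the minimum within which the smallest period is
#'   preferred (default 0.01).
#' @return list with `unit_length`, `consensus`, `mismatch`, or `NULL`.
#' @export
detect_unit <- function(window, min_period = 2L, max_period = NULL,
                        max_mismatch_frac = 0.2, tol = 0.01) {
  n <- nchar(window)
  if (n < 2L) stop("window shorter than 2 bp", call. = FALSE)
  if (is.null(max_period)) max_period <- n %/% 2L
  max_period <- min(max_period, n - 1L)
  if (max_period < min_period) return(NULL)
  raw <- charToRaw(window)
  periods <- min_period:max_period
  mm <- vapply(periods, function(p) {
    a <- raw[1:(n - p)]; b <- raw[(p + 1):n]
    mean(a != b)
  }, 0)
  best <- min(mm)
  if (best > max_mismatch_frac) return(NULL)
  # prefer the fundamental over its harmonics: harmonics of a diverged array
  # fluctuate around the same mismatch level, so allow a band that scales
  # with the attained minimum
  p <- periods[which(mm <= best + tol + 0.25 * best)[1L]]
  # per-column majority consensus over the tiling
  ch <- strsplit(window, "", fixed = TRUE)[[1]]
  col <- rep_len(seq_len(p), n)
  cons <- vapply(seq_len(p), function(cc) {
    tab <- table(ch[col == cc])
    names(tab)[which.max(tab)]
  }, "")
  list(unit_length = as.integer(p),
       consensus = paste(cons, collapse = ""),
       mismatch = mm[match(p, periods)])
}

#' Count forward/reverse unit orientations in a tandem array
#'
#' Tiles the array greedily left to right in steps of the unit length; at
#' each offset the tile is assigned forward or reverse-complement
#' orientation by whichever matches the unit with higher identity (ties,
#' including a unit equal to its own reverse complement, count forward).
#'
#' @param array_seq the array sequence.
#' @param unit the repeat unit (forward orientation).
#' @return named integer vector `c(n_fwd, n_rev)`.
#' @export
count_orientations <- function(array_seq, unit) {
  u <- nchar(unit)
  n <- nchar(array_seq)
  if (u > n) stop("unit longer than array", call. = FALSE)
  ru <- revcomp(unit)
  raw_f <- charToRaw(unit); raw_r <- charToRaw(ru)
  n_tiles <- n %/% u
  n_fwd <- n_rev <- 0L
  for (t in seq_len(n_tiles)) {
    tile <- charToRaw(substr(array_seq, (t - 1L) * u + 1L, t * u))
    idf <- sum(tile == raw_f)
    idr <- sum(tile == raw_r)
    if (idf >= idr) n_fwd <- n_fwd + 1L else n_rev <- n_rev + 1L
  }
  c(n_fwd = n_fwd, n_rev = n_rev)
}

#' Percent identity from global alignment
#'
#' Needleman-Wunsch global end-to-end alignment (default scores: match +1,
#' mismatch -1, gap -2, linear) via [Biostrings::pairwiseAlignment()];
#' identity is matching columns divided by total alignment columns
#' (gap columns included in the denominator) times 100. Arguments are
#' ordered canonically before aligning so the measure is exactly symmetric.
#'
#' @param seq_a,seq_b DNA strings.
#' @param match,mismatch,gap scoring parameters.
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                              gap = -2) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("empty input sequence", call. = FALSE)
  if (seq_b < seq_a) { tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                       substitutionMatrix = sm,
                                       gapOpening = 0,
                                       gapExtension = abs(gap))
  a <- charToRaw(as.character(Biostrings::alignedPattern(aln)))
  b <- charToRaw(as.character(Biostrings::alignedSubject(aln)))
  gap_raw <- charToRaw("-")
  matches <- sum(a == b & a != gap_raw)
  100 * matches / length(a)
}

#' Pairwise identity matrix for a set of sequences
#'
#' @param seqs named character vector.
#' @param ... passed to [pairwise_identity()].
#' @return symmetric matrix of percent identities (diagonal 100).
#' @export
identity_matrix <- function(seqs, ...) {
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n >= 2L)
    for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
      m[a, b] <- m[b, a] <- pairwise_identity(seqs[[a]], seqs[[b]], ...)
    }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via [ape::nj()]); negative branch lengths are
#' clamped to zero. Distances from percent similarity are `100 - similarity`.
#' The two-taxon case returns a single edge split evenly.
#'
#' @param d symmetric distance matrix with labeled rows/columns (zero
#'   diagonal), or a `dist`.
#' @return an [ape] `phylo` tree with branch lengths.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 labels", call. = FALSE)
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), ncol = 2L),
               edge.length = rep(d[1L, 2L] / 2, 2L),
               tip.label = labs, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  dimnames(d) <- list(labs, labs)
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
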