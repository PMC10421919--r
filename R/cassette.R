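#' Build an oriented cassette model with its junction catalogue
#'
#' Concatenates oriented domains (`ST_large`, `A`, `B`, `I`, `ST_small`) into
#' a model sequence and derives one junction per adjacent domain pair, named
#' canonically: `STs-A` (large subtelomeric array to Region-A), `A-B`, `B-I`,
#' `I-B`, `B-ST`, and `INV` for the inversion point between opposite-oriented
#' small subtelomeric blocks. Reverse-complement (primed) instances collapse
#' to the same canonical names.
#'
#' @param domains named list of domain sequences. Keys are free-form part
#'   names referenced by `layout$part` (e.g. `A`, `B1`, `B2`, `I`,
#'   `ST_large`, `ST_small_f`, `ST_small_r`).
#' @param layout data.frame with columns `domain` (canonical class),
#'   `orientation` (`"+"`/`"-"`; `-` parts are reverse-complemented at
#'   assembly), and `part` (key into `domains`). See
#'   [palindromic_cassette_layout()] for the standard layout.
#' @return an object of class `cassette_model`: list with `layout` (with
#'   0-based `start`/`stop` boundary columns), `sequence`, `junctions`
#'   (data.frame `name`, `position`).
#' @export
build_cassette_model <- function(domains, layout) {
  if (!nrow(layout)) stop("empty layout", call. = FALSE)
  if (!all(c("domain", "orientation", "part") %in% names(layout)))
    stop("layout needs columns domain, orientation, part", call. = FALSE)
  seqs <- vapply(seq_len(nrow(layout)), function(r) {
    s <- domains[[layout$part[r]]]
    if (is.null(s) || !nzchar(s))
      stop("missing or empty domain sequence: ", layout$part[r],
           call. = FALSE)
    if (layout$orientation[r] == "-") revcomp(s) else s
  }, "")
  lens <- nchar(seqs)
  stops <- cumsum(lens)
  starts <- stops - lens
  lay <- cbind(as.data.frame(layout),
               data.frame(start = starts, stop = stops))
  jn <- list()
  for (r in seq_len(nrow(lay) - 1L)) {
    nm <- canonical_junction_name(lay$domain[r], lay$orientation[r],
                                  lay$domain[r + 1L],
                                  lay$orientation[r + 1L])
    if (!is.na(nm))
      jn[[length(jn) + 1L]] <- data.frame(name = nm,
                                          position = lay$stop[r],
                                          stringsAsFactors = FALSE)
  }
  junctions <- if (length(jn)) do.call(rbind, jn) else
    data.frame(name = character(), position = integer())
  structure(list(layout = lay,
                 sequence = paste(seqs, collapse = ""),
                 junctions = junctions),
            class = "cassette_model")
}

# canonical junction naming for an adjacent oriented domain pair; primed
# (reverse-orientation) instances collapse onto the forward names
canonical_junction_name <- function(d1, o1, d2, o2) {
  st <- c("ST_large", "ST_small")
  if (d1 %in% st && d2 %in% st) {
    if (d1 == "ST_small" && d2 == "ST_small" && o1 != o2) return("INV")
    return(NA_character_)
  }
  # orient the pair into forward sense
  flip <- (o1 == "-" && o2 == "-") ||
    (d1 %in% st && o2 == "-") || (d2 %in% st && o1 == "-")
  if (flip) { tmp <- d1; d1 <- d2; d2 <- tmp }
  key <- paste(sub("^ST_.*", "ST", d1), sub("^ST_.*", "ST", d2), sep = "|")
  switch(key,
         "ST|A" = "STs-A", "A|ST" = "STs-A",
         "A|B" = "A-B", "B|A" = "A-B",
         "B|I" = "B-I", "I|B" = "I-B",
         "B|ST" = "B-ST", "ST|B" = "B-ST",
         "A|I" = "A-I", "I|A" = "I-A",
         NA_character_)
}

#' Standard palindromic cassette layout
#'
#' The characterized architecture: a forward A+B(I) fusion copy and its
#' reverse complement joined by a small inverted subtelomeric block (forward
#' units then reverse-complement units), flanked by large subtelomeric
#' arrays. Region-I sits inside Region-B after a short prefix, so the
#' forward copy reads `ST_large | A | B-prefix | I | B-rest | ST_small`.
#'
#' @param with_flanks include the large flanking arrays (default `TRUE`).
#' @return a layout data.frame for [build_cassette_model()] expecting domain
#'   parts `ST_large`, `A`, `B1`, `I`, `B2`, `ST_small_f`, `ST_small_r`.
#' @export
palindromic_cassette_layout <- function(with_flanks = TRUE) {
  core <- data.frame(
    domain = c("A", "B", "I", "B", "ST_small", "ST_small",
               "B", "I", "B", "A"),
    orientation = c("+", "+", "+", "+", "+", "-", "-", "-", "-", "-"),
    part = c("A", "B1", "I", "B2", "ST_small_f", "ST_small_r",
             "B2", "I", "B1", "A"),
    stringsAsFactors = FALSE)
  if (!with_flanks) return(core)
  rbind(data.frame(domain = "ST_large", orientation = "+",
                   part = "ST_large", stringsAsFactors = FALSE),
        core,
        data.frame(domain = "ST_large", orientation = "+",
                   part = "ST_large", stringsAsFactors = FALSE))
}

#' Build the cassette model from simulation truth
#'
#' Convenience constructor: assembles the standard palindromic layout from
#' the domain sequences a [build_genomes()] truth records.
#'
#' @param truth the `truth` element of a [build_genomes()] result.
#' @param with_flanks include the large flanking arrays.
#' @return a `cassette_model`.
#' @export
cassette_model_from_truth <- function(truth, with_flanks = TRUE) {
  d <- truth$domains
  domains <- list(
    A = d$A, B1 = d$B1, B2 = d$B2, I = d$I,
    ST_large = st_array(d$st_unit, d$large_fwd, d$large_rev),
    ST_small_f = strrep(d$st_unit, d$small_fwd),
    ST_small_r = strrep(d$st_unit, d$small_rev))
  # ST_small_r is given forward and reverse-complemented by the layout
  build_cassette_model(domains, palindromic_cassette_layout(with_flanks))
}

#' @export
print.cassette_model <- function(x, ...) {
  cat(sprintf("cassette_model: %d domain(s), %d bp, %d junction(s)\n",
              nrow(x$layout), nchar(x$sequence), nrow(x$junctions)))
  if (nrow(x$junctions))
    cat("  junctions:", paste(sprintf("%s@%d", x$junctions$name,
                                      x$junctions$position),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Count junction-spanning reads
#'
#' A read supports a junction when one of its aligned blocks covers the
#' junction position with at least `min_anchor` aligned bases on each side.
#' Reads (or precomputed alignments against the model sequence) are counted
#' per junction instance and pooled under the canonical junction names, as
#' forward and reverse-complement instances of a junction are the same
#' physical boundary.
#'
#' @param x a read set / character vector of reads (mapped internally against
#'   the model sequence), or an `alignments` table whose `ref` is the model.
#' @param model a `cassette_model`.
#' @param min_anchor minimum aligned bases on each side of the junction
#'   (default 100, suitable for long reads; use ~30 for short reads).
#' @param min_block_frac minimum fraction of a read's overlap with the model
#'   that its aligned block must cover for the read to count (default 0.9).
#'   Reads that genuinely derive from the cassette align end-to-end over
#'   their model overlap; reads from unrelated subtelomeric arrays (whose
#'   orientation flips share local context with the inversion point) only
#'   match over the array portion and are filtered here.
#' @param k seed size for internal mapping.
#' @param seed RNG seed for internal mapping tie-breaks.
#' @return a data.table of class `junction_support`: `junction`,
#'   `n_spanning`, `n_instances`, `relative_abundance` (fold of the
#'   minimum-support junction).
#' @export
count_junction_support <- function(x, model, min_anchor = 100L,
                                   min_block_frac = 0.9, k = 21L,
                                   seed = 1L) {
  stopifnot(inherits(model, "cassette_model"))
  if (min_anchor <= 0) stop("'min_anchor' must be > 0", call. = FALSE)
  aln <- if (inherits(x, "alignments")) x else
    map_reads(x, build_index(c(cassette = model$sequence), k = k),
              seed = seed, split_anchor = max(100L, min_anchor))
  aln <- as.data.table(aln)[mapped == TRUE]
  if (nrow(aln)) {
    # overlap window of each read with the model on its alignment diagonal
    mlen <- nchar(model$sequence)
    diag_s <- aln$start - aln$read_start
    w <- pmin(mlen, diag_s + aln$read_len) - pmax(0L, diag_s)
    frac <- (aln$stop - aln$start) / w
    aln <- aln[is.na(frac) | frac >= min_block_frac]
  }
  jt <- model$junctions
  res <- lapply(seq_len(nrow(jt)), function(r) {
    p <- jt$position[r]
    hits <- aln[start <= p - min_anchor & stop >= p + min_anchor]
    data.table(junction = jt$name[r], n = length(unique(hits$read_id)))
  })
  res <- rbindlist(res)
  out <- res[, .(n_spanning = sum(n), n_instances = .N), by = junction]
  nz <- out$n_spanning[out$n_spanning > 0]
  out[, relative_abundance := if (length(nz))
    n_spanning / min(nz) else NA_real_]
  data.table::setattr(out, "class", c("junction_support", class(out)))
  out
}

#' Infer cassette architecture from junction support
#'
#' For a tandem array of palindromic units each unit contributes two copies
#' of every domain junction but only one inversion point, so the
#' inversion-point junction runs at about half the spanning-read support of
#' the others. The call is `palindromic_tandem` when all domain junctions
#' are supported and `INV / median(others)` falls in `palindromic_band`;
#' `simple_tandem` when the ratio is near 1 (at or above `simple_lo`) or no
#' inversion-point junction exists; `unsupported` when any required junction
#' has zero support or the ratio falls between the bands.
#'
#' @param supports a [count_junction_support()] table.
#' @param palindromic_band ratio band for the palindromic call
#'   (default `c(0.35, 0.65)`).
#' @param simple_lo lower ratio bound for the simple-tandem call
#'   (default 0.8).
#' @return a character scalar (`"palindromic_tandem"`, `"simple_tandem"`,
#'   `"unsupported"`) with attribute `inv_ratio`.
#' @export
infer_architecture <- function(supports, palindromic_band = c(0.35, 0.65),
                               simple_lo = 0.8) {
  if (!nrow(supports)) stop("empty support list", call. = FALSE)
  sup <- as.data.table(supports)
  others <- sup[junction != "INV"]
  inv <- sup[junction == "INV"]
  if (any(others$n_spanning == 0))
    return(structure("unsupported", inv_ratio = NA_real_))
  if (!nrow(inv))
    return(structure("simple_tandem", inv_ratio = NA_real_))
  ratio <- inv$n_spanning / median(others$n_spanning)
  call <- if (inv$n_spanning == 0) "unsupported"
  else if (ratio >= palindromic_band[1] && ratio <= palindromic_band[2])
    "palindromic_tandem"
  else if (ratio >= simple_lo) "simple_tandem"
  else "unsupported"
  structure(call, inv_ratio = ratio)
}

#' Arbitrate between alternative local assemblies by spanning reads
#'
#' Maps the same reads to each candidate sequence and counts, at each
#' candidate's designated junction position, reads spanning the junction
#' (with `min_anchor` aligned bases on each side) versus reads whose
#' alignment truncates near it. The candidate whose spanning count exceeds
#' every other's by `win_factor` is declared the winner; otherwise the
#' comparison is inconclusive.
#'
#' @param candidates named character vector of candidate sequences.
#' @param reads reads to map (read set or character vector).
#' @param positions numeric vector (recycled or named per candidate) of the
#'   designated junction position in each candidate (0-based).
#' @param min_anchor minimum anchor on each side (default 100).
#' @param win_factor factor by which the winner must exceed the runner-up
#'   (default 5).
#' @param k seed size for mapping.
#' @param seed RNG seed.
#' @return list with `counts` (data.table `candidate`, `n_spanning`,
#'   `n_truncated`) and `winner` (candidate name or `NA` if inconclusive).
#' @export
validate_alternatives <- function(candidates, reads, positions,
                                  min_anchor = 100L, win_factor = 5,
                                  k = 21L, seed = 1L) {
  if (!length(candidates)) stop("no candidates", call. = FALSE)
  if (is.null(names(candidates)))
    names(candidates) <- paste0("candidate", seq_along(candidates))
  if (length(positions) == 1L)
    positions <- rep(positions, length(candidates))
  if (!is.null(names(positions))) positions <- positions[names(candidates)]
  rows <- lapply(seq_along(candidates), function(ci) {
    idx <- build_index(setNames(candidates[ci], "cand"), k = k)
    aln <- as.data.table(map_reads(reads, idx, seed = seed))[mapped == TRUE]
    p <- positions[[ci]]
    span <- aln[start <= p - min_anchor & stop >= p + min_anchor]
    trunc <- aln[!(read_id %in% span$read_id) &
                   ((abs(stop - p) <= min_anchor) |
                      (abs(start - p) <= min_anchor))]
    data.table(candidate = names(candidates)[ci],
               n_spanning = length(unique(span$read_id)),
               n_truncated = length(unique(trunc$read_id)))
  })
  counts <- rbindlist(rows)
  winner <- NA_character_
  if (nrow(counts) >= 2L) {
    o <- order(-counts$n_spanning)
    best <- counts[o[1L]]; second <- counts[o[2L]]
    if (best$n_spanning > 0 &&
        best$n_spanning >= win_factor * max(1L, second$n_spanning) &&
        best$n_spanning > second$n_spanning)
      winner <- best$candidate
  }
  list(counts = counts, winner = winner)
}

#' Self dot-plot by exact k-mer match chains
#'
#' Finds exact k-mer matches of a sequence against itself on both
#' orientations, chains collinear matches, and reports match segments
#' suitable for dot-plot visualization of repeat macrostructure. The trivial
#' main diagonal is excluded; forward segments are reported once
#' (`pos1 < pos2`).
#'
#' @param sequence a DNA string.
#' @param k k-mer size (default 15).
#' @return data.table with columns `pos1`, `pos2` (0-based starts of the
#'   matching stretches), `length`, `orientation` (`"+"` collinear, `"-"`
#'   inverted).
#' @export
self_dotplot <- function(sequence, k = 15L) {
  n <- nchar(sequence)
  if (n < k) stop("sequence shorter than k", call. = FALSE)
  km <- substring(sequence, 1:(n - k + 1L), k:n)
  dt <- data.table(kmer = km, i = 0:(n - k))
  setkey(dt, kmer)
  # forward: pairs of identical k-mers
  dup <- dt[, .N, by = kmer][N > 1L, kmer]
  fwd <- NULL
  if (length(dup)) {
    dd <- dt[kmer %in% dup]
    pairs <- dd[dd, on = "kmer", allow.cartesian = TRUE]
    pairs <- pairs[i < i.i]
    if (nrow(pairs)) {
      pairs[, offset := i.i - i]
      setorder(pairs, offset, i)
      pairs[, grp := cumsum(c(1L, diff(i) != 1L)), by = offset]
      fwd <- pairs[, .(pos1 = min(i), pos2 = min(i.i),
                       length = max(i) - min(i) + k,
                       orientation = "+"), by = .(offset, grp)][
                         , .(pos1, pos2, length, orientation)]
    }
  }
  # reverse: k-mer equals reverse complement of another k-mer
  rc <- data.table(kmer = revcomp(km), j = 0:(n - k))
  rev_pairs <- dt[rc, on = "kmer", nomatch = 0L, allow.cartesian = TRUE]
  revm <- NULL
  if (nrow(rev_pairs)) {
    rev_pairs <- rev_pairs[i < j]
    if (nrow(rev_pairs)) {
      rev_pairs[, anti := i + j]
      setorder(rev_pairs, anti, i)
      rev_pairs[, grp := cumsum(c(1L, diff(i) != 1L)), by = anti]
      revm <- rev_pairs[, .(pos1 = min(i), pos2 = min(j),
                            length = max(i) - min(i) + k,
                            orientation = "-"), by = .(anti, grp)][
                              , .(pos1, pos2, length, orientation)]
    }
  }
  out <- rbindlist(list(fwd, revm))
  if (is.null(out) || !nrow(out))
    return(data.table(pos1 = integer(), pos2 = integer(),
                      length = integer(), orientation = character()))
  setorder(out, pos1, pos2)
  out[]
}
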