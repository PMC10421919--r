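#' Build a k-mer seed index over a reference
#'
#' Indexes every k-mer position of the reference (forward strand); queries by
#' reverse-complement k-mers are resolved at mapping time by dual lookup, so
#' either strand of a locus is retrievable.
#'
#' @param reference a [genome_model()], a named character vector of
#'   sequences, or a FASTA path.
#' @param k k-mer size, at least 11 (default 21).
#' @return an object of class `seed_index`.
#' @export
build_index <- function(reference, k = 21L) {
  k <- as.integer(k)
  if (k < 11L) stop("'k' must be >= 11", call. = FALSE)
  seqs <- reference_sequences(reference)
  lens <- nchar(seqs)
  if (any(lens < k))
    stop("reference sequence(s) shorter than k: ",
         paste(names(seqs)[lens < k], collapse = ", "), call. = FALSE)
  tabs <- lapply(seq_along(seqs), function(i) {
    n <- lens[i]
    data.table(kmer = substring(seqs[i], 1:(n - k + 1L), k:n),
               chrom = i, pos = 0:(n - k))
  })
  dt <- rbindlist(tabs)
  setkey(dt, kmer)
  structure(list(k = k, dt = dt, seq_names = names(seqs),
                 seq_lengths = unname(lens), sequences = seqs),
            class = "seed_index")
}

reference_sequences <- function(reference) {
  if (inherits(reference, "genome_model")) return(reference$sequences)
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference))
    return(read_genome_fasta(reference))
  if (is.character(reference)) {
    if (is.null(names(reference)))
      names(reference) <- paste0("seq", seq_along(reference))
    return(reference)
  }
  stop("unsupported reference type", call. = FALSE)
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("seed_index: k=%d, %d sequence(s), %d k-mer position(s)\n",
              x$k, length(x$seq_names), nrow(x$dt)))
  invisible(x)
}

# flatten a read_set (or character vector) into single-end ids + sequences
flatten_reads <- function(reads) {
  if (inherits(reads, "read_set")) {
    r <- reads$reads
    if (reads$mode == "short_paired" && nrow(r)) {
      return(data.table(
        id = as.vector(rbind(paste0(r$id, "/1"), paste0(r$id, "/2"))),
        seq = as.vector(rbind(r$seq, r$mate_seq))))
    }
    return(data.table(id = r$id, seq = r$seq))
  }
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    return(data.table(id = ids, seq = unname(reads)))
  }
  if (is.data.frame(reads)) return(as.data.table(reads)[, c("id", "seq")])
  stop("unsupported reads type", call. = FALSE)
}

#' Map reads with seed chaining and exact extension
#'
#' Assigns each read its best-scoring locus: seed k-mers are looked up on both
#' strands, candidate loci are voted by seed agreement on a common diagonal,
#' and each candidate is verified by ungapped extension (the longest exact
#' match run). The aligner is designed for error-free or low-error synthetic
#' reads: with substitution errors a read's aligned block ends at the
#' error-run boundary. Ties among equally scoring loci are broken uniformly at
#' random under `seed` (subtelomeric arrays are intentionally repetitive).
#' Reads overhanging a reference end (e.g. a cassette-model sequence) are
#' aligned over the overlapping part only.
#'
#' A read whose prefix and suffix (each anchoring at least `split_anchor`
#' exactly matching bases) map to discordant loci is reported split, as two
#' alignment rows sharing its `read_id`, enabling junction non-support
#' detection. Degenerate or unplaceable reads are emitted with
#' `mapped = FALSE`.
#'
#' @param reads a [simulate_reads()] read set, a (named) character vector, or
#'   a data.frame with columns `id`, `seq`.
#' @param index a [build_index()] seed index.
#' @param min_anchor_seed_count minimum seed votes for a candidate locus.
#' @param seed RNG seed for multi-mapping tie breaks.
#' @param max_candidates cap on verified candidate loci per read (overflow is
#'   subsampled at random).
#' @param split_anchor minimum exactly matching bases on each side for split
#'   reporting (default 100).
#' @param min_block minimum aligned block length for a mapped record.
#' @param chunk_size reads per processing chunk (memory control).
#' @return a data.table of class `alignments` with columns `read_id`, `ref`,
#'   `start`, `stop` (0-based half-open reference interval of the block),
#'   `strand`, `read_start`, `read_stop` (block interval on the
#'   strand-oriented read), `read_len`, `score`, `mapped`, `split`.
#' @export
map_reads <- function(reads, index, min_anchor_seed_count = 1L, seed = 1L,
                      max_candidates = 50L, split_anchor = 100L,
                      min_block = 50L, chunk_size = 20000L) {
  stopifnot(inherits(index, "seed_index"))
  rd <- flatten_reads(reads)
  set.seed(seed)
  k <- index$k
  out <- vector("list", max(1L, ceiling(nrow(rd) / chunk_size)))
  if (!nrow(rd)) return(empty_alignments())
  for (ci in seq_along(out)) {
    lo <- (ci - 1L) * chunk_size + 1L
    hi <- min(nrow(rd), ci * chunk_size)
    out[[ci]] <- map_chunk(rd[lo:hi], index, k, min_anchor_seed_count,
                           max_candidates, split_anchor, min_block)
  }
  res <- rbindlist(out)
  data.table::setattr(res, "class", c("alignments", class(res)))
  res
}

empty_alignments <- function() {
  res <- data.table(read_id = character(), ref = character(),
                    start = integer(), stop = integer(), strand = character(),
                    read_start = integer(), read_stop = integer(),
                    read_len = integer(), score = integer(),
                    mapped = logical(), split = logical())
  data.table::setattr(res, "class", c("alignments", class(res)))
  res
}

map_chunk <- function(rd, index, k, min_votes, max_candidates, split_anchor,
                      min_block) {
  n <- nrow(rd)
  L <- nchar(rd$seq)
  usable <- L >= k
  unmapped_rows <- function(which_i) data.table(
    read_id = rd$id[which_i], ref = NA_character_, start = NA_integer_,
    stop = NA_integer_, strand = NA_character_, read_start = NA_integer_,
    read_stop = NA_integer_, read_len = L[which_i], score = 0L,
    mapped = FALSE, split = FALSE)

  if (!any(usable))
    return(unmapped_rows(seq_len(n)))

  # seed offsets: 3 for short reads, up to 16 spread along long reads
  ns <- pmin(16L, pmax(3L, ceiling(L / 1000)))
  ns[!usable] <- 0L
  seed_dt <- rbindlist(lapply(which(usable), function(i) {
    offs <- unique(as.integer(round(seq(0L, L[i] - k, length.out = ns[i]))))
    data.table(read_i = i, off = offs)
  }))
  seed_dt[, kmer := substring(rd$seq[read_i], off + 1L, off + k)]
  rc_seq <- revcomp(rd$seq)

  idx <- index$dt
  cand_f <- idx[seed_dt, on = "kmer", nomatch = 0L, allow.cartesian = TRUE]
  cand_f[, `:=`(strand = "+", s = pos - off)]
  seed_rc <- copy(seed_dt)[, kmer := revcomp(kmer)]
  cand_r <- idx[seed_rc, on = "kmer", nomatch = 0L, allow.cartesian = TRUE]
  cand_r[, `:=`(strand = "-", s = pos - (L[read_i] - off - k))]
  cand <- rbindlist(list(cand_f, cand_r))
  if (!nrow(cand)) return(unmapped_rows(seq_len(n)))

  cand <- cand[, .(votes = .N), by = .(read_i, chrom, strand, s)]
  cand <- cand[votes >= min_votes]
  # drop candidates with too little reference overlap
  clen <- index$seq_lengths[cand$chrom]
  cand[, `:=`(ref_lo = pmax(0L, s),
              ref_hi = pmin(clen, s + L[read_i]))]
  cand <- cand[ref_hi - ref_lo >= k]
  if (!nrow(cand)) return(unmapped_rows(seq_len(n)))

  # cap candidates per read (top votes first, random among equals)
  cand[, rnd := runif(.N)]
  setorder(cand, read_i, -votes, rnd)
  cand[, keep := seq_len(.N) <= max_candidates, by = read_i]
  cand <- cand[keep == TRUE][, keep := NULL]

  # verification: ungapped window comparison on the candidate diagonal
  cand[, w := ref_hi - ref_lo]
  cand[, read_lo := ref_lo - s]
  refstr <- substring(index$sequences[cand$chrom], cand$ref_lo + 1L,
                      cand$ref_hi)
  oriented <- ifelse(cand$strand == "+", rd$seq[cand$read_i],
                     rc_seq[cand$read_i])
  readstr <- substring(oriented, cand$read_lo + 1L, cand$read_lo + cand$w)
  cand[, exact := refstr == readstr]

  parts <- list()
  emitted <- logical(n)

  # exact winners: best (longest) exact window, ties at random
  ex <- cand[exact == TRUE]
  if (nrow(ex)) {
    ex[, rnd := runif(.N)]
    setorder(ex, read_i, -w, rnd)
    ex <- ex[!duplicated(read_i)]
    parts$exact <- data.table(
      read_id = rd$id[ex$read_i], ref = index$seq_names[ex$chrom],
      start = ex$ref_lo, stop = ex$ref_hi, strand = ex$strand,
      read_start = ex$read_lo, read_stop = ex$read_lo + ex$w,
      read_len = L[ex$read_i], score = ex$w, mapped = TRUE, split = FALSE)
    emitted[ex$read_i] <- TRUE
  }

  # inexact candidates: longest exact run; split detection
  todo <- setdiff(unique(cand$read_i), which(emitted))
  if (length(todo)) {
    sub <- cand[read_i %in% todo]
    refstr <- substring(index$sequences[sub$chrom], sub$ref_lo + 1L,
                        sub$ref_hi)
    oriented <- ifelse(sub$strand == "+", rd$seq[sub$read_i],
                       rc_seq[sub$read_i])
    readstr <- substring(oriented, sub$read_lo + 1L, sub$read_lo + sub$w)
    m <- nrow(sub)
    run_len <- run_off <- pre_len <- suf_len <- integer(m)
    for (r in seq_len(m)) {
      eq <- as.integer(charToRaw(refstr[r]) == charToRaw(readstr[r]))
      rl <- rle(eq)
      ends <- cumsum(rl$lengths)
      tr <- which(rl$values == 1L)
      if (!length(tr)) next
      b <- tr[which.max(rl$lengths[tr])]
      run_len[r] <- rl$lengths[b]
      run_off[r] <- ends[b] - rl$lengths[b]   # 0-based within window
      if (rl$values[1L] == 1L) pre_len[r] <- rl$lengths[1L]
      if (rl$values[length(rl$values)] == 1L)
        suf_len[r] <- rl$lengths[length(rl$values)]
    }
    sub[, `:=`(run_len = run_len, run_off = run_off,
               pre_len = pre_len, suf_len = suf_len)]
    sub[, rnd := runif(.N)]
    by_read <- split(sub, by = "read_i")
    slow <- vector("list", length(by_read))
    for (bi in seq_along(by_read)) {
      cs <- by_read[[bi]]
      i <- cs$read_i[1L]
      Li <- L[i]
      # split: prefix of the read anchors one locus, suffix another
      pref <- cs[read_lo == 0L & pre_len >= split_anchor]
      suff <- cs[read_lo + w == Li & suf_len >= split_anchor]
      done <- FALSE
      if (nrow(pref) && nrow(suff)) {
        setorder(pref, -pre_len, rnd); p1 <- pref[1L]
        setorder(suff, -suf_len, rnd); s1 <- suff[1L]
        discordant <- !(p1$chrom == s1$chrom & p1$strand == s1$strand &
                          p1$s == s1$s)
        if (discordant) {
          slow[[bi]] <- data.table(
            read_id = rd$id[i],
            ref = index$seq_names[c(p1$chrom, s1$chrom)],
            start = c(p1$ref_lo, s1$ref_hi - s1$suf_len),
            stop = c(p1$ref_lo + p1$pre_len, s1$ref_hi),
            strand = c(p1$strand, s1$strand),
            read_start = c(0L, Li - s1$suf_len),
            read_stop = c(p1$pre_len, Li),
            read_len = Li, score = c(p1$pre_len, s1$suf_len),
            mapped = TRUE, split = TRUE)
          emitted[i] <- TRUE
          done <- TRUE
        }
      }
      if (!done) {
        setorder(cs, -run_len, rnd)
        b <- cs[1L]
        if (b$run_len >= min_block) {
          slow[[bi]] <- data.table(
            read_id = rd$id[i], ref = index$seq_names[b$chrom],
            start = b$ref_lo + b$run_off,
            stop = b$ref_lo + b$run_off + b$run_len,
            strand = b$strand, read_start = b$read_lo + b$run_off,
            read_stop = b$read_lo + b$run_off + b$run_len,
            read_len = Li, score = b$run_len, mapped = TRUE, split = FALSE)
          emitted[i] <- TRUE
        }
      }
    }
    parts$slow <- rbindlist(slow[!vapply(slow, is.null, TRUE)])
  }

  if (!all(emitted)) parts$unmapped <- unmapped_rows(which(!emitted))
  out <- rbindlist(parts, use.names = TRUE)
  out[order(match(read_id, rd$id))]
}

#' Import SAM alignments
#'
#' Converts a SAM text stream into the package's alignment records:
#' coordinates become 0-based half-open, records with FLAG bit 4 are marked
#' unmapped, and the reference span is computed from the CIGAR (`M`/`=`/`X`
#' consume both sequences, `I` the read, `D`/`N` the reference). Malformed
#' records raise an error naming the offending line.
#'
#' @param sam path to a SAM file, or a character vector of SAM lines.
#' @return an `alignments` data.table (see [map_reads()]).
#' @export
import_alignments <- function(sam) {
  lines <- if (length(sam) == 1L && file.exists(sam)) readLines(sam) else sam
  is_rec <- !startsWith(lines, "@") & nzchar(lines)
  sq <- grep("^@SQ", lines, value = TRUE)
  sq_names <- sub(".*SN:([^\t]+).*", "\\1", sq)
  recs <- which(is_rec)
  if (!length(recs)) return(empty_alignments())
  rows <- vector("list", length(recs))
  for (ii in seq_along(recs)) {
    ln <- recs[ii]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L)
      stop(sprintf("malformed SAM at line %d: expected >= 11 fields", ln),
           call. = FALSE)
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag) || is.na(pos))
      stop(sprintf("malformed SAM at line %d: bad FLAG or POS", ln),
           call. = FALSE)
    unmapped <- bitwAnd(flag, 4L) > 0L
    seqlen <- if (f[10] == "*") NA_integer_ else nchar(f[10])
    if (unmapped) {
      rows[[ii]] <- data.table(
        read_id = f[1], ref = NA_character_, start = NA_integer_,
        stop = NA_integer_, strand = NA_character_,
        read_start = NA_integer_, read_stop = NA_integer_,
        read_len = seqlen, score = 0L, mapped = FALSE, split = FALSE)
      next
    }
    cig <- f[6]
    if (cig == "*" || grepl("[^0-9MIDNSHP=X]", cig))
      stop(sprintf("malformed SAM at line %d: bad CIGAR '%s'", ln, cig),
           call. = FALSE)
    ops <- GenomicAlignments::explodeCigarOps(cig)[[1]]
    opl <- GenomicAlignments::explodeCigarOpLengths(cig)[[1]]
    ref_span <- sum(opl[ops %in% c("M", "=", "X", "D", "N")])
    read_span <- sum(opl[ops %in% c("M", "=", "X", "I")])
    lead_clip <- if (length(ops) && ops[1] %in% c("S", "H")) opl[1] else 0L
    if (length(sq_names) && !(f[3] %in% sq_names))
      stop(sprintf("malformed SAM at line %d: RNAME '%s' not in @SQ header",
                   ln, f[3]), call. = FALSE)
    start0 <- pos - 1L
    rows[[ii]] <- data.table(
      read_id = f[1], ref = f[3], start = start0,
      stop = start0 + ref_span,
      strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
      read_start = lead_clip, read_stop = lead_clip + read_span,
      read_len = seqlen, score = as.integer(read_span), mapped = TRUE,
      split = bitwAnd(flag, 2048L) > 0L)
  }
  res <- rbindlist(rows)
  data.table::setattr(res, "class", c("alignments", class(res)))
  res
}
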