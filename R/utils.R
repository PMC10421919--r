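#' @importFrom data.table data.table setkey setkeyv := .N .SD setorder rbindlist fread fwrite as.data.table copy
#' @importFrom stats rlnorm rnorm runif t.test pnorm median var setNames
#' @importFrom utils head tail write.table read.table
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "kmer", "pos", "chrom", "off", "read_i", "strand", "s", "votes",
  "score", "exact", "read_id", "mapped", "start", "stop", "state", "norm",
  "n_spanning", "junction", "seq_name", "event_id", "mean_depth", "L", "w",
  "block_len", "keep", "i", "j", "offset", "grp", "anti", "len", "ref",
  "ref_lo", "ref_hi", "read_lo", "rnd", "run_len", "run_off", "pre_len",
  "suf_len", "V1", "depth", "bases", "n_windows", "p_value", "region",
  "log2fc", "significant", "flagged", "length_printed", "mean_norm_depth",
  "i.i", "N", "pos1", "pos2", "n", "n_fwd", "n_rev", "orientation",
  "terminal", "unit_length", "relative_abundance", "label"
))

#' Reverse-complement DNA strings
#'
#' Vectorized reverse complement over plain character vectors (alphabet
#' `A`, `C`, `G`, `T`, `N`; case preserved for lowercase input).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", stringi::stri_reverse(x))
}

#' Generate random DNA
#'
#' Uniform i.i.d. bases, drawn from the current RNG stream.
#'
#' @param n sequence length in bp.
#' @return a single DNA string of length `n`.
#' @export
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Apply random substitutions at a given per-base fraction; substituted bases
# are forced to differ from the original.
mutate_dna <- function(x, frac) {
  if (frac <= 0) return(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  idx <- which(runif(length(ch)) < frac)
  if (length(idx)) {
    bases <- c("A", "C", "G", "T")
    repl <- vapply(ch[idx], function(b) sample(setdiff(bases, b), 1L), "")
    ch[idx] <- repl
  }
  paste(ch, collapse = "")
}

#' Derive a per-stage seed from a run seed
#'
#' Deterministically fans one top-level seed out to independent stage seeds by
#' hashing the stage name, so each pipeline stage is independently
#' reproducible. The result always fits in a 32-bit integer.
#'
#' @param seed integer run seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587L + 1)
}

# Natural ordering of sequence names: alphabetic prefix, then numeric suffix
# ("Chr2" before "Chr10", all "Chr*" before "Scaffold*").
order_seqnames <- function(x) {
  prefix <- sub("[0-9.]*$", "", x)
  num <- suppressWarnings(as.numeric(sub("^[^0-9]*", "", x)))
  num[is.na(num)] <- 0
  order(prefix, num, x)
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
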