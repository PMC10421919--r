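#' Write a simulated dataset to disk
#'
#' Writes the genome as FASTA, reads as FASTQ (placeholder qualities `I` for
#' error-free reads; paired mode writes `reads_1.fastq`/`reads_2.fastq`),
#' truth CNV intervals and repeat arrays as 0-based half-open BED, and
#' junctions plus read origins as TSV. Reading the files back reproduces the
#' objects.
#'
#' @param genome a [genome_model()].
#' @param reads a [simulate_reads()] read set, or `NULL`.
#' @param truth the truth list from [build_genomes()], or `NULL`.
#' @param dir output directory (created if missing).
#' @return invisibly, a named character vector of the files written.
#' @export
write_outputs <- function(genome, reads = NULL, truth = NULL, dir) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", dir, call. = FALSE)
  files <- c(genome = file.path(dir, "genome.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$sequences), files[["genome"]])
  if (nrow(genome$features)) {
    files[["features"]] <- file.path(dir, "features.bed")
    write_bed(genome$features[, c("chrom", "start", "stop", "name")],
              files[["features"]],
              extra = genome$features[, c("orientation", "class")])
  }
  if (!is.null(reads)) {
    if (reads$mode == "short_paired") {
      files[["reads_1"]] <- file.path(dir, "reads_1.fastq")
      files[["reads_2"]] <- file.path(dir, "reads_2.fastq")
      write_fastq(paste0(reads$reads$id, "/1"), reads$reads$seq,
                  files[["reads_1"]])
      write_fastq(paste0(reads$reads$id, "/2"), reads$reads$mate_seq,
                  files[["reads_2"]])
    } else {
      files[["reads"]] <- file.path(dir, "reads.fastq")
      write_fastq(reads$reads$id, reads$reads$seq, files[["reads"]])
    }
    if (nrow(reads$origins)) {
      files[["read_origins"]] <- file.path(dir, "read_origins.tsv")
      fwrite(reads$origins, files[["read_origins"]], sep = "\t")
    }
  }
  if (!is.null(truth)) {
    files[["truth_cnv"]] <- file.path(dir, "truth_cnv.bed")
    cnv <- truth$cnv_intervals
    write_bed(data.frame(chrom = cnv$chrom, start = cnv$start,
                         stop = cnv$stop,
                         name = sprintf("Region-%s_mult%d", cnv$region,
                                        cnv$expected_multiplicity)),
              files[["truth_cnv"]])
    files[["truth_repeats"]] <- file.path(dir, "truth_repeats.bed")
    ra <- truth$repeat_arrays
    write_bed(data.frame(chrom = ra$chrom, start = ra$start, stop = ra$stop,
                         name = sprintf("%s_u%d_f%d_r%d", ra$class,
                                        ra$unit_length, ra$n_fwd, ra$n_rev)),
              files[["truth_repeats"]])
    files[["truth_junctions"]] <- file.path(dir, "truth_junctions.tsv")
    fwrite(truth$junctions, files[["truth_junctions"]], sep = "\t")
  }
  invisible(files)
}

# BED writer: 0-based half-open, no header (interval length == stop - start)
write_bed <- function(df, path, extra = NULL) {
  out <- df
  if (!is.null(extra)) out <- cbind(out, extra)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' Minimal BED reader for the package's truth files: returns 0-based
#' half-open intervals with whatever extra columns are present.
#'
#' @param path BED file path.
#' @return data.table with columns `chrom`, `start`, `stop`, then `name`,
#'   etc. if present.
#' @export
read_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  base <- c("chrom", "start", "stop", "name", "score", "strand")
  data.table::setnames(dt, seq_len(ncol(dt)),
                       c(base, paste0("V", seq_len(ncol(dt))))[
                         seq_len(ncol(dt))])
  dt
}

# FASTQ writer with constant placeholder quality
write_fastq <- function(ids, seqs, path) {
  stopifnot(length(ids) == length(seqs))
  if (!length(ids)) {
    file.create(path)
    return(invisible(path))
  }
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  Biostrings::writeXStringSet(
    dna, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read reads from FASTQ
#'
#' @param path FASTQ file.
#' @return data.table with columns `id`, `seq`.
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0)
    return(data.table(id = character(), seq = character()))
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.table(id = sub("\\s.*$", "", names(x)), seq = as.character(x))
}

#' Read a per-gene differential-expression table
#'
#' Expects tab-separated columns `gene_id`, `region`, `log2fc`, `p_value`
#' (extra columns such as `label` are kept). Missing statistics may be empty
#' or `NA`.
#'
#' @param path TSV file.
#' @return data.table of DE records.
#' @export
read_de_table <- function(path) {
  dt <- fread(path, sep = "\t", na.strings = c("NA", "", "-"))
  need <- c("gene_id", "region", "log2fc", "p_value")
  if (!all(need %in% names(dt)))
    stop("DE table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  dt
}
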