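# File-format boundaries: FASTA/FASTQ via Biostrings, GFF3 via rtracklayer,
# plain TSV via base R. Sequences travel internally as named character
# vectors; these helpers convert at the edges.

#' Read and write FASTA / FASTQ
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()] that exchange named character vectors.
#' FASTQ output carries a constant placeholder quality, since the simulator
#' does not model quality scores.
#'
#' @param path file path.
#' @param seqs named character vector of nucleotide sequences.
#' @return `read_fasta()` / `read_fastq()` return a named character vector;
#'   the writers return `path` invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  if (length(x)) {
    q <- Biostrings::BStringSet(vapply(Biostrings::width(x), function(w)
      strrep("I", w), character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  } else {
    # writeXStringSet refuses empty sets for fastq; emit an empty file
    file.create(path)
  }
  invisible(path)
}

#' Read and write rRNA feature intervals as GFF3
#'
#' Features use 1-based inclusive coordinates (GFF3 convention). The reader
#' keeps only rows whose type is `rRNA`.
#'
#' @param path GFF3 file path.
#' @param features data.frame with columns `contig`, `start`, `end`.
#' @return `read_rrna_gff3()` returns a data.frame with columns `contig`,
#'   `start`, `end`; the writer returns `path` invisibly.
#' @export
read_rrna_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "rRNA"]
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' @rdname read_rrna_gff3
#' @export
write_rrna_gff3 <- function(features, path) {
  stopifnot(all(c("contig", "start", "end") %in% names(features)))
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    type = "rRNA", source = "bathymet")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read and write tab-separated tables
#'
#' @param path TSV file path.
#' @param x data.frame (or matrix with row names for `write_tsv_matrix()`).
#' @return data.frame (readers) or `path` invisibly (writers).
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, quote = "", comment.char = "")
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_tsv
#' @export
write_tsv_matrix <- function(x, path) {
  df <- data.frame(feature = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
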