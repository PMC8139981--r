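# Genome abundance by depth-normalized competitive read recruitment:
# common-depth subsampling, best-hit mapping with identity / coverage /
# rRNA filters, RPKG tables and recovery summaries.

#' Subsample read sets to a common depth
#'
#' Downsamples every sample, without replacement, to the depth of the
#' shallowest sample. Deterministic given `seed`.
#'
#' @param samples named list of read vectors (named character vectors as
#'   produced by [generate_reads()] or [read_fastq()]).
#' @param seed integer seed.
#' @return named list of read vectors, all of equal length.
#' @export
subsample_reads <- function(samples, seed = 1) {
  stopifnot(is.list(samples), length(samples) >= 1)
  depths <- lengths(samples)
  if (any(depths == 0))
    stop(sprintf("sample '%s' is empty", names(samples)[depths == 0][1L]),
         call. = FALSE)
  target <- min(depths)
  with_seed(seed, lapply(samples, function(r)
    if (length(r) == target) r else r[sort(sample.int(length(r), target))]))
}

#' Competitively map reads against a genome contig database
#'
#' Finds candidate hits by k-mer seeded local alignment (both strands) at
#' `search_min_identity` or better; each read is assigned to at most one
#' genome: the best hit by alignment score, ties broken by higher
#' identity, then lexicographically by genome id. The assignment is kept
#' only when identity is strictly greater than `keep_min_identity`, the
#' aligned fraction of the read is strictly greater than
#' `keep_min_coverage`, and the alignment footprint does not overlap any
#' annotated rRNA interval by one or more bases.
#'
#' @param reads named character vector of reads.
#' @param contigs named character vector of contig sequences.
#' @param contig_genome named character vector mapping contig id to
#'   genome id.
#' @param rrna optional rRNA intervals: data.frame (`contig`, `start`,
#'   `end`, 1-based inclusive) or a GFF3 path.
#' @param search_min_identity candidate search floor, percent
#'   (default 70).
#' @param keep_min_identity assignment identity bound, percent, strict
#'   (default 95).
#' @param keep_min_coverage assignment read-coverage bound, fraction,
#'   strict (default 0.90).
#' @param word_size seed k-mer length (default 13).
#' @return data.frame of class `read_hits`, one row per read with a
#'   candidate hit: `read_id`, `genome_id`, `contig_id`, `identity`,
#'   `read_coverage`, `score`, `overlaps_rRNA`, `assigned`. Assigned rows
#'   form the competitive assignment (at most one per read).
#' @export
competitive_map <- function(reads, contigs, contig_genome, rrna = NULL,
                            search_min_identity = 70,
                            keep_min_identity = 95,
                            keep_min_coverage = 0.90,
                            word_size = 13) {
  if (length(reads) == 0) return(empty_hits())
  stopifnot(!is.null(names(reads)), !is.null(names(contigs)))
  missing_map <- setdiff(names(contigs), names(contig_genome))
  if (length(missing_map))
    stop(sprintf("contig '%s' has no genome assignment", missing_map[1L]),
         call. = FALSE)
  if (is.character(rrna) && length(rrna) == 1) rrna <- read_rrna_gff3(rrna)
  if (!is.null(rrna) && nrow(rrna)) {
    bad <- setdiff(rrna$contig, names(contigs))
    if (length(bad))
      stop(sprintf("rRNA feature on unknown contig '%s'", bad[1L]),
           call. = FALSE)
  }

  hits <- cpp_map_reads(unname(reads), revcomp(unname(reads)),
                        unname(contigs), k = word_size)
  if (nrow(hits) == 0) return(empty_hits())

  hits$read_id <- names(reads)[hits$read_idx]
  hits$contig_id <- names(contigs)[hits$contig_idx]
  hits$genome_id <- unname(contig_genome[hits$contig_id])
  hits$identity <- 100 * hits$matches / hits$aln_len
  read_len <- nchar(reads)[hits$read_idx]
  hits$read_coverage <- (hits$read_end - hits$read_start + 1) / read_len
  hits <- hits[hits$identity >= search_min_identity, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_hits())

  # competitive best hit per read: score, then identity, then genome id
  ord <- order(hits$read_idx, -hits$score, -hits$identity, hits$genome_id,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(hits$read_idx), , drop = FALSE]

  best$overlaps_rRNA <- FALSE
  if (!is.null(rrna) && nrow(rrna)) {
    hit_r <- IRanges::IRanges(start = best$contig_start,
                              end = best$contig_end)
    rr_r <- IRanges::IRanges(start = rrna$start, end = rrna$end)
    ov <- IRanges::findOverlaps(hit_r, rr_r, minoverlap = 1L)
    same_ctg <- best$contig_id[S4Vectors::queryHits(ov)] ==
      rrna$contig[S4Vectors::subjectHits(ov)]
    best$overlaps_rRNA[unique(S4Vectors::queryHits(ov)[same_ctg])] <- TRUE
  }
  best$assigned <- best$identity > keep_min_identity &
    best$read_coverage > keep_min_coverage & !best$overlaps_rRNA

  out <- best[, c("read_id", "genome_id", "contig_id", "identity",
                  "read_coverage", "score", "overlaps_rRNA", "assigned")]
  rownames(out) <- NULL
  class(out) <- c("read_hits", "data.frame")
  out
}

empty_hits <- function() {
  out <- data.frame(read_id = character(0), genome_id = character(0),
                    contig_id = character(0), identity = numeric(0),
                    read_coverage = numeric(0), score = numeric(0),
                    overlaps_rRNA = logical(0), assigned = logical(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_hits", "data.frame")
  out
}

#' Sample sizes in gigabases
#'
#' @param samples named list of read vectors.
#' @return named numeric vector: total bases per sample / 1e9.
#' @export
sample_gbp_from_reads <- function(samples) {
  vapply(samples, function(r) sum(nchar(r)) / 1e9, numeric(1))
}

#' Genome abundance as RPKG
#'
#' `RPKG(g, s) = assigned reads of genome g in sample s /
#' (genome kilobases x sample gigabases)`. Zeros are retained for
#' genome/sample combinations without assignments.
#'
#' @param assignments data.frame with columns `sample_id`, `genome_id`
#'   and `assigned` (e.g. per-sample [competitive_map()] outputs bound
#'   together with a `sample_id` column); only assigned rows are counted.
#' @param genome_kbp named numeric vector, genome size in kb.
#' @param sample_gbp named numeric vector, sample size in Gb (see
#'   [sample_gbp_from_reads()]).
#' @return object of class `rpkg_table`: `values` (genome x sample
#'   matrix), `reads` (assigned read counts), `genome_kbp`, `sample_gbp`.
#' @export
rpkg <- function(assignments, genome_kbp, sample_gbp) {
  stopifnot(all(c("sample_id", "genome_id") %in% names(assignments)))
  if ("assigned" %in% names(assignments))
    assignments <- assignments[assignments$assigned, , drop = FALSE]
  gmiss <- setdiff(assignments$genome_id, names(genome_kbp))
  if (length(gmiss))
    stop(sprintf("no genome size for '%s'", gmiss[1L]), call. = FALSE)
  smiss <- setdiff(assignments$sample_id, names(sample_gbp))
  if (length(smiss))
    stop(sprintf("no sample size for '%s'", smiss[1L]), call. = FALSE)

  genomes <- names(genome_kbp); samples_ <- names(sample_gbp)
  counts <- matrix(0, nrow = length(genomes), ncol = length(samples_),
                   dimnames = list(genomes, samples_))
  if (nrow(assignments)) {
    tab <- table(factor(assignments$genome_id, levels = genomes),
                 factor(assignments$sample_id, levels = samples_))
    counts <- counts + unclass(tab)
  }
  values <- counts / (genome_kbp %o% sample_gbp)
  structure(list(values = values, reads = counts,
                 genome_kbp = genome_kbp, sample_gbp = sample_gbp),
            class = "rpkg_table")
}

#' @export
print.rpkg_table <- function(x, ...) {
  cat(sprintf("RPKG table: %d genomes x %d samples, %d assigned reads\n",
              nrow(x$values), ncol(x$values), sum(x$reads)))
  invisible(x)
}

#' Per-sample read recovery by genome quality class
#'
#' Percentage of each sample's reads recruited by genomes of each quality
#' class (e.g. LQ bins vs MQ/HQ MAGs).
#'
#' @param assignments data.frame with `sample_id`, `genome_id`,
#'   `assigned` columns.
#' @param total_reads named integer vector: reads per sample (the mapping
#'   input depth).
#' @param quality_class named character vector mapping every genome to a
#'   class (`LQ`, `MQ`, `HQ`, ...).
#' @return matrix sample x class of recovery percentages.
#' @export
read_recovery <- function(assignments, total_reads, quality_class) {
  if ("assigned" %in% names(assignments))
    assignments <- assignments[assignments$assigned, , drop = FALSE]
  uncl <- setdiff(assignments$genome_id, names(quality_class))
  if (length(uncl))
    stop(sprintf("genome '%s' has no quality class", uncl[1L]),
         call. = FALSE)
  classes <- sort(unique(unname(quality_class)))
  samples_ <- names(total_reads)
  out <- matrix(0, nrow = length(samples_), ncol = length(classes),
                dimnames = list(samples_, classes))
  if (nrow(assignments)) {
    cl <- quality_class[assignments$genome_id]
    tab <- table(factor(assignments$sample_id, levels = samples_),
                 factor(cl, levels = classes))
    out <- 100 * unclass(tab) / as.numeric(total_reads[samples_])
  }
  out
}

#' Mean RPKG per (basin, fraction) cell
#'
#' Averages genome RPKG over the samples of each ocean-basin x size-
#' fraction cell. Cells whose samples are all zero for a genome are
#' marked absent; cells with no samples at all are `NA` (no data),
#' distinct from absent.
#'
#' @param rpkg an [rpkg()] table.
#' @param metadata data.frame with `sample_id`, `basin`, `fraction`.
#' @return list with `means` (genome x cell matrix, `NA` = no data),
#'   `absent` (logical matrix), and `cells` (data.frame `basin`,
#'   `fraction`, `n_samples`).
#' @export
basin_fraction_means <- function(rpkg, metadata) {
  stopifnot(inherits(rpkg, "rpkg_table"),
            all(c("sample_id", "basin", "fraction") %in% names(metadata)))
  samples_ <- colnames(rpkg$values)
  md <- metadata[match(samples_, metadata$sample_id), ]
  if (anyNA(md$basin) || anyNA(md$fraction))
    stop("every sample needs basin and fraction metadata", call. = FALSE)
  cells <- unique(metadata[c("basin", "fraction")])
  cells <- cells[order(cells$basin, cells$fraction), , drop = FALSE]
  cell_id <- paste(cells$basin, cells$fraction, sep = ".")
  means <- matrix(NA_real_, nrow = nrow(rpkg$values),
                  ncol = length(cell_id),
                  dimnames = list(rownames(rpkg$values), cell_id))
  n_samples <- integer(length(cell_id))
  for (i in seq_along(cell_id)) {
    in_cell <- md$basin == cells$basin[i] & md$fraction == cells$fraction[i]
    n_samples[i] <- sum(in_cell)
    if (n_samples[i] > 0)
      means[, i] <- rowMeans(rpkg$values[, in_cell, drop = FALSE])
  }
  cells$n_samples <- n_samples
  absent <- !is.na(means) & means == 0
  list(means = means, absent = absent, cells = cells)
}
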