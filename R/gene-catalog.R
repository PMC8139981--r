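# Non-redundant gene catalog construction by greedy incremental clustering
# at a nucleotide identity threshold with a coverage bound on the shorter
# sequence, two-set catalog integration, and exclusive / mixed /
# sample-specific gene accounting.

#' Clustering parameters for gene-catalog construction
#'
#' @param identity minimum local-alignment identity `c` in (0, 1]
#'   (matching columns / alignment columns; default 0.95).
#' @param overlap minimum aligned fraction `aS` of the shorter sequence in
#'   (0, 1] (default 0.90).
#' @param min_length genes must be strictly longer than this (nt) to enter
#'   the catalog (default 100).
#' @param word_size k-mer length of the candidate prefilter (default 8).
#'   The prefilter is only applied when a shared-word guarantee holds (a
#'   pair that can reach `identity` at `overlap` coverage must share at
#'   least one word), so it never changes the clustering result.
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(identity = 0.95, overlap = 0.90,
                           min_length = 100, word_size = 8) {
  if (identity <= 0 || identity > 1) stop("`identity` must be in (0, 1]")
  if (overlap <= 0 || overlap > 1) stop("`overlap` must be in (0, 1]")
  stopifnot_scalar_pos(min_length, "min_length")
  if (word_size < 4 || word_size > 16)
    stop("`word_size` must be in [4, 16]")
  structure(list(identity = identity, overlap = overlap,
                 min_length = as.integer(min_length),
                 word_size = as.integer(word_size)),
            class = "cluster_params")
}

# The prefilter is used only when its seed-count bound is valid: the bound
# must increase with alignment length (word short enough relative to the
# error budget) and give at least one guaranteed seed at the shortest
# admissible alignment. Otherwise every candidate pair is aligned.
prefilter_is_safe <- function(params) {
  c0 <- params$identity; k <- params$word_size
  if (c0 - (1 - c0) * (k - 1) <= 0) return(FALSE)
  L <- ceiling(params$overlap * (params$min_length + 1))
  (c0 * L - ((1 - c0) * L + 1) * (k - 1)) >= 1
}

# Best local alignment of a against b over both strands.
# Returns identity (matches/columns), coverage of the shorter sequence
# (aligned span on it / its length), and the alignment score.
pair_alignment <- function(a, b) {
  best <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") a else revcomp(a)
    r <- cpp_sw_align(q, b)
    if (is.null(best) || r$score > best$score) { best <- r; best$strand <- strand }
  }
  if (best$score <= 0 || best$aln_len == 0)
    return(list(identity = 0, coverage_short = 0, score = 0, strand = "+"))
  span <- if (nchar(a) <= nchar(b)) best$a_end - best$a_start + 1L
          else best$b_end - best$b_start + 1L
  list(identity = best$matches / best$aln_len,
       coverage_short = span / min(nchar(a), nchar(b)),
       score = best$score, strand = best$strand)
}

pair_matches <- function(a, b, params) {
  al <- pair_alignment(a, b)
  al$identity >= params$identity && al$coverage_short >= params$overlap
}

# Admissible seed-count prefilter. A qualifying pair (identity >= c over
# >= aS of the shorter sequence, alignment length L >= ceil(aS * shorter))
# has at least (1-c)L non-matched columns breaking its matched columns into
# runs, which yield at least c*L - ((1-c)*L + 1)(k-1) positions of `a`
# whose k-mer occurs in `b`; the bound increases in L whenever
# (k-1) < c/(1-c), so evaluating it at the minimum admissible L is safe.
seed_threshold <- function(len_short, params) {
  L <- ceiling(params$overlap * len_short)
  k <- params$word_size
  max(1, floor(params$identity * L -
                 ((1 - params$identity) * L + 1) * (k - 1)))
}

shares_word <- function(a, b, params) {
  t <- seed_threshold(min(nchar(a), nchar(b)), params)
  cpp_seed_occurrences(a, b, params$word_size) >= t ||
    cpp_seed_occurrences(revcomp(a), b, params$word_size) >= t
}

# Greedy processing order: length descending, ties broken lexicographically
# by gene id (C collation for platform independence).
greedy_order <- function(ids, lens) {
  order(-lens, ids, method = "radix")
}

#' Build a non-redundant gene catalog by greedy identity clustering
#'
#' Genes not longer than `min_length` are excluded. Remaining genes are
#' processed longest-first (ties by gene id); each gene joins the first
#' existing representative whose best local alignment (either strand)
#' reaches the identity threshold and covers at least the `overlap`
#' fraction of the shorter sequence, or founds a new cluster. A shared
#' k-mer prefilter prunes candidate representatives only when it provably
#' cannot change the result.
#'
#' @param genes named character vector (or `DNAStringSet`) of nucleotide
#'   gene sequences over A/C/G/T.
#' @param params a [cluster_params()] object.
#' @return object of class `gene_catalog`: list with `members` (data.frame
#'   `cluster_id`, `representative`, `gene_id`), `sequences` (the retained
#'   input sequences), `params`, and `n_clusters`. Cluster ids equal the
#'   representative gene id.
#' @export
cluster_genes <- function(genes, params = cluster_params()) {
  if (inherits(genes, "DNAStringSet")) genes <- setNames(as.character(genes),
                                                         names(genes))
  stopifnot(inherits(params, "cluster_params"))
  if (length(genes) == 0)
    return(empty_catalog(params))
  if (is.null(names(genes)) || any(!nzchar(names(genes))) ||
      anyDuplicated(names(genes)))
    stop("genes must carry unique non-empty names", call. = FALSE)
  check_nucleotide(genes, "gene")

  keep <- nchar(genes) > params$min_length
  genes <- genes[keep]
  if (length(genes) == 0) return(empty_catalog(params))

  ord <- greedy_order(names(genes), nchar(genes))
  genes <- genes[ord]
  use_prefilter <- prefilter_is_safe(params)

  rep_ids <- character(0)
  assign <- character(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    hit <- NA_character_
    for (rid in rep_ids) {
      if (use_prefilter && !shares_word(g, genes[[rid]], params))
        next
      if (pair_matches(g, genes[[rid]], params)) { hit <- rid; break }
    }
    if (is.na(hit)) {
      rep_ids <- c(rep_ids, names(genes)[i])
      assign[i] <- names(genes)[i]
    } else assign[i] <- hit
  }

  members <- data.frame(cluster_id = assign, representative = assign,
                        gene_id = names(genes), stringsAsFactors = FALSE)
  structure(list(members = members, sequences = genes, params = params,
                 n_clusters = length(rep_ids)),
            class = "gene_catalog")
}

empty_catalog <- function(params) {
  structure(list(
    members = data.frame(cluster_id = character(0),
                         representative = character(0),
                         gene_id = character(0), stringsAsFactors = FALSE),
    sequences = setNames(character(0), character(0)),
    params = params, n_clusters = 0L), class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("Gene catalog: %d clusters from %d genes (c=%.2f, aS=%.2f)\n",
              x$n_clusters, nrow(x$members), x$params$identity,
              x$params$overlap))
  if (!is.null(x$provenance)) {
    tab <- table(x$provenance$provenance)
    cat(sprintf("  integrated: %s\n",
                paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                      collapse = ", ")))
  }
  invisible(x)
}

catalog_representatives <- function(catalog) {
  unique(catalog$members$representative)
}

#' Integrate a new catalog against a reference catalog (two-set mode)
#'
#' Each representative of the new catalog is compared only against the
#' representatives of the reference catalog. Matching clusters are labeled
#' `MG` (mixed: present in both catalogs), non-matching clusters `MPG`
#' (exclusive to the new catalog). The merged catalog contains all
#' reference clusters plus the MPG clusters, so its size is
#' `|reference| + |MPG|`; members of MG clusters fold into the matched
#' reference cluster.
#'
#' @param reference,new `gene_catalog` objects built with compatible
#'   parameters.
#' @param params clustering thresholds for the cross-comparison; defaults
#'   to the new catalog's. A parameter mismatch between the two catalogs
#'   raises a warning and proceeds with `params`.
#' @return a `gene_catalog` with an extra `provenance` data.frame
#'   (`cluster_id` of each new-catalog cluster, `provenance` in
#'   \{"MPG","MG"\}, `matched_reference`) and `new_members` (membership of
#'   the new catalog, for partitioning).
#' @export
integrate_catalogs <- function(reference, new, params = NULL) {
  stopifnot(inherits(reference, "gene_catalog"),
            inherits(new, "gene_catalog"))
  params <- params %||% new$params
  if (!identical(unclass(reference$params), unclass(new$params)))
    warning("catalogs were built with different parameters; ",
            "proceeding with the supplied thresholds")

  ref_reps <- catalog_representatives(reference)
  new_reps <- catalog_representatives(new)
  use_prefilter <- prefilter_is_safe(params)

  prov <- character(length(new_reps))
  matched <- rep(NA_character_, length(new_reps))
  for (i in seq_along(new_reps)) {
    g <- new$sequences[[new_reps[i]]]
    hit <- NA_character_
    for (rid in ref_reps) {
      if (use_prefilter &&
          !shares_word(g, reference$sequences[[rid]], params))
        next
      if (pair_matches(g, reference$sequences[[rid]], params)) {
        hit <- rid; break
      }
    }
    prov[i] <- if (is.na(hit)) "MPG" else "MG"
    matched[i] <- hit
  }
  provenance <- data.frame(cluster_id = new_reps, provenance = prov,
                           matched_reference = matched,
                           stringsAsFactors = FALSE)

  # merged membership: reference clusters + MPG clusters; MG members fold
  # into their matched reference cluster
  new_mem <- new$members
  fold <- setNames(matched, new_reps)
  merged_new <- new_mem
  is_mg <- prov[match(new_mem$cluster_id, new_reps)] == "MG"
  merged_new$cluster_id[is_mg] <- fold[new_mem$cluster_id[is_mg]]
  merged_new$representative <- merged_new$cluster_id
  members <- rbind(reference$members, merged_new)

  structure(list(
    members = members,
    sequences = c(reference$sequences, new$sequences),
    params = params,
    n_clusters = length(unique(members$cluster_id)),
    provenance = provenance,
    new_members = new$members,
    reference_size = reference$n_clusters),
    class = "gene_catalog")
}

#' Partition an integrated catalog into exclusive / mixed / sample-specific
#'
#' Computes the overall fraction of new-catalog clusters that are exclusive
#' (MPG) versus mixed (MG), flags sample-specific clusters (SSG: an MPG
#' cluster whose members all come from a single sample), and reports
#' per-sample exclusive and sample-specific gene fractions over each
#' sample's predicted genes. Percentages are reported to the nearest whole
#' percent.
#'
#' @param catalog an integrated `gene_catalog` (see [integrate_catalogs()]).
#' @param gene_sample_index data.frame with columns `gene_id`, `sample_id`
#'   (a gene may be indexed to several samples).
#' @return list of class `novelty_report`: counts, `mpg_percent`,
#'   `ssg` (named vector cluster -> sample), and `per_sample` data.frame
#'   (`sample_id`, `n_genes`, `exclusive_percent`, `ssg_percent`).
#' @export
partition_genes <- function(catalog, gene_sample_index) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (is.null(catalog$provenance))
    stop("catalog has no provenance; run integrate_catalogs() first",
         call. = FALSE)
  stopifnot(all(c("gene_id", "sample_id") %in% names(gene_sample_index)))

  mem <- catalog$new_members
  unindexed <- setdiff(mem$gene_id, gene_sample_index$gene_id)
  if (length(unindexed))
    stop(sprintf("gene '%s' is not indexed to any sample", unindexed[1L]),
         call. = FALSE)

  prov <- setNames(catalog$provenance$provenance,
                   catalog$provenance$cluster_id)
  n_new <- length(prov)
  mpg_count <- sum(prov == "MPG")
  mg_count <- sum(prov == "MG")

  idx <- split(gene_sample_index$sample_id, gene_sample_index$gene_id)
  cluster_samples <- lapply(split(mem$gene_id, mem$cluster_id),
                            function(g) unique(unlist(idx[g])))
  is_ssg <- vapply(names(cluster_samples), function(cl)
    prov[[cl]] == "MPG" && length(cluster_samples[[cl]]) == 1L, logical(1))
  ssg <- vapply(cluster_samples[is_ssg], `[`, character(1), 1L)

  gene_cluster <- setNames(mem$cluster_id, mem$gene_id)
  samples <- sort(unique(gene_sample_index$sample_id))
  per_sample <- do.call(rbind, lapply(samples, function(s) {
    gs <- unique(gene_sample_index$gene_id[gene_sample_index$sample_id == s])
    gs <- gs[gs %in% names(gene_cluster)]  # genes retained in the catalog
    cl <- gene_cluster[gs]
    in_ssg <- ifelse(cl %in% names(ssg), ssg[cl] == s, FALSE)
    data.frame(sample_id = s, n_genes = length(gs),
               exclusive_percent = round(100 * mean(prov[cl] == "MPG")),
               ssg_percent = round(100 * mean(in_ssg)),
               stringsAsFactors = FALSE)
  }))

  structure(list(
    n_new_clusters = n_new, mpg_count = mpg_count, mg_count = mg_count,
    mpg_percent = round(100 * mpg_count / n_new),
    mg_percent = round(100 * mg_count / n_new),
    ssg = ssg, per_sample = per_sample), class = "novelty_report")
}

#' @export
print.novelty_report <- function(x, ...) {
  cat(sprintf(
    "Novelty: %d/%d exclusive clusters (%d%%), %d mixed, %d sample-specific\n",
    x$mpg_count, x$n_new_clusters, x$mpg_percent, x$mg_count, length(x$ssg)))
  invisible(x)
}
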