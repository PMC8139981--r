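# Independent oracles used to validate the package's own implementations.
# They deliberately take different routes: Biostrings dynamic programming
# for alignment, an all-pairs greedy reference for clustering, closed-form
# distance decompositions for PERMANOVA.

oracle_submat <- Biostrings::nucleotideSubstitutionMatrix(
  match = 1, mismatch = -2, baseOnly = TRUE)

# Best local alignment over both strands via Biostrings::pairwiseAlignment
# with the same scoring scheme as the package kernel (gap of length L costs
# 2 + L). Returns identity, coverage of the shorter sequence, and score.
oracle_pair_alignment <- function(a, b) {
  best <- NULL
  for (query in c(a, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(a))))) {
    pa <- Biostrings::pairwiseAlignment(
      query, b, type = "local", substitutionMatrix = oracle_submat,
      gapOpening = 2, gapExtension = 1)
    if (is.null(best) || Biostrings::score(pa) > Biostrings::score(best))
      best <- pa
  }
  sc <- Biostrings::score(best)
  if (sc <= 0) return(list(identity = 0, coverage_short = 0, score = 0))
  aln_len <- nchar(as.character(Biostrings::alignedPattern(best)))
  span_a <- Biostrings::width(Biostrings::pattern(best))
  span_b <- Biostrings::width(Biostrings::subject(best))
  span_short <- if (nchar(a) <= nchar(b)) span_a else span_b
  list(identity = Biostrings::nmatch(best) / aln_len,
       coverage_short = span_short / min(nchar(a), nchar(b)),
       score = sc)
}

# Brute-force greedy clustering reference: same ordering and thresholds as
# cluster_genes(), no prefilter, full dynamic programming on every pair.
oracle_greedy_cluster <- function(genes, params) {
  genes <- genes[nchar(genes) > params$min_length]
  if (length(genes) == 0) return(setNames(character(0), character(0)))
  ord <- order(-nchar(genes), names(genes), method = "radix")
  genes <- genes[ord]
  reps <- character(0)
  assign <- character(length(genes))
  for (i in seq_along(genes)) {
    hit <- NA_character_
    for (rid in reps) {
      al <- oracle_pair_alignment(genes[[i]], genes[[rid]])
      if (al$identity >= params$identity &&
          al$coverage_short >= params$overlap) { hit <- rid; break }
    }
    if (is.na(hit)) { reps <- c(reps, names(genes)[i]); hit <- names(genes)[i] }
    assign[i] <- hit
  }
  setNames(assign, names(genes))
}

# Closed-form one-way PERMANOVA pseudo-F from raw pairwise distances
# (total and within-group squared distances), independent of the package's
# Gower-centering route.
oracle_oneway_pseudo_f <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  ss_total <- sum(dm[upper.tri(dm)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- dm[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  a <- length(unique(groups))
  ss_between <- ss_total - ss_within
  list(f = (ss_between / (a - 1)) / (ss_within / (n - a)),
       r2 = ss_between / ss_total)
}
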