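# Shared fixtures: tiny marker panels and communities sized for fast tests.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# A compact marker panel (subset of the shipped one, plus groups spanning
# several metabolism classes) keeps synthetic communities small.
small_panel <- function() {
  panel <- default_marker_panel()
  panel[panel$ko_id %in% c("K01601", "K00855", "K03520", "K00362",
                           "K00363", "K00394"), ]
}

small_community <- function(n_genomes = 3, seed = 11, ...) {
  generate_community(n_genomes, n_kos = 12, marker_panel = small_panel(),
                     seed = seed, genes_per_genome = 5,
                     gene_length_range = c(200, 400), ...)
}

# Rand index between two flat cluster labelings (named by element).
rand_index <- function(labels_a, labels_b) {
  ids <- names(labels_a)
  stopifnot(setequal(ids, names(labels_b)))
  labels_b <- labels_b[ids]
  n <- length(ids)
  agree <- 0L; total <- 0L
  for (i in seq_len(n - 1)) {
    same_a <- labels_a[i] == labels_a[(i + 1):n]
    same_b <- labels_b[i] == labels_b[(i + 1):n]
    agree <- agree + sum(same_a == same_b)
    total <- total + length(same_a)
  }
  agree / total
}

# All permutations of 1:n (n small), one per row.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
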