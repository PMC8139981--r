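# Greedy catalog clustering: threshold semantics, determinism, catalog
# integration and exclusive/mixed/sample-specific accounting.

test_that("identical sequences collapse into one cluster, longest-first", {
  set.seed(1)
  s <- rand_dna(300)
  genes <- c(g2 = s, g1 = s, g3 = s)
  cat1 <- cluster_genes(genes)
  expect_equal(cat1$n_clusters, 1L)
  # equal lengths: representative is the lexicographically first id
  expect_equal(unique(cat1$members$representative), "g1")
  expect_setequal(cat1$members$gene_id, c("g1", "g2", "g3"))
})

test_that("the minimum length bound is exclusive at 100 nt", {
  set.seed(2)
  genes <- c(short = rand_dna(99), edge = rand_dna(100),
             kept = rand_dna(101))
  cat1 <- cluster_genes(genes)
  expect_false("short" %in% cat1$members$gene_id)
  expect_false("edge" %in% cat1$members$gene_id)   # strict: keep > 100
  expect_true("kept" %in% cat1$members$gene_id)
})

test_that("96% identity over full overlap joins; 75% overlap splits", {
  set.seed(3)
  a <- rand_dna(300)
  b <- a
  pos <- sample(300, 12)
  for (p in pos) {
    old <- substr(b, p, p)
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  al <- oracle_pair_alignment(b, a)
  expect_gte(al$identity, 0.95)
  joined <- cluster_genes(c(A = a, B = b))
  expect_equal(joined$n_clusters, 1L)

  # 300-nt A and 200-nt B identical only over 150 nt of B
  set.seed(4)
  a2 <- rand_dna(300)
  b2 <- paste0(substr(a2, 76, 225), rand_dna(50))  # 150 shared + 50 random
  al2 <- oracle_pair_alignment(b2, a2)
  expect_lt(al2$coverage_short, 0.9)
  split2 <- cluster_genes(c(A = a2, B = b2))
  expect_equal(split2$n_clusters, 2L)
})

test_that("matching considers both strands", {
  set.seed(5)
  a <- rand_dna(240)
  genes <- c(fwd = a, rev = bathymet:::revcomp(a))
  expect_equal(cluster_genes(genes)$n_clusters, 1L)
})

test_that("degenerate inputs are rejected or yield empty catalogs", {
  expect_equal(cluster_genes(setNames(character(0),
                                      character(0)))$n_clusters, 0L)
  expect_error(cluster_genes(c(ok = strrep("A", 150),
                               bad = paste0(strrep("A", 150), "N"))),
               "bad")
  expect_error(cluster_genes(setNames(c(strrep("A", 150),
                                        strrep("A", 150)),
                                      c("x", "x"))), "unique")
})

test_that("greedy clustering equals the all-pairs dynamic-programming oracle", {
  params <- cluster_params(min_length = 100)
  for (case in 1:8) {
    set.seed(100 + case)
    sources <- replicate(3, rand_dna(sample(150:260, 1)))
    genes <- character(0)
    for (i in seq_along(sources)) {
      for (j in 1:sample(1:3, 1)) {
        genes <- c(genes, bathymet:::mutate_seq(sources[i],
                                                sample(c(0, 0.02, 0.1), 1)))
      }
    }
    genes <- c(genes, replicate(3, rand_dna(sample(120:260, 1))))
    names(genes) <- sprintf("g%02d", seq_along(genes))
    mine <- cluster_genes(genes, params)
    ours <- setNames(mine$members$cluster_id, mine$members$gene_id)
    ref <- oracle_greedy_cluster(genes, params)
    expect_identical(ours[sort(names(ours))], ref[sort(names(ref))])
  }
})

test_that("raising identity or overlap thresholds never merges clusters", {
  cm <- small_community(n_genomes = 2, seed = 31)
  pool <- generate_gene_pool(cm, redundancy = 2, mutation_rate = 0.03,
                             seed = 6)
  genes <- pool$genes[1:40]
  n_low <- cluster_genes(genes, cluster_params(identity = 0.90))$n_clusters
  n_mid <- cluster_genes(genes, cluster_params(identity = 0.95))$n_clusters
  n_hi <- cluster_genes(genes, cluster_params(identity = 0.99))$n_clusters
  expect_true(n_low <= n_mid && n_mid <= n_hi)
  n_ov1 <- cluster_genes(genes, cluster_params(overlap = 0.6))$n_clusters
  n_ov2 <- cluster_genes(genes, cluster_params(overlap = 0.95))$n_clusters
  expect_lte(n_ov1, n_ov2)
})

test_that("mutation-free pools are recovered with Rand index 1", {
  cm <- small_community(n_genomes = 2, seed = 41)
  pool <- generate_gene_pool(cm, redundancy = 3, mutation_rate = 0,
                             seed = 7)
  catal <- cluster_genes(pool$genes)
  got <- setNames(catal$members$cluster_id, catal$members$gene_id)
  truth <- setNames(pool$cluster_truth$true_cluster,
                    pool$cluster_truth$gene_id)
  expect_equal(rand_index(got, truth[names(got)]), 1.0)
})

test_that("two-set integration labels exclusive and mixed clusters", {
  set.seed(8)
  ref_genes <- setNames(replicate(5, rand_dna(250)), paste0("ref", 1:5))
  new_genes <- setNames(replicate(3, rand_dna(250)), paste0("new", 1:3))
  ref_cat <- cluster_genes(ref_genes)
  new_cat <- cluster_genes(new_genes)

  # disjoint: everything exclusive
  merged <- integrate_catalogs(ref_cat, new_cat)
  expect_equal(merged$n_clusters, 8L)
  expect_true(all(merged$provenance$provenance == "MPG"))

  # one near-identical cross pair: one mixed gene, merged size 7
  new_genes2 <- new_genes
  new_genes2[["new1"]] <- bathymet:::mutate_seq(ref_genes[["ref2"]], 0.02)
  merged2 <- integrate_catalogs(ref_cat, cluster_genes(new_genes2))
  expect_equal(sum(merged2$provenance$provenance == "MG"), 1L)
  expect_equal(merged2$n_clusters, 7L)
  # the mixed members fold into the matched reference cluster
  expect_equal(
    merged2$members$cluster_id[merged2$members$gene_id == "new1"], "ref2")

  # empty new catalog: merged equals the reference
  empty <- cluster_genes(setNames(character(0), character(0)))
  merged3 <- integrate_catalogs(ref_cat, empty)
  expect_equal(merged3$n_clusters, ref_cat$n_clusters)
  expect_equal(nrow(merged3$provenance), 0L)

  # parameter mismatch warns but proceeds
  other <- cluster_genes(new_genes, cluster_params(identity = 0.9))
  expect_warning(integrate_catalogs(ref_cat, other), "different parameters")
})

test_that("partitioning counts MPG/MG/SSG and per-sample fractions", {
  set.seed(9)
  ref_genes <- setNames(replicate(4, rand_dna(250)), paste0("ref", 1:4))
  # new catalog: n1/n2 exclusive (n2 seen in two samples), n3 mixed
  new_genes <- c(n1 = rand_dna(250), n2 = rand_dna(250),
                 n3 = bathymet:::mutate_seq(ref_genes[["ref1"]], 0.01))
  merged <- integrate_catalogs(cluster_genes(ref_genes),
                               cluster_genes(new_genes))
  idx <- data.frame(
    gene_id = c("n1", "n2", "n2", "n3"),
    sample_id = c("s1", "s1", "s2", "s2"), stringsAsFactors = FALSE)
  rep_ <- partition_genes(merged, idx)
  expect_equal(rep_$n_new_clusters, 3L)
  expect_equal(rep_$mpg_count + rep_$mg_count, rep_$n_new_clusters)
  expect_equal(rep_$mpg_count, 2L)
  expect_equal(rep_$mpg_percent, round(100 * 2 / 3))
  # SSG: only n1 (single-sample, exclusive); SSG implies MPG
  expect_equal(names(rep_$ssg), "n1")
  expect_true(all(names(rep_$ssg) %in%
                    merged$provenance$cluster_id[
                      merged$provenance$provenance == "MPG"]))
  ps <- rep_$per_sample
  expect_equal(ps$exclusive_percent[ps$sample_id == "s1"], 100)
  expect_equal(ps$ssg_percent[ps$sample_id == "s1"], 50)
  expect_equal(ps$exclusive_percent[ps$sample_id == "s2"], 50)

  # all-mixed case: zero exclusive, zero sample-specific
  all_mg <- c(m1 = bathymet:::mutate_seq(ref_genes[["ref1"]], 0.01),
              m2 = bathymet:::mutate_seq(ref_genes[["ref2"]], 0.01))
  merged_mg <- integrate_catalogs(cluster_genes(ref_genes),
                                  cluster_genes(all_mg))
  rep_mg <- partition_genes(
    merged_mg, data.frame(gene_id = c("m1", "m2"),
                          sample_id = c("s1", "s1")))
  expect_equal(rep_mg$mpg_count, 0L)
  expect_length(rep_mg$ssg, 0L)

  expect_error(partition_genes(merged, idx[idx$gene_id != "n1", ]), "n1")
})
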