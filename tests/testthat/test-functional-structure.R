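# Abundance tables, rarefaction, Bray-Curtis, NMDS and PERMANOVA.

toy_counts <- function() {
  m <- matrix(c(3, 4, 10, 0,
                0, 0, 5, 2), nrow = 4,
              dimnames = list(c("gA", "gB", "gC", "gD"), c("s1", "s2")))
  m
}

test_that("table building sums gene counts per feature", {
  ann <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                    feature = c("K1", "K1", "K2", NA))
  tab <- build_abundance_table(ann, toy_counts())
  expect_equal(tab$counts["K1", "s1"], 7)             # 3 + 4
  expect_equal(tab$counts["K2", ], c(s1 = 10, s2 = 5))
  expect_equal(tab$counts["unannotated", "s2"], 2)

  # length correction: equal reads, half the length => double the signal
  ann2 <- data.frame(gene_id = c("long", "short"), feature = c("Ka", "Kb"))
  cnt2 <- matrix(c(10, 10), nrow = 2,
                 dimnames = list(c("long", "short"), "s1"))
  tab2 <- build_abundance_table(ann2, cnt2, length_correct = TRUE,
                                gene_lengths = c(long = 1000, short = 500))
  expect_equal(unname(tab2$counts["Kb", 1] / tab2$counts["Ka", 1]), 2)

  # all genes unannotated: a single explicit row
  ann3 <- data.frame(gene_id = rownames(toy_counts()),
                     feature = NA_character_)
  expect_equal(rownames(build_abundance_table(ann3, toy_counts())$counts),
               "unannotated")

  expect_error(build_abundance_table(ann[1:3, ], toy_counts()), "gD")
})

test_that("rarefaction subsamples exactly and without replacement", {
  set.seed(10)
  m <- matrix(rpois(60, 30), nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  tab <- abundance_table(m)
  deep <- min(colSums(m))
  rar <- rarefy(tab, 50, seed = 3)
  expect_true(all(colSums(rar$counts) == 50))
  expect_true(all(rar$counts <= m))          # without replacement
  expect_equal(rar$rarefied_to, 50L)
  expect_identical(rar$counts, rarefy(tab, 50, seed = 3)$counts)

  # depth equal to a column total leaves that column unchanged
  one <- abundance_table(m[, 1, drop = FALSE])
  expect_equal(rarefy(one, colSums(m)[1], seed = 1)$counts[, 1],
               m[, 1], ignore_attr = TRUE)

  expect_error(rarefy(tab, deep + 10^6, seed = 1),
               "'s1' has .* less than depth")
})

test_that("rarefied counts track the hypergeometric expectation", {
  # one feature at proportion 0.3 of a 100-read sample, rarefied to 50:
  # E[count] = 15, and the mean over many seeds concentrates there
  m <- matrix(c(30, 70), nrow = 2,
              dimnames = list(c("target", "rest"), "s1"))
  tab <- abundance_table(m)
  draws <- vapply(1:300, function(s)
    rarefy(tab, 50, seed = s)$counts["target", 1], numeric(1))
  sd_one <- sqrt(50 * 0.3 * 0.7 * (100 - 50) / (100 - 1))
  expect_lt(abs(mean(draws) - 15), 2.576 * sd_one / sqrt(300) * 1.5)
})

test_that("Bray-Curtis follows its formula and bounds", {
  m <- matrix(c(2, 0, 1, 1, 1, 1), nrow = 3,
              dimnames = list(paste0("f", 1:3), c("x", "y")))
  d <- bray_curtis(m)
  expect_equal(as.vector(d), 1 / 3)          # (1+1+0) / (3+3)

  same <- matrix(c(5, 2, 5, 2), nrow = 2,
                 dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(as.vector(bray_curtis(same)), 0)

  disjoint <- matrix(c(5, 0, 0, 7), nrow = 2,
                     dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(as.vector(bray_curtis(disjoint)), 1)

  zz <- matrix(0, nrow = 2, ncol = 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(bray_curtis(zz), "all-zero")
  expect_error(bray_curtis(m[, 1, drop = FALSE]), "two samples")
})

test_that("NMDS embeds perfect configurations and depends only on ranks", {
  pts <- matrix(c(0, 0, 3, 0, 0, 4), ncol = 2, byrow = TRUE)
  fit <- nmds(dist(pts), k = 2, n_starts = 5, seed = 1)
  expect_lt(fit$stress, 1e-6)

  set.seed(20)
  X <- matrix(rnorm(14 * 5), 14)
  d <- dist(X)
  f1 <- nmds(d, seed = 2)
  f2 <- nmds(d^1.9, seed = 2)          # strictly increasing transform
  expect_lt(abs(f1$stress - f2$stress), 1e-6)
  ord1 <- order(as.vector(dist(f1$points)))
  ord2 <- order(as.vector(dist(f2$points)))
  expect_identical(ord1, ord2)

  expect_identical(nmds(d, seed = 5)$points, nmds(d, seed = 5)$points)
  dd <- dist(rbind(diag(3) * 2))       # all pairwise distances equal
  expect_warning(nmds(dd, k = 1, n_starts = 2, seed = 1), "degenerate")
})

test_that("PERMANOVA partitions variance to 1 and matches vegan::adonis2", {
  set.seed(30)
  n <- 12
  md <- data.frame(sample_id = sprintf("s%02d", 1:n),
                   fraction = rep(c("FL", "PA"), each = 6),
                   basin = rep(paste0("b", 1:3), 4))
  Y <- matrix(rpois(n * 25, 15), nrow = 25,
              dimnames = list(paste0("f", 1:25), md$sample_id))
  d <- bray_curtis(Y)
  res <- permanova(d, md, c("fraction", "basin"), n_perm = 499, seed = 1)
  expect_equal(sum(res$r2) + res$residual_r2, 1, tolerance = 1e-9)

  ora <- vegan::adonis2(d ~ fraction + basin, data = md, by = "terms",
                        permutations = 499)
  expect_equal(unname(res$r2), ora$R2[1:2], tolerance = 1e-10)
  expect_equal(unname(res$pseudo_F), ora$F[1:2], tolerance = 1e-10)
  expect_true(all(res$p >= 1 / (res$n_perm + 1) & res$p <= 1))
})

test_that("PERMANOVA saturates at R2 = 1 for perfectly separated duplicates", {
  # two groups of duplicated points: within-distance 0, between 1
  m <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1), nrow = 2,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  d <- bray_curtis(m)
  md <- data.frame(sample_id = paste0("s", 1:4),
                   grp = c("g1", "g1", "g2", "g2"))
  res <- permanova(d, md, "grp", n_perm = 99, seed = 1)
  expect_equal(unname(res$r2), 1, tolerance = 1e-12)
  expect_equal(res$residual_r2, 0, tolerance = 1e-12)
})

test_that("exhaustively enumerated permutation p equals the closed-form oracle", {
  set.seed(40)
  n <- 6
  md <- data.frame(sample_id = paste0("s", 1:n),
                   grp = rep(c("A", "B"), each = 3))
  Y <- matrix(rpois(n * 12, 10), nrow = 12,
              dimnames = list(paste0("f", 1:12), md$sample_id))
  d <- bray_curtis(Y)
  perms <- all_permutations(n)
  expect_equal(nrow(perms), 720)
  res <- permanova(d, md, "grp", permutations = perms)

  ora <- oracle_oneway_pseudo_f(d, md$grp)
  expect_equal(unname(res$pseudo_F), ora$f, tolerance = 1e-10)
  expect_equal(unname(res$r2), ora$r2, tolerance = 1e-10)

  dm <- as.matrix(d)
  f_perm <- apply(perms, 1, function(pi)
    oracle_oneway_pseudo_f(stats::as.dist(dm[pi, pi]), md$grp)$f)
  p_exact <- mean(f_perm >= ora$f - 1e-12)
  expect_equal(unname(res$p), p_exact, tolerance = 1e-12)
})

test_that("a strong planted lifestyle effect dominates the R2 partition", {
  cm <- generate_community(2, n_kos = 15, marker_panel = small_panel(),
                           seed = 55, genes_per_genome = 10,
                           gene_length_range = c(200, 400))
  ann <- community_annotations(cm)
  top <- vapply(1:20, function(r) {
    ss <- generate_samples(cm, 6, 6, delta = 10, seed = 5500 + r,
                           depth = 4000, concentration = 100,
                           delta_basin = 0.3, n_basins = 2)
    tab <- build_abundance_table(ann, ss$counts, scheme = "KO")
    res <- permanova(bray_curtis(tab), ss$metadata,
                     c("fraction", "basin"), n_perm = 99, seed = r)
    names(which.max(res$r2)) == "fraction"
  }, logical(1))
  expect_gte(sum(top), 19)
})

test_that("confounded or incomplete designs are rejected", {
  md <- data.frame(sample_id = paste0("s", 1:4),
                   a = c("x", "x", "y", "y"),
                   b = c("x", "x", "y", "y"))
  m <- matrix(rpois(16, 9), nrow = 4,
              dimnames = list(paste0("f", 1:4), md$sample_id))
  d <- bray_curtis(m)
  expect_error(permanova(d, md, c("a", "b"), n_perm = 99), "confounded")
  md2 <- md; md2$a[1] <- NA
  expect_error(permanova(d, md2, "a", n_perm = 99), "missing")
})
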