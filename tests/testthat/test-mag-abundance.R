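# Competitive read recruitment, RPKG accounting, recovery and
# basin/fraction summaries.

# Two-genome fixture: genome B is a diverged (4% substitutions) copy of A,
# so error-free reads from A have an unambiguous best hit but a plausible
# competitor.
map_fixture <- function(seed = 60, len = 4000) {
  set.seed(seed)
  a <- rand_dna(len)
  b <- bathymet:::mutate_seq(a, 0.04)
  contigs <- c(A_c1 = a, B_c1 = b)
  list(contigs = contigs,
       contig_genome = c(A_c1 = "A", B_c1 = "B"))
}

read_from <- function(contigs, contig, start, len = 100) {
  substr(contigs[[contig]], start, start + len - 1)
}

mutate_at <- function(s, pos) {
  for (p in pos) {
    old <- substr(s, p, p)
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  s
}

test_that("each read is assigned to its single best genome", {
  fx <- map_fixture()
  reads <- c(r1 = read_from(fx$contigs, "A_c1", 501),
             r2 = read_from(fx$contigs, "B_c1", 1201))
  hits <- competitive_map(reads, fx$contigs, fx$contig_genome)
  expect_equal(nrow(hits), 2)                      # <=1 row per read
  expect_equal(hits$genome_id[hits$read_id == "r1"], "A")
  expect_equal(hits$genome_id[hits$read_id == "r2"], "B")
  expect_true(all(hits$assigned))
  expect_true(all(hits$identity == 100))
  expect_true(all(hits$read_coverage == 1))
})

test_that("identity and coverage bounds are strict", {
  fx <- map_fixture(seed = 61)
  # 5 interior mismatches in a 100-mer: identity exactly 95 -> rejected
  r95 <- mutate_at(read_from(fx$contigs, "A_c1", 301),
                   c(10, 30, 50, 70, 90))
  # 4 mismatches: identity 96 -> kept
  r96 <- mutate_at(read_from(fx$contigs, "A_c1", 1301),
                   c(10, 35, 60, 85))
  # only 85 of 100 bases align anywhere: coverage 0.85 -> rejected
  rcov <- paste0(read_from(fx$contigs, "A_c1", 2301, len = 85),
                 strrep("A", 15))
  hits <- competitive_map(c(x95 = r95, x96 = r96, xcov = rcov),
                          fx$contigs, fx$contig_genome)
  h <- setNames(hits$assigned, hits$read_id)
  expect_false(h[["x95"]])
  expect_true(h[["x96"]])
  expect_false(h[["xcov"]])
  ident <- setNames(hits$identity, hits$read_id)
  expect_equal(unname(ident[["x95"]]), 95)
  expect_lte(unname(hits$read_coverage[hits$read_id == "xcov"]), 0.9)
})

test_that("reads overlapping annotated rRNA are discarded", {
  fx <- map_fixture(seed = 62)
  rrna <- data.frame(contig = "A_c1", start = 1001, end = 1150)
  inside <- read_from(fx$contigs, "A_c1", 1020)
  edge <- read_from(fx$contigs, "A_c1", 902)   # overlaps base 1001 only
  clear <- read_from(fx$contigs, "A_c1", 1151) # starts just past the rRNA
  hits <- competitive_map(c(ri = inside, re = edge, rc = clear),
                          fx$contigs, fx$contig_genome, rrna = rrna)
  h <- setNames(hits$assigned, hits$read_id)
  expect_false(h[["ri"]])
  expect_false(h[["re"]])
  expect_true(h[["rc"]])
  expect_true(all(hits$overlaps_rRNA[hits$read_id %in% c("ri", "re")]))
  expect_error(
    competitive_map(c(r = inside), fx$contigs, fx$contig_genome,
                    rrna = data.frame(contig = "ghost", start = 1,
                                      end = 5)),
    "unknown contig")
})

test_that("competitive exclusivity and filter monotonicity hold", {
  cm <- small_community(n_genomes = 3, seed = 63)
  ss <- generate_samples(cm, 2, 2, delta = 0, seed = 3, depth = 1000)
  cm <- ss$community
  rd <- generate_reads(cm, ss$metadata$sample_id[1], 400, 100,
                       error_rate = 0.02, seed = 4)
  base <- competitive_map(rd$reads, cm$contigs, cm$contig_genome,
                          rrna = cm$rrna)
  expect_lte(max(table(base$read_id)), 1L)

  for (p in list(c(96, 0.90), c(95, 0.95), c(98, 0.98))) {
    stricter <- competitive_map(rd$reads, cm$contigs, cm$contig_genome,
                                rrna = cm$rrna, keep_min_identity = p[1],
                                keep_min_coverage = p[2])
    expect_lte(sum(stricter$assigned), sum(base$assigned))
  }
})

test_that("subsampling equalizes depth without replacement", {
  set.seed(64)
  mk <- function(n, tag) setNames(replicate(n, rand_dna(50)),
                                  sprintf("%s_%03d", tag, 1:n))
  samples <- list(s1 = mk(10, "a"), s2 = mk(7, "b"), s3 = mk(12, "c"))
  sub <- subsample_reads(samples, seed = 1)
  expect_equal(unname(lengths(sub)), c(7L, 7L, 7L))
  expect_identical(sub$s2, samples$s2)               # already at minimum
  expect_true(all(names(sub$s1) %in% names(samples$s1)))
  expect_equal(anyDuplicated(names(sub$s1)), 0L)
  expect_identical(sub, subsample_reads(samples, seed = 1))
  expect_identical(subsample_reads(samples["s1"], seed = 2)$s1,
                   samples$s1)                       # single sample
  expect_error(subsample_reads(list(s1 = character(0))), "empty")
})

test_that("RPKG follows its formula and scale laws", {
  asg <- data.frame(sample_id = rep("s1", 1000), genome_id = "G1",
                    assigned = TRUE)
  tab <- rpkg(asg, genome_kbp = c(G1 = 2500, G2 = 1000),
              sample_gbp = c(s1 = 1.25))
  expect_equal(tab$values["G1", "s1"], 1000 / (2500 * 1.25))  # 0.32
  expect_equal(tab$values["G2", "s1"], 0)                     # retained zero

  half <- rpkg(asg, c(G1 = 2500, G2 = 1000), c(s1 = 2.5))
  expect_equal(half$values["G1", "s1"], tab$values["G1", "s1"] / 2)

  expect_error(rpkg(asg, c(G2 = 1000), c(s1 = 1.25)), "genome size")
  expect_error(rpkg(asg, c(G1 = 2500), c(s9 = 1)), "sample size")
})

test_that("read recovery reports per-class percentages", {
  asg <- data.frame(sample_id = rep("s1", 40),
                    genome_id = rep(c("G1", "G2"), c(32, 8)),
                    assigned = TRUE)
  rec <- read_recovery(asg, total_reads = c(s1 = 100),
                       quality_class = c(G1 = "MQ", G2 = "LQ"))
  expect_equal(rec["s1", "MQ"], 32)
  expect_equal(rec["s1", "LQ"], 8)
  expect_lte(sum(rec["s1", ]), 100)

  none <- read_recovery(asg[0, ], c(s1 = 100), c(G1 = "MQ", G2 = "LQ"))
  expect_true(all(none == 0))
  expect_error(read_recovery(asg, c(s1 = 100), c(G1 = "MQ")),
               "quality class")
})

test_that("basin/fraction means separate absence from missing cells", {
  asg <- data.frame(
    sample_id = c(rep("s1", 2), rep("s2", 4), rep("s5", 5), "s5", "s6"),
    genome_id = c(rep("G1", 6), rep("G1", 5), "G2", "G2"),
    assigned = TRUE)
  tab <- rpkg(asg, genome_kbp = c(G1 = 1, G2 = 1),
              sample_gbp = setNames(rep(1, 6), paste0("s", 1:6)))
  md <- data.frame(sample_id = paste0("s", 1:6),
                   basin = rep(c("b1", "b2", "b3"), each = 2),
                   fraction = rep(c("FL", "PA"), 3))
  bf <- basin_fraction_means(tab, md)
  expect_equal(bf$means["G1", "b1.FL"], 2)     # single-sample cell
  expect_equal(bf$means["G1", "b1.PA"], 4)
  expect_true(bf$absent["G1", "b2.FL"])        # mapped nothing: absent
  expect_false(bf$absent["G1", "b3.FL"])
  expect_equal(bf$means["G2", "b3.FL"], 1)
  md_bad <- md; md_bad$basin[1] <- NA
  expect_error(basin_fraction_means(tab, md_bad), "basin and fraction")
})
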