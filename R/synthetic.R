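# Synthetic bathypelagic communities with full ground truth: genomes with
# KO-annotated genes and planted per-cell marker copy numbers, redundant gene
# pools with known cluster membership, FL/PA sample sets with a planted
# lifestyle effect, and reads with known genome of origin.

recA_KO <- "K03553"
recA_COG <- "COG0468"

#' Energy-metabolism marker panel
#'
#' Returns the default marker-gene panel: 49 KEGG orthologs covering
#' inorganic carbon fixation, CO, hydrogen, methane/C1, nitrogen and sulfur
#' metabolisms, each with a gene symbol (where conventional), a pathway
#' group used for aggregation, and a metabolism class.
#'
#' @return data.frame with columns `ko_id`, `gene_symbol`, `pathway_group`,
#'   `metabolism_class`.
#' @export
default_marker_panel <- function() {
  path <- system.file("extdata", "marker_panel.tsv", package = "bathymet")
  panel <- read_tsv(path)
  validate_marker_panel(panel)
  panel
}

validate_marker_panel <- function(panel) {
  need <- c("ko_id", "gene_symbol", "pathway_group", "metabolism_class")
  if (!all(need %in% names(panel)))
    stop("marker panel must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(panel$ko_id))
    stop("marker panel ko_ids must be unique", call. = FALSE)
  if (any(is.na(panel$pathway_group) | !nzchar(panel$pathway_group)))
    stop("every marker panel entry needs a pathway_group", call. = FALSE)
  invisible(panel)
}

#' Simulate a multi-genome community with known ground truth
#'
#' Generates random nucleotide genomes partitioned into contigs. Each genome
#' carries KO-annotated genes: exactly one recA-equivalent single-copy gene
#' (`K03553`), zero or more copies of each marker-panel KO (the planted
#' per-cell copy numbers are recorded in the truth object), and "filler"
#' genes drawn from a background KO universe. One rRNA-labeled interval is
#' planted per genome so rRNA-exclusion filters can be exercised.
#'
#' @param n_genomes number of genomes (>= 2).
#' @param n_kos size of the background (non-marker) KO universe.
#' @param marker_panel data.frame as returned by [default_marker_panel()].
#' @param seed integer seed; all outputs are deterministic given `seed`.
#' @param contigs_per_genome contigs per genome.
#' @param genes_per_genome background genes per genome.
#' @param gene_length_range min/max gene length (nt).
#' @param spacer_length_range min/max intergenic spacer length (nt).
#' @param rrna_length length of the planted rRNA interval (nt).
#' @param max_marker_copies maximum planted per-cell copy number for a
#'   marker KO.
#' @return an object of class `community_truth`: a list with contigs, gene
#'   sequences and coordinates, KO assignments, per-cell marker copy
#'   numbers, rRNA intervals, and cluster truth. Sample compositions and
#'   lifestyle labels are attached later by [generate_samples()].
#' @export
generate_community <- function(n_genomes, n_kos = 40,
                               marker_panel = default_marker_panel(),
                               seed = 1,
                               contigs_per_genome = 2,
                               genes_per_genome = 20,
                               gene_length_range = c(300, 900),
                               spacer_length_range = c(50, 150),
                               rrna_length = 120,
                               max_marker_copies = 3) {
  stopifnot_scalar_pos(n_genomes, "n_genomes")
  stopifnot_scalar_pos(n_kos, "n_kos")
  if (n_genomes < 2) stop("`n_genomes` must be >= 2", call. = FALSE)
  validate_marker_panel(marker_panel)
  if (nrow(marker_panel) < 1) stop("marker panel is empty", call. = FALSE)

  with_seed(seed, {
    genome_ids <- sprintf("G%02d", seq_len(n_genomes))
    filler_kos <- sprintf("K9%04d", seq_len(n_kos))
    panel_kos <- setdiff(marker_panel$ko_id, recA_KO)

    gene_rows <- list()
    contig_seqs <- character(0)
    contig_genome <- character(0)
    rrna <- list()
    copies_rows <- list()

    for (g in genome_ids) {
      # planted per-cell copy numbers; recA is always exactly single copy
      mk_copies <- if (length(panel_kos))
        sample(0:max_marker_copies, length(panel_kos), replace = TRUE,
               prob = c(0.45, 0.3, 0.15, 0.1)[seq_len(max_marker_copies + 1)])
      else integer(0)
      names(mk_copies) <- panel_kos
      copies_rows[[g]] <- data.frame(
        genome = g, ko = c(recA_KO, panel_kos),
        copies = c(1L, unname(mk_copies)), stringsAsFactors = FALSE)

      kos <- c(recA_KO, rep(panel_kos, times = mk_copies))
      filler_ko <- sample(filler_kos, genes_per_genome, replace = TRUE)
      filler_ko[runif(genes_per_genome) < 0.2] <- NA_character_
      kos <- c(kos, filler_ko)
      n_genes <- length(kos)

      lens <- sample(seq(gene_length_range[1], gene_length_range[2]),
                     n_genes, replace = TRUE)
      seqs <- vapply(lens, random_dna, character(1))
      ids <- sprintf("%s_g%03d", g, seq_len(n_genes))

      # assemble contigs: genes round-robin, separated by random spacers
      assign_ctg <- rep_len(seq_len(contigs_per_genome), n_genes)
      for (ci in seq_len(contigs_per_genome)) {
        cid <- sprintf("%s_c%d", g, ci)
        idx <- which(assign_ctg == ci)
        parts <- character(0)
        pos <- 0L
        if (ci == 1L) {  # plant the rRNA interval at the head of contig 1
          spacer <- random_dna(sample(seq(spacer_length_range[1],
                                          spacer_length_range[2]), 1))
          rr <- random_dna(rrna_length)
          parts <- c(spacer, rr)
          rrna[[g]] <- data.frame(
            contig = cid, start = nchar(spacer) + 1L,
            end = nchar(spacer) + rrna_length, stringsAsFactors = FALSE)
          pos <- nchar(spacer) + rrna_length
        }
        for (j in idx) {
          spacer <- random_dna(sample(seq(spacer_length_range[1],
                                          spacer_length_range[2]), 1))
          parts <- c(parts, spacer, seqs[j])
          start <- pos + nchar(spacer) + 1L
          pos <- start + lens[j] - 1L
          gene_rows[[ids[j]]] <- data.frame(
            gene_id = ids[j], genome = g, contig = cid,
            start = start, end = pos, strand = "+",
            length = lens[j], ko = kos[j],
            is_marker = !is.na(kos[j]) && kos[j] %in% c(recA_KO, panel_kos),
            is_recA = !is.na(kos[j]) && kos[j] == recA_KO,
            stringsAsFactors = FALSE)
        }
        tail_spacer <- random_dna(sample(seq(spacer_length_range[1],
                                             spacer_length_range[2]), 1))
        contig_seqs[[cid]] <- paste(c(parts, tail_spacer), collapse = "")
        contig_genome[[cid]] <- g
      }
    }

    gene_info <- do.call(rbind, gene_rows)
    rownames(gene_info) <- NULL
    genes <- setNames(
      substr_genes(contig_seqs, gene_info), gene_info$gene_id)
    genome_lengths <- vapply(split(nchar(contig_seqs),
                                   unlist(contig_genome)), sum, numeric(1))
    genome_lengths <- genome_lengths[genome_ids]

    ko_assignments <- lapply(
      split(gene_info$ko[!is.na(gene_info$ko)],
            gene_info$genome[!is.na(gene_info$ko)]), unique)

    structure(list(
      genome_ids = genome_ids,
      contigs = contig_seqs,
      contig_genome = unlist(contig_genome),
      genome_lengths = genome_lengths,
      genes = genes,
      gene_info = gene_info,
      ko_assignments = ko_assignments,
      per_cell_marker_copies = do.call(rbind, c(copies_rows,
                                                make.row.names = FALSE)),
      rrna = do.call(rbind, c(rrna, make.row.names = FALSE)),
      cluster_truth = setNames(gene_info$gene_id, gene_info$gene_id),
      marker_panel = marker_panel,
      filler_kos = filler_kos,
      sample_compositions = NULL,
      lifestyle_labels = NULL,
      basin_labels = NULL,
      lifestyle_effect_size = NULL,
      seed = as.integer(seed)
    ), class = "community_truth")
  })
}

substr_genes <- function(contigs, gene_info) {
  vapply(seq_len(nrow(gene_info)), function(i)
    substr(contigs[[gene_info$contig[i]]], gene_info$start[i],
           gene_info$end[i]), character(1))
}

#' @export
print.community_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic community: %d genomes, %d contigs, %d genes (%d marker)\n",
    length(x$genome_ids), length(x$contigs), length(x$genes),
    sum(x$gene_info$is_marker)))
  if (!is.null(x$sample_compositions))
    cat(sprintf("  %d samples attached (FL=%d, PA=%d)\n",
                length(x$lifestyle_labels),
                sum(x$lifestyle_labels == "FL"),
                sum(x$lifestyle_labels == "PA")))
  invisible(x)
}

#' Emit a redundant gene pool with known cluster membership
#'
#' Each source gene of the community is emitted `redundancy` times with
#' i.i.d. point substitutions at `mutation_rate` per base. True cluster
#' membership (the source gene) is recorded. The expected pairwise identity
#' between two copies of the same gene is `(1 - mu)^2 + mu^2/3`; copies whose
#' expected identity falls below `separability_threshold` are flagged
#' `separable` in the truth (a clustering run at that identity threshold is
#' expected to split them).
#'
#' @param community a `community_truth` object.
#' @param redundancy copies emitted per source gene (>= 1).
#' @param mutation_rate per-base substitution rate in \[0, 0.2\].
#' @param seed integer seed.
#' @param separability_threshold identity threshold used for the
#'   `separable` flag (default 0.95, the catalog clustering default).
#' @return list with `genes` (named character vector of copies) and
#'   `cluster_truth` (data.frame: `gene_id`, `true_cluster`, `sample_id`,
#'   `expected_identity`, `separable`).
#' @export
generate_gene_pool <- function(community, redundancy, mutation_rate = 0,
                               seed = 1, separability_threshold = 0.95) {
  stopifnot(inherits(community, "community_truth"))
  stopifnot_scalar_pos(redundancy, "redundancy")
  if (redundancy < 1) stop("`redundancy` must be >= 1", call. = FALSE)
  if (!is.numeric(mutation_rate) || mutation_rate < 0 || mutation_rate > 0.2)
    stop("`mutation_rate` must be in [0, 0.2]", call. = FALSE)

  with_seed(seed, {
    src <- community$genes
    ids <- as.vector(t(outer(names(src), seq_len(redundancy),
                             function(g, r) sprintf("%s_r%d", g, r))))
    copies <- rep(unname(src), each = redundancy)
    if (mutation_rate > 0)
      copies <- vapply(copies, mutate_seq, character(1),
                       rate = mutation_rate, USE.NAMES = FALSE)
    e_ident <- (1 - mutation_rate)^2 + mutation_rate^2 / 3
    truth <- data.frame(
      gene_id = ids,
      true_cluster = rep(names(src), each = redundancy),
      sample_id = rep(community$gene_info$genome, each = redundancy),
      expected_identity = e_ident,
      separable = e_ident < separability_threshold,
      stringsAsFactors = FALSE)
    list(genes = setNames(copies, ids), cluster_truth = truth)
  })
}

#' Simulate FL/PA sample sets with a planted lifestyle effect
#'
#' Draws per-gene read counts for `n_fl` free-living and `n_pa`
#' particle-attached samples from a Dirichlet-multinomial compositional
#' model. Per-sample gene weights are proportional to genome relative
#' abundance x gene length x planted per-cell copy number. In
#' particle-attached samples, the weights of genes annotated to the
#' designated effect KOs are multiplied by `(1 + delta)`; `delta = 0` makes
#' FL and PA samples exchangeable. An optional basin effect of size
#' `delta_basin` multiplies a basin-specific KO subset the same way.
#'
#' @param community a `community_truth` object.
#' @param n_fl,n_pa number of free-living / particle-attached samples
#'   (`n_fl + n_pa >= 4`).
#' @param delta non-negative lifestyle effect size.
#' @param seed integer seed.
#' @param depth reads per sample.
#' @param concentration Dirichlet concentration; larger means less
#'   overdispersion, `Inf` gives plain multinomial sampling.
#' @param effect_kos KOs carrying the lifestyle effect; default is a random
#'   20% subset of the background KO universe.
#' @param delta_basin non-negative basin effect size (default 0).
#' @param n_basins number of basins, assigned round-robin across samples.
#' @param compositions optional sample x genome matrix of relative
#'   abundances (rows summing to 1); default random Dirichlet per sample.
#' @return list of class `sample_set`: `community` (with compositions and
#'   labels attached), `counts` (gene x sample matrix), `metadata`
#'   (data.frame with `sample_id`, `fraction`, `ocean`, `basin`, `depth_m`),
#'   `effect_kos`, `basin_effect_kos`.
#' @export
generate_samples <- function(community, n_fl, n_pa, delta = 0, seed = 1,
                             depth = 30000, concentration = 300,
                             effect_kos = NULL, delta_basin = 0,
                             n_basins = 4, compositions = NULL) {
  stopifnot(inherits(community, "community_truth"))
  stopifnot_scalar_pos(n_fl, "n_fl"); stopifnot_scalar_pos(n_pa, "n_pa")
  if (n_fl + n_pa < 4) stop("`n_fl + n_pa` must be >= 4", call. = FALSE)
  stopifnot_scalar_pos(delta, "delta", strict = FALSE)
  stopifnot_scalar_pos(delta_basin, "delta_basin", strict = FALSE)

  with_seed(seed, {
    n <- n_fl + n_pa
    fraction <- c(rep("FL", n_fl), rep("PA", n_pa))
    sample_ids <- sprintf("S%02d_%s", seq_len(n), fraction)
    basins <- paste0("basin", rep_len(seq_len(n_basins), n))
    oceans <- paste0("ocean", (as.integer(sub("basin", "", basins)) - 1) %/%
                       max(1L, ceiling(n_basins / 2)) + 1L)

    gi <- community$gene_info
    ng <- nrow(gi)
    if (is.null(effect_kos)) {
      k <- max(1L, round(0.2 * length(community$filler_kos)))
      effect_kos <- sample(community$filler_kos, k)
    }
    basin_effect_kos <- if (delta_basin > 0) {
      pool <- setdiff(community$filler_kos, effect_kos)
      setNames(lapply(unique(basins), function(b)
        sample(pool, max(1L, round(0.1 * length(pool))))), unique(basins))
    } else NULL

    if (is.null(compositions)) {
      compositions <- t(vapply(seq_len(n), function(i) {
        a <- rgamma(length(community$genome_ids), shape = 5)
        a / sum(a)
      }, numeric(length(community$genome_ids))))
      dimnames(compositions) <- list(sample_ids, community$genome_ids)
    } else {
      compositions <- compositions[rep_len(seq_len(nrow(compositions)), n),
                                   , drop = FALSE]
      dimnames(compositions) <- list(sample_ids, community$genome_ids)
    }

    counts <- matrix(0L, nrow = ng, ncol = n,
                     dimnames = list(gi$gene_id, sample_ids))
    for (i in seq_len(n)) {
      w <- compositions[i, gi$genome] * gi$length
      in_effect <- !is.na(gi$ko) & gi$ko %in% effect_kos
      if (fraction[i] == "PA") w[in_effect] <- w[in_effect] * (1 + delta)
      if (!is.null(basin_effect_kos)) {
        bk <- basin_effect_kos[[basins[i]]]
        in_bk <- !is.na(gi$ko) & gi$ko %in% bk
        w[in_bk] <- w[in_bk] * (1 + delta_basin)
      }
      p <- w / sum(w)
      if (is.finite(concentration)) {
        g <- rgamma(ng, shape = concentration * p)
        if (sum(g) == 0) g <- p
        p <- g / sum(g)
      }
      counts[, i] <- rmultinom(1, size = depth, prob = p)[, 1]
    }

    community$sample_compositions <- compositions
    community$lifestyle_labels <- setNames(fraction, sample_ids)
    community$basin_labels <- setNames(basins, sample_ids)
    community$lifestyle_effect_size <- delta

    metadata <- data.frame(
      sample_id = sample_ids, fraction = fraction, ocean = oceans,
      basin = basins, depth_m = round(4000 + runif(n, -300, 300)),
      stringsAsFactors = FALSE)

    structure(list(community = community, counts = counts,
                   metadata = metadata, effect_kos = effect_kos,
                   basin_effect_kos = basin_effect_kos,
                   params = list(n_fl = n_fl, n_pa = n_pa, delta = delta,
                                 depth = depth,
                                 concentration = concentration,
                                 seed = as.integer(seed))),
              class = "sample_set")
  })
}

#' Gene-to-feature annotation map of a synthetic community
#'
#' @param community a `community_truth` object.
#' @return data.frame with columns `gene_id`, `feature` (the KO; `NA` for
#'   genes without functional annotation, which
#'   [build_abundance_table()] tallies in an explicit "unannotated" row).
#' @export
community_annotations <- function(community) {
  gi <- community$gene_info
  data.frame(gene_id = gi$gene_id, feature = gi$ko,
             stringsAsFactors = FALSE)
}

#' Expected per-cell marker copy numbers for a sample composition
#'
#' The abundance-weighted mean planted copy number of each marker KO, i.e.
#' the value an ideal recA normalization should recover under uniform
#' sequencing coverage.
#'
#' @param community a `community_truth` object.
#' @param composition named numeric vector of genome relative abundances
#'   (sums to 1).
#' @return named numeric vector, one value per marker KO (recA excluded).
#' @export
expected_percell_copies <- function(community, composition) {
  pc <- community$per_cell_marker_copies
  pc <- pc[pc$ko != recA_KO, ]
  comp <- composition[pc$genome]
  vapply(split(pc$copies * comp, pc$ko), sum, numeric(1))
}

#' Simulate single-end reads with known origins
#'
#' Reads are drawn from genomes proportional to sample composition x genome
#' length, uniformly along contigs, on a uniform random strand, with i.i.d.
#' base-substitution errors at `error_rate`.
#'
#' @param community a `community_truth` object with sample compositions
#'   attached (see [generate_samples()]).
#' @param sample sample identifier.
#' @param n_reads number of reads (0 allowed).
#' @param read_length read length (must not exceed the shortest contig).
#' @param error_rate per-base substitution rate in \[0, 0.1\].
#' @param seed integer seed.
#' @return list with `reads` (named character vector) and `origins`
#'   (data.frame: `read_id`, `genome`, `contig`, `start`, `strand`).
#' @export
generate_reads <- function(community, sample, n_reads, read_length = 100,
                           error_rate = 0, seed = 1) {
  stopifnot(inherits(community, "community_truth"))
  if (is.null(community$sample_compositions))
    stop("community has no sample compositions; run generate_samples() first",
         call. = FALSE)
  if (!sample %in% rownames(community$sample_compositions))
    stop(sprintf("unknown sample '%s'", sample), call. = FALSE)
  if (!is.numeric(n_reads) || n_reads < 0)
    stop("`n_reads` must be >= 0", call. = FALSE)
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 0.1)
    stop("`error_rate` must be in [0, 0.1]", call. = FALSE)
  if (read_length > min(nchar(community$contigs)))
    stop("`read_length` exceeds the shortest contig", call. = FALSE)

  with_seed(seed, {
    if (n_reads == 0) {
      return(list(reads = setNames(character(0), character(0)),
                  origins = data.frame(read_id = character(0),
                                       genome = character(0),
                                       contig = character(0),
                                       start = integer(0),
                                       strand = character(0),
                                       stringsAsFactors = FALSE)))
    }
    comp <- community$sample_compositions[sample, ]
    gw <- comp * community$genome_lengths[names(comp)]
    genome <- sample(names(gw), n_reads, replace = TRUE, prob = gw / sum(gw))
    ctg_by_genome <- split(names(community$contig_genome),
                           community$contig_genome)
    reads <- character(n_reads)
    contig <- character(n_reads)
    start <- integer(n_reads)
    strand <- character(n_reads)
    for (i in seq_len(n_reads)) {
      ctgs <- ctg_by_genome[[genome[i]]]
      clen <- nchar(community$contigs[ctgs])
      npos <- clen - read_length + 1L
      ci <- if (length(ctgs) == 1L) ctgs else
        sample(ctgs, 1L, prob = npos / sum(npos))
      pos <- sample.int(nchar(community$contigs[[ci]]) - read_length + 1L, 1L)
      s <- substr(community$contigs[[ci]], pos, pos + read_length - 1L)
      st <- sample(c("+", "-"), 1L)
      if (st == "-") s <- revcomp(s)
      if (error_rate > 0) s <- mutate_seq(s, error_rate)
      reads[i] <- s; contig[i] <- ci; start[i] <- pos; strand[i] <- st
    }
    ids <- sprintf("%s_R%06d", sample, seq_len(n_reads))
    list(reads = setNames(reads, ids),
         origins = data.frame(read_id = ids, genome = genome,
                              contig = contig, start = start,
                              strand = strand, stringsAsFactors = FALSE))
  })
}

#' Write a synthetic community and its truth to disk
#'
#' Writes genome contigs and gene sequences as FASTA, gene/marker truth
#' tables as TSV, planted rRNA intervals as GFF3, and a JSON truth summary.
#'
#' @param community a `community_truth` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community_truth <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(community$contigs, file.path(dir, "genomes.fasta"))
  write_fasta(community$genes, file.path(dir, "genes.fasta"))
  write_tsv(community$gene_info, file.path(dir, "gene_info.tsv"))
  write_tsv(community$per_cell_marker_copies,
            file.path(dir, "marker_copies.tsv"))
  write_tsv(data.frame(contig = names(community$contig_genome),
                       genome = unname(community$contig_genome)),
            file.path(dir, "contig_genome.tsv"))
  write_rrna_gff3(community$rrna, file.path(dir, "rrna.gff3"))
  jsonlite::write_json(
    list(genome_ids = community$genome_ids,
         genome_lengths = as.list(community$genome_lengths),
         seed = community$seed),
    file.path(dir, "truth_summary.json"), auto_unbox = TRUE)
  invisible(dir)
}
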