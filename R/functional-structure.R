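# Functional community structure: feature x sample abundance tables,
# rarefaction without replacement, Bray-Curtis dissimilarity, NMDS
# ordination and PERMANOVA variance partitioning.

#' Feature-by-sample abundance table
#'
#' @param counts non-negative numeric matrix, features as rows, samples as
#'   columns (both dimensions named).
#' @param scheme annotation scheme, one of `KO`, `COG`, `Pfam`, `EC`.
#' @param rarefied_to optional integer depth if the table has been rarefied.
#' @return object of class `abundance_table`.
#' @export
abundance_table <- function(counts, scheme = c("KO", "COG", "Pfam", "EC"),
                            rarefied_to = NULL) {
  scheme <- match.arg(scheme)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature row names and sample column names",
         call. = FALSE)
  if (!is.null(rarefied_to) &&
      any(abs(colSums(counts) - rarefied_to) > 1e-9))
    stop("rarefied_to is set but column sums do not match it",
         call. = FALSE)
  structure(list(counts = counts, scheme = scheme,
                 rarefied_to = rarefied_to), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance table [%s]: %d features x %d samples%s\n",
              x$scheme, nrow(x$counts), ncol(x$counts),
              if (!is.null(x$rarefied_to))
                sprintf(" (rarefied to %d)", x$rarefied_to) else ""))
  invisible(x)
}

#' Build a functional abundance table from gene counts
#'
#' Sums per-gene read counts into one row per functional feature. Genes
#' whose annotation is `NA` contribute to an explicit `"unannotated"` row.
#' With `length_correct = TRUE`, each gene's counts are divided by its
#' length in kilobases before summation (reads per gene kilobase), the
#' convention used for coverage-style functional profiles.
#'
#' @param annotations data.frame with columns `gene_id`, `feature`
#'   (`NA` = gene known but unannotated); a gene may map to several
#'   features. Every counted gene must appear here.
#' @param gene_counts numeric matrix, genes x samples, with row and column
#'   names.
#' @param scheme annotation scheme label for the resulting table.
#' @param length_correct divide gene counts by gene length in kb.
#' @param gene_lengths named vector of gene lengths (nt); required when
#'   `length_correct = TRUE`.
#' @return an [abundance_table()].
#' @export
build_abundance_table <- function(annotations, gene_counts, scheme = "KO",
                                  length_correct = FALSE,
                                  gene_lengths = NULL) {
  stopifnot(all(c("gene_id", "feature") %in% names(annotations)))
  gene_counts <- as.matrix(gene_counts)
  unknown <- setdiff(rownames(gene_counts), annotations$gene_id)
  if (length(unknown))
    stop(sprintf("count for unknown gene '%s'", unknown[1L]), call. = FALSE)

  if (length_correct) {
    if (is.null(gene_lengths))
      stop("`gene_lengths` is required when length_correct = TRUE",
           call. = FALSE)
    kb <- gene_lengths[rownames(gene_counts)] / 1000
    if (anyNA(kb)) stop("missing gene length", call. = FALSE)
    gene_counts <- gene_counts / kb
  }

  ann <- annotations[annotations$gene_id %in% rownames(gene_counts), ]
  ann$feature[is.na(ann$feature)] <- "unannotated"
  ann <- unique(ann[c("gene_id", "feature")])

  feats <- sort(unique(ann$feature))
  out <- matrix(0, nrow = length(feats), ncol = ncol(gene_counts),
                dimnames = list(feats, colnames(gene_counts)))
  for (f in feats) {
    g <- ann$gene_id[ann$feature == f]
    out[f, ] <- colSums(gene_counts[g, , drop = FALSE])
  }
  abundance_table(out, scheme)
}

#' Rarefy an abundance table without replacement
#'
#' Subsamples every sample (column) hypergeometrically to exactly `depth`
#' reads, without replacement, via [vegan::rrarefy()]. Deterministic given
#' `seed`.
#'
#' @param table an [abundance_table()] with integer counts.
#' @param depth target depth; must not exceed any column sum.
#' @param seed integer seed.
#' @return a rarefied [abundance_table()] with `rarefied_to = depth`.
#' @export
rarefy <- function(table, depth, seed = 1) {
  stopifnot(inherits(table, "abundance_table"))
  stopifnot_scalar_pos(depth, "depth")
  counts <- table$counts
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("rarefaction requires integer counts", call. = FALSE)
  cs <- colSums(counts)
  low <- cs < depth
  if (any(low))
    stop(sprintf("sample '%s' has only %d reads, less than depth %d",
                 colnames(counts)[low][1L], as.integer(cs[low][1L]),
                 as.integer(depth)), call. = FALSE)
  rar <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(t(round(counts)), depth),
    # rrarefy speculates about tables whose smallest count is large;
    # depth and integerness are validated above, so silence that hint
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  abundance_table(t(rar), table$scheme, rarefied_to = as.integer(depth))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)` over features, computed
#' with [vegan::vegdist()].
#'
#' @param table an [abundance_table()] (or a feature x sample matrix) with
#'   at least two samples.
#' @return a `dist` object over samples, values in \[0, 1\].
#' @export
bray_curtis <- function(table) {
  counts <- if (inherits(table, "abundance_table")) table$counts
            else as.matrix(table)
  if (ncol(counts) < 2) stop("need at least two samples", call. = FALSE)
  zero <- colSums(counts) == 0
  if (sum(zero) >= 2)
    stop(sprintf(
      "all-zero samples ('%s', ...) have undefined pairwise distance",
      colnames(counts)[zero][1L]), call. = FALSE)
  vegan::vegdist(t(counts), method = "bray")
}

#' Nonmetric multidimensional scaling with random restarts
#'
#' Minimises Kruskal stress-1 by monotone regression (global model of
#' [vegan::monoMDS()]) from `n_starts` random initial configurations and
#' returns the lowest-stress solution. Deterministic given `seed`.
#'
#' @param dist a `dist` object.
#' @param k number of ordination dimensions.
#' @param n_starts number of random starts.
#' @param seed integer seed.
#' @return list of class `nmds_fit`: `points` (n x k configuration),
#'   `stress` (Kruskal stress-1), `n_starts`.
#' @export
nmds <- function(dist, k = 2, n_starts = 20, seed = 1) {
  stopifnot(inherits(dist, "dist"))
  n <- attr(dist, "Size")
  if (n < k + 1) stop("need at least k + 1 points", call. = FALSE)
  dv <- as.vector(dist)
  if (length(unique(round(dv, 12))) == 1L)
    warning("degenerate distance matrix: all distances equal")
  best <- with_seed(seed, {
    best <- NULL
    for (s in seq_len(n_starts)) {
      y0 <- matrix(runif(n * k, -1, 1), nrow = n)
      fit <- vegan::monoMDS(dist, y = y0, k = k, model = "global",
                            maxit = 500, sfgrmin = 1e-7, sratmax = 1 - 1e-7)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    best
  })
  pts <- best$points
  rownames(pts) <- attr(dist, "Labels")
  structure(list(points = pts, stress = best$stress, n_starts = n_starts),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("NMDS fit: %d points, %d dimensions, stress = %.4g\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}

# Gower-centered matrix of a distance object: G = (I - J/n) (-d^2/2) (I - J/n)
gower_center <- function(dist) {
  d <- as.matrix(dist)
  a <- -0.5 * d^2
  n <- nrow(a)
  rm_ <- rowMeans(a); gm <- mean(a)
  sweep(sweep(a, 1, rm_), 2, rm_) + gm
}

#' PERMANOVA: distance-based variance partitioning
#'
#' Permutational multivariate analysis of variance with sequential
#' (Type-I) sums of squares computed from the Gower-centered distance
#' matrix. For each term the pseudo-F statistic is the term mean square
#' over the residual mean square; p-values come from free (unrestricted)
#' permutation of samples. Term order matters and is taken from `terms`.
#'
#' @param dist a `dist` object over samples.
#' @param metadata data.frame with a `sample_id` column and one column per
#'   factor, covering every sample in `dist`.
#' @param terms character vector of metadata column names, in the order
#'   they should enter the model.
#' @param n_perm number of random permutations (ignored when
#'   `permutations` is supplied).
#' @param seed integer seed for the permutations.
#' @param permutations optional integer matrix with one permutation of
#'   `1:n` per row (e.g. an exhaustive enumeration including the identity);
#'   when supplied, p-values are the exact fraction of enumerated
#'   permutations with `F >= F_observed`.
#' @return object of class `permanova_result` with fields `terms`, `df`,
#'   `ss`, `r2`, `pseudo_F`, `p`, `residual_r2`, `residual_df`, `total_ss`,
#'   `n_perm`.
#' @export
permanova <- function(dist, metadata, terms, n_perm = 10000, seed = 1,
                      permutations = NULL) {
  stopifnot(inherits(dist, "dist"))
  labs <- attr(dist, "Labels")
  n <- attr(dist, "Size")
  if (is.null(labs)) labs <- as.character(seq_len(n))
  if (!"sample_id" %in% names(metadata))
    stop("metadata needs a `sample_id` column", call. = FALSE)
  if (!all(labs %in% metadata$sample_id))
    stop("metadata does not cover every sample in the distance matrix",
         call. = FALSE)
  if (!all(terms %in% names(metadata)))
    stop("unknown term(s): ",
         paste(setdiff(terms, names(metadata)), collapse = ", "),
         call. = FALSE)
  md <- metadata[match(labs, metadata$sample_id), terms, drop = FALSE]
  if (anyNA(md)) stop("metadata has missing factor levels", call. = FALSE)
  if (is.null(permutations)) {
    if (n_perm < 99) stop("`n_perm` must be >= 99", call. = FALSE)
  }

  G <- gower_center(dist)
  ss_total <- sum(diag(G))

  # sequential projection matrices
  hat <- function(X) {
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  H_prev <- matrix(1 / n, n, n)
  rank_prev <- 1L
  P <- list(); df <- integer(length(terms))
  for (j in seq_along(terms)) {
    X <- stats::model.matrix(
      stats::as.formula(paste("~", paste(terms[seq_len(j)], collapse = "+"))),
      data = md)
    H <- hat(X)
    r <- qr(X)$rank
    df[j] <- r - rank_prev
    if (df[j] < 1)
      stop(sprintf("term '%s' is confounded with preceding terms",
                   terms[j]), call. = FALSE)
    P[[j]] <- H - H_prev
    H_prev <- H; rank_prev <- r
  }
  resid_df <- n - rank_prev
  if (resid_df < 1)
    stop("zero residual degrees of freedom", call. = FALSE)
  P_resid <- diag(n) - H_prev

  stat <- function(Gp) {
    ss <- vapply(P, function(p) sum(p * Gp), numeric(1))
    ss_res <- sum(P_resid * Gp)
    list(ss = ss, ss_res = ss_res,
         f = (ss / df) / (ss_res / resid_df))
  }
  obs <- stat(G)

  if (is.null(permutations)) {
    exceed <- integer(length(terms))
    with_seed(seed, {
      for (i in seq_len(n_perm)) {
        pi <- sample.int(n)
        f <- stat(G[pi, pi])$f
        exceed <- exceed + (f >= obs$f - 1e-12)
      }
    })
    p <- (exceed + 1) / (n_perm + 1)
  } else {
    stopifnot(is.matrix(permutations), ncol(permutations) == n)
    n_perm <- nrow(permutations)
    exceed <- integer(length(terms))
    for (i in seq_len(n_perm)) {
      pi <- permutations[i, ]
      f <- stat(G[pi, pi])$f
      exceed <- exceed + (f >= obs$f - 1e-12)
    }
    p <- exceed / n_perm
  }

  structure(list(
    terms = terms, df = setNames(df, terms),
    ss = setNames(obs$ss, terms),
    r2 = setNames(obs$ss / ss_total, terms),
    pseudo_F = setNames(obs$f, terms),
    p = setNames(p, terms),
    residual_ss = obs$ss_res,
    residual_r2 = obs$ss_res / ss_total,
    residual_df = resid_df,
    total_ss = ss_total,
    n_perm = n_perm), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%d permutations)\n", x$n_perm))
  tab <- data.frame(Df = x$df, SumOfSqs = signif(x$ss, 5),
                    R2 = signif(x$r2, 4), F = signif(x$pseudo_F, 4),
                    `Pr(>F)` = signif(x$p, 4), check.names = FALSE)
  print(tab)
  cat(sprintf("Residual: Df = %d, R2 = %.4f\n", x$residual_df,
              x$residual_r2))
  invisible(x)
}
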