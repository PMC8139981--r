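# Energy-metabolism marker profiling: recA single-copy normalization to
# per-cell copy proxies, occurrence, pathway aggregation, FL-vs-PA
# enrichment testing and marker cross-correlation.

#' Normalize a functional table by the recA single-copy gene
#'
#' Divides every feature's per-sample abundance by the abundance assigned
#' to the prokaryotic single-copy recombinase recA, yielding an
#' approximate copies-per-cell proxy. Samples with zero recA reads are
#' flagged and carry no values. Normalization is meant to run on
#' un-rarefied tables (subsampling cancels out of the ratio but discards
#' information); a rarefied input triggers a warning.
#'
#' @param table an [abundance_table()].
#' @param recA_feature feature id(s) identifying recA in the table's
#'   scheme; the first alias found is used. Defaults cover the COG
#'   (`COG0468`) and KO (`K03553`) schemes.
#' @return object of class `normalized_abundance`: `values` (marker x
#'   sample matrix, units reads per recA read; `NA` in flagged samples),
#'   `recA_counts`, `flagged` (sample ids with recA = 0), `recA_feature`.
#' @export
recA_normalize <- function(table, recA_feature = c("COG0468", "K03553")) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.null(table$rarefied_to))
    warning("normalizing a rarefied table; recA normalization is intended ",
            "for un-rarefied counts")
  counts <- table$counts
  hit <- recA_feature[recA_feature %in% rownames(counts)]
  if (length(hit) == 0)
    stop(sprintf("recA feature (%s) absent from the table",
                 paste(recA_feature, collapse = "/")), call. = FALSE)
  recA <- counts[hit[1L], ]
  values <- counts[setdiff(rownames(counts), hit[1L]), , drop = FALSE]
  values <- sweep(values, 2, recA, "/")
  flagged <- colnames(counts)[recA == 0]
  values[, flagged] <- NA_real_
  structure(list(values = values, recA_counts = recA, flagged = flagged,
                 recA_feature = hit[1L]), class = "normalized_abundance")
}

#' @export
print.normalized_abundance <- function(x, ...) {
  cat(sprintf(
    "recA-normalized abundance (%s): %d markers x %d samples, %d flagged\n",
    x$recA_feature, nrow(x$values), ncol(x$values), length(x$flagged)))
  invisible(x)
}

unflagged_values <- function(norm) {
  keep <- setdiff(colnames(norm$values), norm$flagged)
  if (length(keep) == 0)
    stop("all samples are flagged (recA = 0)", call. = FALSE)
  norm$values[, keep, drop = FALSE]
}

#' Occurrence of markers across samples
#'
#' Percentage of unflagged samples in which a marker (or any member of a
#' marker set) exceeds the detection threshold, reported to the nearest
#' whole percent.
#'
#' @param norm a `normalized_abundance`.
#' @param markers marker ids to consider; default all.
#' @param tau detection threshold; detection means value strictly greater
#'   than `tau` (default 0).
#' @param combine `"per-marker"` returns one percentage per marker;
#'   `"any"` returns a single percentage for the set (detected if any
#'   member exceeds `tau`).
#' @return named numeric vector of whole-percent occurrences (or a single
#'   value for `combine = "any"`).
#' @export
occurrence <- function(norm, markers = NULL, tau = 0,
                       combine = c("per-marker", "any")) {
  stopifnot(inherits(norm, "normalized_abundance"))
  combine <- match.arg(combine)
  vals <- unflagged_values(norm)
  markers <- markers %||% rownames(vals)
  missing <- setdiff(markers, rownames(vals))
  if (length(missing))
    stop("unknown marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  vals <- vals[markers, , drop = FALSE]
  if (combine == "per-marker")
    round(100 * rowMeans(vals > tau))
  else
    round(100 * mean(apply(vals > tau, 2, any)))
}

#' Aggregate marker abundances into pathway groups
#'
#' Sums normalized marker values over the panel's pathway groups. Markers
#' absent from the panel are returned in an `ungrouped` attribute with a
#' warning.
#'
#' @param norm a `normalized_abundance`.
#' @param panel marker panel data.frame (see [default_marker_panel()]);
#'   duplicate KO ids (a marker in two groups) are rejected.
#' @return pathway_group x sample matrix; attribute `ungrouped` holds any
#'   markers not covered by the panel.
#' @export
pathway_aggregate <- function(norm, panel = default_marker_panel()) {
  stopifnot(inherits(norm, "normalized_abundance"))
  validate_marker_panel(panel)
  if (nrow(panel) == 0) stop("empty marker panel", call. = FALSE)
  vals <- norm$values
  grouped <- rownames(vals) %in% panel$ko_id
  if (any(!grouped))
    warning("markers not in any pathway group: ",
            paste(rownames(vals)[!grouped], collapse = ", "))
  groups <- unique(panel$pathway_group)
  out <- matrix(0, nrow = length(groups), ncol = ncol(vals),
                dimnames = list(groups, colnames(vals)))
  for (g in groups) {
    kos <- intersect(panel$ko_id[panel$pathway_group == g], rownames(vals))
    out[g, ] <- if (length(kos))
      colSums(vals[kos, , drop = FALSE]) else 0
  }
  out[, norm$flagged] <- NA_real_
  attr(out, "ungrouped") <- vals[!grouped, , drop = FALSE]
  out
}

#' Free-living vs particle-attached enrichment tests
#'
#' Two-sided Wilcoxon rank-sum test per pathway (row) between FL and PA
#' samples. The exact null distribution is used when the smaller group has
#' at most 10 samples and there are no ties; otherwise the normal
#' approximation with tie correction applies. Rows with `p < alpha` are
#' flagged, with the enriched side being the fraction with the larger rank
#' sum.
#'
#' @param pathways pathway x sample matrix (e.g. from
#'   [pathway_aggregate()]).
#' @param metadata data.frame with `sample_id` and `fraction` columns
#'   (`FL`/`PA`); each fraction needs at least 2 unflagged samples.
#' @param alpha significance threshold for flagging (default 0.05).
#' @return data.frame: `pathway`, `W`, `p`, `enriched_side` (`FL`, `PA` or
#'   `none`), `significant`.
#' @export
lifestyle_enrichment <- function(pathways, metadata, alpha = 0.05) {
  stopifnot(all(c("sample_id", "fraction") %in% names(metadata)))
  frac <- setNames(metadata$fraction, metadata$sample_id)
  keep <- colnames(pathways)[colSums(is.na(pathways)) < nrow(pathways)]
  fl <- keep[frac[keep] == "FL"]; pa <- keep[frac[keep] == "PA"]
  if (length(fl) < 2 || length(pa) < 2)
    stop("need at least 2 samples per fraction", call. = FALSE)

  rows <- lapply(rownames(pathways), function(pw) {
    x <- pathways[pw, fl]; y <- pathways[pw, pa]
    exact <- min(length(x), length(y)) <= 10 &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact))
    r <- rank(c(x, y))
    mean_fl <- mean(r[seq_along(x)]); mean_pa <- mean(r[-seq_along(x)])
    side <- if (wt$p.value < alpha) {
      if (mean_fl > mean_pa) "FL" else "PA"
    } else "none"
    data.frame(pathway = pw, W = unname(wt$statistic), p = wt$p.value,
               enriched_side = side, significant = wt$p.value < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman correlation between two markers
#'
#' Tie-corrected Spearman rank correlation over samples where both markers
#' are unflagged, with the usual t-approximation p-value (exact when no
#' ties and few samples, as in [stats::cor.test()]).
#'
#' @param norm a `normalized_abundance`.
#' @param a,b marker ids.
#' @return list with `rho`, `p`, `n`.
#' @export
marker_correlation <- function(norm, a, b) {
  vals <- unflagged_values(norm)
  for (m in c(a, b))
    if (!m %in% rownames(vals))
      stop(sprintf("marker '%s' not in table", m), call. = FALSE)
  x <- vals[a, ]; y <- vals[b, ]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 4)
    stop("markers share fewer than 4 unflagged samples", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant marker vector: Spearman correlation undefined",
         call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
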