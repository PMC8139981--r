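# Genome-bin scoring: QC gating into MAGs, KEGG-module completeness,
# taxonomy-rank novelty and rule-based metabolic trait classification.

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

#' Construct a genome bin
#'
#' @param bin_id identifier.
#' @param completeness estimated genome completeness, percent.
#' @param contamination estimated contamination (single-copy gene
#'   redundancy), percent.
#' @param domain `bacteria`, `archaea` or `other`.
#' @param taxonomy named character vector over the ranks
#'   domain...species; unassigned ranks are `NA`. Assigned ranks must form
#'   a prefix (no species without genus).
#' @param ko_presence character vector of KO ids present in the bin.
#' @param pfam_presence character vector of Pfam ids present.
#' @param contig_lengths integer contig lengths (bp).
#' @param transporter_gene_count number of organic-compound transporter
#'   genes.
#' @param rrna_intervals optional data.frame (`contig`, `start`, `end`,
#'   1-based inclusive) of rRNA features.
#' @return object of class `genome_bin`.
#' @export
genome_bin <- function(bin_id, completeness, contamination,
                       domain = c("bacteria", "archaea", "other"),
                       taxonomy = NULL, ko_presence = character(0),
                       pfam_presence = character(0),
                       contig_lengths = integer(0),
                       transporter_gene_count = 0L,
                       rrna_intervals = NULL) {
  domain <- match.arg(domain)
  if (is.na(completeness) || is.na(contamination))
    stop(sprintf("bin '%s' is missing completeness or contamination",
                 bin_id), call. = FALSE)
  if (completeness < 0 || completeness > 100)
    stop(sprintf("bin '%s': completeness must be in [0, 100]", bin_id),
         call. = FALSE)
  if (contamination < 0)
    stop(sprintf("bin '%s': contamination must be >= 0", bin_id),
         call. = FALSE)
  tax <- setNames(rep(NA_character_, length(TAXONOMY_RANKS)),
                  TAXONOMY_RANKS)
  if (!is.null(taxonomy)) {
    bad <- setdiff(names(taxonomy), TAXONOMY_RANKS)
    if (length(bad)) stop("unknown taxonomy rank(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    tax[names(taxonomy)] <- ifelse(nzchar(taxonomy), taxonomy,
                                   NA_character_)
  }
  assigned <- !is.na(tax)
  if (any(assigned) && !all(assigned[seq_len(max(which(assigned)))]))
    stop(sprintf("bin '%s': assigned taxonomy ranks must form a prefix",
                 bin_id), call. = FALSE)
  structure(list(bin_id = bin_id, completeness = completeness,
                 contamination = contamination, domain = domain,
                 taxonomy = tax,
                 ko_presence = unique(ko_presence),
                 pfam_presence = unique(pfam_presence),
                 contig_lengths = contig_lengths,
                 transporter_gene_count = transporter_gene_count,
                 rrna_intervals = rrna_intervals),
            class = "genome_bin")
}

#' @export
print.genome_bin <- function(x, ...) {
  cat(sprintf("Genome bin %s [%s]: completeness %.1f%%, contamination %.1f%%, %d KOs\n",
              x$bin_id, x$domain, x$completeness, x$contamination,
              length(x$ko_presence)))
  invisible(x)
}

#' Quality-gate genome bins into MAGs
#'
#' Keeps bins with completeness at or above `min_completeness` and
#' contamination strictly below `max_contamination` (the medium/high
#' quality MAG convention), and reports bin counts per domain.
#'
#' @param bins list of [genome_bin()] objects.
#' @param min_completeness inclusive lower completeness bound (default 50).
#' @param max_contamination exclusive upper contamination bound
#'   (default 10).
#' @return list with `mags` (the retained bins), `n`, and `domain_counts`.
#' @export
qc_filter <- function(bins, min_completeness = 50, max_contamination = 10) {
  stopifnot(all(vapply(bins, inherits, logical(1), "genome_bin")))
  keep <- vapply(bins, function(b)
    b$completeness >= min_completeness &&
      b$contamination < max_contamination, logical(1))
  mags <- bins[keep]
  domains <- vapply(mags, `[[`, character(1), "domain")
  counts <- table(factor(domains, levels = c("bacteria", "archaea",
                                             "other")))
  list(mags = mags, n = length(mags),
       domain_counts = setNames(as.integer(counts), names(counts)))
}

#' Load pathway-module definitions
#'
#' Reads a JSON module snapshot (`module_id`, `label`, `kos` per module).
#' The default snapshot ships with the package and is assembled from the
#' energy-metabolism marker panel; users analysing real genomes should
#' supply their own KEGG release snapshot in the same format.
#'
#' @param path JSON file; default the shipped snapshot.
#' @return named list of module definitions (each with `module_id`,
#'   `label`, `kos`).
#' @export
read_module_definitions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "modules.json",
                                package = "bathymet")
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
  mods <- lapply(parsed$modules, function(m) {
    if (length(m$kos) == 0)
      stop(sprintf("module '%s' has an empty KO set", m$module_id),
           call. = FALSE)
    list(module_id = m$module_id, label = m$label,
         kos = unique(unlist(m$kos)))
  })
  setNames(mods, vapply(mods, `[[`, character(1), "module_id"))
}

#' Pathway-module completeness of a genome bin
#'
#' Completeness of module M is `100 * |ko_presence(bin) ∩ M| / |M|`; KO
#' presence is binary, so multi-copy annotations count once.
#'
#' @param bin a [genome_bin()].
#' @param modules module definitions (see [read_module_definitions()]).
#' @return named numeric vector of per-module completeness percentages.
#' @export
module_completeness <- function(bin, modules = read_module_definitions()) {
  stopifnot(inherits(bin, "genome_bin"))
  if (length(modules) == 0) stop("no module definitions", call. = FALSE)
  vapply(modules, function(m) {
    if (length(m$kos) == 0)
      stop(sprintf("module '%s' has an empty KO set", m$module_id),
           call. = FALSE)
    100 * length(intersect(bin$ko_presence, m$kos)) / length(m$kos)
  }, numeric(1))
}

#' Candidate taxonomic novelty of a MAG
#'
#' The candidate novelty level is the rank immediately below the deepest
#' assigned rank: a MAG assigned to genus but not species is a candidate
#' novel species; one assigned only to phylum is a candidate novel class.
#' A fully assigned MAG has novelty `none`.
#'
#' @param mag a [genome_bin()].
#' @return character scalar: `"none"` or `"novel <rank>"`.
#' @export
novelty_rank <- function(mag) {
  stopifnot(inherits(mag, "genome_bin"))
  assigned <- !is.na(mag$taxonomy)
  if (!any(assigned)) return("novel domain")
  deepest <- max(which(assigned))
  if (deepest == length(TAXONOMY_RANKS)) return("none")
  paste("novel", TAXONOMY_RANKS[deepest + 1L])
}

#' Per-rank classification summary of a MAG set
#'
#' @param mags list of [genome_bin()] objects.
#' @return data.frame: `domain`, `rank`, `classified_fraction`,
#'   `unclassified_fraction`, `n`.
#' @export
novelty_summary <- function(mags) {
  domains <- vapply(mags, `[[`, character(1), "domain")
  do.call(rbind, lapply(unique(domains), function(d) {
    set <- mags[domains == d]
    do.call(rbind, lapply(TAXONOMY_RANKS, function(r) {
      cl <- mean(vapply(set, function(m) !is.na(m$taxonomy[[r]]),
                        logical(1)))
      data.frame(domain = d, rank = r, classified_fraction = cl,
                 unclassified_fraction = 1 - cl, n = length(set),
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Load metabolic trait rules
#'
#' @param path JSON rule file; default the shipped rules. The file defines
#'   a `symbol_map` (gene symbol to KO id, user-editable) and a list of
#'   rules; a rule fires when all its clauses hold, and a clause holds
#'   when any listed feature is present (namespaces `ko`, `pfam`,
#'   `symbol`, `rubisco_form`, `domain`) or, for `transporters`, when the
#'   bin's transporter gene count reaches `min`.
#' @return list with `symbol_map` and `rules`.
#' @export
read_trait_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "trait_rules.json",
                                package = "bathymet")
  jsonlite::read_json(path, simplifyVector = TRUE,
                      simplifyDataFrame = FALSE)
}

TRAIT_NAMESPACES <- c("ko", "pfam", "symbol", "rubisco_form", "domain",
                      "transporters")

#' Rule-based metabolic trait classification of a MAG
#'
#' Evaluates every trait rule against the bin's KO/Pfam presence, domain,
#' transporter gene count and (when the bin carries RuBisCO genes) the
#' supplied RuBisCO form labels. Form labels are an input, since form
#' assignment is reference/phylogeny-based: carbon-fixation traits require
#' an autotrophic Form I or II RuBisCO; Form IV alone never grants
#' autotrophy.
#'
#' @param mag a [genome_bin()].
#' @param rules trait rules (see [read_trait_rules()]).
#' @param rubisco_forms named character vector mapping the bin's RuBisCO
#'   genes to forms (`"I"`, `"II"`, `"IV"`); required when the bin carries
#'   K01601 or K01602.
#' @return character vector of trait labels attached to the bin.
#' @export
classify_traits <- function(mag, rules = read_trait_rules(),
                            rubisco_forms = NULL) {
  stopifnot(inherits(mag, "genome_bin"))
  carries_rubisco <- any(c("K01601", "K01602") %in% mag$ko_presence)
  if (carries_rubisco && is.null(rubisco_forms))
    stop(sprintf("bin '%s' carries RuBisCO genes; `rubisco_forms` required",
                 mag$bin_id), call. = FALSE)
  forms <- if (is.null(rubisco_forms)) character(0)
           else unique(unname(rubisco_forms))
  symbol_map <- unlist(rules$symbol_map)

  clause_ok <- function(cl) {
    ns <- cl$namespace
    if (!ns %in% TRAIT_NAMESPACES)
      stop(sprintf("trait rule references unknown namespace '%s'", ns),
           call. = FALSE)
    switch(ns,
      ko = any(unlist(cl$any_of) %in% mag$ko_presence),
      pfam = any(unlist(cl$any_of) %in% mag$pfam_presence),
      symbol = {
        syms <- unlist(cl$any_of)
        unknown <- setdiff(syms, names(symbol_map))
        if (length(unknown))
          stop(sprintf("symbol '%s' missing from symbol_map", unknown[1L]),
               call. = FALSE)
        any(symbol_map[syms] %in% mag$ko_presence)
      },
      rubisco_form = any(unlist(cl$any_of) %in% forms),
      domain = mag$domain %in% unlist(cl$any_of),
      transporters = mag$transporter_gene_count >= cl$min)
  }

  labels <- vapply(rules$rules, function(r)
    if (all(vapply(r$clauses, clause_ok, logical(1)))) r$label
    else NA_character_, character(1))
  labels[!is.na(labels)]
}
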