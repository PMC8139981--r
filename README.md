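# bathymet

Gene-centric and genome-centric analysis of bathypelagic (deep-ocean)
shotgun metagenomes, for microbial ecologists who want the standard
deep-ocean workflow — gene catalog, functional structure, marker
metabolism, MAG scoring, genome abundance — as tested, reusable R
functions rather than a chain of one-off scripts.

## What it computes

* **Non-redundant gene catalogs.** Greedy incremental clustering of
  nucleotide coding sequences, longest first, joining a representative
  when the best local alignment (either strand) has identity ≥ *c*
  (default 0.95, matching columns / alignment columns) and covers ≥ *aS*
  (default 0.90) of the shorter sequence; genes ≤ 100 nt are excluded.
  Two-set integration against a reference catalog labels clusters
  exclusive (MPG) or mixed (MG), and sample-specific clusters (SSG:
  exclusive + single-sample) are flagged per sample.
* **Functional community structure.** Feature × sample tables under
  KO/COG/Pfam/EC schemes, rarefaction without replacement, Bray–Curtis
  dissimilarity *d(x,y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)*, NMDS (Kruskal stress-1,
  random restarts), and PERMANOVA with sequential sums of squares from the
  Gower-centered distance matrix, free permutations, per-term R² and
  pseudo-F.
* **Marker metabolism.** A 49-KO panel of energy-metabolism markers
  (carbon fixation, CO, H₂, methane/C1, nitrogen, sulfur) normalized by
  the single-copy gene *recA* — marker reads / recA reads as a
  copies-per-cell proxy — plus occurrence, pathway aggregation,
  FL-vs-PA Wilcoxon enrichment and Spearman marker correlation.
* **Genome (MAG) scoring.** Quality gating (completeness ≥ 50%,
  contamination < 10%), flat-fraction KEGG-module completeness,
  taxonomy-rank novelty (the rank below the deepest assignment), and
  rule-based traits (NCD, AOA/AOB/NOB, SOB, CO/H₂ oxidizers,
  CBB-autotrophs, mixotroph candidates).
* **Genome abundance.** Competitive read recruitment (best hit by score,
  identity > 95%, read coverage > 90%, rRNA-overlapping hits discarded)
  expressed as RPKG = assigned reads / (genome kbp × sample Gbp), with
  read-recovery and basin × size-fraction summaries.
* **Synthetic communities.** A simulator producing genomes, redundant
  gene pools, FL/PA sample sets with a planted lifestyle effect of size
  δ, and reads with known origins — full ground truth for validating
  every stage.

## Worked example

Simulate a 12-sample free-living / particle-attached design with a
lifestyle effect (δ = 4) planted on the DNRA genes (*nirB*/*nirD*) and
*hoxH*, then recover it:

```r
library(bathymet)

cm  <- generate_community(n_genomes = 3, n_kos = 15, seed = 42)
ss  <- generate_samples(cm, n_fl = 6, n_pa = 6, delta = 4, seed = 43,
                        effect_kos = c("K00362", "K00363", "K00436"))
tab <- build_abundance_table(community_annotations(cm), ss$counts,
                             scheme = "KO")
rar <- rarefy(tab, depth = 25000, seed = 44)
permanova(bray_curtis(rar), ss$metadata, c("fraction", "basin"),
          n_perm = 999, seed = 45)
#> PERMANOVA (999 permutations)
#>          Df SumOfSqs     R2     F Pr(>F)
#> fraction  1  0.12839 0.2794 4.219  0.001
#> basin     3  0.11810 0.2570 1.294  0.157
#> Residual: Df = 7, R2 = 0.4636
```

The lifestyle term dominates the variance partition (R² = 0.28,
p = 0.001) while the unplanted basin term does not. The same effect shows
up as PA-side enrichment of the recA-normalized pathway profiles
(`pathway_aggregate()` warns about KOs outside the marker panel;
suppressed here):

```r
norm <- recA_normalize(tab)
agg  <- suppressWarnings(pathway_aggregate(norm))
enr  <- lifestyle_enrichment(agg, ss$metadata)
head(enr[order(enr$p), c("pathway", "p", "enriched_side")], 3)
#>                                   pathway           p enriched_side
#> 8                            H2 oxidation 0.002164502            PA
#> 15 dissimilatory nitrate reduction (DNRA) 0.025974026            PA
#> 6            3-hydroxypropionate bi-cycle 0.064935065          none
```

Both planted pathways are flagged on the particle-attached side; the
best unplanted pathway is not significant.

## Layout

* `R/`, `src/` — implementation (R plus an Rcpp Smith–Waterman /
  seeded-mapping kernel)
* `inst/extdata/` — marker panel (TSV), module snapshot and trait rules
  (JSON)
* `vignettes/bathymet-methods.Rmd` — model, assumptions, parameter and
  design choices, limitations
* `tests/testthat/` — unit, property and acceptance suites (alignment
  and clustering validated against independent `Biostrings` /
  `vegan::adonis2` oracles)
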