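---
title: "Methods: gene catalogs, functional structure and genome abundance in deep-ocean metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene catalogs, functional structure and genome abundance in deep-ocean metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`bathymet` implements the computational core of a gene- and genome-centric
analysis of bathypelagic (deep-ocean) shotgun metagenomes:

1. **Gene catalogs** — greedy incremental clustering of predicted coding
   sequences at a nucleotide-identity threshold, two-set integration
   against a reference catalog, and exclusive / mixed / sample-specific
   gene accounting.
2. **Functional structure** — feature-by-sample abundance tables,
   rarefaction without replacement, Bray–Curtis dissimilarity, NMDS
   ordination and PERMANOVA variance partitioning across lifestyle
   (free-living, FL, 0.2–0.8 µm vs particle-attached, PA, 0.8–20 µm),
   basin and ocean factors.
3. **Marker metabolism** — per-cell-proxy profiles of energy-metabolism
   marker genes obtained by dividing marker read counts by reads assigned
   to the single-copy recombinase *recA*, pathway aggregation, occurrence,
   FL-vs-PA rank-sum enrichment and marker cross-correlation.
4. **Genome metabolism** — quality gating of genome bins into MAGs,
   flat-fraction pathway-module completeness, taxonomy-rank novelty, and
   rule-based trait classification (diazotrophy, nitrifier guilds,
   CO/H2/sulfur oxidation, CBB autotrophy, mixotrophy candidates).
5. **MAG abundance** — competitive read recruitment with identity,
   read-coverage and rRNA-exclusion filters, expressed as RPKG (reads per
   genomic kilobase and sample gigabase).
6. **Synthetic communities** — a simulator that generates genomes, genes,
   redundant gene pools, FL/PA sample sets and reads with complete ground
   truth, so every downstream stage can be validated against known
   answers.

Assembly, binning, gene prediction and annotation are out of scope: the
package consumes their outputs (sequences, annotations, QC estimates,
taxonomy ranks) as inputs.

# Gene-catalog clustering

Genes strictly longer than 100 nt enter the catalog. They are processed
longest-first (ties broken lexicographically by gene id, C collation), and
each gene joins the first existing representative whose best local
alignment — on either strand — reaches identity `c` (default 0.95, defined
as matching columns over alignment columns) while covering at least the
fraction `aS` (default 0.90) of the shorter sequence. Otherwise the gene
founds a new cluster. This mirrors the semantics of greedy
nucleotide-space catalog builders used for ocean gene catalogs (local
alignment scoring, both strands, coverage of the shorter sequence).

The alignment kernel is a Smith–Waterman implementation (Rcpp) with match
+1, mismatch −2 and affine gaps costing 2 + L for a gap of length L. A
candidate prefilter counts positions of the query whose k-mer (default
word size 8) occurs in the candidate representative. The prefilter is
*admissible*: an alignment with identity ≥ c over L columns has at most
(1−c)·L non-matching columns, which break the matched columns into runs
contributing at least `c·L − ((1−c)·L + 1)(k−1)` seed positions, so any
pair that could qualify must reach that count. The bound increases with L
whenever `(k−1) < c/(1−c)`, so it is evaluated at the shortest admissible
alignment; if the parameters make the bound vacuous the prefilter is
disabled rather than risked. Tests verify clustering output is identical
to a brute-force greedy reference that aligns all pairs with
`Biostrings::pairwiseAlignment`.

Catalog integration runs in two-set mode: each new-catalog representative
is compared only against reference representatives; matches become mixed
(MG) clusters folded into the reference cluster, non-matches stay
exclusive (MPG), so the merged catalog has `|reference| + |MPG|` clusters.
A cluster is sample-specific (SSG) when it is exclusive *and* all its
members come from a single sample; SSG ⊆ MPG by construction. Percentages
are reported to the nearest whole percent, matching how such accounting is
usually published.

Because the greedy order among equal-length sequences is not dictated by
the method we target, we fix lexicographic tie-breaking for determinism
without claiming to reproduce any particular external representative set.

# Functional structure

Abundance tables sum per-gene read counts into one row per functional
feature (KO, COG, Pfam or EC); genes without annotation are kept in an
explicit `unannotated` row so column totals are conserved. An optional
length correction divides each gene's counts by its length in kilobases
before aggregation (the convention of coverage-derived functional
profiles); whether any coverage weighting should apply before or after
length correction is not standardized across annotation pipelines, so the
table builder exposes the flag rather than hard-wiring one choice.

Rarefaction subsamples every sample without replacement to a common depth
via `vegan::rrarefy` (hypergeometric margins; column sums exactly equal
the target depth). Bray–Curtis dissimilarity is `vegan::vegdist`. NMDS
minimizes Kruskal stress-1 by monotone regression (`vegan::monoMDS`,
global model) from a configurable number of random starts (default 20),
returning the lowest-stress solution; because monotone regression uses
only the rank order of the input dissimilarities, any strictly increasing
transform of the distances leaves the fit unchanged, which the tests
assert. The exclusion of outlier samples from ordination figures is a
caller-level filter, not hard-coded behavior.

PERMANOVA is implemented in the package: the distance matrix is
Gower-double-centered (`G = (I − J/n)(−d²/2)(I − J/n)`), sequential
(Type-I) sums of squares are traces of `G` against the projection
increments of the nested design matrices, pseudo-F is the term mean square
over the residual mean square, and p-values come from free (unrestricted)
permutation of samples, `p = (1 + #{F* ≥ F}) / (n_perm + 1)`. Supplying an
explicit permutation matrix (for example the full enumeration on six
samples) switches to exact enumeration, `p = #{F* ≥ F} / n_perm`. The
implementation is cross-checked in the tests against `vegan::adonis2`
(identical R² and F) and against a closed-form one-way decomposition of
raw pairwise distances. Sequential SS makes term order meaningful; the
default analysis order is lifestyle first, then basin, then ocean,
matching how these factors are usually reported for bathypelagic
communities. Free permutations are used because no restricted exchange
structure is imposed by the design.

# Marker metabolism

The shipped panel covers 49 KEGG orthologs spanning inorganic carbon
fixation (rTCA, CBB, 3-HP bi-cycle, hydroxypropionate–hydroxybutyrate),
CO and H2 oxidation, methane/C1 metabolism, nitrogen cycling
(nitrification, N2 fixation, DNRA, denitrification, assimilatory nitrate
reduction) and dissimilatory sulfate reduction, each with a pathway group
used for aggregation. recA is identified by a configurable feature id
(`COG0468` with a `K03553` alias) because the normalizing feature may live
in a different annotation scheme than the profiled markers; the mapping
must be explicit, so the panel file carries ids per scheme. Normalization
runs on un-rarefied counts — the ratio cancels depth, and subsampling
would only discard information — and samples with zero recA reads are
flagged and excluded from summaries rather than silently dropped. Markers
absent from a dataset are reported as absent, since absence (e.g. of
anammox markers in oxygenated bathypelagic water) is itself a finding.

Detection in `occurrence()` means strictly greater than the threshold
`tau`, which defaults to 0 because no detection floor is part of the
method; occurrence is monotone non-increasing in `tau`. FL-vs-PA
enrichment uses the two-sided Wilcoxon rank-sum test with the exact null
when the smaller group has ≤ 10 samples and no ties, and the
tie-corrected normal approximation otherwise; the enriched side is the
fraction with the larger mean rank. Marker co-occurrence uses
tie-corrected Spearman correlation.

# Genome metabolism

Bins become MAGs when completeness ≥ 50% and contamination < 10%
(inclusive lower bound, strict upper bound). Module completeness is the
flat percentage of a module's KOs present in the bin; KO presence is
binary, so multi-copy annotations count once. Some published module
colorings use boolean block logic (AND/OR within a module definition)
instead of the flat fraction; the flat fraction is what this package
implements, and block logic is intentionally not guessed at. The shipped
module snapshot is assembled from the marker panel's pathway groups and is
versioned; users analysing real genomes should supply their own KEGG
release snapshot in the same JSON format, because module membership
drifts across releases.

Taxonomic novelty is purely structural: the candidate level is the rank
immediately below the deepest assigned rank (genus-but-no-species →
candidate novel species), with no parsing of placeholder names. Trait
rules are data (JSON): each rule is a conjunction of clauses over KO,
Pfam, gene-symbol, RuBisCO-form, domain and transporter-count namespaces,
with gene symbols resolved through an editable symbol map (nifD/nifK KO
ids, for instance, are conventions the user can override). RuBisCO form
labels are an input because form assignment is phylogenetic and out of
scope; autotrophy-dependent labels require Form I or II plus
phosphoribulokinase, and Form IV alone never grants them. The mixotrophy
transporter threshold defaults to 4 — the bottom of the observed range of
organic-compound transporter counts in RuBisCO-carrying deep-ocean MAGs —
and is exposed in the rule file because no hard cutoff is established.

# MAG abundance

Reads are first subsampled, without replacement, to the depth of the
shallowest sample, so abundances are compared at equal depth; sample
gigabases are computed from the retained reads. Competitive mapping finds
candidate hits by k-mer seeded (word size 13) banded local alignment with
the same scoring as the catalog kernel, searches both strands, and keeps
at most one assignment per read: best score, ties broken by higher
identity and then lexicographically by genome id (the last tie rule is
ours, fixed for determinism). An assignment survives only if identity is
strictly above 95%, the aligned fraction of the read is strictly above
90%, and the alignment footprint does not overlap any annotated rRNA
interval by even one base — rRNA regions are conserved enough to attract
spurious cross-taxon hits. "Alignment coverage" is interpreted against
the read (the mapped unit); the alternative denominator (the alignment on
the reference) is not used, and this interpretation is deliberately
explicit. RPKG is `assigned reads / (genome kbp × sample Gbp)`; zeros are
retained, and basin × fraction summaries distinguish *absent* (all
observed values zero) from *no data* (no samples in the cell).

# The synthetic-community generator

The simulator is first-class, tested code, and its defaults define the
study conditions for all recovery tests:

* genomes are uniform-random nucleotide sequences (A/C/G/T only — no
  ambiguity codes, keeping alignment oracles simple) partitioned into
  contigs, with one rRNA-labeled interval planted per genome so the
  rRNA-exclusion filter is exercised;
* every genome carries exactly one recA-equivalent single-copy gene;
  marker-panel KOs are planted at 0–3 copies per cell and recorded as
  truth; background genes draw from a configurable KO universe with 20%
  unannotated;
* gene pools emit each gene `redundancy` times with i.i.d. point
  substitutions; expected pairwise identity between copies,
  `(1 − µ)² + µ²/3`, is recorded, and copies expected to fall below the
  clustering threshold are flagged separable;
* per-sample gene counts come from a Dirichlet-multinomial whose weights
  are genome abundance × gene length × copy number, with a designated KO
  subset multiplied by `(1 + δ)` in PA samples (δ = 0 gives exchangeable
  samples, the PERMANOVA null) and an optional basin effect of the same
  form; the Dirichlet concentration controls overdispersion so the
  permutation null is exercised against realistic noise;
* reads are single-end, sampled proportional to composition × genome
  length, uniformly along contigs, on a uniform strand, with i.i.d.
  substitution errors. Pairing is omitted because it adds no tested
  behavior; read pairs would simply count as two reads in gigabase
  accounting.

The generator does **not** emulate insert-size, GC or coverage biases,
real gene phylogenies, horizontally shared genes, or quality-score
profiles. Passing recovery tests therefore demonstrates correctness of
the pipeline's logic under its stated model, not robustness to every
artifact of real libraries.

# Numerical choices and problem sizes

* Greedy order ties and competitive-mapping ties are broken
  lexicographically; all stochastic steps take explicit seeds and restore
  the caller's RNG state.
* NMDS uses 20 random starts and tight stop tolerances
  (`sfgrmin = 1e-7`); monotone-regression ties get the primary
  (averaging) treatment of the underlying optimizer.
* The validation suite sizes its simulations for a desk machine: null
  calibration uses 200 replicates of 12 samples with 199 permutations
  each (rejecting at p ≤ 0.05, whose null rate is exactly 0.05 for a
  valid permutation test); the clustering oracle comparison runs 50
  random pools of roughly 10–15 genes; per-cell recovery samples 400,000
  reads over ~200 genes so every gene sits far above 100 reads, and
  asserts the 90th percentile of relative error below 10% (at exactly 100
  reads the counting noise alone is ~10%, so the criterion is read as an
  aggregate bound, with the median additionally below 5%); RPKG recovery
  maps 2,500 reads per sample at 1% error against five genomes. The
  multinomial sanity check on error-free recruitment uses a chi-square
  goodness-of-fit at the 99% level, the joint analogue of per-genome
  exact bounds.

# Known limitations

* The greedy catalog is quadratic in the number of clusters per query in
  the worst case; it is meant for method validation and moderate inputs,
  not for reproducing catalogs with tens of millions of genes.
* PERMANOVA assumes exchangeability under free permutation; no
  restricted permutation schemes or dispersion diagnostics are provided.
* Module completeness ignores within-module boolean structure.
* The read mapper is a self-contained recruitment kernel with the filter
  semantics above; it does not aim for score-for-score parity with any
  external search tool, and acceptance of the abundance stage rests on
  filter semantics and recovery properties instead.
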