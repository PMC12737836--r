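---
title: "Tracing allotetraploid subgenome origins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing allotetraploid subgenome origins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokin)
```

## The problem

An allotetraploid species carries two diverged diploid genomes — an A and
a B subgenome — in a single nucleus, the product of an interspecific
hybridization followed by genome doubling. Identifying which extant wild
diploids are closest to each subgenome is a question about genetic
relatedness across a reference panel: dissect the polyploid's assembly
into its subgenomes, genotype each component at the same markers used to
genotype the wild panel, and ask which wild accession each component
resembles most. `allokin` implements that chain end to end and ships a
synthetic study generator with known ground truth, so every stage can be
validated against an answer that is known by construction.

## In-silico probe genotyping

The marker unit is an Axiom-style probe set: a biallelic SNP written
`[X/Y]` between two 35 bp flanking arms, 71 bp in total. Genotyping an
assembly in silico means finding where a probe's two allele sequences
place on the assembly and reading off the allele:

* Both allele sequences are searched on both strands, ungapped and
  full-length only. Because alignments with indels or partial length are
  excluded anyway, the search is defined directly as mismatch-bounded
  exact placement, with a completeness contract: the result equals an
  exhaustive scan of every offset and strand. The implementation seeds
  candidates with exact half-arm matches (pigeonhole: with at most one
  mismatch per arm, at least one of the two disjoint halves of each arm
  is exact) and verifies every candidate in full, so the contract holds
  by construction; the test suite checks it against a literal
  exhaustive scan.
* The SNP base itself must match one allele exactly. Each flanking arm
  tolerates at most one mismatch (`per_arm` mode, the default). The
  alternative reading — at most one mismatch in the two arms combined —
  is available as `align_config(mismatch_mode = "total")`.
* A call is made only when exactly one placement survives; zero
  placements are logged as `absent`, two or more as `ambiguous`, and
  both emit the missing code `N`.

For a tetraploid assembly the chromosomes are partitioned into
subgenomes (by default from the leading `A`/`B` of the chromosome name)
and the search space and the uniqueness rule are restricted to each
subgenome separately. Without this, every marker whose flanks are
conserved between the subgenomes would be vetoed by its homoeologous
copy, and the dissected call sets would collapse.

## Panel building and the three-step filter

Wild-panel array calls and dissected in-silico calls are merged over the
intersection of their marker lists (`merge_panels`). Because all samples
share one ordered marker list, per-sample "pseudosequences" —
concatenated calls, `N` for missing — are positionally comparable with
no realignment step; any multiple-alignment pass over such sequences
would be the identity, which is why none exists in this package.

Filtering applies three steps in order (`run_filter_pipeline`):

1. **Polymorphism**: markers with fewer than two distinct non-missing
   IUPAC codes are dropped. Distinctness is at the code level, so a
   heterozygous call against a homozygous one counts as polymorphism —
   assembly columns are haploid while array columns may be heterozygous.
2. **Minor allele frequency**: allele copies are counted from the codes
   (homozygote = 2, heterozygote = 1 + 1, `N` skipped); markers with MAF
   strictly below 0.05 are dropped, so a marker sitting exactly at the
   threshold survives. Markers showing more than two alleles are dropped
   with their own reason code.
3. **Missingness**: markers with more than 3% missing calls are dropped.
   The bound can instead be applied to sample columns
   (`missing_axis = "sample"`); the marker axis is the default because
   the analysis-ready object is a marker set.

## Relatedness readouts

Three views of the same matrix, deliberately kept consistent:

* **IBS similarity** (`ibs_matrix`): per pair, over markers where both
  calls are present, each site contributes the shared-allele count of
  the two genotypes divided by two (`A` vs `A` scores 1, `A` vs `M`
  scores 0.5, `A` vs `C` scores 0); similarity is the mean site score.
  Missing data are excluded pairwise and never imputed, which keeps the
  headline nearest-relative readout imputation-free.
* **PCA** (`encode_dosage`, `euclidean_distances`, `pcoa`): calls are
  encoded as major-allele dosages (0/1/2; ties between alleles resolve
  to the lexicographically smaller base, which only relabels the axis
  and provably leaves all distances unchanged), missing dosages are
  mean-imputed per marker, and classical scaling of the Euclidean
  distance matrix is applied. For Euclidean input, classical scaling
  coincides with covariance PCA: scores match up to sign and the
  reported eigenvalues are on the covariance scale. `select_pcs` returns
  the smallest component count whose cumulative explained variance
  strictly exceeds 80%.
* **Tree** (`pdistance_matrix`, `bootstrap_support`): pairwise distances
  are one minus the mean IBS site score — the exact complement of the
  similarity — followed by canonical neighbor joining. NJ replaces
  likelihood-based inference deliberately: at array scale (a few
  thousand SNP sites, shallow divergence) distance methods are adequate,
  and NJ admits an exact oracle — on additive distances the true tree is
  recovered exactly — which makes the inference testable in a way an
  approximate-likelihood heuristic is not. This is the package's largest
  methodological substitution and it is intentional. Support values are
  nonparametric bootstrap proportions over marker columns; they are not
  numerically comparable to approximate-likelihood resampling supports,
  and only the qualitative maximal-support regime carries over.

`find_sister` reads the sister group of a focal clade across its stem
edge in the unrooted tree. The far end of the stem edge touches two
clades; the smaller one is returned (ties break on lexicographic tip
labels), which matches the conventional rooted sister whenever the
larger side contains the outgroup. For a tip whose two adjacent clades
tie in size the choice is a convention, and it is stated rather than
hidden.

### Which matrix feeds which readout

PCA and the tree run on the fully filtered matrix. The IBS
nearest-neighbor ranking in `run_pipeline` runs on the merged matrix
after the polymorphism filter only. The reason is ascertainment: once
the tetraploid columns are merged, a marker private to the true parent
accession is carried by the parent plus the tetraploid tips — but a
marker private to any *other* single accession has minor allele
frequency 2 copies out of ~68 and is removed by the MAF step. MAF
filtering therefore strips exactly the accession-level variation that
separates the parent from its conspecifics, while species-level
variation (which drives the PCA clusters and the tree's clades)
survives. Ranking similarity on the lightly filtered matrix keeps the
accession-level signal; IBS needs no missingness filter because missing
data are excluded pairwise by definition.

## Lineage-specific variant windows

Given a multi-lineage VCF in a common reference coordinate system, a
variant is specific to a focal lineage when the focal genotype is
explicitly called as an alternate allele and the comparator lineage is
explicitly called as the reference; a missing call on either side
excludes the variant, in both roles. Counts are taken in half-open
windows tiling each chromosome from coordinate 0 (2 Mb by default, 100
kb for fine grain; the last window truncates at the chromosome length),
with a variant assigned to the window containing `pos - 1`. Multi-bp
variants are assigned by start position — one unambiguous rule for both
window assignment and BED-region membership, chosen because any
span-based rule would make the two operations inconsistent with each
other. Restriction to genic BED intervals uses the same rule, and
`max_variant_span` reports the largest reference-allele length.

## The synthetic study generator

`simulate_panel` generates the statistical structure the inference
chain assumes, not a demographic reconstruction:

* A uniform-random proto-genome diverges into A- and B-pool ancestors,
  species ancestors, and accessions down a star-of-stars topology by
  substitutions only. Per-branch rates are substitutions/site, so two
  accessions of one species differ in expectation by about twice the
  accession rate. A star-of-stars is sufficient to create the nested
  clade structure the tree and IBS stages must recover; it is *not* a
  coalescent and should not be read as one.
* Substitution-only evolution keeps every genome the same length, so
  coordinates are homologous panel-wide and probes, truth variants and
  homoeologous-exchange segments need no alignment bookkeeping.
* One tetraploid origin: a chosen A-pool accession and a chosen B-pool
  accession are concatenated (chromosomes renamed `A01..`, `B01..`),
  each tetraploid sample then accumulates its own post-hybridization
  substitutions, and optional homoeologous-exchange segments copy one
  subgenome over the other at homologous coordinates — the process that
  erodes subgenome-specific signal in real polyploids.
* Probes are designed at sites segregating within each pool, with flanks
  taken from the pool ancestor. Flanks are required to be unique in that
  ancestor (either strand) and probe footprints may not overlap within a
  pool, which isolates the aligner's multi-hit logic to dedicated
  planted-copy tests instead of leaving it entangled with the generator.
* Array calls record the true base at each probe site for every diploid
  accession, then noise is applied: missing with probability `m`
  (default 0.01), flipped to the *other probe allele* with probability
  `e` (default 0) — a third allele is never introduced, matching
  biallelic array chemistry.

Default scale: 2 chromosomes of 200 kb per subgenome, 4 A-species and 2
B-species with 5 accessions each (30 diploids), 2 tetraploids, 800
probes per pool. These sizes give each stage real statistical structure
(hundreds of markers surviving the filters, resolvable clades) while a
full pipeline run stays well under half a minute; the replicated
acceptance analyses run ten such studies.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: recombination and incomplete
lineage sorting, indels and structural variation (probe placements on
real assemblies face gapped paralogy the ungapped model excludes by
filtering), array-specific artifacts such as off-target hybridization or
cluster-calling bias, heterozygosity in the wild panel (the simulated
diploids are effectively selfing/haploid), and uneven species sampling.

## Numerical choices and degenerate inputs

* MAF boundary is strict `<` removal; cumulative-variance PC selection
  is strict `>` exceedance. Both boundaries are tested at equality.
* Negative NJ branch lengths are clamped to zero after estimation
  (standard practice); the count is kept in `attr(tree, "n_clamped")`.
* In a bootstrap replicate a pair can, rarely, lose all comparable
  sites; that pair is assigned the maximum distance observed in the
  replicate rather than aborting the replicate. The reference-tree
  computation has no such fallback — there it is an error.
* A pair with no comparable markers gets an `NA` IBS value; markers
  missing in every sample are dropped (with a warning) before
  mean-imputation for PCA.
* Empty variant sets produce full zero-count tilings; an empty marker
  matrix passes through the filter pipeline as an empty report chain.
* `pcoa` reports `variance_percent` over the positive eigenvalues only;
  tiny negative eigenvalues from floating-point noise are reported but
  carry no variance share.

## Known limitations

* The placement search is exact and ungapped by design; it is not a
  general read mapper and does not model indel-containing placements at
  all (they are excluded, not scored).
* Bootstrap supports on very short pseudosequences (tens of markers) are
  noisy; the pipeline reports them as computed and leaves thresholding
  to the caller.
* The sister-group convention for size-tied adjacent clades is
  lexicographic and therefore arbitrary for perfectly balanced trees.
* Counts reported by different stages (markers surviving each filter,
  samples in each view) are the package's own; on real data they will
  not reconcile with externally curated marker sets marker-for-marker.
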