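---
title: "Somatic mtDNA heteroplasmy: filtering, annotation and selection statistics"
author: "mitoPattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic mtDNA heteroplasmy: filtering, annotation and selection statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoPattern)
```

## The problem

Tumour mitochondria carry hundreds to thousands of mtDNA copies per cell, so
somatic mutations exist as *heteroplasmies*: a fraction of molecules (the
variant allele frequency, VAF) carries the variant. Deep capture sequencing
of the 16,569 bp mitochondrial genome resolves heteroplasmies down to 1%,
but at that depth the dominant error modes are artifactual, not stochastic:
oxidative 8-oxoG damage during library preparation produces spurious low-VAF
C:G>A:T transversions, and formalin fixation (FFPE) produces low-VAF damage
calls recognisable by their read-pair orientation imbalance. Once filtered,
the *placement* of somatic mutations across the genome — control region
versus coding region, hypervariable versus conserved control-region
segments, OXPHOS complexes, tRNA stems versus loops — and the heteroplasmy
each mutation reaches are read-outs of the selective pressure a tumour
lineage exerts on its mitochondrial genome.

`mitoPattern` implements that analysis chain as composable pieces: a
validated rCRS coordinate model, the read-count-level filter cascade with
somatic classification, mtDNA copy-number estimation, strand-resolved
annotation, the region/complex/tRNA selection statistics, outcome
stratification, and a synthetic cohort generator with a planted-truth
ledger that exercises the chain end to end.

## The reference map

`buildReferenceMap()` assembles a circular, 1-based model of the rCRS:

* the 1122 bp control region (mtCTR) wrapping the origin as
  16024–16569 plus 1–576;
* hypervariable segments HVS1 16024–16383, HVS2 57–372, HVS3 438–574
  (813 bp total) and the derived 309 bp non-HVS remainder. The printed
  literature reports only the totals (813/309 bp); these segment
  coordinates are the standard definition uniquely consistent with them.
  Note that under these coordinates the masked homopolymer run at 303–311
  lies inside HVS2;
* all 13 protein genes with OXPHOS complex membership (I: ND1–ND6 and
  ND4L; III: CYB; IV: CO1–CO3; V: ATP6/ATP8) and coding strand (all heavy
  strand except ND6), 22 tRNA and 2 rRNA genes, and the light-strand
  replication origin;
* five masked repeat intervals (66–71, 303–311, 514–523, 12418–12425,
  16184–16193), ingested from BED (0-based half-open) with explicit
  conversion;
* derived intergenic spacers, so every position 1..16569 maps to at least
  one category (the small gaps between genes belong to no canonical
  category; an explicit `intergenic` label keeps lookups total);
* a per-gene tRNA cloverleaf element model (below).

All invariants — the 1122/813/309 totals, gene counts, complex membership,
full positional coverage, tRNA element partitions — are checked by the
`MitoGenomeMap` validity method at construction, so a user-supplied region
table that violates them fails with an error naming the rule.

```{r}
map <- buildReferenceMap()
map
locateRegion(map, c(310, 12300, 16300))
```

### The bundled sequence is a synthetic stand-in

The package bundles `inst/extdata/rcrs_synthetic.fa`: a *synthetic* 16,569
nucleotide sequence with rCRS-like base composition on NC_012920.1
coordinates (position 12300 fixed to G so the documented m.12300G>A
anticodon-loop example is representable). Every coordinate annotation is the
real rCRS model; only the base string is random. Consequence calls and
spectra computed against the stand-in are internally consistent and fully
testable, but are not the consequences of real rCRS alleles: for production
use, pass the genuine NC_012920.1 FASTA via
`buildReferenceMap(sequenceFile = ...)`.

### tRNA cloverleaf model

Per-gene stem/loop boundaries for the 22 mitochondrial tRNAs are not
tabulated in a machine-readable source we can ship, so the package derives
each gene's partition from the canonical cloverleaf template — acceptor
stem (7), D arm (4+8+4), anticodon arm (5+7+5), variable region (4), T arm
(5+5+7), closing acceptor stem (7) — scaled to the gene's length: surplus
positions extend the variable region then the D loop; deficits shrink the D
loop first (the D-arm-less mt-tRNA-Ser(AGY)) then the variable region.
Genes encoded on the light strand are laid out 3'→5' in genome coordinates.
The anticodon is the middle three bases of the anticodon loop; the two
3'-most anticodon bases pair the first and second codon nucleotides and are
flagged (`pairs_codon12`). This is a structural *model*, overridable with a
curated table via `buildReferenceMap(trnaTable = ...)`; analyses that
depend only on the stem-versus-loop dichotomy are insensitive to
single-position boundary shifts.

## The filter cascade

`applyFilters()` evaluates six rules on strand- and orientation-resolved
read counts and reports *all* failed rules per site (the decision is a pure
function of the rule set, so it is order-independent — a property the test
suite asserts by permuting rule order):

1. at least 3 alternative reads on *each* strand;
2. site depth at least 100x;
3. VAF at least 1% on each strand separately (strand-specific
   denominators; the per-strand convention is configurable because pooled
   denominators are equally defensible);
4. position outside the masked repeat intervals;
5. no C:G>A:T transversion at pooled VAF ≤ 10% — the 8-oxoG signature,
   read strand-symmetrically (reference C>A or reference G>T);
6. for FFPE material at pooled VAF ≤ 10%: at least 20 alternative reads
   and strand orientation bias SOB = |F1R2 − F2R1| / (F1R2 + F2R1) ≤ 0.25
   over the alternative-supporting read pairs. The SOB scorer is pluggable
   in the sense that the orientation counts are plain columns; the formula
   above is the implemented default.

All thresholds live in `FilterConfig` with the defaults exactly as listed;
comparisons are inclusive as written (≥3, ≥100, ≥1%, ≤10%, ≥20, ≤0.25).
Only SNVs are processed; indel rows are dropped with a logged count.
`classifySomatic()` then labels a passing tumour call *somatic* when the
paired control (blood or adjacent tissue) carries the wild-type allele
(control VAF < 0.1%), *shared* when the control reaches that bound, and
*unclassifiable* — never somatic — when the control does not cover the
position.

Rules 5 and 6 deliberately sacrifice real low-VAF C:G>A:T transversions
and orientation-skewed calls: at VAF ≤ 10% they are statistically
indistinguishable from damage. Recovery benchmarks therefore plant
transition mutations by default (see the generator section).

## mtDNA copy number

`mtCopyNumber()` implements
$\mathrm{mtCN} = 2 \cdot \bar d_{\mathrm{mt}} / \bar d_{\mathrm{nuc}}$,
where $\bar d_{\mathrm{nuc}}$ is the unweighted mean depth over the
reference nuclear probe loci (six in the assay design; any count ≥ 1 is
accepted since locus identity is a free input). The estimate is invariant
to rescaling all depths. Depth summaries are taken as given — any
per-individual consensus-reference correction happens upstream of this
package.

## Annotation

`strandClass()` names every SNV in L-strand notation with its heavy-strand
synonym; because the reference is the light strand, the
replication-associated heavy-strand C>T class (CH>TH) appears as reference
G>A. `codonEffect()` translates the affected codon before and after the
substitution under the vertebrate mitochondrial genetic code, honouring
reading frame and coding strand (ND6 by reverse complement); stop gains are
*truncating*. Genes ending in incomplete codons (ND1, ND2, ND3, ND4, CO3,
CYB) are completed by polyadenylation, so the terminal codon is padded with
A before translation. Where protein genes overlap (ATP8/ATP6, ND4L/ND4,
ATP6/CO3 at a boundary position) the more severe consequence is reported
and all region categories are retained. Pathogenicity is *consumed*, not
computed: APOGEE2 categories for missense variants and a MitoTIP-derived
benign/deleterious dichotomy for tRNA variants are joined from a
user-supplied annotation table keyed by (pos, ref, alt); absent rows give
`unclassified`, conflicting duplicates are an error. Mutations with
VAF > 50% are flagged high-VAF.

## Selection statistics

* **Mutation density** is mutations per cohort sample per kb of region;
  zero-mutation samples count in the denominator.
* **Spectrum proportions** divide each of the 12 strand-resolved class
  counts by the region's total.
* **Cumulative heteroplasmy** comparisons use the two-sample
  Kolmogorov–Smirnov statistic (asymptotic p by default, exact by option);
  a delayed accumulation of high-heteroplasmy control-region mutations is
  the package's read-out of negative selection on the mtCTR.
* **Complex standardisation**: the heavy-strand C>T mutability of a gene
  tracks DssH, the relative time its heavy strand spends single-stranded
  during asymmetric strand-displacement replication. Per gene, the CH>TH
  density is regressed on DssH across the 13 genes (ordinary least squares
  with intercept — regression through the origin is available by
  pre-centring, and a `residual` mode replaces the observed/expected ratio
  with length-weighted residuals for users who prefer additive scale); the
  per-complex standardised density is observed density over the
  length-weighted fitted expectation. If all DssH values coincide the fit
  is singular and the expectation falls back to the mean density with a
  warning. The packaged DssH table is computed from the replication model
  (leading fork from the heavy-strand origin at 191, lagging synthesis
  from the light-strand origin at 5747 in the reverse direction; DssH(p) =
  time between displacement and re-synthesis, normalised by genome
  length, averaged over gene positions); it reproduces the canonical
  gradient (CO1 lowest, CYB highest) and is overridable where measured
  values are preferred.
* **Group tests** route to the standard machinery (chi-square without
  continuity correction by default, Mann–Whitney U, one-way ANOVA with
  Bonferroni-adjusted pairwise post hoc, Spearman, Student's t) behind a
  uniform interface. Heteroplasmy enters the ANOVA untransformed.

## Outcome analysis

`stratifySamples()` flags carriers of any configurable mutation class
(any, protein-coding, nonsynonymous, high-VAF, high-VAF-nonsynonymous,
mtCTR, mtCDR, HVS, tRNA, rRNA). `kmEstimator()` and `logrankTest()` wrap
the `survival` package's product-limit estimator and Mantel–Cox test
(hypergeometric variance; censoring at an event time keeps the subject at
risk through that time); the tests verify both against hand-computed risk
sets and O−E tables. Significance is two-sided at α = 0.05. Cox
regression and multivariable adjustment are out of scope.

## The synthetic cohort generator

`simulateCohort()` produces the full data shape the pipeline consumes —
tumour and paired control site counts, depth summaries, clinical records —
plus a truth ledger in which every alt-supporting row traces to a planted
event. Defaults emulate a realistic capture-sequencing cohort: 239 tumour samples,
~2.08 real mutations per sample (497/239), mean depth 5000x with
negative-binomial overdispersion (size 2.8, giving a ~±3000x spread of
mean depth across samples), heteroplasmy from a low-skewed Beta(0.35, 2.5)
rescaled to [1%, 100%], and a heavy-strand C>T excess (pChTh = 0.6)
weighted along the DssH gradient. Design choices worth knowing:

* positions are drawn uniformly within target region groups excluding the
  masked intervals, without replacement per sample; infeasible demand is
  an error;
* real variants split reads Binomial(0.5) across strands and orientations;
  artifacts skew orientations with probability 0.95, placing them far
  beyond the SOB = 0.25 boundary at any plantable support;
* oxo-G artifacts are C:G>A:T at VAF 1–8%; FFPE artifacts are C>T class
  at the same VAFs and arise only under FFPE preservation;
* planted real mutations are transitions by default
  (`transitionFraction = 1`): somatic mtDNA spectra are overwhelmingly
  transitions, and the cascade removes low-VAF C:G>A:T transversions *by
  design*, so planting them would make 100% artifact rejection and ≥99%
  recall jointly unattainable — a property of the filter design, not of
  this implementation;
* copy number is log-normal with optional log-scale coupling to mutation
  burden; survival is exponential with named log hazard ratios per planted
  mutation class and uniform censoring.

What the generator does *not* emulate: alignment and base-quality error
profiles, nuclear-mitochondrial segments (NUMTs), contamination,
haplogroup structure, and position-specific mutational hotspots. Passing
recovery benchmarks therefore demonstrates the correctness of the cascade's
logic under its own error model, not performance on real libraries.

`simulateCalledTable()` skips the read level and emits called-mutation
rows directly, which keeps the statistics-only benchmarks (100 replicates
per scenario) inside a few minutes on one CPU.

## Numerical and design notes

* Coordinates are 1-based inclusive everywhere except BED ingestion;
  the contig is `chrM`.
* VAF dialects: `readMutationTable(vafDialect = "percent")` divides by
  100; the default is fractions.
* Benchmarks in the test suite use 50–100 samples per replicate and 100
  replicates per scenario, and 1000 replicates for null calibration —
  sizes at which the planted effects are overwhelmingly detectable while
  the whole suite stays fast.
* The null-calibration check is itself stochastic: even a perfectly
  calibrated test falls outside the 95% binomial band around 0.05 in 5%
  of runs.
* Degenerate inputs error loudly rather than silently: empty groups for
  the KS/Mann–Whitney tests, constant responses for ANOVA, zero nuclear
  depth for copy number, no events for the log-rank test, unknown region
  or class names for lookups.

## End-to-end example

```{r, message = FALSE}
cfg <- simConfig(seed = 7, nTumour = 30, depthMean = 3000,
                 oxogPerSample = 1, sharedPerSample = 0.5)
sim <- simulateCohort(cfg, map)
calls <- applyFilters(sim$tumourCounts, filterConfig(), map)
pass <- classifySomatic(calls[calls$filter_status == "PASS", ],
                        sim$controlCounts)
somatic <- pass[pass$somatic_status == "somatic", ]
ann <- annotateMutations(somatic, map)
table(ann$consequence)
mutationDensity(nrow(ann), cfg@nTumour, 16569)$density
head(mtCopyNumber(sim$depthSummary))
```
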