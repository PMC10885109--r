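---
title: "Characterizing common light chain BCR repertoires with bcrflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing common light chain BCR repertoires with bcrflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrflow)
```

## The analysis problem

A common light chain (cLC) mouse carries one prearranged kappa V/J segment
in place of the endogenous J cluster, so that — receptor editing aside —
every B cell expresses the same light chain germline while the heavy chain
repertoire diversifies normally. Judging whether such a strain is useful for
antibody discovery is a repertoire-analysis problem: from single-cell V(D)J
annotation tables one must (i) keep only cells with an unambiguous
heavy/light pair, (ii) group cells into clonotypes, (iii) quantify clonal
diversity against a wildtype comparator at matched depth, (iv) measure how
strongly and where somatic hypermutation (SHM) alters the supposedly common
light chain, and (v) ask whether the resulting antibodies cover distinct
epitopes. `bcrflow` implements each stage as a plain function over data
frames, plus `run_pipeline()` to chain them reproducibly.

## Pairing filter

`pair_cells()` keeps a cell iff it has exactly one productive IGH record and
exactly one productive IGK/IGL record. Two conventions are fixed here
because annotation tables leave them open:

* non-productive chains are removed before counting — the analysis concerns
  expressed receptors;
* a cell with one heavy plus one kappa *and* one lambda is a multi-light
  multiplet, not a pair.

The returned `pairing_report` partitions every input cell into
`paired + multiplet + unpaired`, an invariant the tests assert.

## Clonotype definition and clustering

Two cells share a clonotype iff they share (1) the heavy V gene at gene
level (allele suffixes such as `*01` are stripped on ingestion), (2) CDR-H3
amino-acid length, and (3) CDR-H3 identity at or above a threshold.
The threshold defaults to 0.8: a published ">80% identity" rule is read as
`>= 0.8`, the inclusive convention of greedy clustering tools, and the
choice is surfaced as a parameter rather than buried.

Within each (V gene, length) block, clustering is greedy and incremental in
the CD-HIT style: unique CDR-H3s are visited in descending multiplicity,
ties broken lexicographically; a sequence joins the first cluster whose
*founding representative* it matches at threshold, else founds a new
cluster. Because block length is constant, abundance replaces CD-HIT's
length-ordering. The ordering rule makes the partition deterministic, and a
brute-force reference implementation over random blocks confirms the greedy
code path in the test suite.

Consensus sequences are computed for clonotypes of at least
`min_consensus_size = 5` members as the per-position modal residue, ties
resolved to the lexicographically smallest residue. When members differ in
full-VH length (indel-bearing clonotypes), the consensus and Hamming
computations fall back to CDR-H3 with a logged downgrade; full-VH is the
default because it is the stricter reading and the Hamming distance is then
sensitive to framework SHM as well.

### Liabilities and clone selection

`flag_liabilities()` scans CDRs for N-glycosylation sequons
(`N-X-[S/T]`, `X != P`, optionally completed by a two-residue right flank)
and cysteines, which inside a CDR are presumed unpaired. The `cdr3_aa`
column is expected to follow the AIRR convention of *excluding* the
conserved junction anchors (Cys104/Trp118); a junction-style column that
includes them would flag every sequence.

`select_clones()` reproduces a discovery-oriented picking rule: candidates
are liability-free members of clonotypes with >= 5 cells, ranked by
clonotype size (descending), Hamming distance to consensus (ascending), then
sequence id; one clone is taken per clonotype before any clonotype
contributes a second. The round-robin rule is made explicit because a bare
"prefer larger clonotypes" criterion does not determine a unique set of 48
picks.

## Diversity statistics

* `gini()` uses the population (uncorrected) mean-absolute-difference form
  over the supplied counts including zeros, the common default of R
  inequality implementations; a one-hot vector of length *n* scores exactly
  `(n-1)/n`.
* `d50()` returns the smallest number of categories whose counts reach
  **at least** 50% of the total ("occupy 50%" with the inclusive tie rule).
* `topn_fraction()` reports rank-range occupancy (defaults 1–10, 11–50,
  51–500); ranks beyond the table contribute zero.
* `downsample()` draws uniformly without replacement under an explicit seed;
  the pipeline **re-assigns clonotypes on the subsample** rather than
  inheriting labels, since clonotype counts are depth-dependent.
* `compare_usage_chisq()` is a Pearson chi-squared test on the 2 x K usage
  table after zero-filling to a shared label space; pooled-zero categories
  are dropped and no continuity correction is applied.
* `compare_groups_wilcoxon()` runs two-sided rank-sum tests with
  Benjamini–Hochberg adjustment across the batch. BH is a declared choice:
  "adjusted p-values" alone does not name a method, and BH is the field's
  default for repertoire-scale comparisons.

## Light-chain SHM profile

`align_to_germline()` compares a light chain to the prearranged germline
positionally when lengths match, otherwise by global Needleman–Wunsch
(BLOSUM62, gap opening 10, gap extension 0.5 — the Biostrings penalty
convention). Gap columns are flagged as indels and excluded from
substitution counting; records below 50% identity over aligned columns are
rejected as not derived from this germline. `shm_profile()` aggregates
per-position frequencies as *mutated records / records covering the
position* on the packaged Chothia-style numbering, a per-sequence mutation
histogram, and per-CDR summaries (fraction of sequences with >= 1 mutation
per CDR; fraction with none in any CDR).

The numbering is a static index-to-label table for the packaged light chain
(V segment ending at label 95, J contributing 96–107), not a general
antibody-numbering engine: the analysis needs a handful of fixed positions
(30–32, 83, 92–96) on one chain, and a full numbering algorithm would add a
heavy dependency for no gain. Region boundaries default to CDR-L1 = 24–34,
CDR-L2 = 50–56, CDR-L3 = 89–97 and are caller-overridable.

Dual-allele expression (both prearranged alleles expressed and mutated
independently in a homozygous animal) is *not* deconvolved: profiles are
computed over the mixture, matching what single-cell sequencing can observe.

## Epitope binning

`net_geomean()` implements `net = total_geomean - reference_alone` per
(reference, panel) pair. Negative values — possible with noisy single-bead
controls — are retained, not clipped, because clipping would distort the
profile correlations. `correlate_profiles()` uses Pearson correlation
(matching the spreadsheet convention the assay community uses);
zero-variance profiles are excluded with a flag rather than silently
propagating NaN. `assign_bins()` groups antibodies by single-linkage
agglomeration at `r >= 0.8`: published binning protocols state that bins
were formed from the correlation matrix without stating a rule, so a
configurable threshold with chain-linkage (the reading that reproduces
block-structured heatmaps) is declared and echoed in the output.
`benchmark_binning()` assigns each panel antibody the bin of its
best-correlated benchmark at the same threshold, flagging the rest as novel.

## Structure mapping

`compute_sasa()` is a self-contained Shrake–Rupley implementation (no R
package in the dependency stack provides numeric SASA without an external
binary): atoms are expanded by a 1.4 Å probe, sampled on a deterministic
golden-spiral grid (default 242 points/atom), and occlusion is tested
against grid-bucketed neighbors. Relative SASA divides residue totals by the
Tien et al. (2013) theoretical Gly-X-Gly maxima; values can slightly exceed
1 at exposed termini and are reported uncapped. Tests pin the implementation
to analytic oracles (isolated sphere, two-sphere union, caged atom),
quadrature self-convergence (< 2% on doubling the grid), and rigid-motion
invariance (< 1% at 2000 points).

`rsasa_at_positions()` and `map_profile_to_structure()` resolve numbering
labels onto chain residues through an explicit label-to-residue table
supplied by the caller; for real crystal structures (e.g. a Fab with an
IGKV10-96-derived light chain such as PDB 5DO2) the user provides the
structure file and mapping, since neither is redistributable inside the
package. Whether to compute SASA on a whole assembly or a chain subset is
exposed via the `chain` argument; the default is the full structure, so
burial by partner chains is respected.

## The synthetic generator

`generate_repertoire()` emulates the *output* of single-cell V(D)J
annotation, not the biology upstream of it. Planted structure, with
defaults chosen as the study conditions the package targets:

* **Clonotype pool and sizes** — cells are assigned to a pool of clonotypes
  with probabilities proportional to `rank^-s`. The generic default is
  `s = 2`, `pool = 515`; the presets solve `s` so the planted top-10
  occupancy matches the condition being emulated
  (`sim_config_clc()`: 515 clonotypes, top-10 = 26%, 3915 cells;
  `sim_config_wildtype()`: 704 clonotypes, top-10 = 14%, 6173 cells). The
  true clone-size law of real repertoires is unknown; the power law is a
  stand-in that reproduces the qualitative skew, and the exponent is
  configuration, not inference.
* **Light-chain SHM** — per-cell independent Bernoulli substitution masks
  over the numbering, with hotspot rates at positions 30–32, 92–94 and 83
  and a uniform background scaled so the rates sum to 4.9 expected
  mutations per chain (6.4 in the wildtype preset). Substituted residues are
  drawn uniformly from the 19 alternatives — no substitution matrix is
  claimed. Because masks are independent across cells, empirical
  frequencies converge to the planted rates with binomial standard errors,
  which is exactly what the recovery tests assert. Clonal correlation of
  light-chain SHM (shared lineage mutations) is deliberately *not* modeled;
  the `dual allele` annotation records which of two alleles a cell reports
  without changing the marginal law.
* **Heavy chains** — V gene and founder CDR-H3 are fixed per clonotype;
  cells accumulate Poisson framework substitutions (`heavy_shm_rate = 2`)
  and rare CDR-H3 substitutions (`cdrh3_shm_rate = 0.15`, low enough that
  within-clone identity stays above the clustering threshold).
* **Annotation artifacts** — isotype labels (IgG2B/IgG2C-dominated with 10%
  IgG1), a lambda fraction (0.02% cLC-like, 2% wildtype-like), and chain
  multiplets at a rate chosen so the preset pools shrink to ~2884 surviving
  pairs, the depth at which the two conditions are compared.
* **Binning panels** — `generate_binning_panel()` plants bin labels and
  suppresses the binding signal by `competition_factor` when reference and
  panel antibody share a bin; log-normal noise with configured CV acts on
  the signal term only, so single-bead controls are exact and the noise-free
  examples are closed-form.

Germline sequences shipped with the package are synthetic stand-ins of
realistic length and composition (documented as such); real IMGT references
drop in through `germline_set()`.

### What passing tests do and do not show

The simulator provides planted truth, so the tests demonstrate that the
implementations recover what they are defined to measure: exact clonotype
counts under high within-clone identity, hotspot positions and mean mutation
load at depth 5000, planted occupancy and diversity orderings across seeded
replicates, and exact bin partitions at 5% noise. They do *not* validate the
generator as a model of murine immunology: real repertoires have non-uniform
CDR-H3 length and composition, lineage-correlated SHM, nucleotide-level
mutation targeting, and annotation errors the generator does not emulate.
Conclusions about real data rest on the correctness of the operations, not
on the realism of the synthetic inputs.

## Problem sizes and determinism

The shipped test suite runs repertoires of 2000–6173 cells (5 seeds for
exact clonotype recovery, 20 replicate pairs for the diversity ordering,
depth 5000 for SHM recovery) and 10-seed binning panels; the full suite
completes in a few minutes on one core. Every sampling step takes an
explicit integer seed; `generate_repertoire()`, `downsample()` and
`run_pipeline()` are byte-reproducible given their configuration, and the
pipeline MANIFEST records content hashes of every output.

## Known limitations

* Heavy-chain-only clonotyping; light chains do not enter the clone
  definition (by design, matching the discovery workflow).
* No nucleotide-level SHM analysis, lineage trees, or selection-pressure
  statistics; no rarefaction/Hill-number diversity measures.
* The Chothia numbering is a fixed table for the packaged light chain;
  arbitrary antibodies require a user-supplied numbering map.
* Epitope-bin labels depend on the declared threshold/linkage rule; they are
  reported with the threshold rather than claimed as assay ground truth.
* The wildtype preset reaches its paired-cell depth through the multiplet
  rate alone, which conflates the several reasons real cells fail the
  1H+1L filter.
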