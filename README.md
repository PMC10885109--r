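# bcrflow

Characterization of paired B-cell receptor (BCR) immune repertoires for
common light chain (cLC) antibody discovery.

Engineered mouse strains that carry a single prearranged kappa light chain
(for example an IGKV10-96/IGKJ1 segment with the CDR-L3 tryptophan at
Chothia position 96 replaced by leucine) produce antibody repertoires in
which every antibody shares one light chain — the raw material for
three-chain bispecific IgG discovery. Evaluating such a strain against a
wildtype comparator raises a recurring set of computational questions:
after single-cell V(D)J annotation, which cells carry exactly one heavy and
one light chain? How do the paired sequences cluster into clonotypes? How
diverse is the repertoire, how heavily is the common light chain somatically
mutated and where, and do the discovered antibodies cover the same epitopes
as wildtype antibodies? `bcrflow` implements that analysis as a tested,
reusable R pipeline, together with a seeded synthetic-repertoire generator
so every stage is verifiable without sequencing data.

## What it computes

* **Ingestion and pairing** — AIRR Rearrangement TSV and 10x-style contig
  CSV readers with gene-level call normalization; the exactly-one-VH /
  one-VL pairing filter with a full accounting report.
* **Clonotyping** — greedy, CD-HIT-style incremental clustering: cells share
  a clonotype iff they share the heavy V gene, CDR-H3 length, and CDR-H3
  amino-acid identity ≥ 0.8 (configurable). Per-clonotype consensus (size
  ≥ 5), per-member Hamming distances, CDR liability flags (N-glycosylation
  sequons `N-X-S/T, X ≠ P`; cysteines), and the clone-selection ranking
  (size ↓, Hamming ↑, one pick per clonotype first).
* **Diversity** — Gini coefficient `G = Σᵢ Σⱼ |xᵢ − xⱼ| / (2 n² x̄)`, D50
  (smallest number of clonotypes holding ≥ 50% of the repertoire), top-N
  rank occupancy, seeded down-sampling with re-clonotyping, V-gene usage
  tables, chi-squared usage comparison, Wilcoxon rank-sum with
  Benjamini–Hochberg adjustment.
* **SHM profiling** — per-position amino-acid mutation frequencies of light
  chains against the prearranged germline on a fixed Chothia-style
  numbering, per-sequence mutation histograms, CDR region summaries and
  hotspot ranking.
* **Epitope binning** — net fluorescence geomean
  (`total − reference-alone`), Pearson correlation of competition profiles,
  single-linkage bin assignment at r ≥ 0.8, and benchmark matching with
  novel-bin flagging.
* **Structure mapping** — Shrake–Rupley solvent-accessible surface area,
  relative SASA against Tien et al. residue maxima, and projection of
  mutation frequencies onto structure residues.
* **Simulation** — `generate_repertoire()` / `generate_binning_panel()`
  emit annotated tables with planted ground truth (clonotype pool with
  power-law sizes, per-position light-chain SHM hotspots, isotype mix,
  multiplets, planted epitope bins).

## Worked example

```r
library(bcrflow)

rep    <- generate_repertoire(sim_config_clc(seed = 7))   # cLC-like pool
paired <- pair_cells(rep$records)
paired$report
#> Pairing: 3915 cells in (4382 heavy, 4424 light records)
#>   kept 1H+1L : 2939
#>   multiplets : 976
#>   unpaired   : 0

cts <- assign_clonotypes(paired$cells, threshold = 0.8)
cts
#> Clonotype set: 477 clonotypes over 2939 cells (threshold 0.80)
#>   largest:
#>     CT00425 IGHV5-9 len 11 size 205
#>     ...

diversity_summary(cts$clonotypes$size)
#> Diversity: 477 categories, Gini 0.579, D50 48
#>   occupancy: ranks 1-10 = 26.7%; ranks 11-50 = 24.2%; ranks 51-500 = 49.1%

kappa <- paired$cells$v_call_light == "IGKV10-96"
shm_profile(paired$cells$sequence_aa_light[kappa])
#> SHM profile: 2938 light chains (0 rejected)
#>   mean mutations/chain: 4.89
#>   sequences with >=1 CDR mutation: CDR-L1 76%, CDR-L2 15%, CDR-L3 84%
#>   no CDR mutation: 3.5%
#>   top positions: 92 (0.50, CDR-L3); 93 (0.48, CDR-L3); 31 (0.41, CDR-L1);
#>                  30 (0.39, CDR-L1); 83 (0.31, FR)

select_clones(cts, k = 5)[, c("clonotype_id", "clonotype_size",
                              "hamming_to_consensus")]
#>   clonotype_id clonotype_size hamming_to_consensus
#> 1      CT00425            205                    0
#> 2      CT00320            131                    0
#> ...
```

Reading the output: 2939 of 3915 simulated cells pass the strict 1H+1L
filter; they collapse into 477 clonotypes whose ten largest members occupy
26.7% of the repertoire (D50 = 48 — 48 clonotypes cover half of all cells).
The prearranged kappa chain carries on average 4.9 amino-acid substitutions,
concentrated at CDR-L3 positions 92–93, CDR-L1 positions 30–31 and framework
position 83 — the structure the generator plants and the profiler must
recover. Clone selection returns liability-free members of the largest
clonotypes, closest to each clonotype consensus.

`run_pipeline(pipeline_config(...))` chains all stages, writes per-stage
TSVs, a JSON report and a hash MANIFEST, and is byte-reproducible under a
fixed seed.

## Vignette

`vignettes/repertoire-characterization.Rmd` documents the model and its
assumptions, every tunable threshold, what the synthetic generator does and
does not emulate, and the package's numerical conventions.
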