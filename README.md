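# bmpcrep

Clonal-structure and origin analysis of human bone marrow plasma cell
(BMPC) single-cell repertoires.

## The problem

Long-lived BMPCs maintain circulating antibody levels for years. Two
cellular ancestries can feed the pool: memory B cells (MBC) that
re-differentiate into plasma cells upon antigen recall, and germinal
center (GC) B cells exported directly as plasma cells. The two routes
leave different fingerprints in paired single-cell gene-expression
(GEX/CITE-seq) and heavy-chain VDJ data:

* **Somatic hypermutation (SHM)** — MBC leave the GC earlier than
  plasma-cell exports, so MBC-derived BMPCs carry less SHM.
* **Intraclonal sequence variance** — MBC recall expands one fixed
  sequence (*isogenic* clones, or *singlets*), while ongoing GC output
  produces expanded clones whose members differ in mutations
  (*heterogenic* clones).
* **Surface CD19** — low CD19 marks longer-lived plasma-cell subsets;
  MBC-derived cells concentrate in the CD19-low compartment.

`bmpcrep` implements the full analysis chain that turns these
fingerprints into statistics, plus a seeded synthetic-repertoire
generator that plants known origins so every stage is verifiable against
ground truth.

## What the package computes

For each cell with barcode-matched GEX and VDJ information:

1. **QC** — keep cells with mitochondrial fraction < 5%, total RNA in
   [200, 4000], and no expression of T/NK/myeloid/erythroid lineage
   markers (first-failing-rule accounting).
2. **Isotype assignment** — VDJ constant-region calls take precedence;
   otherwise the top IGHC subclass is assigned from transcript counts iff
   it holds strictly more than half of the summed IGHC counts *and*
   strictly more than 20 counts (`benchmark_isotype_inference()`
   quantifies how well the GEX-only rule recovers VDJ truth).
3. **SHM** — percent mismatch between the heavy-chain sequence and its
   germline over comparable (non-N, non-gap) positions.
4. **Clonal families** — cells partitioned by identical IGHV/IGHJ gene
   and CDR3 length, then single-linkage clustered at 0.85 CDR3
   amino-acid similarity (normalized hamming distance ≤ 0.15).
5. **Clone structure** — singlet / isogenic / heterogenic by exact
   nucleotide-sequence uniqueness among members.
6. **Binning and rank statistics** — CD19 ADT counts are log-transformed
   and Z-scored per batch, then cells are rank-binned 30/40/30 into
   low/mid/high CD19 (and SHM) bins; Mann-Whitney / Kruskal-Wallis /
   Friedman tests (exact by enumeration for n ≤ 10 without ties,
   tie-corrected asymptotics otherwise) with all-pairs Dunn/Holm post-hoc
   comparisons link SHM, CD19, clone structure and gene expression
   (e.g. JCHAIN).

## Worked example

```r
library(bmpcrep)

sim <- simulate_repertoire(sim_config(n_cells = 2000, seed = 1))
res <- analyze_repertoire(sim$vdj, sim$counts, sim$meta,
                          pipeline_config(seed = 1))

res$tests$shm_by_cd19_bin
#> kruskal_wallis (asymptotic): statistic = 433.3, p = 8.247e-95
#> groups: low (n=512), mid (n=686), high (n=500)
#> post hoc (holm-adjusted):
#>  group1 group2 statistic   p_adjusted
#>     low    mid -11.69997 2.549864e-31
#>     low   high -20.80163 1.254914e-95
#>     mid   high -10.62153 2.366439e-26

table(res$clones$structure)
#> heterogenic    isogenic     singlet
#>         124         120         744
```

SHM rises monotonically across CD19 bins (the Kruskal-Wallis test and
every pairwise contrast are strongly significant), and expanded clones
split into heterogenic and isogenic families with singlets making up
roughly half of all cells — the planted GC-vs-MBC structure recovered
end-to-end. `res$tables$jchain_by_cd19_bin_summary` shows the planted
JCHAIN shift: median log-expression 4.49 in CD19-low vs 3.58 in
CD19-high cells.

File-based runs use the same machinery: `write_simulation()` emits AIRR
TSV + counts + metadata, `run_pipeline(pipeline_config(vdj_path = ...,
counts_path = ..., meta_path = ..., outdir = ...))` (or a YAML config via
`read_pipeline_config()`) reads them, runs all stages and writes
per-cell, per-clone and statistics tables with a JSON run manifest.

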