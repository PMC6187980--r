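# scPatchQC

Quality control for **patch-seq** single-cell transcriptomes — cells whose
mRNA is aspirated through a patch-clamp pipette after electrophysiological
recording. Compared with dissociation-based scRNA-seq, patch-seq samples
carry two characteristic technical artifacts:

1. **Off-target cell-type contamination.** On its way to (and from) the
   recorded soma the pipette passes through the processes of neighbouring
   cells — pyramidal dendrites, astrocyte and microglial processes — and
   picks up their transcripts.
2. **Variable mRNA content.** Aspiration is hard to control, so the amount
   of mRNA extracted (and with it the number of detectable genes) varies
   strongly from cell to cell.

scPatchQC quantifies both against a dissociated-cell reference atlas and
feeds the resulting per-cell quality weights into downstream
gene–electrophysiology analyses.

## The scores

For a cell *c* of broad type *A* and a panel of markers specific to another
type *B*, the summed marker expression is

    M(c; B) = sum over markers m of B of log2(x_m + 1)

with `x_m` the normalized expression (TPM or UMI counts per million). With
`d(A, B)` the median of `M(·; B)` over *reference* cells of type *A*, the
**contamination score** of type *B* in cell *c* is

    CS(c; B) = ( M(c; B) − d(A, B) ) / ( d(B, B) − d(A, B) )

floored at 0 and capped at 1: the cell's excess of *B*-marker signal, on a
scale where 1 means "as much as a typical dissociated *B* cell". The
**contamination index** CI is the sum of CS over all applicable broad
off-target types (GABAergic sources are skipped for GABAergic cells), and
the **quality score** is the Spearman correlation between the cell's
expression over the combined marker panel and the mean dissociated-cell
profile of its own type, floored at 0.1 and used as an analysis weight.

Marker panels are derived from reference atlases by enrichment
(mean > 10× every other type, mean > 100), prevalence (> 10 in > 75 % of
own-type cells), and, for contamination-source panels, specificity filters
against the patch-seq target types. Detected-gene counts are modelled by
ordinary least squares on z-scored technical factors (library size,
ERCC spike-in read share, unmapped read share, contamination index), and
gene–ephys association uses weighted Pearson correlations with
Benjamini–Hochberg FDR per feature; cell-type-pooled analyses weight each
type by the harmonic mean of its expression and ephys cell counts.

## Worked example

Everything below runs on the package's ground-truth simulator (no
downloads): a 4-type miniature atlas (Ndnf-like GABAergic target plus
Pyramidal / Astrocyte / Microglia contamination sources) and 550 patch-seq
cells spanning planted contamination fractions 0–1.

```r
library(scPatchQC)

cfg    <- simulationConfig(seed = 1)
refSim <- simulateReference(cfg)
markers <- buildMarkerSet(refSim$ref,
                          targetTypes = "Ndnf",
                          broadTypes = c("Pyramidal", "Astrocyte", "Microglia"),
                          gabaergicTypes = "Ndnf")
baselines <- computeBaselines(refSim$ref, markers)
baselines
#> ReferenceBaseline: 4 cell types x 4 marker sources
#>             Ndnf Pyramidal Astrocyte Microglia
#> Astrocyte  38.81     39.30    425.05     38.85
#> Microglia  38.96     38.94     38.21    424.97
#> Ndnf      424.52     38.95     38.55     40.23
#> Pyramidal  38.35    424.82     38.35     39.42
```

Each row is the expected summed log2 marker expression of every marker
panel (columns) in dissociated cells of one type: panels light up in their
own type (~425) and stay near baseline (~39) elsewhere — the
discrimination the contamination score is built on.

```r
psSim    <- simulatePatchseq(cfg, refSim$truth)
profiles <- scoreCells(psSim$ps, markers, baselines, refSim$ref)
head(scoreTable(profiles)[, c("cell_id", "CS_Pyramidal", "CS_Astrocyte",
                              "CS_Microglia", "contam_index",
                              "quality_score", "contaminated")], 3)
#>       cell_id CS_Pyramidal CS_Astrocyte CS_Microglia contam_index quality_score contaminated
#> 1 Ndnf_ps_001            0   0.02461905            0   0.02461905     0.6246248        FALSE
#> 2 Ndnf_ps_002            0   0.00000000            0   0.00000000     0.6788116        FALSE
#> 3 Ndnf_ps_003            0   0.00000000            0   0.00000000     0.6956281        FALSE

fit <- fitFactorModel(techFactorTable(psSim$accounting, profiles))
fit
#> Standardized technical-factor model (n = 550 cells)
#>                   beta std_error
#> library_size   -0.0018    0.0193
#> spike_in_ratio -0.9106    0.0203
#> unmapped_ratio -0.2556    0.0202
#> contam_index    0.1333    0.0194
#> variance explained: 79.7%
```

The first three cells are uncontaminated (planted fraction 0): their
contamination scores sit at ~0 and they fall below the 0.5 calling
threshold. The factor model recovers the designed read-accounting
structure: cells with a larger ERCC spike-in share (less extracted mRNA)
detect far fewer genes, unmapped reads cost detections, and contaminated
cells detect slightly more genes — together explaining ~80 % of the
cell-to-cell variance in detected-gene counts.

The same workflow is scriptable from a shell via the thin CLI:

```sh
Rscript inst/cli/patchseq-qc.R simulate --out-dir sims --seed 1
Rscript inst/cli/patchseq-qc.R run --config run.yaml
```

with subcommands `select-markers`, `score`, `tech-factors`, `ephys-corr`,
`simulate` and `run`.

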