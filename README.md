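# apbquant

Quantification of ALT-associated PML bodies (APBs), telomere foci and
telomeric DNA synthesis from multi-channel 3D fluorescence microscopy, with
a synthetic ground-truth simulator and the per-cell / per-tumor statistics
used to compare experimental groups.

## Who this is for

Labs scoring ALT (alternative lengthening of telomeres) phenotypes by
imaging: telomere FISH + PML immunofluorescence (+ optional EdU) z-stacks of
interphase nuclei, quantified per cell. The package replaces ad-hoc macro
scripting with a tested pipeline whose every stage can be validated against
simulated images with exact ground truth.

## The method

For each field the pipeline computes, per channel, a maximum-intensity
projection of the z-stack (0.2 µm steps over 5 µm by default), removes
background with a **white tophat** (image minus its grayscale opening by a
disk), finds foci as **local maxima with topographic prominence ≥ k·σ̂**
(σ̂ = 1.4826·MAD of the filtered image), and segments each focus at half its
peak height with marker-watershed splitting of contested pixels. Nuclei are
segmented from DAPI (blur → Otsu → fill → label, border nuclei excluded) and
foci are assigned to cells by centroid containment. Cross-channel events are
called by **object mask overlap**: an APB is a distinct telomere object
sharing ≥ 1 pixel with a PML object; a cell is **APB-positive when it has
more than five** such events. Groups are compared per cell with the
two-tailed Mann–Whitney U test (exact by enumeration for combined n ≤ 16
without ties, otherwise tie-corrected normal approximation with continuity
correction; medians as summaries) or per tumor with the pooled-variance
unpaired t-test on per-tumor means, labelled `ns`, `*`, `**`, `***`, `****`
at strict cuts 0.05, 0.01, 0.001, 0.0001.

The simulator renders nuclei with Poisson-distributed telomere foci,
nearest-neighbour telomere clustering (area-conserving merges), PML bodies
colocalized at a controllable APB rate, EdU foci at APBs, Gaussian PSF blur,
and Poisson + read noise — emitting exact truth tables for validation.

## Worked example

```r
library(apbquant)

# a field of 16 nuclei, 30% of telomeres carrying a PML body
cfg <- simulation_config(apb_prob = 0.3)
sim <- simulate_field(cfg, field_id = "demo", seed = 7)

tel <- detect_foci(sim$field, "telomere")
pml <- detect_foci(sim$field, "pml")
nuc <- segment_nuclei(max_project(sim$field, "dapi"))
ph  <- build_phenotypes(list(telomere = tel, pml = pml), nuc,
                        field_id = "demo")
head(ph[, c("cell_id", "telomere_count", "apb_count", "apb_positive")], 3)
#>   cell_id telomere_count apb_count apb_positive
#> 1       1             27         5        FALSE
#> 2       2             32        10         TRUE
#> 3       3             56        16         TRUE

detection_metrics(tel, sim$truth)[c("precision", "recall", "f1")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1
#> $f1
#> [1] 1

mann_whitney(c(1, 2, 3), c(4, 5, 6))
#> mann_whitney: statistic = 0, two-sided p = 0.1 [ns]
#>   group a: n = 3, median = 2 | group b: n = 3, median = 5
#>   p-value branch: exact enumeration
```

Cell 1 sits below the "more than five APBs" rule and is classified
APB-negative; the per-cell counts track the simulator's ground truth
(`sim$truth$cells`), and `detection_metrics()` scores detected centroids
against true focus positions by optimal one-to-one matching at a 2 px
radius (all 726 telomere foci of this field are recovered exactly).

A full two-condition experiment — simulate, detect, phenotype, compare, with
CSV outputs, scatter plots and a parameter log — runs via
`run_pipeline(run_config(...))`, or from a shell through the thin wrapper
`inst/cli/apbquant.R` (`simulate` and `run` subcommands, YAML configs).

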