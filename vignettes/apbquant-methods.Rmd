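---
title: "Quantifying APBs and telomere phenotypes from fluorescence images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying APBs and telomere phenotypes from fluorescence images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Cancer cells that maintain telomeres by the alternative lengthening of
telomeres (ALT) pathway show a characteristic microscopy phenotype:
promyelocytic leukemia nuclear bodies (PML-NBs) colocalized with telomeric
DNA — ALT-associated PML bodies, APBs — together with telomere clustering
(fewer, larger telomere foci per nucleus) and telomeric DNA synthesis
outside S phase (EdU incorporation at telomeres). These readouts are scored
from multi-channel 3D fluorescence stacks: DAPI for nuclei, a PNA FISH probe
for telomeres, immunofluorescence for PML, and EdU click chemistry.

`apbquant` implements the full quantification chain as a reproducible,
testable pipeline:

1. maximum-intensity projection (MIP) of each channel's z-stack;
2. white-tophat background subtraction;
3. prominence-based local-maxima detection and per-peak segmentation;
4. DAPI nucleus segmentation and per-cell assignment of foci;
5. object-overlap calling of APBs (telomere x PML), EdU-at-telomere and
   triple events, per-cell metrics and the APB-positive classification;
6. two-group statistics per cell (two-tailed Mann-Whitney U) or per tumor
   (unpaired t on per-tumor means of per-cell values), with the
   ns/*/**/***/**** significance coding.

Because public raw image sets for this assay are not available, the package
ships a synthetic 3D microscopy generator with exact ground truth, and every
stage is validated end-to-end against that truth or against brute-force
oracles.

# Conventions

All pixel coordinates are 1-based `(y, x)` indices, origin at the top-left
of the first z-slice; distances are in pixels unless the name ends in
`_um`. Stacks are stored `(channel, z, y, x)`. The default z geometry is
26 slices at 0.2 um spacing — a 5 um stack with inclusive endpoints. The
default lateral pixel size is 0.1 um and the default camera depth 16 bits;
neither is dictated by the assay, so both are configurable and recorded in
every output.

# The detection chain

**Projection.** Detection runs on the 2D MIP only, matching how the assay
is normally scored; no 3D detection is attempted.

**White tophat.** `tophat_subtract()` subtracts the grayscale opening
(erosion then dilation by a disk) from the image. Structure wider than the
disk — uneven background, nucleoplasmic haze — is removed; foci narrower
than the disk survive unchanged. The default radius of 5 px is about twice
the effective focus radius. The morphological engine is EBImage; because
its grayscale morphology assumes intensities in [0, 1] the filter rescales
by the image range first (morphology commutes with positive affine maps).

**Maxima by prominence.** `find_maxima()` reports 8-connected local maxima
whose topographic prominence — the height above the lowest level at which
the peak's region would merge into a region with a higher peak, or above
the image minimum for the global maximum — reaches a threshold. This is the
package's reading of an intensity-based "find maxima with noise tolerance"
step: prominence has the same practical meaning but a precise, flood-order-
independent definition. Implementation is a persistence-style descending
flood with union-find; ties between equal-height merging peaks retain the
peak with the smaller `(y, x)`, and a plateau of equal maxima is reported
once, at the plateau pixel nearest its centroid. The threshold defaults to
`k * (1.4826 * MAD)` of the tophat image, a robust noise scale. `k = 7`
keeps the expected number of spurious noise maxima per 416 x 416 field near
zero even on sparse channels (an empty channel is mostly noise, where a
laxer threshold of ~5 robust SDs admits tens of junk peaks per field),
while costing no recall at realistic focus signal-to-noise (peak ~100x the
noise scale).

**Segmentation.** Each peak's object is the 8-connected set of pixels at or
above `peak_fraction` (default 0.5, i.e. full width at half maximum) of
that peak's height, grown from the peak; pixels claimed by several peaks
are split by a marker-based watershed (descending priority flood from the
peaks; the flood is restricted to pixels that could belong to any object,
which leaves object territories unchanged). Objects below
`min_focus_area_px` (default 2) are discarded.

**Nuclei.** `segment_nuclei()` uses Gaussian blur (sigma 2 px), Otsu
thresholding, hole filling and 8-connected labelling; components smaller
than `min_area_px` are dropped, and nuclei touching the image border are
excluded (their number is reported, since they affect the denominator of
"APB-positive cells (%)"). The assay itself does not prescribe a nucleus
segmentation method; this one is the package's choice and is deliberately
simple.

**Per-cell assignment.** A focus belongs to the nucleus containing its
rounded centroid; background foci are dropped and counted.

# Colocalization and per-cell phenotypes

An APB event is a **distinct telomere object overlapping at least one PML
object by at least one pixel** of their segmented masks. Telomere-anchored
counting makes `apb_count <= telomere_count` and is stable when one PML
body fragments into two; a pair-counting mode is available for comparison.
A centroid-distance criterion (pairs within `max_centroid_distance_px`) is
provided for robustness experiments with sparse labels. EdU-at-telomere
counts and triple (telomere + PML + EdU) counts follow the same anchoring
rule. A cell is **APB-positive when it shows strictly more than five**
telomere + PML colocalization events; cells with zero foci stay in all
distributions as zeros.

# The statistical layer

Per-cell comparisons use the **two-tailed Mann-Whitney U** test: U by rank
summation with midranks; the p-value by full enumeration of all
`choose(n_a + n_b, n_a)` group assignments when the combined sample is at
most 16 and tie-free, otherwise a normal approximation with tie-corrected
variance and a 0.5 continuity correction. Group summaries are medians. The
continuity-corrected normal branch agrees with the exact branch to within
about 0.011 in p at n = 8 + 8 (worst case over random draws; under 0.006 on
average).

Tumor-level comparisons average the per-cell metric within each tumor and
compare per-tumor means with the **pooled-variance (Student) unpaired t**
test, df = n_a + n_b - 2; summaries are means. Welch's test is deliberately
not the default because the simulator models equal arm variances; zero
pooled variance returns p = 1 (equal means) or p = 0 with a warning.

Significance labels use strict cuts exactly as printed in the assay's
figure legends: `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01,
`*` p < 0.05, else `ns`; a p sitting exactly on a cut gets the weaker
label. No multiple-testing correction is applied; the pipeline reports all
pairwise p-values and logs how many tests were run.

# The synthetic microscopy generator

`simulate_field()` draws, per field: elliptical nuclei (nominal semi-axes
42 x 34 px = 8.4 x 6.8 um, +/-15% axis jitter, random orientation) placed
on a stratified jittered grid — dense packing with guaranteed non-overlap;
telomere focus counts ~ Poisson(45) per nucleus, placed uniformly inside
the nucleus with a 4.5 px minimum separation (about 2.4 effective spot
sigmas, so neighbouring foci remain resolvable as two maxima; spacing is
also at least four PSF sigmas); clustering, in which each focus is merged
into its nearest neighbour with probability `merge_prob`, the survivor
growing so focus area (r^2) is conserved; PML partners placed concentric
with a telomere with probability `apb_prob` (APBs), plus ~ Poisson(10) free
PML bodies kept at least `4 * focus_radius_px` from every telomere so that
truth-level colocalization stays unambiguous after blurring; and EdU foci
at APBs with probability `edu_at_apb_prob` (default 0.7). Focus placement
is random-sequential; in a crowded nucleus the attainable count saturates
(excluded volume) and the truth tables record what was actually placed.

Rendering: each focus is a 3D Gaussian spot whose lateral scale composes
the focus radius with the PSF (`sigma = sqrt(r^2 + psf^2)`, defaults 1.5
and 1.0 px), confined to an axial band (sigma 1.5 slices); DAPI fills the
nucleus ellipse with a soft edge and an axial taper. The camera model is
Poisson shot noise on signal + background followed by Gaussian read noise,
rounding and clipping. Shot noise is drawn exactly below 30 expected
counts and via the standard N(lambda, lambda) Gaussian approximation above
— at the 50-count background the approximation error is far below the read
noise — with Gaussian draws from a Marsaglia polar generator on R's
uniform stream, so identical seeds give bit-identical stacks.

Telomere count mean 45 and free-PML mean 10 are field-realistic defaults
(46 chromosomes give ~92 telomeres, which MIP scoring typically resolves
into a few tens of foci; PML-NB counts of order 10 per nucleus are
typical); the assay's source material does not pin these down, so they are
exposed in `simulation_config()` rather than asserted.

**What the generator does not emulate:** chromatin texture, optical
aberrations and depth-dependent PSFs, deconvolution artifacts, nucleoli and
DAPI heterogeneity, touching or overlapping nuclei, segmentation-confusing
debris, and intensity variation between foci beyond the noise model.
Passing the recovery tests therefore shows the pipeline is correct under
its stated model, not that its defaults are optimal on any particular
microscope's data.

# Experiment designs

`simulate_experiment()` emits a two-arm design, optionally split into
grouping units ("tumors"): `n_units` may differ per arm (for instance 7
control vs 8 treated tumors). Each unit can draw its own APB rate from a
logit-normal distribution around its arm's rate (`unit_logit_sd`, default
0.2 in the xenograft analyses) — a realistic between-animal variability
absent from the flat cell-level design. Per-field seeds derive
deterministically from the base seed, and a manifest CSV records every
field, condition, unit and seed. `simulate_cell_counts()` exposes the count
marginal of the generative model (Poisson telomeres, merge thinning,
binomial APB and EdU draws — geometry does not enter these distributions)
as the fast path for power studies; `xenograft_power()` uses it to estimate
the power of the two-level design over many repetitions.

# Validation harness and problem sizes

The test suite checks, among others: the tophat against a brute-force
erosion/dilation oracle and the maxima finder against an exhaustive
threshold-descent prominence oracle (exact agreement on random 32 x 32
images); object colocalization against the all-pairs mask-intersection
oracle (exact agreement, up to 20 objects per channel); per-channel
detection F1 >= 0.95 against ground truth at 2 px matching radius (optimal
one-to-one assignment via the Hungarian algorithm on the within-radius
bipartite graph) over 64 simulated nuclei; recovery of the APB-positive
cell fraction to within 5 percentage points at ~208 cells; strict
monotonicity of detected per-cell telomere count (down) and mean focus
area (up) across merge probabilities 0, 0.25, 0.5 at ~208 cells per level;
exact Mann-Whitney p against full enumeration for every tie-free rank
pattern with group sizes up to 5, a Monte-Carlo type-I error in
[0.04, 0.06] at nominal 0.05 over 2000 null replicates, and the exact
label coding on boundary probes; and the 7-vs-8-unit design at 200 cells
per unit, with power >= 90% over 100 repetitions at the configured strong
APB-rate reduction (0.15 vs 0.03). In the test suite the imaging-backed
xenograft run uses 2 fields (32 cells) per tumor to keep the suite fast;
`scripts/acceptance.R` runs it at 13 fields (208 cells) per tumor.

# Numerical and design choices

* Equal-height merge ties in the maxima finder resolve toward the smaller
  `(y, x)`; plateau maxima collapse to the plateau pixel nearest the
  centroid with the same tie-break. Output is therefore deterministic and
  independent of scan order.
* A p-value exactly on a star-coding cut takes the weaker label (the cuts
  are printed as strict inequalities).
* The exact-enumeration cutoff for the Mann-Whitney test is a combined
  sample of 16 (at most 12870 assignments).
* Degenerate inputs: an all-flat image yields no maxima; an all-zero DAPI
  image yields an empty nucleus map (not an error); empty samples are
  validation errors in the statistics layer; an undefined precision or
  recall (zero detections or zero truth) is reported as 0 with a flag.
* Nucleus capacity violations (more nuclei than the non-overlap grid can
  hold) raise an error naming the limiting parameters.

# Known limitations

Detection is 2D-projection-based by design, so axially stacked foci fuse;
the simulator's clustering mechanism is a pairwise nearest-neighbour merge
chosen as the simplest process producing the fewer-but-larger signature,
with no claim of biophysical realism; intensity-correlation colocalization
(Pearson/Manders) and metaphase-spread analyses are out of scope; and the
default detection parameters are documented package choices, not values
tuned to any particular instrument.
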