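---
title: "Quantifying xyl transcript localization relative to the bacterial nucleoid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying xyl transcript localization relative to the bacterial nucleoid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tolfish)
```

## The measurement problem

RNA-FISH against the catabolic *xyl* operons of the TOL plasmid pWW0 of
*Pseudomonas putida* produces one or two diffraction-limited red foci per
induced cell. The scientific question is *where* those transcripts sit
relative to the DAPI-stained nucleoid and to the plasmid itself: bacterial
cells have no nucleus, yet transcript position is far from random. tolfish
implements the image-analysis half of that experiment as a reusable,
testable pipeline:

1. **Cell segmentation** from phase contrast (Otsu threshold, hole filling,
   distance-map watershed), or verbatim adoption of a supplied label mask.
2. **Per-cell channel normalization** of every fluorescence channel to
   [0, 1] by min–max over the cell's pixels, so red and blue intensities
   are comparable regardless of staining efficiency.
3. **Dual-level nucleoid contours**: marching-squares iso-contours of the
   normalized DAPI channel at two levels, `L_dense = 0.5` (the compact
   chromosomal DNA) and `L_diffuse = 0.2` (the surrounding diffuse DNA),
   with subpixel vertices obtained by linear interpolation between pixel
   centres.
4. **Focus detection**: multiscale Laplacian-of-Gaussian (LoG) filtering,
   thresholding, non-maximum suppression, and centre-of-mass refinement to
   subpixel precision.
5. **Three-zone classification** of each mRNA focus: NUCLEOID_OVERLAP
   (inside a dense contour), PERIPHERAL (inside diffuse, outside dense),
   NUCLEOID_FREE (outside both).
6. **mRNA–plasmid pairing** of red against green (tetO DNA-FISH) foci by
   greedy nearest-neighbour matching with distance bands: COLOCALIZED
   (≤ 2 px), ADJACENT (≤ 8 px), SEPARATE otherwise.
7. **Dispersion scoring** (the rifampin phenotype): the focal fraction of a
   cell is the share of its background-subtracted signal inside discs of
   radius 4.5 px (3 × PSF σ) around detected foci; cells below 0.5 are
   DISPERSED.
8. **Summaries**: per-condition foci-per-cell means, zone fractions and
   pairing fractions with cell-level bootstrap CIs (1,000 replicates).

Because no micrographs are publicly deposited for this experiment, the
package also contains a first-class synthetic micrograph generator with
full ground truth; every stage of the pipeline is validated against it.

## The regulatory model

`expressed_transcripts()` encodes the TOL regulatory interplay as a
three-level (OFF/LOW/HIGH) discrete function. Upper-pathway effectors
(*m*-xylene, toluene, and the gratuitous inducer *o*-xylene) activate XylR,
which fires *Pu* (→ *xylUW* HIGH) and overproduces XylS, which fires *Pm*
(→ *xylX* HIGH). Lower-pathway substrates (benzoate, 3-methyl benzoate)
activate XylS directly (*xylX* only). When *Pu* is replaced by a T7
promoter, *xylUW* follows T7 RNA polymerase instead: HIGH with IPTG, LOW
without (the chromosomal *lacI^q^/Plac-T7pol* cassette is leaky), and OFF
in hosts lacking T7 polymerase. Rifampin inhibits the host RNA polymerase
— every host-transcribed gene drops to OFF — but not T7 polymerase, so
T7-driven *xylUW* persists; rifampin additionally switches the expression
state to non-focal (dispersed signal). The LOW level is a modelling
convention for leaky expression: it halves the probability that a cell
shows any focus and halves focus intensity. The model is total over all
4 genotypes × 6 inducers × IPTG × rifampin combinations
(`expression_truth_table()`).

## What the generator emulates

`generate_field()` draws non-overlapping spherocylindrical cells
(2–4 µm × 0.9–1.1 µm at 0.065 µm/px, uniform orientation; rejection
sampling with a 1,000-retry budget), gives each a one- or two-lobed
anisotropic Gaussian nucleoid occupying ~60% of the cell length, and
renders four channels: phase contrast (dark cells), DAPI (nucleoid plus a
faint 5% contribution at plasmid positions, since DAPI stains plasmid DNA
too), red mRNA foci, and green plasmid foci. Spots are isotropic Gaussians
of σ = 1.5 px (amplitude 2000 counts over a 100-count background); noise
is Poisson shot noise (0.2 photons/count) plus Gaussian read noise
(σ = 10 counts), clipped to 16 bits. Plasmid counts per cell are 1 or 2
with probabilities 0.7/0.3 (mean 1.3), following the observed
once-or-twice-per-cell, roughly one-molecule pattern of a low-copy
replicon.

mRNA placement follows a two-stage scheme. Each focus first draws a
pairing class (colocalized 0.3 / adjacent 0.5 / independent 0.2).
Colocalized and adjacent foci are placed at, or 5 px away from, a plasmid;
each consumes a *distinct* plasmid anchor, because one-to-one matching can
never recover two transcripts tethered to the same locus — when anchors
run out the focus is demoted to independent placement, so the realized
pairing mix recorded in the truth table is the reference for recovery
tests. Independent foci are placed by the three-zone mixture
`w = (0.01, 0.15, 0.84)` over the noiseless nucleoid density — the
observed pattern for these transcripts (almost never on the dense
nucleoid, a minority peripheral, the bulk in nucleoid-free space).

Ground-truth zones are defined on the per-cell normalized *noiseless* DAPI
channel: DENSE where density ≥ 0.5, PERIPHERAL in [0.2, 0.5), FREE below.
Focus positions are drawn uniformly over the pixels of the chosen zone and
returned at pixel centres. With positions at pixel centres, linear
marching squares guarantees that a pixel with value ≥ level lies inside
the iso-polygon, so contour classification of the noiseless channel
reproduces the truth labels exactly — the pipeline's agreement on *noisy*
data (≥ 95% at default SNR) then measures only the effect of noise.
Zone-component specks smaller than 3 px are excluded from placement, since
contour extraction discards sub-2 px² polygons as noise.

Under rifampin the red channel is instead rendered by `render_dispersed()`:
the cell's total spot-equivalent intensity is spread over the mask as a
low-spatial-frequency random field (smoothed white noise, relative
amplitude = the heterogeneity parameter, 0.5 by default; 0 gives a
perfectly uniform fill), conserving total intensity exactly.

**What the generator does not emulate**: 3-D optics and defocus, camera
gain and fixed-pattern noise, photobleaching, autofluorescence gradients,
cell crowding/overlap, division septa, and irregular cell shapes. Passing
the recovery tests therefore demonstrates correctness of the *analysis*
under the stated imaging model, not robustness to every artefact of real
micrographs; on real data the segmentation and the contrast gate (below)
are the stages most likely to need retuning.

## Numerical and design choices

- **Coordinates** are 0-based with pixel centres at integer positions
  (x = column, y = row); contour vertices, centroids and profiles all live
  in this one frame.
- **Contour closure**: per-cell rasters are masked (NA outside the cell);
  for contouring, masked pixels become 0 and the grid is zero-padded, so
  nucleoids touching the cell edge still produce closed polygons along the
  mask boundary. Unmasked rasters are contoured as-is and a constant
  raster yields no contours. Polygons under 2 px² are discarded.
- **LoG scale range** defaults to [1.0, 1.6] px around the 1.5 px PSF.
  A wider top scale (e.g. 2.5 px) acts as a matched filter for *merged
  pairs*: for two spots 4–5 px apart the midpoint response at σ = 2.5
  exceeds either spot's matched response, collapsing the pair into one
  detection. Keeping the range tight resolves pairs down to ~4 px; foci
  closer than the 3 px minimum separation merge by contract.
- **Detection threshold** 0.2 (on the scale-normalized LoG response of the
  per-cell normalized raster, where the brightest focus responds at ~0.5):
  high enough to reject the smooth ~4 px blobs of dispersed signal
  (response < ~0.12), low enough for every rendered focus.
- **Centroid refinement** is a clipped, background-subtracted centre of
  mass in a ±3 px window, iterated three times with recentring. When two
  detections are close, the window shrinks so it cannot overlap the
  neighbour's core, which would otherwise bias both centroids by > 1 px.
  At the default imaging SNR the field-level RMSE is ~0.09 px.
- **Per-cell contrast gate**: min–max normalization stretches a
  signal-free cell's noise to [0, 1], so the pipeline requires a cell's
  smoothed raw contrast (max − median) to exceed 5 robust noise SDs
  (estimated from non-cell background pixels) before running detection;
  failing cells are NO_SIGNAL.
- **DAPI pre-smoothing** σ = 0.5 px before normalization and contouring:
  enough to suppress shot-noise contour jitter; heavier smoothing flattens
  the nucleoid peak and, after min–max normalization, systematically
  inflates both iso-contours (free foci start counting as peripheral).
- **Peripheral definition**: inside-diffuse-minus-dense (the two levels the
  method actually defines), with a fixed-width band around the dense
  contour available as `peripheral_mode = "band"`.
- **Overlap statistic**: area(A ∩ B)/area(A) by exact polygon clipping
  (Clipper, via polyclip), normalized by the red region because the
  question is "what share of red signal coincides with DNA"; Jaccard is an
  option.
- **Bootstrap** resamples cells, not foci — cells are the independent
  units — with 1,000 replicates and a fixed seed, making CIs reproducible
  bit for bit.
- **Foci-per-cell denominator**: all segmented cells in the condition
  (configurable to cells-with-foci), since induced populations are scored
  whole.
- **Normalization scope** is per cell (`normalize_scope = "cell"`),
  matching a per-cell contouring workflow; per-field is available.
- **Determinism**: every stochastic step (generation, noise, bootstraps)
  is driven by explicit seeds; per-field seeds are derived from the run
  seed, and repeated runs write byte-identical outputs.

## Validation fixtures and problem sizes

The recovery suites use 15 default-preset fields of 20 cells (~300 cells,
~440 red foci) for zone-fraction and spot-metrology checks, 60 cells per
mode for dispersed-vs-focal classification, and 300 cells per arm for the
chromosomal-integration (+30% foci) comparison. Zone-fraction and
metrology fixtures set the pairing mix to fully independent: paired foci
inherit the plasmid's position by construction (colocalized pairs lie
below the detector's minimum separation and merge by design), so only
independently placed foci probe the zone weights and the detector's
resolution. Geometry operations are validated against hand-written
oracles — ray-casting point-in-polygon and 10× supersampled rasterization
— that share no code with the pracma/polyclip implementation paths.

## Known limitations

- Foci closer than ~4 px are reported as one detection; the counts of
  strongly clustered transcripts (e.g. the T7 preset's 3 foci/cell) are
  therefore conservative.
- The dispersion index needs the contrast gate to distinguish a uniformly
  dim cell from an empty one; in normalized units alone the two are
  indistinguishable.
- The regulatory model is qualitative by design: OFF/LOW/HIGH levels and a
  focal/dispersed flag, not promoter kinetics.
- Greedy 1:1 pairing coincides with optimal assignment only for the 1–2
  foci per channel per cell regime it is built for.
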