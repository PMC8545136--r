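# tolfish

Single-cell image analysis of TOL-plasmid (*xyl*) transcript localization
in bacterial FISH micrographs — plus a fully ground-truthed synthetic
micrograph generator that makes every stage verifiable.

## The problem

RNA-FISH against the *xylUW* (upper) and *xylX* (lower) catabolic operons
of the TOL plasmid pWW0 shows one or two discrete red foci per induced
*Pseudomonas putida* cell. Combined with DAPI (nucleoid), phase contrast
(cell outline) and a green tetO DNA-FISH tag on the plasmid, each cell
yields a small spatial dataset: where do transcripts sit relative to the
dense and diffuse nucleoid, and relative to their own DNA template?
tolfish is for microscopists and quantitative biologists who need those
per-cell statistics reproducibly: per-cell channel normalization to
[0, 1], subpixel nucleoid iso-contours at two density levels, LoG spot
detection with subpixel centroids, three-zone focus classification,
contour-overlap scoring, mRNA–plasmid pairing, arrow-projected line
profiles, and a dispersion index that separates focal from diffuse signal
(the rifampin phenotype).

## The statistics at the core

For each cell *c* with normalized DAPI channel *D_c* ∈ [0, 1], the
nucleoid is described by two marching-squares iso-contours,
Γ_dense = {D_c = 0.5} and Γ_diffuse = {D_c = 0.2}. Each mRNA focus with
subpixel centroid **x** is classified

- NUCLEOID_OVERLAP if **x** ∈ int Γ_dense,
- PERIPHERAL if **x** ∈ int Γ_diffuse \ int Γ_dense,
- NUCLEOID_FREE otherwise,

and zone fractions are reported with cell-level bootstrap CIs. Contour
commonality between red and blue signal is area(A ∩ B)/area(A) by exact
polygon clipping. Red–green pairing uses greedy nearest-neighbour
matching with bands d ≤ 2 px (colocalized) and d ≤ 8 px (adjacent). The
dispersion index of a cell is the fraction of its background-subtracted
signal within 4.5 px discs around detected foci; below 0.5 the cell is
DISPERSED. A discrete model of the TOL regulatory network
(`expressed_transcripts()`) decides which transcripts any
genotype/inducer/IPTG/rifampin combination expresses, and drives the
simulator.

## Worked example

```r
library(tolfish)

preset <- preset_params("wt_mxylene")        # WT pWW0 + m-xylene, tetO tag
field  <- generate_field(preset$params, preset$cond, seed = 1)
res    <- analyze_stack(field$stack, analysis_params())
summ   <- summarize_foci(res$records, res$cells, seed = 1)
summ$red
#> <summary_stats> red: 20 cells, 28 foci, 1.400 foci/cell [1.200, 1.600]
#>   zones: overlap 10.7%, peripheral 21.4%, free 67.9%
summ$green
#> <summary_stats> green: 20 cells, 25 foci, 1.250 foci/cell [1.100, 1.450]
#>   zones: overlap 20.0%, peripheral 20.0%, free 60.0%

head(res$records[res$records$channel == "red",
                 c("cell_id", "x", "y", "zone", "pair_label", "pair_distance")])
#>    cell_id         x         y             zone  pair_label pair_distance
#> 1        1 221.96773 100.01134    NUCLEOID_FREE    ADJACENT      5.053389
#> 4        2  74.98264  26.99308    NUCLEOID_FREE    SEPARATE            NA
#> 5        2  62.95454  28.00062 NUCLEOID_OVERLAP COLOCALIZED      1.014681
#> 7        3  34.99708 185.01184    NUCLEOID_FREE COLOCALIZED      1.019231
#> 9        4 225.99550  53.02573    NUCLEOID_FREE    ADJACENT      4.958832
#> 11       5 221.01372 141.01825       PERIPHERAL    ADJACENT      4.989379
```

One field of 20 simulated cells: red mRNA foci average 1.4 per cell, most
of them in nucleoid-free space; green plasmid foci appear once or twice
per cell; paired rows show a transcript sitting on its plasmid
(colocalized, ~1 px) or ~5 px away (adjacent). On this single small field
the red zone split (11/21/68%) scatters around the generator's placement
weights (1/15/84%); the recovery tests in `tests/testthat/` show the
estimates concentrate on the weights at n ≥ 300 foci.

`run_pipeline()` orchestrates the same stages from a YAML/list config
(simulate or analyze mode) and writes CSV tables plus a JSON manifest;
`inst/scripts/tolfish-cli.R` is a thin command-line wrapper with
`simulate`, `analyze`, `report` and `probes-validate` subcommands.

## Package layout

- `R/tol_logic.R` — discrete TOL regulatory model.
- `R/sim_params.R`, `R/simulate.R` — synthetic micrograph generator with
  ground truth.
- `R/segment.R` — cell segmentation, per-cell normalization, subpixel
  iso-contours, nucleoid zones.
- `R/spots.R` — LoG focus detection, centroid refinement, dispersion
  index.
- `R/coloc.R` — zone classification, region overlap, pairing, line
  profiles.
- `R/report.R`, `R/pipeline.R`, `R/io.R` — summaries, bootstrap CIs,
  probe-manifest validation, orchestration, TIFF/CSV/JSON I/O.
- `vignettes/tolfish-methods.Rmd` — model, assumptions, parameter
  rationale, limitations.
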