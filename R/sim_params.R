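#' Simulation parameters for synthetic micrograph fields
#'
#' Bundles every knob of the synthetic fluorescence micrograph generator.
#' Defaults emulate wide-field imaging of *P. putida* at 100x magnification:
#' rod-shaped cells 2--4 um long and ~1 um wide on a 0.065 um/px grid, a
#' nucleoid occupying ~60% of the cell length with one or two lobes, red mRNA
#' foci placed by a three-zone mixture over the nucleoid density
#' (dense / peripheral / nucleoid-free), 1--2 green plasmid foci per cell, a
#' diffraction-limited Gaussian PSF, Poisson shot noise plus Gaussian read
#' noise, and a low-spatial-frequency dispersed signal mode for
#' rifampin-treated cells.
#'
#' @param field_size integer c(width, height) of the field in pixels.
#' @param pixel_size_um physical pixel size in micrometres per pixel.
#' @param n_cells number of cells to place in the field.
#' @param cell_length_um,cell_width_um c(min, max) cell dimensions in um.
#' @param nucleoid_frac fraction of the cell length occupied by the nucleoid
#'   (the +-2 SD extent of its axial profile).
#' @param lobe_probs probabilities of a 1-lobed vs 2-lobed nucleoid.
#' @param nucleoid_peak peak DAPI intensity of the nucleoid in raw counts.
#' @param L_dense,L_diffuse iso-levels (on the per-cell normalized noiseless
#'   density) defining ground-truth DENSE and PERIPHERAL/FREE zones.
#' @param zone_weights numeric c(dense, peripheral, free) mixture weights for
#'   independent mRNA focus placement; must sum to 1.
#' @param mean_mrna_foci mean mRNA foci per induced (HIGH) cell; counts are
#'   drawn from \{1, 2\} with the matching mean.
#' @param t7_mean_foci mean mRNA foci per cell under full T7 drive (counts
#'   Poisson, truncated at 1).
#' @param low_presence_prob probability that a LOW-expression cell shows any
#'   focus at all (LOW also halves focus intensity).
#' @param foci_multiplier multiplier on the mRNA focus count mean (1.3 for
#'   the chromosomal-integration preset, reflecting its ~30% higher counts).
#' @param plasmid_foci_probs probabilities of 1 vs 2 plasmid foci per cell.
#' @param plasmid_placement c(nucleoid, peripheral) mixture for plasmid
#'   placement: on the nucleoid (density >= L_diffuse) or off it.
#' @param pairing_mix c(colocalized, adjacent, independent) mixture giving,
#'   per red focus, its spatial relation to a plasmid focus.
#' @param adjacency_offset_px centre-to-centre distance used for ADJACENT
#'   placement, in pixels.
#' @param psf_sigma Gaussian PSF standard deviation in pixels.
#' @param mrna_amplitude,plasmid_amplitude peak spot intensities (raw counts).
#' @param plasmid_dapi_frac faint DAPI contribution at plasmid positions, as
#'   a fraction of `nucleoid_peak` (DAPI stains plasmid DNA too).
#' @param background constant background level in raw counts (all channels).
#' @param photon_scale photons per raw count for shot noise; larger is less
#'   noisy.
#' @param read_sigma Gaussian read noise SD in raw counts.
#' @param dispersed_heterogeneity heterogeneity in [0,1] of the dispersed
#'   (rifampin) signal mode; 0 fills the cell uniformly.
#' @param depth maximum representable intensity (16-bit by default).
#' @param max_place_retries rejection-sampling budget per cell for
#'   non-overlapping placement.
#' @param green_channel logical; render the plasmid (tetO-tag) channel.
#' @return object of class `sim_params` (a validated list).
#' @seealso [generate_field()], [preset_params()]
#' @export
sim_params <- function(field_size = c(256L, 256L),
                       pixel_size_um = 0.065,
                       n_cells = 20L,
                       cell_length_um = c(2.0, 4.0),
                       cell_width_um = c(0.9, 1.1),
                       nucleoid_frac = 0.6,
                       lobe_probs = c(0.5, 0.5),
                       nucleoid_peak = 3000,
                       L_dense = 0.5,
                       L_diffuse = 0.2,
                       zone_weights = c(dense = 0.01, peripheral = 0.15, free = 0.84),
                       mean_mrna_foci = 1.5,
                       t7_mean_foci = 3,
                       low_presence_prob = 0.5,
                       foci_multiplier = 1,
                       plasmid_foci_probs = c(0.7, 0.3),
                       plasmid_placement = c(nucleoid = 0.5, peripheral = 0.5),
                       pairing_mix = c(colocalized = 0.3, adjacent = 0.5, independent = 0.2),
                       adjacency_offset_px = 5,
                       psf_sigma = 1.5,
                       mrna_amplitude = 2000,
                       plasmid_amplitude = 1500,
                       plasmid_dapi_frac = 0.05,
                       background = 100,
                       photon_scale = 0.2,
                       read_sigma = 10,
                       dispersed_heterogeneity = 0.5,
                       depth = 65535,
                       max_place_retries = 1000L,
                       green_channel = TRUE) {
  p <- as.list(environment())
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(length(p$field_size) == 2, all(p$field_size >= 32),
            p$pixel_size_um > 0, p$n_cells >= 0,
            length(p$cell_length_um) == 2, diff(p$cell_length_um) >= 0,
            length(p$cell_width_um) == 2, diff(p$cell_width_um) >= 0,
            p$nucleoid_frac > 0, p$nucleoid_frac <= 1,
            length(p$lobe_probs) == 2, all(p$lobe_probs >= 0),
            0 < p$L_diffuse, p$L_diffuse < p$L_dense, p$L_dense < 1,
            p$psf_sigma > 0, p$photon_scale > 0, p$read_sigma >= 0,
            p$dispersed_heterogeneity >= 0, p$dispersed_heterogeneity <= 1,
            p$depth > 0, p$max_place_retries >= 1)
  w <- p$zone_weights
  if (length(w) != 3 || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("zone_weights must be three nonnegative values summing to 1")
  m <- p$pairing_mix
  if (length(m) != 3 || any(m < 0) || abs(sum(m) - 1) > 1e-9)
    stop("pairing_mix must be three nonnegative values summing to 1")
  q <- p$plasmid_foci_probs
  if (length(q) != 2 || any(q < 0) || abs(sum(q) - 1) > 1e-9)
    stop("plasmid_foci_probs must be two nonnegative values summing to 1")
  invisible(TRUE)
}

#' Preset parameter/condition bundles mirroring the imaging experiments
#'
#' Each preset pairs a [sim_params()] object with the [tol_condition()] it
#' emulates:
#' \describe{
#'   \item{wt_mxylene}{Wild-type pWW0 host induced with m-xylene; both
#'     transcripts HIGH, tetO-tagged plasmid visible in green.}
#'   \item{uninduced}{Wild-type host on succinate, no aromatic effector;
#'     no red signal.}
#'   \item{paw140_mxylene}{Chromosomally integrated operons; focus-count
#'     multiplier 1.3.}
#'   \item{t7_iptg}{T7-driven upper operon with IPTG; more foci per cell
#'     (mean 3), mostly in nucleoid-free space.}
#'   \item{rifampin}{T7 host under rifampin; only T7-driven xylUW remains and
#'     its signal is dispersed, not focal.}
#' }
#'
#' @param name preset name.
#' @param ... overrides forwarded to [sim_params()].
#' @return list with elements `params` and `cond`.
#' @export
preset_params <- function(name = c("wt_mxylene", "uninduced", "paw140_mxylene",
                                   "t7_iptg", "rifampin"), ...) {
  name <- match.arg(name)
  switch(name,
    wt_mxylene = list(params = sim_params(...),
                      cond = tol_condition("WT_pWW0", "M_XYLENE")),
    uninduced = list(params = sim_params(...),
                     cond = tol_condition("WT_pWW0", "NONE")),
    paw140_mxylene = list(params = sim_params(foci_multiplier = 1.3,
                                              green_channel = FALSE, ...),
                          cond = tol_condition("PAW140_CHROMOSOMAL", "M_XYLENE")),
    t7_iptg = list(params = sim_params(...),
                   cond = tol_condition("PUXT7_IN_T7_HOST", "NONE", iptg = TRUE)),
    rifampin = list(params = sim_params(...),
                    cond = tol_condition("PUXT7_IN_T7_HOST", "M_XYLENE",
                                         iptg = TRUE, rifampin = TRUE))
  )
}
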