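#' Spot detection parameters
#'
#' Settings of the multiscale Laplacian-of-Gaussian (LoG) focus detector,
#' mirroring standard smFISH practice for diffraction-limited spots.
#'
#' @param sigma_range c(min, max) LoG scales in px; should bracket the PSF
#'   sigma of the data narrowly. Scales well above the PSF act as matched
#'   filters for merged pairs and cannot resolve foci 4--5 px apart, so the
#'   default range is deliberately tight around the ~1.5 px PSF.
#' @param n_scales number of scales, geometrically spaced over the range.
#' @param threshold detection threshold on the scale-normalized LoG response
#'   of the normalized raster (a matched-scale Gaussian of normalized peak A
#'   responds at about A/2, so the brightest focus of a cell sits near 0.5).
#'   The default also rejects the smooth low-frequency blobs of dispersed
#'   (rifampin-like) signal, which respond below ~0.12 at PSF scales.
#' @param min_sep minimum separation between accepted foci in px
#'   (non-maximum suppression radius).
#' @param window centroid refinement window half-width in px (>= 2).
#' @return list of class `detection_params`.
#' @export
detection_params <- function(sigma_range = c(1.0, 1.6), n_scales = 3,
                             threshold = 0.2, min_sep = 3, window = 3) {
  stopifnot(length(sigma_range) == 2, all(sigma_range > 0),
            sigma_range[1] <= sigma_range[2], n_scales >= 1,
            threshold > 0, min_sep >= 0, window >= 2)
  structure(list(sigma_range = sigma_range, n_scales = n_scales,
                 threshold = threshold, min_sep = min_sep, window = window),
            class = "detection_params")
}

# Scale-normalized negative-LoG response (bright blobs positive), computed
# by direct convolution with a truncated LoG kernel on a median-padded crop.
log_response <- function(raster, sigma) {
  r <- ceiling(4 * sigma)
  ax <- (-r):r
  g <- exp(-ax^2 / (2 * sigma^2))
  gx <- outer(g, g)
  xx <- outer(ax^2, rep(1, length(ax))) + outer(rep(1, length(ax)), ax^2)
  # LoG = (r^2 - 2 sigma^2) / sigma^4 * G; gx lacks G's 1/(2 pi sigma^2)
  k <- -sigma^2 * gx * (xx - 2 * sigma^2) / sigma^4 / (2 * pi * sigma^2)
  k <- k - mean(k) # zero-DC so flat regions respond 0
  as.matrix(EBImage::filter2(EBImage::Image(raster), k))
}

#' Detect fluorescent foci in a per-cell normalized channel
#'
#' Local maxima of the scale-normalized LoG response over a range of scales,
#' thresholded and non-maximum suppressed at `min_sep`, then refined to
#' subpixel precision with [refine_centroid()]. Pixels outside the cell are
#' replaced by the in-cell median before filtering so the mask edge does not
#' generate spurious responses; candidate maxima are restricted to the cell
#' mask (dilated by 1 px).
#'
#' @param norm_raster per-cell normalized raster ([normalize_channel()]).
#' @param cell a [cell_region()].
#' @param params a [detection_params()].
#' @return data.frame of foci: `x`, `y` (subpixel centroid), `peak`
#'   (bilinear intensity at the centroid), `integrated`
#'   (background-subtracted sum over the refinement window), `response`
#'   (LoG response at detection), `cell_id`. Empty for signal-free cells.
#' @export
detect_foci <- function(norm_raster, cell, params = detection_params()) {
  stopifnot(is.matrix(norm_raster), inherits(params, "detection_params"))
  m <- cell$mask
  if (!any(m)) return(empty_foci())
  v <- norm_raster
  med <- stats::median(v[m], na.rm = TRUE)
  v[is.na(v) | !m] <- med
  sig <- if (params$n_scales == 1) params$sigma_range[1] else
    exp(seq(log(params$sigma_range[1]), log(params$sigma_range[2]),
            length.out = params$n_scales))
  resp <- log_response(v, sig[1])
  for (s in sig[-1]) resp <- pmax(resp, log_response(v, s))
  # strict 3x3 local maxima above threshold, inside the (dilated) cell
  H <- nrow(v); W <- ncol(v)
  dil <- as.matrix(EBImage::dilate(EBImage::Image(m * 1),
                                   EBImage::makeBrush(3, "box"))) > 0
  cand <- which(resp > params$threshold & dil, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < H & cand[, 2] > 1 & cand[, 2] < W,
               , drop = FALSE]
  if (!nrow(cand)) return(empty_foci())
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    nb <- resp[(r - 1):(r + 1), (c - 1):(c + 1)]
    resp[r, c] >= max(nb)
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (!nrow(cand)) return(empty_foci())
  # non-maximum suppression at min_sep, strongest first
  vals <- resp[cand]
  ord <- order(vals, decreasing = TRUE)
  keep <- integer(0)
  for (i in ord) {
    p <- cand[i, ]
    if (!length(keep) ||
        all((cand[keep, 1] - p[1])^2 + (cand[keep, 2] - p[2])^2 >=
            params$min_sep^2))
      keep <- c(keep, i)
  }
  cand <- cand[keep, , drop = FALSE]
  vals <- vals[keep]
  out <- lapply(seq_len(nrow(cand)), function(i) {
    approx <- c(cand[i, 2] - 1, cand[i, 1] - 1) # (x, y), 0-based
    # shrink the centroiding window so it cannot overlap a neighbouring
    # candidate's core, which would bias the centre of mass toward it
    hw <- params$window
    if (nrow(cand) > 1) {
      d2 <- (cand[-i, 1, drop = FALSE] - cand[i, 1])^2 +
            (cand[-i, 2, drop = FALSE] - cand[i, 2])^2
      hw <- max(1, min(hw, floor((sqrt(min(d2)) - 1) / 2)))
    }
    pos <- refine_centroid(norm_raster, approx, hw)
    win <- window_values(v, pos, params$window)
    data.frame(x = pos[1], y = pos[2],
               peak = bilinear_at(v, pos[1], pos[2]),
               integrated = sum(pmax(win - med, 0)),
               response = vals[i], cell_id = cell$id)
  })
  do.call(rbind, out)
}

empty_foci <- function() {
  data.frame(x = numeric(0), y = numeric(0), peak = numeric(0),
             integrated = numeric(0), response = numeric(0),
             cell_id = integer(0))
}

window_values <- function(raster, pos, hw) {
  xs <- max(0, round(pos[1]) - hw):min(ncol(raster) - 1, round(pos[1]) + hw)
  ys <- max(0, round(pos[2]) - hw):min(nrow(raster) - 1, round(pos[2]) + hw)
  raster[ys + 1, xs + 1]
}

#' Refine a focus centroid to subpixel precision
#'
#' Background-subtracted intensity-weighted centre of mass within a window
#' around the approximate position, iterated three times with window
#' recentring. The background is the median of the in-raster (non-NA)
#' values; weights are clipped at zero. If every weight vanishes (uniform
#' window), the approximate position is returned unchanged with a warning.
#'
#' @param norm_raster normalized raster (NA allowed outside the cell).
#' @param approx c(x, y) approximate position, 0-based.
#' @param window half-width of the centroiding window in px.
#' @return c(x, y) refined subpixel position.
#' @export
refine_centroid <- function(norm_raster, approx, window = 3) {
  stopifnot(length(approx) == 2, window >= 1)
  v <- norm_raster
  bg <- stats::median(v[!is.na(v)])
  v[is.na(v)] <- bg
  pos <- as.numeric(approx)
  for (iter in 1:3) {
    xs <- max(0, round(pos[1]) - window):min(ncol(v) - 1, round(pos[1]) + window)
    ys <- max(0, round(pos[2]) - window):min(nrow(v) - 1, round(pos[2]) + window)
    w <- pmax(v[ys + 1, xs + 1, drop = FALSE] - bg, 0)
    tot <- sum(w)
    if (tot == 0) {
      warning("uniform window; returning approximate position")
      return(as.numeric(approx))
    }
    gx <- outer(rep(1, length(ys)), xs)
    gy <- outer(ys, rep(1, length(xs)))
    pos <- c(sum(w * gx), sum(w * gy)) / tot
  }
  pos
}

#' Focal-versus-dispersed signal scoring for one cell
#'
#' The focal fraction is the share of the cell's background-subtracted
#' signal contained in discs of radius `disc_radius` around the detected
#' foci (background = in-cell median, subtraction clipped at 0). Patterns:
#' FOCAL when the fraction reaches `t_focal`; DISPERSED when below it with
#' total signal above `signal_floor`; NO_SIGNAL otherwise. A perfectly
#' uniform cell (zero median-subtracted total) is DISPERSED when its median
#' level exceeds the floor -- a cell nonuniformly filled with signal has
#' signal, it just is not focal.
#'
#' @param norm_raster per-cell normalized raster.
#' @param cell a [cell_region()].
#' @param foci data.frame from [detect_foci()] on the same raster.
#' @param disc_radius disc radius in px (default 3x the typical PSF sigma).
#' @param t_focal focal-fraction threshold separating FOCAL from DISPERSED.
#' @param signal_floor minimum total (median-subtracted) signal to call any
#'   signal at all.
#' @return list of class `dispersion_result`: `cell_id`, `channel` (NA here;
#'   filled by the pipeline), `focal_fraction`, `pattern`.
#' @export
dispersion_index <- function(norm_raster, cell, foci, disc_radius = 4.5,
                             t_focal = 0.5, signal_floor = 0) {
  m <- cell$mask
  v <- norm_raster
  vin <- v[m]
  med <- stats::median(vin, na.rm = TRUE)
  sub <- pmax(vin - med, 0)
  total <- sum(sub, na.rm = TRUE)
  if (total <= signal_floor) {
    pattern <- if (total == 0 && med > signal_floor) "DISPERSED" else "NO_SIGNAL"
    return(structure(list(cell_id = cell$id, channel = NA_character_,
                          focal_fraction = 0, pattern = pattern),
                     class = "dispersion_result"))
  }
  idx <- which(m, arr.ind = TRUE)
  px <- idx[, 2] - 1; py <- idx[, 1] - 1
  in_disc <- rep(FALSE, nrow(idx))
  for (i in seq_len(nrow(foci)))
    in_disc <- in_disc | ((px - foci$x[i])^2 + (py - foci$y[i])^2 <=
                            disc_radius^2)
  frac <- sum(sub[in_disc], na.rm = TRUE) / total
  pattern <- if (frac >= t_focal) "FOCAL" else "DISPERSED"
  structure(list(cell_id = cell$id, channel = NA_character_,
                 focal_fraction = frac, pattern = pattern),
            class = "dispersion_result")
}
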