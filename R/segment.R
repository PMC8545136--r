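#' Construct a cell region
#'
#' The per-cell analysis unit: a labelled binary mask with its bounding box
#' and area.
#'
#' @param id integer cell id.
#' @param mask logical matrix (full field size), TRUE inside the cell.
#' @return object of class `cell_region` with fields `id`, `mask`, `bbox`
#'   (named vector xmin/xmax/ymin/ymax, 0-based pixel coordinates) and `area`
#'   (pixel count).
#' @export
cell_region <- function(id, mask) {
  stopifnot(is.matrix(mask), is.logical(mask), any(mask))
  idx <- which(mask, arr.ind = TRUE)
  bbox <- c(xmin = min(idx[, 2]) - 1, xmax = max(idx[, 2]) - 1,
            ymin = min(idx[, 1]) - 1, ymax = max(idx[, 1]) - 1)
  structure(list(id = id, mask = mask, bbox = bbox, area = nrow(idx)),
            class = "cell_region")
}

#' Segmentation parameters
#'
#' @param min_area,max_area area filter in px^2 for accepted cells.
#' @param watershed_tolerance tolerance of the distance-map watershed used to
#'   split touching cells.
#' @return list of class `segment_params`.
#' @export
segment_params <- function(min_area = 50, max_area = 5000,
                           watershed_tolerance = 1) {
  structure(list(min_area = min_area, max_area = max_area,
                 watershed_tolerance = watershed_tolerance),
            class = "segment_params")
}

#' Segment single cells from a phase-contrast image or a label mask
#'
#' With a label `mask` supplied (integer matrix, 0 = background), regions are
#' passed through verbatim, one [cell_region()] per label, subject only to
#' the area filter being disabled. Otherwise the phase-contrast raster is
#' inverted and normalized, thresholded by Otsu's method, holes are filled,
#' touching cells are split by a watershed on the distance map, and connected
#' regions are filtered by area.
#'
#' @param raster 2-D numeric matrix (phase contrast; cells darker than
#'   background). Ignored when `mask` is given.
#' @param params a [segment_params()].
#' @param mask optional integer label matrix (ground truth or external
#'   segmentation) passed through verbatim.
#' @return list of [cell_region()] objects (possibly empty).
#' @export
segment_cells <- function(raster, params = segment_params(), mask = NULL) {
  if (!is.null(mask)) {
    stopifnot(is.matrix(mask))
    labs <- sort(setdiff(unique(as.vector(mask)), 0))
    return(lapply(seq_along(labs),
                  function(i) cell_region(i, mask == labs[i])))
  }
  stopifnot(is.matrix(raster))
  rng <- range(raster)
  if (diff(rng) == 0) return(list())
  inv <- (rng[2] - raster) / (rng[2] - rng[1]) # cells bright
  th <- EBImage::otsu(EBImage::Image(inv), range = c(0, 1))
  bw <- inv > th
  if (!any(bw)) return(list())
  bw_img <- EBImage::fillHull(EBImage::Image(bw * 1))
  dm <- EBImage::distmap(bw_img)
  lab <- EBImage::watershed(dm, tolerance = params$watershed_tolerance)
  lab <- as.matrix(EBImage::imageData(lab))
  out <- list()
  for (l in sort(setdiff(unique(as.vector(lab)), 0))) {
    m <- lab == l
    a <- sum(m)
    if (a >= params$min_area && a <= params$max_area)
      out[[length(out) + 1]] <- cell_region(length(out) + 1L, m)
  }
  out
}

#' Min-max normalize a channel over one cell
#'
#' Rescales the in-cell pixel values to [0, 1] by `(v - min) / (max - min)`
#' computed over the cell mask, enabling direct comparison between channels
#' regardless of absolute intensity scale. Pixels outside the cell are NA.
#' A flat channel (max = min) normalizes to all zeros with a warning.
#'
#' @param raster numeric matrix.
#' @param cell a [cell_region()] (anything with a logical `$mask` works).
#' @param keep_outside if TRUE, apply the same affine map to out-of-cell
#'   pixels instead of masking them with NA (values there may fall outside
#'   [0, 1]). Useful for spot detection, where the PSF tail of a focus at the
#'   cell edge carries real signal beyond the mask.
#' @return numeric matrix, in [0, 1] inside the cell; NA outside unless
#'   `keep_outside`.
#' @export
normalize_channel <- function(raster, cell, keep_outside = FALSE) {
  m <- cell$mask
  stopifnot(is.matrix(raster), identical(dim(raster), dim(m)), any(m))
  v <- raster[m]
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("flat channel over cell mask; normalizing to all zeros")
    out <- matrix(NA_real_, nrow(raster), ncol(raster))
    out[m] <- 0
    if (keep_outside) out[!m] <- 0
    return(out)
  }
  if (keep_outside) {
    out <- (raster - rng[1]) / (rng[2] - rng[1])
  } else {
    out <- matrix(NA_real_, nrow(raster), ncol(raster))
    out[m] <- (v - rng[1]) / (rng[2] - rng[1])
  }
  out
}

#' Extract subpixel iso-contours at a given level
#'
#' Marching-squares contour extraction with linear interpolation between
#' pixel centres (via [grDevices::contourLines()]), on the per-cell
#' normalized raster. When the raster carries a mask (NA outside the cell),
#' masked pixels are treated as 0 and the grid is zero-padded, so contours
#' clipped by the cell boundary close along the cell-mask edge. Unmasked
#' rasters are contoured as-is (a constant raster has no crossings); any
#' open contour is closed by joining its endpoints. Polygons enclosing less
#' than `min_area` px^2 are discarded as noise.
#'
#' Coordinates are 0-based with pixel centres at integer positions
#' (x = column, y = row), matching the rest of the package.
#'
#' @param norm_raster normalized raster (in [0,1] inside the cell, NA
#'   allowed outside).
#' @param level iso-level in (0, 1).
#' @param min_area smallest enclosed polygon area kept, in px^2.
#' @return list of contours, each of class `tol_contour`: list with
#'   `vertices` (n x 2 matrix of x, y; closed, first row == last row),
#'   `level`, and `area` (enclosed area in px^2, shoelace formula).
#' @export
contour_at_level <- function(norm_raster, level, min_area = 2) {
  stopifnot(is.matrix(norm_raster), level > 0, level < 1)
  masked <- anyNA(norm_raster)
  z <- norm_raster
  z[is.na(z)] <- 0
  if (!masked && diff(range(z)) == 0) return(list()) # constant: no crossings
  if (masked) {
    # crop to the support plus a zero pad so boundary contours close along
    # the mask edge
    nz <- which(z > 0, arr.ind = TRUE)
    if (!nrow(nz)) return(list())
    r0 <- max(1, min(nz[, 1]) - 2); r1 <- min(nrow(z), max(nz[, 1]) + 2)
    c0 <- max(1, min(nz[, 2]) - 2); c1 <- min(ncol(z), max(nz[, 2]) + 2)
    sub <- z[r0:r1, c0:c1]
    sub <- rbind(0, cbind(0, sub, 0), 0)
    xs <- (c0 - 2):(c1)   # 0-based x of padded columns: (c0-1)-1 ... (c1-1)+1
    ys <- (r0 - 2):(r1)
  } else {
    sub <- z
    xs <- 0:(ncol(z) - 1)
    ys <- 0:(nrow(z) - 1)
  }
  cl <- grDevices::contourLines(x = xs, y = ys, z = t(sub), levels = level)
  out <- list()
  for (cc in cl) {
    vx <- cc$x; vy <- cc$y
    if (length(vx) < 2) next
    if (vx[1] != vx[length(vx)] || vy[1] != vy[length(vy)]) {
      vx <- c(vx, vx[1]); vy <- c(vy, vy[1])
    }
    a <- abs(polygon_area(vx, vy))
    if (a < min_area) next
    out[[length(out) + 1]] <- structure(
      list(vertices = cbind(x = vx, y = vy), level = level, area = a),
      class = "tol_contour")
  }
  out
}

# Signed shoelace area.
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  sum(x * y[i2] - x[i2] * y) / 2
}

#' Dual-level nucleoid contours for one cell
#'
#' Extracts the dense (`L_dense`) and diffuse (`L_diffuse`) iso-contours of
#' the per-cell normalized DAPI channel -- the black and yellow outlines of
#' nucleoid imagery: the densest DNA regions and the relatively less
#' concentrated sections around them. Level nesting (every dense region
#' geometrically inside the diffuse region) is enforced.
#'
#' @param norm_dapi per-cell normalized DAPI raster.
#' @param cell a [cell_region()] (used for error reporting).
#' @param L_dense,L_diffuse iso-levels, `0 < L_diffuse < L_dense < 1`.
#' @return object of class `nucleoid_zones`: list with `cell_id`, `dense`
#'   (list of contours at L_dense) and `diffuse` (list at L_diffuse).
#' @export
nucleoid_zones <- function(norm_dapi, cell, L_dense = 0.5, L_diffuse = 0.2) {
  stopifnot(0 < L_diffuse, L_diffuse < L_dense, L_dense < 1)
  dense <- contour_at_level(norm_dapi, L_dense)
  diffuse <- contour_at_level(norm_dapi, L_diffuse)
  for (d in dense) {
    cen <- colMeans(d$vertices[-nrow(d$vertices), , drop = FALSE])
    inside <- any(vapply(diffuse, function(f)
      point_in_polygon(cen[1], cen[2], f$vertices), logical(1)))
    if (length(diffuse) && !inside)
      stop(sprintf("nesting violated for cell %s: dense contour not inside diffuse region",
                   as.character(cell$id)))
  }
  structure(list(cell_id = cell$id, dense = dense, diffuse = diffuse),
            class = "nucleoid_zones")
}
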