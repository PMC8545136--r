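# Point-in-polygon with boundary counted as inside. vertices: closed or open
# n x 2 matrix.
point_in_polygon <- function(x, y, vertices) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  if (vx[1] == vx[n] && vy[1] == vy[n]) { vx <- vx[-n]; vy <- vy[-n] }
  res <- pracma::inpolygon(x, y, vx, vy, boundary = TRUE)
  as.logical(res)
}

#' Classify a focus relative to the nucleoid zones
#'
#' A focus centroid inside any dense contour is scored NUCLEOID_OVERLAP;
#' otherwise inside any diffuse contour, PERIPHERAL; otherwise NUCLEOID_FREE.
#' Boundary points count as inside. With `mode = "band"` the peripheral class
#' is instead a geometric band of width `band_width` px around the dense
#' contours (an alternative reading of "peripheral regions of genomic DNA").
#'
#' @param focus list or one-row data.frame with numeric `x`, `y` (the
#'   subpixel centroid).
#' @param zones a [nucleoid_zones()] object for the same cell.
#' @param mode `"contour"` (default; peripheral = inside diffuse, outside
#'   dense) or `"band"`.
#' @param band_width band half-width in px for `mode = "band"`.
#' @return one of `"NUCLEOID_OVERLAP"`, `"PERIPHERAL"`, `"NUCLEOID_FREE"`.
#' @export
classify_focus_zone <- function(focus, zones, mode = c("contour", "band"),
                                band_width = 3) {
  mode <- match.arg(mode)
  x <- focus$x; y <- focus$y
  stopifnot(is.numeric(x), is.numeric(y), length(x) == 1)
  if (!length(zones$dense) && !length(zones$diffuse)) {
    warning(sprintf("cell %s has no nucleoid contours; scoring NUCLEOID_FREE",
                    as.character(zones$cell_id)))
    return("NUCLEOID_FREE")
  }
  in_dense <- any(vapply(zones$dense, function(ct)
    point_in_polygon(x, y, ct$vertices), logical(1)))
  if (in_dense) return("NUCLEOID_OVERLAP")
  if (mode == "contour") {
    in_diff <- any(vapply(zones$diffuse, function(ct)
      point_in_polygon(x, y, ct$vertices), logical(1)))
    if (in_diff) return("PERIPHERAL")
    return("NUCLEOID_FREE")
  }
  # band mode: distance from the point to the nearest dense contour edge
  dmin <- Inf
  for (ct in zones$dense)
    dmin <- min(dmin, dist_point_polyline(x, y, ct$vertices))
  if (is.finite(dmin) && dmin <= band_width) "PERIPHERAL" else "NUCLEOID_FREE"
}

dist_point_polyline <- function(x, y, vertices) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  ax <- vx[-n]; ay <- vy[-n]; bx <- vx[-1]; by <- vy[-1]
  ex <- bx - ax; ey <- by - ay
  len2 <- ex^2 + ey^2
  tt <- ifelse(len2 > 0, ((x - ax) * ex + (y - ay) * ey) / len2, 0)
  tt <- pmin(pmax(tt, 0), 1)
  px <- ax + tt * ex; py <- ay + tt * ey
  sqrt(min((x - px)^2 + (y - py)^2))
}

# Convert a contour list to polyclip's format (open rings, CCW).
contours_to_polyclip <- function(contours) {
  lapply(contours, function(ct) {
    v <- ct$vertices
    n <- nrow(v)
    if (v[1, 1] == v[n, 1] && v[1, 2] == v[n, 2]) v <- v[-n, , drop = FALSE]
    if (polygon_area(v[, 1], v[, 2]) < 0) v <- v[rev(seq_len(nrow(v))), ]
    list(x = v[, 1], y = v[, 2])
  })
}

polyclip_area <- function(rings) {
  if (!length(rings)) return(0)
  sum(vapply(rings, function(r) polygon_area(r$x, r$y), numeric(1)))
}

#' Overlap fraction between two contour sets
#'
#' Scores the commonality between two sets of filled contours as
#' `area(A intersect B) / area(A)` by exact polygon clipping, where A is the
#' union of the first argument's polygons (conventionally the red mRNA
#' signal) and B the second's (the blue DNA signal). `denom = "jaccard"`
#' normalizes by the union area instead.
#'
#' @param contoursA,contoursB lists of contours as returned by
#'   [contour_at_level()] (any objects with closed `$vertices` work).
#' @param denom `"first"` (default, area of A) or `"jaccard"`.
#' @return overlap fraction in [0, 1]; NA when area(A) is zero.
#' @export
region_overlap <- function(contoursA, contoursB, denom = c("first", "jaccard")) {
  denom <- match.arg(denom)
  A <- contours_to_polyclip(contoursA)
  B <- contours_to_polyclip(contoursB)
  if (!length(A)) return(NA_real_)
  uA <- if (length(A) > 1) polyclip::polyclip(A, A, "union") else A
  areaA <- polyclip_area(uA)
  if (areaA <= 0) return(NA_real_)
  if (!length(B)) return(0)
  uB <- if (length(B) > 1) polyclip::polyclip(B, B, "union") else B
  inter <- polyclip::polyclip(uA, uB, "intersection")
  ai <- polyclip_area(inter)
  if (denom == "first") return(ai / areaA)
  un <- polyclip::polyclip(uA, uB, "union")
  ai / polyclip_area(un)
}

#' Pair mRNA foci with plasmid foci by distance
#'
#' Greedy nearest-neighbour matching: candidate red-green pairs within
#' `d_adj` are matched in order of increasing centroid distance, each focus
#' used at most once. Matched pairs are labelled COLOCALIZED (distance <=
#' `d_coloc`) or ADJACENT (<= `d_adj`); unmatched red foci are SEPARATE.
#'
#' @param red,green data.frames of foci with numeric columns `x`, `y` (as
#'   produced by [detect_foci()]), from the same cell.
#' @param d_coloc,d_adj distance bands in px, `d_coloc < d_adj`.
#' @return data.frame with one row per red focus: `red_index`, `green_index`
#'   (NA if unmatched), `pair_label`, `distance` (NA for SEPARATE).
#' @export
pair_mrna_plasmid <- function(red, green, d_coloc = 2, d_adj = 8) {
  stopifnot(d_coloc < d_adj)
  nr <- nrow(red); ng <- if (is.null(green)) 0L else nrow(green)
  out <- data.frame(red_index = seq_len(nr), green_index = NA_integer_,
                    pair_label = rep("SEPARATE", nr), distance = NA_real_)
  if (nr == 0 || ng == 0) return(out)
  dmat <- outer(seq_len(nr), seq_len(ng), function(i, j)
    sqrt((red$x[i] - green$x[j])^2 + (red$y[i] - green$y[j])^2))
  cand <- which(dmat <= d_adj, arr.ind = TRUE)
  if (nrow(cand)) {
    ord <- order(dmat[cand])
    used_r <- logical(nr); used_g <- logical(ng)
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_r[i] || used_g[j]) next
      used_r[i] <- TRUE; used_g[j] <- TRUE
      d <- dmat[i, j]
      out$green_index[i] <- j
      out$distance[i] <- d
      out$pair_label[i] <- if (d <= d_coloc) "COLOCALIZED" else "ADJACENT"
    }
  }
  out
}

# Bilinear interpolation at continuous 0-based (x, y); clamped at borders.
bilinear_at <- function(raster, x, y) {
  x <- pmin(pmax(x, 0), ncol(raster) - 1)
  y <- pmin(pmax(y, 0), nrow(raster) - 1)
  x0 <- pmin(floor(x), ncol(raster) - 2); x1 <- x0 + 1
  y0 <- pmin(floor(y), nrow(raster) - 2); y1 <- y0 + 1
  fx <- x - x0; fy <- y - y0
  v00 <- raster[cbind(y0 + 1, x0 + 1)]
  v01 <- raster[cbind(y0 + 1, x1 + 1)]
  v10 <- raster[cbind(y1 + 1, x0 + 1)]
  v11 <- raster[cbind(y1 + 1, x1 + 1)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

#' Arrow-projected intensity profile
#'
#' Samples each channel of a stack along the segment from `p0` to `p1`,
#' averaging bilinear interpolations across the perpendicular width, then
#' normalizes each channel by its own profile maximum -- the relative
#' fluorescence intensity versus pixel distance projected on the arrow.
#'
#' @param stack an [image_stack()] (or a named list of matrices).
#' @param p0,p1 c(x, y) continuous endpoints of the arrow, 0-based.
#' @param width averaging width perpendicular to the arrow, in px (>= 1).
#' @param samples_per_px sampling density along the arrow.
#' @return data.frame with `distance` (px along the arrow, nondecreasing) and
#'   one column of relative intensity per channel.
#' @export
line_profile <- function(stack, p0, p1, width = 1, samples_per_px = 4) {
  channels <- if (inherits(stack, "image_stack")) stack$channels else stack
  stopifnot(is.list(channels), length(p0) == 2, length(p1) == 2, width >= 1)
  dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) stop("zero-length profile segment")
  ux <- dx / len; uy <- dy / len      # along the arrow
  nx <- -uy; ny <- ux                 # perpendicular
  ts <- seq(0, len, length.out = max(2, ceiling(len * samples_per_px) + 1))
  offs <- seq(-(width - 1) / 2, (width - 1) / 2, by = 1)
  out <- data.frame(distance = ts)
  for (ch in names(channels)) {
    vals <- vapply(ts, function(t) {
      px <- p0[1] + t * ux + offs * nx
      py <- p0[2] + t * uy + offs * ny
      mean(bilinear_at(channels[[ch]], px, py))
    }, numeric(1))
    mx <- max(vals)
    out[[ch]] <- if (mx > 0) vals / mx else vals
  }
  out
}
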