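# Independent geometry oracles and fixture builders. These deliberately do
# not call the package's geometry code paths (pracma/polyclip): point-in-
# polygon is a hand-rolled ray cast, areas come from supersampled counting.

# Ray-casting point-in-polygon (even-odd rule). vertices: n x 2, open or
# closed ring.
ray_cast_pip <- function(x, y, vertices) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  if (vx[1] == vx[n] && vy[1] == vy[n]) { vx <- vx[-n]; vy <- vy[-n]; n <- n - 1 }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((vy[i] > y) != (vy[j] > y)) &&
        (x < (vx[j] - vx[i]) * (y - vy[i]) / (vy[j] - vy[i]) + vx[i]))
      inside <- !inside
    j <- i
  }
  inside
}

in_any_polygon <- function(x, y, contours) {
  for (ct in contours) if (ray_cast_pip(x, y, ct$vertices)) return(TRUE)
  FALSE
}

# Supersampled rasterization of area(A intersect B) / area(A) over the joint
# bounding box, grid spacing 1/factor px.
supersample_overlap <- function(contoursA, contoursB, factor = 10) {
  allv <- do.call(rbind, lapply(c(contoursA, contoursB), `[[`, "vertices"))
  xs <- seq(min(allv[, 1]), max(allv[, 1]), by = 1 / factor)
  ys <- seq(min(allv[, 2]), max(allv[, 2]), by = 1 / factor)
  nA <- 0; nAB <- 0
  for (y in ys) for (x in xs) {
    inA <- in_any_polygon(x, y, contoursA)
    if (inA) {
      nA <- nA + 1
      if (in_any_polygon(x, y, contoursB)) nAB <- nAB + 1
    }
  }
  nAB / nA
}

# Supersampled enclosed area of one polygon, px^2.
supersample_area <- function(vertices, factor = 10) {
  xs <- seq(min(vertices[, 1]), max(vertices[, 1]), by = 1 / factor)
  ys <- seq(min(vertices[, 2]), max(vertices[, 2]), by = 1 / factor)
  cnt <- 0
  for (y in ys) for (x in xs) if (ray_cast_pip(x, y, vertices)) cnt <- cnt + 1
  cnt / factor^2
}

# Random star-shaped (hence simple) polygon around a centre.
random_star_polygon <- function(n = 10, cx = 0, cy = 0, rmin = 3, rmax = 8) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  rad <- stats::runif(n, rmin, rmax)
  v <- cbind(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
  structure(list(vertices = rbind(v, v[1, , drop = FALSE]), level = NA,
                 area = abs(tolfish:::polygon_area(v[, 1], v[, 2]))),
            class = "tol_contour")
}

# A rectangle contour (closed ring).
rect_contour <- function(x0, y0, x1, y1) {
  v <- cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y1))
  v[5, ] <- c(x0, y0)
  structure(list(vertices = v, level = NA,
                 area = abs((x1 - x0) * (y1 - y0))),
            class = "tol_contour")
}

# Whole-raster cell region for unit fixtures.
full_cell <- function(H, W, id = 1L) cell_region(id, matrix(TRUE, H, W))

# Gaussian "nucleoid" raster, peak 1 at (cx, cy) (0-based coords).
gauss_raster <- function(H, W, cx, cy, sx, sy = sx) {
  gx <- outer(rep(1, H), 0:(W - 1))
  gy <- outer(0:(H - 1), rep(1, W))
  exp(-((gx - cx)^2 / (2 * sx^2) + (gy - cy)^2 / (2 * sy^2)))
}

# Shared heavy fixture for acceptance checks: 15 default-preset fields with
# independent focus placement, analyzed with default parameters, plus the
# truth-vs-detection matching (<= 1 px).
acceptance_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pp <- preset_params("wt_mxylene", pairing_mix = c(0, 0, 1))
    ap <- analysis_params()
    matches <- list(); truth_all <- list(); det_all <- list()
    tp <- 0; fn <- 0; fp <- 0
    for (s in 1:15) {
      f <- generate_field(pp$params, pp$cond, s)
      res <- analyze_stack(f$stack, ap, mask = f$mask, field_id = s)
      tr <- f$foci[f$foci$channel == "red", ]
      det <- res$records[res$records$channel == "red", ]
      used <- rep(FALSE, nrow(det))
      for (i in seq_len(nrow(tr))) {
        d <- sqrt((det$x - tr$x[i])^2 + (det$y - tr$y[i])^2)
        d[used] <- Inf
        j <- which.min(d)
        if (length(j) && d[j] <= 1) {
          tp <- tp + 1; used[j] <- TRUE
          matches[[length(matches) + 1]] <- data.frame(
            err = d[j], truth_zone = tr$zone[i], est_zone = det$zone[j])
        } else fn <- fn + 1
      }
      fp <- fp + sum(!used)
      tr$field_id <- s
      truth_all[[s]] <- f$foci
      det_all[[s]] <- res$records
      det_all[[s]]$n_cells <- nrow(f$cells)
    }
    cache <<- list(matches = do.call(rbind, matches), tp = tp, fn = fn,
                   fp = fp, truth = do.call(rbind, truth_all),
                   records = do.call(rbind, det_all),
                   n_cells = 15 * 20, w = c(0.01, 0.15, 0.84))
    cache
  }
})
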