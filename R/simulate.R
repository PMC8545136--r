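#' Construct a multi-channel image stack
#'
#' @param channels named list of numeric matrices (identical dimensions,
#'   nonnegative), conventionally `phase`, `dapi`, `red`, `green`.
#' @param pixel_size_um physical pixel size (um/px).
#' @param depth maximum representable intensity.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size_um = 0.065, depth = 65535) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all channels must have identical dimensions")
  if (any(vapply(channels, function(m) any(m < 0), logical(1))))
    stop("channel intensities must be nonnegative")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 depth = depth),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %d x %d px, channels: %s, %.3f um/px\n",
              d[2], d[1], paste(names(x$channels), collapse = ", "),
              x$pixel_size_um))
  invisible(x)
}

# ---- geometry helpers (0-based coordinates, x = column, y = row) ----------

# Pixels of a spherocylindrical cell. Returns 0-based x/y, axial coordinate s,
# transverse coordinate t, all as vectors, restricted to the field.
cell_pixel_coords <- function(pose, nrow_px, ncol_px, margin = 0) {
  half <- pose$length_px / 2 + margin + 1
  xs <- max(0, floor(pose$cx - half)):min(ncol_px - 1, ceiling(pose$cx + half))
  ys <- max(0, floor(pose$cy - half)):min(nrow_px - 1, ceiling(pose$cy + half))
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  dx <- gx - pose$cx
  dy <- gy - pose$cy
  s <- dx * cos(pose$theta) + dy * sin(pose$theta)
  tt <- -dx * sin(pose$theta) + dy * cos(pose$theta)
  a <- pmax(0, pose$length_px / 2 - pose$width_px / 2) # half-length of axis
  sc <- pmin(pmax(s, -a), a)
  d <- sqrt((s - sc)^2 + tt^2) # distance to the axial segment
  keep <- d <= pose$width_px / 2 + margin
  list(x = gx[keep], y = gy[keep], s = s[keep], t = tt[keep])
}

point_in_cell <- function(pose, x, y, margin = 0) {
  dx <- x - pose$cx
  dy <- y - pose$cy
  s <- dx * cos(pose$theta) + dy * sin(pose$theta)
  tt <- -dx * sin(pose$theta) + dy * cos(pose$theta)
  a <- pmax(0, pose$length_px / 2 - pose$width_px / 2)
  sc <- pmin(pmax(s, -a), a)
  sqrt((s - sc)^2 + tt^2) <= pose$width_px / 2 + margin
}

# Unnormalized nucleoid density at local coordinates (s, t) for a cell pose.
nucleoid_density_local <- function(pose, s, t) {
  L <- pose$length_px
  W <- pose$width_px
  frac <- pose$nucleoid_frac
  sig_t <- W / 4
  if (pose$lobes == 1L) {
    sig_s <- frac * L / 4
    exp(-s^2 / (2 * sig_s^2) - t^2 / (2 * sig_t^2))
  } else {
    c0 <- frac * L / 4
    sig_s <- frac * L / 8
    (exp(-(s - c0)^2 / (2 * sig_s^2)) + exp(-(s + c0)^2 / (2 * sig_s^2))) *
      exp(-t^2 / (2 * sig_t^2))
  }
}

# ---- elementary render/noise operations -----------------------------------

#' Render a diffraction-limited spot into a raster
#'
#' Adds an isotropic 2-D Gaussian `amplitude * exp(-r^2 / (2 sigma^2))`
#' centred at a continuous position; the added mass is
#' `amplitude * 2 * pi * sigma^2` up to truncation at a 5-sigma window
#' (< 0.01% lost).
#'
#' @param raster numeric matrix.
#' @param position c(x, y), 0-based continuous coordinates (x = column).
#' @param amplitude peak intensity added at the centre.
#' @param psf_sigma Gaussian SD in pixels.
#' @return the raster with the spot added.
#' @export
render_spot <- function(raster, position, amplitude, psf_sigma) {
  stopifnot(length(position) == 2, psf_sigma > 0)
  x0 <- position[1]
  y0 <- position[2]
  if (x0 < 0 || y0 < 0 || x0 > ncol(raster) - 1 || y0 > nrow(raster) - 1)
    stop("spot position outside raster")
  if (amplitude == 0) return(raster)
  r <- ceiling(5 * psf_sigma)
  xs <- max(0, floor(x0 - r)):min(ncol(raster) - 1, ceiling(x0 + r))
  ys <- max(0, floor(y0 - r)):min(nrow(raster) - 1, ceiling(y0 + r))
  gx <- outer(rep(1, length(ys)), xs)
  gy <- outer(ys, rep(1, length(xs)))
  g <- amplitude * exp(-((gx - x0)^2 + (gy - y0)^2) / (2 * psf_sigma^2))
  raster[ys + 1, xs + 1] <- raster[ys + 1, xs + 1] + g
  raster
}

#' Render dispersed (non-focal) signal over a cell
#'
#' Spreads `total_intensity` across the cell mask as a low-spatial-frequency
#' random field, emulating transcripts that diffuse through the cytoplasm
#' instead of forming discrete foci (the rifampin phenotype). With
#' `heterogeneity = 0` the fill is exactly uniform; larger values modulate the
#' fill with a smoothed noise field of proportional relative amplitude. The
#' rendered total over the cell equals `total_intensity` exactly.
#'
#' @param raster numeric matrix to add signal to.
#' @param cell_mask logical matrix, same shape, TRUE inside the cell.
#' @param total_intensity total intensity to distribute over the cell.
#' @param heterogeneity relative modulation amplitude in [0, 1].
#' @param smooth_sigma spatial scale (px) of the modulation field.
#' @return the raster with the dispersed signal added.
#' @export
render_dispersed <- function(raster, cell_mask, total_intensity,
                             heterogeneity = 0.5, smooth_sigma = 4) {
  stopifnot(identical(dim(raster), dim(cell_mask)),
            heterogeneity >= 0, heterogeneity <= 1)
  n <- sum(cell_mask)
  if (n == 0 || total_intensity <= 0) return(raster)
  field <- rep(1, n)
  if (heterogeneity > 0) {
    noise <- matrix(stats::rnorm(length(raster)), nrow(raster))
    sm <- as.matrix(EBImage::gblur(EBImage::Image(noise), sigma = smooth_sigma))
    v <- sm[cell_mask]
    sdv <- stats::sd(v)
    if (sdv > 0) field <- pmax(0, 1 + heterogeneity * (v - mean(v)) / sdv)
  }
  field <- field * (total_intensity / sum(field))
  raster[cell_mask] <- raster[cell_mask] + field
  raster
}

#' Apply shot and read noise to an image stack
#'
#' Each pixel value v becomes `rpois(v * photon_scale) / photon_scale +
#' rnorm(0, read_sigma)`, clipped to `[0, depth]`. Shot noise therefore has
#' variance v / photon_scale, the Poisson-limited behaviour of a photon
#' detector, and `photon_scale -> Inf` with `read_sigma = 0` recovers the
#' noiseless image.
#'
#' @param stack an [image_stack()] (or a single numeric matrix).
#' @param photon_scale photons per intensity count.
#' @param read_sigma Gaussian read noise SD in counts.
#' @return noisy stack (or matrix) of the same shape.
#' @export
apply_noise <- function(stack, photon_scale = 0.2, read_sigma = 10) {
  if (is.matrix(stack)) return(noisy_raster(stack, photon_scale, read_sigma, Inf))
  stopifnot(inherits(stack, "image_stack"))
  stack$channels <- lapply(stack$channels, noisy_raster,
                           photon_scale = photon_scale,
                           read_sigma = read_sigma, depth = stack$depth)
  stack
}

noisy_raster <- function(m, photon_scale, read_sigma, depth) {
  v <- stats::rpois(length(m), pmax(m, 0) * photon_scale) / photon_scale
  if (read_sigma > 0) v <- v + stats::rnorm(length(m), 0, read_sigma)
  matrix(pmin(pmax(v, 0), depth), nrow(m))
}

# ---- focus placement ------------------------------------------------------

# Per-cell zone pixel sets on a per-cell normalized noiseless density.
# Components smaller than min_px pixels are excluded (a focus "in" a speck
# that contour extraction discards as noise is ill-defined).
zone_pixel_sets <- function(cell_mask, norm_density, L_dense = 0.5,
                            L_diffuse = 0.2, min_px = 3L) {
  zone <- matrix("", nrow(cell_mask), ncol(cell_mask))
  v <- norm_density
  zone[cell_mask & !is.na(v) & v >= L_dense] <- "DENSE"
  zone[cell_mask & !is.na(v) & v >= L_diffuse & v < L_dense] <- "PERIPHERAL"
  zone[cell_mask & (is.na(v) | v < L_diffuse)] <- "FREE"
  out <- list()
  for (z in c("DENSE", "PERIPHERAL", "FREE")) {
    bw <- zone == z & cell_mask
    if (any(bw)) {
      lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
      counts <- table(lab[lab > 0])
      keep <- as.integer(names(counts)[counts >= min_px])
      bw <- matrix(as.matrix(lab) %in% keep, nrow(bw))
    }
    idx <- which(bw, arr.ind = TRUE)
    out[[z]] <- if (nrow(idx)) cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
                else cbind(x = numeric(0), y = numeric(0))
  }
  out
}

#' Sample a focus position from the three-zone mixture
#'
#' Chooses a zone (dense-nucleoid / peripheral / nucleoid-free) categorically
#' with weights `w`, then draws a position uniformly from the pixels of that
#' zone inside the cell. The returned label always matches the zone of the
#' returned position. If the requested zone has no pixels in this cell, the
#' draw falls back to the remaining zones with a warning.
#'
#' @param cell_mask logical matrix, TRUE inside the cell.
#' @param norm_density per-cell normalized noiseless nucleoid density (values
#'   in [0,1] inside the cell; NA allowed outside).
#' @param w numeric c(dense, peripheral, free), nonnegative, summing to 1.
#' @param L_dense,L_diffuse zone thresholds on the normalized density.
#' @return list with `position` (c(x, y), 0-based pixel-centre coordinates)
#'   and `zone` (one of "DENSE", "PERIPHERAL", "FREE").
#' @export
sample_focus_position <- function(cell_mask, norm_density, w,
                                  L_dense = 0.5, L_diffuse = 0.2) {
  stopifnot(abs(sum(w) - 1) <= 1e-9, all(w >= 0), length(w) == 3)
  sets <- zone_pixel_sets(cell_mask, norm_density, L_dense, L_diffuse)
  draw_focus_from_sets(sets, w)
}

draw_focus_from_sets <- function(sets, w) {
  zones <- c("DENSE", "PERIPHERAL", "FREE")
  avail <- vapply(sets, nrow, integer(1)) > 0
  wz <- w
  z <- sample(zones, 1, prob = wz)
  if (!avail[[z]]) {
    warning(sprintf("requested zone %s is empty in this cell; resampling", z))
    wz[!avail] <- 0
    if (sum(wz) == 0) wz <- as.numeric(avail)
    if (sum(wz) == 0) stop("cell has no zone pixels at all")
    z <- sample(zones, 1, prob = wz)
  }
  px <- sets[[z]]
  i <- sample.int(nrow(px), 1)
  list(position = c(x = unname(px[i, "x"]), y = unname(px[i, "y"])), zone = z)
}

zone_at_pixel <- function(norm_density, cell_mask, x, y, L_dense, L_diffuse) {
  v <- norm_density[round(y) + 1, round(x) + 1]
  if (!cell_mask[round(y) + 1, round(x) + 1] || is.na(v)) return("FREE")
  if (v >= L_dense) "DENSE" else if (v >= L_diffuse) "PERIPHERAL" else "FREE"
}

# Number of mRNA foci for one cell given its expression level.
draw_mrna_count <- function(level, genotype, params) {
  if (level == "OFF") return(0L)
  m <- if (genotype == "PUXT7_IN_T7_HOST") params$t7_mean_foci
       else params$mean_mrna_foci
  m <- m * params$foci_multiplier
  if (level == "LOW" && stats::runif(1) > params$low_presence_prob) return(0L)
  if (m <= 2) 1L + stats::rbinom(1, 1, max(0, m - 1))
  else max(1L, stats::rpois(1, m))
}

# ---- field generation -----------------------------------------------------

#' Generate a synthetic multi-channel micrograph field with ground truth
#'
#' Places non-overlapping rod-shaped cells, paints a one- or two-lobed
#' nucleoid per cell, draws plasmid foci (1--2 per cell) and -- according to
#' [expressed_transcripts()] for the given condition -- mRNA foci placed
#' either near a plasmid (colocalized / adjacent, per the pairing mixture) or
#' by the three-zone mixture over the nucleoid density. Channels are rendered
#' with a Gaussian PSF, a faint DAPI contribution at plasmid positions, and
#' Poisson + Gaussian noise. Under rifampin (non-focal expression state) the
#' red signal is rendered dispersed over the cell instead of as spots.
#'
#' The ground-truth zone of every focus is the zone of its pixel on the
#' per-cell normalized noiseless DAPI channel thresholded at
#' `L_dense` / `L_diffuse`, so recovery can be scored exactly.
#'
#' @param params a [sim_params()] object.
#' @param cond a [tol_condition()].
#' @param seed integer RNG seed; identical (params, cond, seed, probe) give
#'   bit-identical output.
#' @param probe which transcript the red FISH probe targets, `"xylUW"` or
#'   `"xylX"`.
#' @return object of class `sim_field`: list with
#'   \describe{
#'     \item{stack}{[image_stack()] with `phase`, `dapi`, `red` (and `green`)
#'       channels, noise applied.}
#'     \item{cells}{data.frame of cell poses (cell_id, cx, cy, theta,
#'       length_px, width_px, lobes, expression mode).}
#'     \item{foci}{data.frame of true foci (cell_id, channel, x, y, zone,
#'       pair_label, amplitude).}
#'     \item{mask}{integer label matrix (the true segmentation).}
#'     \item{noiseless_dapi}{background-free noiseless DAPI channel (nucleoid
#'       plus faint plasmid contribution), for truth-consistency checks.}
#'     \item{expression}{the `expression_state` used.}
#'   }
#' @export
generate_field <- function(params, cond, seed, probe = c("xylUW", "xylX")) {
  stopifnot(inherits(params, "sim_params"), inherits(cond, "tol_condition"))
  probe <- match.arg(probe)
  set.seed(as.integer(seed))
  state <- expressed_transcripts(cond)
  level <- state$levels[[probe]]

  W <- params$field_size[1]
  H <- params$field_size[2]
  px_per_um <- 1 / params$pixel_size_um

  # -- place cells by rejection sampling --
  occupied <- matrix(FALSE, H, W)
  label <- matrix(0L, H, W)
  cells <- list()
  for (i in seq_len(params$n_cells)) {
    placed <- FALSE
    for (try in seq_len(params$max_place_retries)) {
      L <- stats::runif(1, params$cell_length_um[1], params$cell_length_um[2]) * px_per_um
      Wd <- stats::runif(1, params$cell_width_um[1], params$cell_width_um[2]) * px_per_um
      margin <- L / 2 + 3
      if (2 * margin >= min(W, H)) stop("cells do not fit in the field")
      pose <- list(cx = stats::runif(1, margin, W - 1 - margin),
                   cy = stats::runif(1, margin, H - 1 - margin),
                   theta = stats::runif(1, 0, pi),
                   length_px = L, width_px = Wd,
                   nucleoid_frac = params$nucleoid_frac,
                   lobes = sample(1:2, 1, prob = params$lobe_probs))
      pc <- cell_pixel_coords(pose, H, W, margin = 2) # 2 px clearance
      idx <- cbind(pc$y + 1, pc$x + 1)
      if (!any(occupied[idx])) {
        occupied[idx] <- TRUE
        inner <- cell_pixel_coords(pose, H, W)
        label[cbind(inner$y + 1, inner$x + 1)] <- i
        pose$cell_id <- i
        cells[[i]] <- pose
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("failed to place cell %d after %d retries (max_place_retries)",
                   i, params$max_place_retries))
  }

  # -- nucleoid density, per cell normalized to peak 1 --
  nucleoid <- matrix(0, H, W)
  for (pose in cells) {
    pc <- cell_pixel_coords(pose, H, W)
    d <- nucleoid_density_local(pose, pc$s, pc$t)
    d <- d / max(d)
    nucleoid[cbind(pc$y + 1, pc$x + 1)] <- d
  }

  # -- plasmid foci (counts independent of the mRNA channel) --
  plasmids <- list()
  for (pose in cells) {
    cm <- label == pose$cell_id
    nd <- nucleoid # already peak-normalized per cell
    n_g <- sample(1:2, 1, prob = params$plasmid_foci_probs)
    idx <- which(cm, arr.ind = TRUE)
    vals <- nd[cm]
    on_nuc <- vals >= params$L_diffuse
    for (k in seq_len(n_g)) {
      where <- sample(c("nucleoid", "peripheral"), 1,
                      prob = params$plasmid_placement)
      cand <- if (where == "nucleoid") which(on_nuc) else which(!on_nuc)
      if (!length(cand)) cand <- seq_along(vals)
      j <- idx[sample(cand, 1), ]
      plasmids[[length(plasmids) + 1]] <-
        list(cell_id = pose$cell_id, x = j[2] - 1, y = j[1] - 1)
    }
  }

  # -- noiseless DAPI (nucleoid + faint plasmid DNA), defines truth zones --
  noiseless_dapi <- nucleoid * params$nucleoid_peak
  for (pl in plasmids)
    noiseless_dapi <- render_spot(noiseless_dapi, c(pl$x, pl$y),
                                  params$plasmid_dapi_frac * params$nucleoid_peak,
                                  params$psf_sigma)

  # -- red mRNA foci --
  foci <- list()
  dispersed_cells <- integer(0)
  dispersed_totals <- numeric(0)
  for (pose in cells) {
    cm <- label == pose$cell_id
    norm_dens <- normalize_channel(noiseless_dapi, list(mask = cm))
    n_r <- draw_mrna_count(level, cond$genotype, params)
    amp_factor <- if (level == "LOW") 0.5 else 1
    cell_plasmids <- Filter(function(p) p$cell_id == pose$cell_id, plasmids)
    if (n_r > 0 && !state$focal) {
      # rifampin: the same transcriptional output, spread over the cell
      dispersed_cells <- c(dispersed_cells, pose$cell_id)
      dispersed_totals <- c(dispersed_totals,
        n_r * amp_factor * params$mrna_amplitude * 2 * pi * params$psf_sigma^2)
      next
    }
    if (n_r == 0) next
    sets <- zone_pixel_sets(cm, norm_dens, params$L_dense, params$L_diffuse)
    # each paired transcript consumes a distinct plasmid anchor: one-to-one
    # matching cannot recover two transcripts tethered to the same locus
    free_anchors <- if (length(cell_plasmids))
      sample.int(length(cell_plasmids)) else integer(0)
    for (k in seq_len(n_r)) {
      lab <- sample(c("COLOCALIZED", "ADJACENT", "INDEPENDENT"), 1,
                    prob = params$pairing_mix)
      pos <- NULL
      if (lab != "INDEPENDENT" && length(free_anchors)) {
        anchor <- cell_plasmids[[free_anchors[1]]]
        pos <- place_paired(anchor, lab, pose, cm, params)
        if (!is.null(pos)) free_anchors <- free_anchors[-1]
      }
      if (is.null(pos)) { # independent, anchors exhausted, or no room
        dr <- draw_focus_from_sets(sets, params$zone_weights)
        pos <- dr$position
        lab <- "INDEPENDENT"
      }
      zone <- zone_at_pixel(norm_dens, cm, pos[1], pos[2],
                            params$L_dense, params$L_diffuse)
      foci[[length(foci) + 1]] <- data.frame(
        cell_id = pose$cell_id, channel = "red",
        x = unname(pos[1]), y = unname(pos[2]), zone = zone,
        pair_label = lab,
        amplitude = amp_factor * params$mrna_amplitude)
    }
  }
  for (pl in plasmids) {
    cm <- label == pl$cell_id
    norm_dens <- normalize_channel(noiseless_dapi, list(mask = cm))
    foci[[length(foci) + 1]] <- data.frame(
      cell_id = pl$cell_id, channel = "green", x = pl$x, y = pl$y,
      zone = zone_at_pixel(norm_dens, cm, pl$x, pl$y,
                           params$L_dense, params$L_diffuse),
      pair_label = NA_character_, amplitude = params$plasmid_amplitude)
  }
  foci <- if (length(foci)) do.call(rbind, foci)
          else data.frame(cell_id = integer(0), channel = character(0),
                          x = numeric(0), y = numeric(0), zone = character(0),
                          pair_label = character(0), amplitude = numeric(0))

  # -- render channels --
  bg <- params$background
  dapi <- noiseless_dapi + bg
  red <- matrix(bg, H, W)
  rf <- foci[foci$channel == "red", , drop = FALSE]
  for (k in seq_len(nrow(rf)))
    red <- render_spot(red, c(rf$x[k], rf$y[k]), rf$amplitude[k], params$psf_sigma)
  for (k in seq_along(dispersed_cells))
    red <- render_dispersed(red, label == dispersed_cells[k], dispersed_totals[k],
                            params$dispersed_heterogeneity,
                            smooth_sigma = 4)
  green <- NULL
  if (params$green_channel) {
    green <- matrix(bg, H, W)
    gf <- foci[foci$channel == "green", , drop = FALSE]
    for (k in seq_len(nrow(gf)))
      green <- render_spot(green, c(gf$x[k], gf$y[k]), gf$amplitude[k],
                           params$psf_sigma)
  }
  phase <- matrix(3000, H, W)
  phase[label > 0] <- 800
  phase <- as.matrix(EBImage::gblur(EBImage::Image(phase), sigma = 1))

  chans <- list(phase = phase, dapi = dapi, red = red)
  if (!is.null(green)) chans$green <- green
  stack <- image_stack(chans, params$pixel_size_um, params$depth)
  stack <- apply_noise(stack, params$photon_scale, params$read_sigma)

  cells_df <- do.call(rbind, lapply(cells, function(p)
    data.frame(cell_id = p$cell_id, cx = p$cx, cy = p$cy, theta = p$theta,
               length_px = p$length_px, width_px = p$width_px,
               lobes = p$lobes,
               mode = if (p$cell_id %in% dispersed_cells) "DISPERSED"
                      else if (any(foci$cell_id == p$cell_id &
                                   foci$channel == "red")) "FOCAL"
                      else "NO_SIGNAL")))

  structure(list(stack = stack, cells = cells_df, foci = foci, mask = label,
                 noiseless_dapi = noiseless_dapi, expression = state,
                 params = params, cond = cond, seed = as.integer(seed),
                 probe = probe),
            class = "sim_field")
}

# Place a paired red focus at a pixel centre near its anchor plasmid.
# COLOCALIZED: the anchor pixel or an in-cell 4-neighbour (distance <= 1 px).
# ADJACENT: the in-cell pixel nearest to anchor + offset in a random
# direction (several directions tried). Returns NULL when impossible.
place_paired <- function(anchor, lab, pose, cell_mask, params) {
  H <- nrow(cell_mask); W <- ncol(cell_mask)
  if (lab == "COLOCALIZED") {
    cand <- rbind(c(anchor$x, anchor$y),
                  c(anchor$x + 1, anchor$y), c(anchor$x - 1, anchor$y),
                  c(anchor$x, anchor$y + 1), c(anchor$x, anchor$y - 1))
    cand <- cand[cand[, 1] >= 0 & cand[, 1] < W &
                 cand[, 2] >= 0 & cand[, 2] < H, , drop = FALSE]
    ok <- cell_mask[cbind(cand[, 2] + 1, cand[, 1] + 1)]
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    i <- sample.int(nrow(cand), 1)
    return(c(x = cand[i, 1], y = cand[i, 2]))
  }
  for (try in 1:24) {
    ang <- stats::runif(1, 0, 2 * pi)
    x <- round(anchor$x + params$adjacency_offset_px * cos(ang))
    y <- round(anchor$y + params$adjacency_offset_px * sin(ang))
    if (x < 0 || y < 0 || x >= W || y >= H) next
    if (!cell_mask[y + 1, x + 1]) next
    d <- sqrt((x - anchor$x)^2 + (y - anchor$y)^2)
    if (d > 2 && d <= params$adjacency_offset_px + 2) return(c(x = x, y = y))
  }
  NULL
}
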