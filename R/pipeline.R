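#' Analysis parameters
#'
#' Settings of the image-analysis half of the pipeline (segmentation,
#' nucleoid contouring, detection, zoning, pairing, dispersion scoring).
#'
#' @param L_dense,L_diffuse nucleoid iso-levels on the per-cell normalized
#'   DAPI channel.
#' @param dapi_smooth_sigma Gaussian pre-smoothing of the DAPI channel (px)
#'   before normalization and contouring; 0 disables. Light smoothing (0.5)
#'   suppresses shot-noise contour jitter; heavier smoothing flattens the
#'   nucleoid peak and, after min-max normalization, systematically inflates
#'   the iso-contours.
#' @param detection a [detection_params()].
#' @param segment a [segment_params()].
#' @param d_coloc,d_adj mRNA-plasmid pairing distance bands (px).
#' @param disc_radius dispersion-index disc radius (px; 3x the PSF sigma).
#' @param t_focal focal-fraction threshold of [dispersion_index()].
#' @param contrast_k per-cell signal gate: a channel is considered present in
#'   a cell only when its smoothed raw in-cell contrast (max - median)
#'   exceeds `contrast_k` robust noise SDs estimated from the field
#'   background. Per-cell min-max normalization otherwise stretches pure
#'   noise to [0, 1].
#' @param peripheral_mode `"contour"` or `"band"` (see
#'   [classify_focus_zone()]).
#' @param band_width band half-width (px) for `peripheral_mode = "band"`.
#' @param normalize_scope `"cell"` (default) or `"field"` min-max scope.
#' @param denominator foci-per-cell denominator rule for [summarize_foci()].
#' @return list of class `analysis_params`.
#' @export
analysis_params <- function(L_dense = 0.5, L_diffuse = 0.2,
                            dapi_smooth_sigma = 0.5,
                            detection = detection_params(),
                            segment = segment_params(),
                            d_coloc = 2, d_adj = 8,
                            disc_radius = 4.5, t_focal = 0.5,
                            contrast_k = 5,
                            peripheral_mode = c("contour", "band"),
                            band_width = 3,
                            normalize_scope = c("cell", "field"),
                            denominator = c("all_cells", "cells_with_foci")) {
  peripheral_mode <- match.arg(peripheral_mode)
  normalize_scope <- match.arg(normalize_scope)
  denominator <- match.arg(denominator)
  structure(as.list(environment()), class = "analysis_params")
}

# Robust background noise SD of a raster from non-cell pixels.
estimate_noise_sd <- function(raster, cell_masks) {
  bg <- matrix(TRUE, nrow(raster), ncol(raster))
  for (m in cell_masks) bg <- bg & !m
  v <- raster[bg]
  if (length(v) < 50) v <- as.vector(raster)
  stats::mad(v)
}

#' Analyze a multi-channel stack into per-focus records
#'
#' The full single-field analysis: segment cells (phase contrast or supplied
#' mask), extract dual-level nucleoid contours from the per-cell normalized
#' (optionally pre-smoothed) DAPI channel, gate each fluorescence channel on
#' raw in-cell contrast, detect and refine foci, classify red foci into the
#' three nucleoid zones, pair red with green foci, and score focal versus
#' dispersed signal per cell.
#'
#' @param stack an [image_stack()] with `dapi` and `red` channels (`phase`
#'   and `green` optional).
#' @param params an [analysis_params()].
#' @param mask optional integer label matrix forwarded to [segment_cells()].
#' @param field_id identifier recorded in the output tables.
#' @return list with
#'   \describe{
#'     \item{cells}{data.frame: field_id, cell_id, area, pattern (red-channel
#'       dispersion pattern).}
#'     \item{records}{per-focus data.frame: field_id, cell_id, channel, x, y,
#'       peak, integrated, zone, pair_label, pair_distance.}
#'     \item{dispersion}{data.frame: field_id, cell_id, channel,
#'       focal_fraction, pattern.}
#'     \item{zones}{list of [nucleoid_zones()] per cell.}
#'   }
#' @export
analyze_stack <- function(stack, params = analysis_params(), mask = NULL,
                          field_id = 1L) {
  stopifnot(inherits(stack, "image_stack"),
            all(c("dapi", "red") %in% names(stack$channels)))
  ch <- stack$channels
  cells <- if (!is.null(mask)) segment_cells(NULL, params$segment, mask = mask)
           else segment_cells(ch$phase, params$segment)
  if (!length(cells))
    return(list(cells = data.frame(), records = data.frame(),
                dispersion = data.frame(), zones = list()))
  masks <- lapply(cells, `[[`, "mask")

  dapi <- ch$dapi
  if (params$dapi_smooth_sigma > 0)
    dapi <- as.matrix(EBImage::gblur(EBImage::Image(dapi),
                                     sigma = params$dapi_smooth_sigma))
  fluor <- intersect(c("red", "green"), names(ch))
  noise_sd <- lapply(ch[fluor], estimate_noise_sd, cell_masks = masks)
  smoothed <- lapply(ch[fluor], function(m)
    as.matrix(EBImage::gblur(EBImage::Image(m), sigma = 1.5)))
  smoothed_noise_sd <- lapply(smoothed, estimate_noise_sd, cell_masks = masks)

  field_norm <- NULL
  if (params$normalize_scope == "field") {
    field_norm <- lapply(ch, function(m) {
      r <- range(m); if (diff(r) == 0) m * 0 else (m - r[1]) / diff(r)
    })
  }

  records <- list(); disp <- list(); zone_list <- list(); cell_rows <- list()
  for (cell in cells) {
    norm_dapi <- if (is.null(field_norm)) normalize_channel(dapi, cell) else {
      v <- field_norm$dapi; v[!cell$mask] <- NA; v
    }
    zones <- nucleoid_zones(norm_dapi, cell, params$L_dense, params$L_diffuse)
    zone_list[[length(zone_list) + 1]] <- zones

    foci_by_ch <- list()
    for (cn in fluor) {
      raw <- ch[[cn]]
      sm <- smoothed[[cn]]
      contrast <- max(sm[cell$mask]) - stats::median(sm[cell$mask])
      present <- contrast > params$contrast_k * smoothed_noise_sd[[cn]]
      if (!present) {
        foci_by_ch[[cn]] <- empty_foci()
        if (cn == "red")
          disp[[length(disp) + 1]] <- data.frame(
            field_id = field_id, cell_id = cell$id, channel = cn,
            focal_fraction = 0, pattern = "NO_SIGNAL")
        next
      }
      nr <- if (is.null(field_norm))
        normalize_channel(raw, cell, keep_outside = TRUE)
        else field_norm[[cn]]
      f <- detect_foci(nr, cell, params$detection)
      foci_by_ch[[cn]] <- f
      if (cn == "red") {
        d <- dispersion_index(nr, cell, f, params$disc_radius, params$t_focal)
        disp[[length(disp) + 1]] <- data.frame(
          field_id = field_id, cell_id = cell$id, channel = cn,
          focal_fraction = d$focal_fraction, pattern = d$pattern)
      }
    }

    red <- foci_by_ch$red
    green <- foci_by_ch$green
    pairs <- if (!is.null(red) && nrow(red))
      pair_mrna_plasmid(red, green, params$d_coloc, params$d_adj) else NULL
    for (cn in fluor) {
      f <- foci_by_ch[[cn]]
      if (is.null(f) || !nrow(f)) next
      zn <- vapply(seq_len(nrow(f)), function(i)
        classify_focus_zone(f[i, ], zones, params$peripheral_mode,
                            params$band_width), character(1))
      rec <- data.frame(field_id = field_id, cell_id = cell$id, channel = cn,
                        x = f$x, y = f$y, peak = f$peak,
                        integrated = f$integrated, zone = zn,
                        pair_label = NA_character_, pair_distance = NA_real_)
      if (cn == "red" && !is.null(pairs)) {
        rec$pair_label <- pairs$pair_label
        rec$pair_distance <- pairs$distance
      }
      records[[length(records) + 1]] <- rec
    }
    red_pat <- if (length(disp)) disp[[length(disp)]]$pattern else NA_character_
    cell_rows[[length(cell_rows) + 1]] <-
      data.frame(field_id = field_id, cell_id = cell$id, area = cell$area,
                 pattern = red_pat)
  }
  bind_or_empty <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  list(cells = bind_or_empty(cell_rows,
         data.frame(field_id = integer(0), cell_id = integer(0),
                    area = numeric(0), pattern = character(0))),
       records = bind_or_empty(records,
         data.frame(field_id = integer(0), cell_id = integer(0),
                    channel = character(0), x = numeric(0), y = numeric(0),
                    peak = numeric(0), integrated = numeric(0),
                    zone = character(0), pair_label = character(0),
                    pair_distance = numeric(0))),
       dispersion = bind_or_empty(disp,
         data.frame(field_id = integer(0), cell_id = integer(0),
                    channel = character(0), focal_fraction = numeric(0),
                    pattern = character(0))),
       zones = zone_list)
}

# ---- config and orchestration ---------------------------------------------

default_config <- function() {
  list(mode = "simulate", seed = 1L, n_fields = 1L, probe = "xylUW",
       condition = list(genotype = "WT_pWW0", inducer = "M_XYLENE",
                        iptg = FALSE, rifampin = FALSE),
       sim = list(), analysis = list(),
       input = NULL, mask = NULL,
       n_boot = 1000L, write_tiff = FALSE)
}

validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(base, config)
  stopifnot(cfg$mode %in% c("simulate", "analyze"),
            is.numeric(cfg$seed), cfg$n_fields >= 1,
            cfg$probe %in% c("xylUW", "xylX"))
  if (cfg$mode == "analyze" && is.null(cfg$input))
    stop("analyze mode requires config$input (a TIFF path)")
  bad_sim <- setdiff(names(cfg$sim), names(formals(sim_params)))
  if (length(bad_sim))
    stop("unknown sim parameter(s): ", paste(bad_sim, collapse = ", "))
  bad_an <- setdiff(names(cfg$analysis), names(formals(analysis_params)))
  if (length(bad_an))
    stop("unknown analysis parameter(s): ", paste(bad_an, collapse = ", "))
  cfg
}

#' Run the full pipeline from a config
#'
#' Orchestrates simulate (optional) -> segment -> detect -> zone/pair ->
#' summarize, writing CSV tables and a JSON manifest to `out_dir`. The run
#' is deterministic for a fixed config: per-field seeds are derived from
#' `config$seed`, and repeated runs produce byte-identical outputs.
#'
#' Config keys (YAML file or list): `mode` ("simulate" or "analyze"),
#' `seed`, `n_fields`, `probe`, `condition` (genotype/inducer/iptg/rifampin),
#' `sim` (overrides for [sim_params()]), `analysis` (overrides for
#' [analysis_params()]), `input`/`mask` (TIFF paths for analyze mode),
#' `n_boot`, `write_tiff`.
#'
#' @param config list, or path to a YAML config file.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with `records`, `cells`, `dispersion`,
#'   `summary`, `truth` (simulate mode) and the paths written.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("tolfish_run_")) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aparams <- do.call(analysis_params, cfg$analysis)

  all_records <- list(); all_cells <- list(); all_disp <- list()
  truth <- list()
  if (cfg$mode == "simulate") {
    sparams <- do.call(sim_params, cfg$sim)
    cond <- do.call(tol_condition, cfg$condition)
    for (f in seq_len(cfg$n_fields)) {
      fseed <- (as.integer(cfg$seed) + 7919L * (f - 1L)) %% 2147483647L
      field <- generate_field(sparams, cond, fseed, probe = cfg$probe)
      res <- analyze_stack(field$stack, aparams, mask = field$mask,
                           field_id = f)
      all_records[[f]] <- res$records
      all_cells[[f]] <- res$cells
      all_disp[[f]] <- res$dispersion
      tf <- field$foci
      if (nrow(tf)) tf$field_id <- f
      truth[[f]] <- tf
      if (isTRUE(cfg$write_tiff))
        write_stack_tiff(field$stack,
                         file.path(out_dir, sprintf("field_%03d.tif", f)))
    }
  } else {
    stack <- read_stack_tiff(cfg$input)
    mask <- if (!is.null(cfg$mask)) read_mask_tiff(cfg$mask) else NULL
    res <- analyze_stack(stack, aparams, mask = mask, field_id = 1L)
    all_records[[1]] <- res$records
    all_cells[[1]] <- res$cells
    all_disp[[1]] <- res$dispersion
  }
  records <- do.call(rbind, all_records)
  cells <- do.call(rbind, all_cells)
  dispersion <- do.call(rbind, all_disp)
  # unique cell key across fields
  if (nrow(cells)) cells$cell_id <- cells$field_id * 100000L + cells$cell_id
  if (nrow(records)) records$cell_id <- records$field_id * 100000L + records$cell_id

  summ <- if (nrow(records))
    summarize_foci(records, cells, n_boot = cfg$n_boot,
                   seed = as.integer(cfg$seed),
                   denominator = aparams$denominator) else list()
  summary_df <- summary_to_long(summ)

  paths <- c(records = file.path(out_dir, "focus_records.csv"),
             cells = file.path(out_dir, "cells.csv"),
             dispersion = file.path(out_dir, "dispersion.csv"),
             summary = file.path(out_dir, "summary.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(records, paths["records"], row.names = FALSE)
  utils::write.csv(cells, paths["cells"], row.names = FALSE)
  utils::write.csv(dispersion, paths["dispersion"], row.names = FALSE)
  utils::write.csv(summary_df, paths["summary"], row.names = FALSE)
  if (length(truth)) {
    tr <- do.call(rbind, truth)
    utils::write.csv(tr, file.path(out_dir, "truth_foci.csv"),
                     row.names = FALSE)
  }
  manifest <- list(package = "tolfish",
                   version = as.character(utils::packageVersion("tolfish")),
                   config = cfg[setdiff(names(cfg), c("sim", "analysis"))],
                   sim_overrides = cfg$sim, analysis_overrides = cfg$analysis)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(records = records, cells = cells, dispersion = dispersion,
                 summary = summ, summary_df = summary_df,
                 truth = if (length(truth)) do.call(rbind, truth) else NULL,
                 paths = paths, out_dir = out_dir))
}

# Long-format (group x statistic) summary table.
summary_to_long <- function(summ) {
  rows <- list()
  for (s in summ) {
    add <- function(stat, value)
      rows[[length(rows) + 1]] <<- data.frame(group = s$group, statistic = stat,
                                              value = value)
    add("n_cells", s$n_cells)
    add("n_foci", s$n_foci)
    add("foci_per_cell_mean", unname(s$foci_per_cell["mean"]))
    add("foci_per_cell_lo", unname(s$foci_per_cell["lo"]))
    add("foci_per_cell_hi", unname(s$foci_per_cell["hi"]))
    for (z in names(s$zone_fractions))
      add(paste0("zone_frac_", z), unname(s$zone_fractions[z]))
    if (!is.null(s$pair_fractions))
      for (p in names(s$pair_fractions))
        add(paste0("pair_frac_", p), unname(s$pair_fractions[p]))
    if (!is.na(s$dispersed_fraction))
      add("dispersed_cell_fraction", s$dispersed_fraction)
  }
  if (!length(rows))
    return(data.frame(group = character(0), statistic = character(0),
                      value = numeric(0)))
  do.call(rbind, rows)
}

# ---- TIFF I/O -------------------------------------------------------------

#' Write an image stack as a multi-page TIFF
#'
#' One 16-bit page per channel, in the stack's channel order. Baseline TIFF
#' has no portable per-page naming, so channel names, pixel size and depth
#' are recorded in a JSON sidecar (`<path>.json`) that [read_stack_tiff()]
#' picks up automatically.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(stack$channels, function(m)
    pmin(pmax(m / stack$depth, 0), 1))
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(list(channels = names(stack$channels),
                            pixel_size_um = stack$pixel_size_um,
                            depth = stack$depth),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page channel TIFF
#'
#' Reads a stack written by [write_stack_tiff()] (channel names from the
#' JSON sidecar). For foreign TIFFs without a sidecar, pages are assumed to
#' follow the conventional order: `dapi, red` for 2 pages, `phase, dapi,
#' red` for 3, `phase, dapi, red, green` for 4; other page counts are named
#' page1, page2, ...
#'
#' @param path TIFF path.
#' @return an [image_stack()].
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  depth <- 65535
  px <- 0.065
  nms <- switch(as.character(length(pages)),
                "2" = c("dapi", "red"),
                "3" = c("phase", "dapi", "red"),
                "4" = c("phase", "dapi", "red", "green"),
                paste0("page", seq_along(pages)))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (length(meta$channels) == length(pages)) nms <- meta$channels
    if (!is.null(meta$pixel_size_um)) px <- meta$pixel_size_um
    if (!is.null(meta$depth)) depth <- meta$depth
  }
  channels <- lapply(pages, function(m) {
    attributes(m) <- list(dim = dim(m))
    m * depth
  })
  names(channels) <- nms
  image_stack(channels, pixel_size_um = px, depth = depth)
}

read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  attributes(m) <- list(dim = dim(m))
  matrix(as.integer(round(m)), nrow(m))
}
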