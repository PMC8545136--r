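#' Export a simulated field to disk
#'
#' Writes the multi-page channel TIFF, ground-truth foci and cell tables
#' (CSV), and a JSON run manifest containing the full parameter set and seed.
#'
#' @param field a `sim_field` from [generate_field()].
#' @param dir output directory (created if missing).
#' @param basename file stem for the outputs.
#' @return invisibly, named character vector of the written paths.
#' @export
write_field <- function(field, dir, basename = "field") {
  stopifnot(inherits(field, "sim_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tiff = file.path(dir, paste0(basename, ".tif")),
    mask = file.path(dir, paste0(basename, "_mask.tif")),
    foci = file.path(dir, paste0(basename, "_truth_foci.csv")),
    cells = file.path(dir, paste0(basename, "_cells.csv")),
    manifest = file.path(dir, paste0(basename, "_manifest.json")))
  write_stack_tiff(field$stack, paths["tiff"])
  tiff::writeTIFF(field$mask / 65535, paths["mask"], bits.per.sample = 16L)
  utils::write.csv(field$foci, paths["foci"], row.names = FALSE)
  utils::write.csv(field$cells, paths["cells"], row.names = FALSE)
  manifest <- list(package = "tolfish",
                   version = as.character(utils::packageVersion("tolfish")),
                   seed = field$seed, probe = field$probe,
                   condition = unclass(field$cond),
                   expression = list(levels = as.list(field$expression$levels),
                                     focal = field$expression$focal),
                   params = unclass(field$params))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(paths)
}

#' Export nucleoid contours as GeoJSON
#'
#' One FeatureCollection per field: each contour becomes a Polygon feature
#' with `cell_id`, `level` and `kind` ("dense" or "diffuse") properties.
#' Coordinates are in the package's 0-based pixel frame.
#'
#' @param zones_list list of [nucleoid_zones()] objects.
#' @param path output .geojson path.
#' @return invisibly, the path.
#' @export
write_zones_geojson <- function(zones_list, path) {
  features <- list()
  for (z in zones_list) {
    for (kind in c("dense", "diffuse")) {
      for (ct in z[[kind]]) {
        coords <- lapply(seq_len(nrow(ct$vertices)), function(i)
          c(ct$vertices[i, 1], ct$vertices[i, 2]))
        features[[length(features) + 1]] <- list(
          type = "Feature",
          properties = list(cell_id = z$cell_id, level = ct$level,
                            kind = kind, area_px2 = ct$area),
          geometry = list(type = "Polygon", coordinates = list(coords)))
      }
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
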