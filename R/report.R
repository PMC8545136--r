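#' Summarize a focus-record table into per-group statistics
#'
#' Groups the per-focus record table (one row per detected focus, with zone
#' and pairing labels) and computes the summary statistics of the imaging
#' experiments: cells, foci, foci per cell with a bootstrap CI, zone
#' fractions (dense overlap / peripheral / free) with bootstrap CIs, pairing
#' fractions, and the dispersed-cell fraction. Bootstrap resamples cells
#' (the independent experimental units), not foci.
#'
#' @param records data.frame with at least `cell_id`, `channel`, `zone`,
#'   `pair_label`; a `group` column (condition label) is used when present.
#' @param cells data.frame of all segmented cells with `cell_id` (and
#'   optional `group`); defines the foci-per-cell denominator when
#'   `denominator = "all_cells"`.
#' @param group_by column names of `records` to group by (default
#'   channel, plus group when present).
#' @param n_boot bootstrap replicate count.
#' @param seed RNG seed for reproducible CIs.
#' @param conf confidence level.
#' @param denominator `"all_cells"` (every segmented cell counts) or
#'   `"cells_with_foci"`.
#' @return list of `summary_stats` objects, one per nonempty group. Each has
#'   `group`, `n_cells`, `n_foci`, `foci_per_cell` (mean, lo, hi),
#'   `zone_fractions` (3-vector summing to 1) with `zone_ci` (2x3),
#'   `pair_fractions`, `dispersed_fraction`, and `per_cell_counts` (the
#'   per-cell focus counts underlying the bootstrap).
#' @export
summarize_foci <- function(records, cells, group_by = NULL, n_boot = 1000,
                           seed = 1, conf = 0.95,
                           denominator = c("all_cells", "cells_with_foci")) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("cell_id", "channel", "zone") %in% names(records)))
  if (is.null(group_by))
    group_by <- intersect(c("group", "channel"), names(records))
  key <- if (length(group_by))
    interaction(records[group_by], drop = TRUE, sep = "|") else
    factor(rep("all", nrow(records)))
  groups <- levels(key)
  out <- list()
  for (g in groups) {
    rec <- records[key == g, , drop = FALSE]
    if (!nrow(rec)) {
      warning(sprintf("group %s is empty; omitted", g))
      next
    }
    cell_pool <- if ("group" %in% names(cells) && "group" %in% group_by) {
      gparts <- strsplit(g, "|", fixed = TRUE)[[1]]
      glab <- gparts[match("group", group_by)]
      cells[cells$group == glab, , drop = FALSE]
    } else cells
    ids <- if (denominator == "all_cells") unique(cell_pool$cell_id)
           else unique(rec$cell_id)
    counts <- as.integer(table(factor(rec$cell_id, levels = ids)))
    zones <- c(NUCLEOID_OVERLAP = sum(rec$zone == "NUCLEOID_OVERLAP"),
               PERIPHERAL = sum(rec$zone == "PERIPHERAL"),
               NUCLEOID_FREE = sum(rec$zone == "NUCLEOID_FREE"))
    zf <- zones / sum(zones)
    pairs <- if ("pair_label" %in% names(rec)) {
      pl <- rec$pair_label[!is.na(rec$pair_label)]
      if (length(pl)) prop.table(table(factor(pl,
        levels = c("COLOCALIZED", "ADJACENT", "SEPARATE")))) else NULL
    } else NULL
    disp_frac <- if ("pattern" %in% names(cell_pool))
      mean(cell_pool$pattern == "DISPERSED", na.rm = TRUE) else NA_real_

    # bootstrap over cells
    set.seed(seed)
    alpha <- (1 - conf) / 2
    nb <- n_boot
    boot_mean <- numeric(nb)
    boot_zone <- matrix(NA_real_, nb, 3)
    zlev <- c("NUCLEOID_OVERLAP", "PERIPHERAL", "NUCLEOID_FREE")
    counts_by_id <- stats::setNames(counts, as.character(ids))
    zone_by_id <- lapply(split(factor(rec$zone, levels = zlev), rec$cell_id),
                         tabulate, nbins = 3)
    for (b in seq_len(nb)) {
      pick <- as.character(sample(ids, length(ids), replace = TRUE))
      boot_mean[b] <- mean(counts_by_id[pick])
      zl <- zone_by_id[pick]
      zl <- zl[!vapply(zl, is.null, logical(1))]
      zcount <- if (length(zl)) Reduce(`+`, zl) else c(0, 0, 0)
      if (sum(zcount)) boot_zone[b, ] <- zcount / sum(zcount)
    }
    zci <- apply(boot_zone, 2, stats::quantile,
                 probs = c(alpha, 1 - alpha), na.rm = TRUE)
    colnames(zci) <- zlev
    out[[g]] <- structure(list(
      group = g, n_cells = length(ids), n_foci = nrow(rec),
      foci_per_cell = c(mean = mean(counts),
                        lo = unname(stats::quantile(boot_mean, alpha)),
                        hi = unname(stats::quantile(boot_mean, 1 - alpha))),
      zone_fractions = zf, zone_ci = zci,
      pair_fractions = pairs, dispersed_fraction = disp_frac,
      per_cell_counts = stats::setNames(counts, ids)),
      class = "summary_stats")
  }
  out
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> %s: %d cells, %d foci, %.3f foci/cell [%.3f, %.3f]\n",
              x$group, x$n_cells, x$n_foci, x$foci_per_cell["mean"],
              x$foci_per_cell["lo"], x$foci_per_cell["hi"]))
  cat(sprintf("  zones: overlap %.1f%%, peripheral %.1f%%, free %.1f%%\n",
              100 * x$zone_fractions[1], 100 * x$zone_fractions[2],
              100 * x$zone_fractions[3]))
  invisible(x)
}

#' Compare foci-per-cell means between two conditions
#'
#' Percentage change of the foci-per-cell mean of `b` relative to `a`, with
#' a bootstrap CI of the change obtained by resampling cells independently
#' within each condition.
#'
#' @param a,b `summary_stats` objects (same channel).
#' @param n_boot bootstrap replicate count.
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return list with `mean_a`, `mean_b`, `pct_change` and `ci` (2-vector);
#'   `pct_change` is NA when the baseline mean is zero.
#' @export
compare_conditions <- function(a, b, n_boot = 1000, seed = 1, conf = 0.95) {
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  ma <- unname(a$foci_per_cell["mean"])
  mb <- unname(b$foci_per_cell["mean"])
  if (ma == 0)
    return(list(mean_a = ma, mean_b = mb, pct_change = NA_real_,
                ci = c(NA_real_, NA_real_)))
  set.seed(seed)
  ca <- a$per_cell_counts
  cb <- b$per_cell_counts
  boot <- vapply(seq_len(n_boot), function(i) {
    xa <- mean(sample(ca, length(ca), replace = TRUE))
    xb <- mean(sample(cb, length(cb), replace = TRUE))
    if (xa == 0) NA_real_ else 100 * (xb - xa) / xa
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(mean_a = ma, mean_b = mb, pct_change = 100 * (mb - ma) / ma,
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE)))
}

#' Parse and validate a FISH probe manifest
#'
#' Reads a comma- or tab-separated table with header columns `probe_id`,
#' `sequence`, `fluorophore`, `target` and validates each sequence against
#' the nucleotide alphabet (A/C/G/T/U, case-insensitive; stored uppercase).
#' Probe length is computed from the sequence.
#'
#' @param input path to the manifest file, or a character vector of its
#'   lines.
#' @return data.frame with columns `probe_id`, `sequence`, `fluorophore`,
#'   `target`, `length`.
#' @export
parse_probe_manifest <- function(input) {
  lines <- if (length(input) == 1 && file.exists(input)) readLines(input)
           else input
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("probe_id", "sequence", "fluorophore", "target")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  df$sequence <- toupper(trimws(as.character(df$sequence)))
  for (i in seq_len(nrow(df))) {
    s <- df$sequence[i]
    if (is.na(s) || !nzchar(s)) stop(sprintf("row %d: empty sequence", i))
    bad <- regmatches(s, regexpr("[^ACGTU]", s))
    if (length(bad) && nzchar(bad))
      stop(sprintf("row %d: invalid nucleotide '%s' in sequence", i, bad))
  }
  df$length <- nchar(df$sequence)
  df[c(need, "length")]
}
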