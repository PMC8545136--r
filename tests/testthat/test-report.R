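fake_records <- function(counts, zones = "NUCLEOID_FREE", channel = "red") {
  ids <- rep(seq_along(counts), counts)
  data.frame(cell_id = ids, channel = channel,
             zone = rep_len(zones, length(ids)),
             pair_label = NA_character_)
}

test_that("foci-per-cell means come out as counts over cells", {
  # 62 cells with 2 foci + 90 with 1 = 214 foci over 152 cells
  counts <- c(rep(2, 62), rep(1, 90))
  rec <- fake_records(counts)
  cells <- data.frame(cell_id = seq_along(counts))
  s <- summarize_foci(rec, cells, n_boot = 200, seed = 7)[[1]]
  expect_equal(s$n_foci, 214)
  expect_equal(s$n_cells, 152)
  expect_equal(unname(s$foci_per_cell["mean"]), 214 / 152)
  expect_lt(s$foci_per_cell["lo"], 214 / 152)
  expect_gt(s$foci_per_cell["hi"], 214 / 152)
})

test_that("zone fractions are a simplex and degenerate tables behave", {
  rec <- fake_records(c(2, 1, 3), zones = c("NUCLEOID_FREE"))
  cells <- data.frame(cell_id = 1:3)
  s <- summarize_foci(rec, cells, n_boot = 50)[[1]]
  expect_equal(unname(s$zone_fractions),
               c(0, 0, 1))
  rec2 <- fake_records(c(2, 2), zones = c("NUCLEOID_OVERLAP", "PERIPHERAL",
                                          "NUCLEOID_FREE", "PERIPHERAL"))
  s2 <- summarize_foci(rec2, data.frame(cell_id = 1:2), n_boot = 50)[[1]]
  expect_equal(sum(s2$zone_fractions), 1, tolerance = 1e-9)
})

test_that("the all-cells denominator includes zero-focus cells", {
  rec <- fake_records(c(2, 1))
  cells <- data.frame(cell_id = 1:4) # two cells without foci
  s_all <- summarize_foci(rec, cells, n_boot = 50)[[1]]
  expect_equal(unname(s_all$foci_per_cell["mean"]), 3 / 4)
  s_pos <- summarize_foci(rec, cells, n_boot = 50,
                          denominator = "cells_with_foci")[[1]]
  expect_equal(unname(s_pos$foci_per_cell["mean"]), 3 / 2)
})

test_that("summaries are reproducible and row-order invariant", {
  set.seed(10)
  rec <- fake_records(rpois(40, 1.4) + 1,
                      zones = sample(c("NUCLEOID_FREE", "PERIPHERAL"), 60,
                                     replace = TRUE))
  cells <- data.frame(cell_id = 1:40)
  s1 <- summarize_foci(rec, cells, n_boot = 200, seed = 3)[[1]]
  s2 <- summarize_foci(rec, cells, n_boot = 200, seed = 3)[[1]]
  expect_identical(s1[c("foci_per_cell", "zone_ci")],
                   s2[c("foci_per_cell", "zone_ci")])
  shuffled <- rec[sample(nrow(rec)), ]
  s3 <- summarize_foci(shuffled, cells, n_boot = 200, seed = 3)[[1]]
  expect_identical(s1[c("foci_per_cell", "zone_fractions", "zone_ci")],
                   s3[c("foci_per_cell", "zone_fractions", "zone_ci")])
})

test_that("condition comparison reports percent change with a sane CI", {
  a <- summarize_foci(fake_records(rep(1, 100)),
                      data.frame(cell_id = 1:100), n_boot = 100)[[1]]
  b <- summarize_foci(fake_records(c(rep(2, 30), rep(1, 70))),
                      data.frame(cell_id = 1:100), n_boot = 100)[[1]]
  cmp <- compare_conditions(a, b, n_boot = 400, seed = 2)
  expect_equal(cmp$pct_change, 30)
  same <- compare_conditions(a, a, n_boot = 400, seed = 2)
  expect_equal(same$pct_change, 0)
  expect_lte(same$ci[1], 0)
  expect_gte(same$ci[2], 0)
})

test_that("chromosomal-integration preset recovers the ~30% focus increase", {
  wt <- preset_params("wt_mxylene", field_size = c(200L, 200L), n_cells = 15L)
  pw <- preset_params("paw140_mxylene", field_size = c(200L, 200L),
                      n_cells = 15L)
  count_per_cell <- function(pp, seeds) {
    unlist(lapply(seeds, function(s) {
      f <- generate_field(pp$params, pp$cond, s)
      red <- f$foci[f$foci$channel == "red", ]
      as.integer(table(factor(red$cell_id, levels = f$cells$cell_id)))
    }))
  }
  ca <- count_per_cell(wt, 1:20)  # 300 cells per arm
  cb <- count_per_cell(pw, 21:40)
  a <- summarize_foci(fake_records(ca), data.frame(cell_id = seq_along(ca)),
                      n_boot = 100)[[1]]
  b <- summarize_foci(fake_records(cb), data.frame(cell_id = seq_along(cb)),
                      n_boot = 100)[[1]]
  cmp <- compare_conditions(a, b, n_boot = 1000, seed = 5)
  expect_lte(cmp$ci[1], 30)
  expect_gte(cmp$ci[2], 30)
})

test_that("probe manifests validate sequences and compute lengths", {
  path <- system.file("extdata", "probes_example.csv", package = "tolfish")
  pr <- parse_probe_manifest(path)
  expect_equal(pr$length[pr$probe_id == "tetO_LNA"], 18L)
  expect_true(all(grepl("^[ACGTU]+$", pr$sequence)))
  # lowercase input is uppercased
  lc <- parse_probe_manifest(c("probe_id,sequence,fluorophore,target",
                               "p1,acgt,FAM,demo"))
  expect_identical(lc$sequence, "ACGT")
  expect_equal(lc$length, 4L)
  # invalid alphabet names the row and offending character
  expect_error(parse_probe_manifest(
    c("probe_id,sequence,fluorophore,target", "p1,ACGX,FAM,demo")),
    "row 1.*'X'")
  expect_error(parse_probe_manifest(
    c("probe_id,sequence,fluorophore,target", "p1,,FAM,demo")),
    "empty")
})
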