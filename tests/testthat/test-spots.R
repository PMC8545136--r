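test_that("two rendered spots are found with subpixel accuracy", {
  set.seed(17)
  r <- matrix(100, 31, 31)
  r <- render_spot(r, c(8, 8), 2000, 1.5)
  r <- render_spot(r, c(20, 14), 2000, 1.5)
  r <- apply_noise(r, 0.2, 10) # SNR well above 10
  cell <- full_cell(31, 31)
  f <- detect_foci(normalize_channel(r, cell, keep_outside = TRUE), cell)
  expect_equal(nrow(f), 2)
  for (p in list(c(8, 8), c(20, 14))) {
    d <- sqrt((f$x - p[1])^2 + (f$y - p[2])^2)
    expect_lt(min(d), 0.25)
  }
})

test_that("a zero raster yields no foci and near-duplicates are suppressed", {
  cell <- full_cell(25, 25)
  expect_length(detect_foci(matrix(0, 25, 25), cell)$x, 0)
  r <- matrix(0, 25, 25)
  r <- render_spot(r, c(12, 12), 100, 1.5)
  r <- render_spot(r, c(13, 12), 100, 1.5) # closer than min separation
  f <- detect_foci(normalize_channel(r, cell), cell)
  expect_equal(nrow(f), 1)
})

test_that("centroid refinement reaches 0.1 px on a clean subpixel spot", {
  r <- matrix(0, 41, 31)
  r <- render_spot(r, c(10.3, 20.7), 1, 1.5)
  pos <- refine_centroid(r, c(10, 21), 3)
  expect_lt(sqrt((pos[1] - 10.3)^2 + (pos[2] - 20.7)^2), 0.1)
  # with additive noise (peak SNR 20)
  set.seed(3)
  errs <- replicate(200, {
    rn <- r + matrix(stats::rnorm(41 * 31, 0, 0.05), 41, 31)
    p <- refine_centroid(rn, c(10, 21), 3)
    sqrt((p[1] - 10.3)^2 + (p[2] - 20.7)^2)
  })
  expect_lt(sqrt(mean(errs^2)), 0.1)
})

test_that("centroid refinement degenerate rules hold", {
  r <- matrix(0, 11, 11)
  r[6, 6] <- 1 # 0-based (5, 5)
  expect_equal(refine_centroid(r, c(5, 5), 2), c(5, 5))
  expect_warning(p <- refine_centroid(matrix(0.4, 11, 11), c(4, 6), 2),
                 "uniform")
  expect_equal(p, c(4, 6))
})

test_that("dispersion index separates focal, dispersed and empty cells", {
  cell <- full_cell(21, 21)
  # all signal inside one disc around the focus: FOCAL with fraction ~ 1
  r <- matrix(0, 21, 21)
  r[10:12, 10:12] <- 1
  foci <- data.frame(x = 10, y = 10)
  d <- dispersion_index(r, cell, foci, disc_radius = 3)
  expect_identical(d$pattern, "FOCAL")
  expect_gt(d$focal_fraction, 0.95)
  # uniform in-cell signal, no foci: DISPERSED with fraction 0
  du <- dispersion_index(matrix(0.5, 21, 21), cell, tolfish:::empty_foci())
  expect_identical(du$pattern, "DISPERSED")
  expect_equal(du$focal_fraction, 0)
  # empty raster: NO_SIGNAL
  dn <- dispersion_index(matrix(0, 21, 21), cell, tolfish:::empty_foci())
  expect_identical(dn$pattern, "NO_SIGNAL")
})

test_that("focal fraction decreases as signal spreads from one disc to uniform", {
  # five-point morph of a fixed total intensity, from one diffraction-limited
  # focus to a uniform fill, imaged with the default noise model
  cell <- full_cell(25, 25)
  total <- 2000 * 2 * pi * 1.5^2
  fr <- vapply(seq(1, 0, length.out = 5), function(a) {
    set.seed(50)
    r <- matrix(100, 25, 25)
    if (a > 0) r <- render_spot(r, c(12, 12), a * total / (2 * pi * 1.5^2), 1.5)
    r[cell$mask] <- r[cell$mask] + (1 - a) * total / sum(cell$mask)
    r <- apply_noise(r, 0.2, 10)
    nr <- normalize_channel(r, cell, keep_outside = TRUE)
    dispersion_index(nr, cell, detect_foci(nr, cell),
                     disc_radius = 4.5)$focal_fraction
  }, numeric(1))
  expect_true(all(diff(fr) < 0))
})

test_that("generator dispersion modes are recovered through the pipeline", {
  ap <- analysis_params()
  agree_d <- 0; n_d <- 0; agree_f <- 0; n_f <- 0
  pr <- preset_params("rifampin", field_size = c(160L, 160L), n_cells = 6L)
  pf <- preset_params("wt_mxylene", field_size = c(160L, 160L), n_cells = 6L)
  for (s in 1:4) {
    f <- generate_field(pr$params, pr$cond, s)
    res <- analyze_stack(f$stack, ap, mask = f$mask)
    m <- merge(f$cells[, c("cell_id", "mode")],
               res$dispersion[, c("cell_id", "pattern")], by = "cell_id")
    n_d <- n_d + sum(m$mode == "DISPERSED")
    agree_d <- agree_d + sum(m$mode == "DISPERSED" & m$pattern == "DISPERSED")
    f2 <- generate_field(pf$params, pf$cond, s)
    res2 <- analyze_stack(f2$stack, ap, mask = f2$mask)
    m2 <- merge(f2$cells[, c("cell_id", "mode")],
                res2$dispersion[, c("cell_id", "pattern")], by = "cell_id")
    n_f <- n_f + sum(m2$mode == "FOCAL")
    agree_f <- agree_f + sum(m2$mode == "FOCAL" & m2$pattern == "FOCAL")
  }
  expect_gt(n_d, 15); expect_gt(n_f, 15)
  expect_gte(agree_d / n_d, 0.95)
  expect_gte(agree_f / n_f, 0.95)
})
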