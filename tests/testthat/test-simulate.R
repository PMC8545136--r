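small_params <- function(...) sim_params(field_size = c(160L, 160L),
                                         n_cells = 6L, ...)

test_that("identical seeds give bit-identical fields", {
  pp <- preset_params("wt_mxylene")
  p <- small_params()
  f1 <- generate_field(p, pp$cond, 11)
  f2 <- generate_field(p, pp$cond, 11)
  expect_identical(f1$stack$channels, f2$stack$channels)
  expect_identical(f1$foci, f2$foci)
  expect_identical(f1$cells, f2$cells)
  f3 <- generate_field(p, pp$cond, 12)
  expect_false(identical(f1$stack$channels$red, f3$stack$channels$red))
})

test_that("uninduced cells carry no mRNA signal", {
  f <- generate_field(small_params(), tol_condition("WT_pWW0", "NONE"), 5)
  expect_equal(sum(f$foci$channel == "red"), 0)
  # red channel is background + noise only: no pixel anywhere near spot level
  expect_lt(max(f$stack$channels$red),
            f$params$background + f$params$mrna_amplitude / 2)
  expect_true(all(f$cells$mode == "NO_SIGNAL"))
})

test_that("degenerate zone weights pin every independent focus to that zone", {
  p <- small_params(zone_weights = c(0, 0, 1), pairing_mix = c(0, 0, 1))
  f <- generate_field(p, tol_condition("WT_pWW0", "M_XYLENE"), 7)
  red <- f$foci[f$foci$channel == "red", ]
  expect_gt(nrow(red), 0)
  expect_true(all(red$zone == "FREE"))
})

test_that("every generated focus lies inside its cell mask", {
  f <- generate_field(small_params(), tol_condition("WT_pWW0", "M_XYLENE"), 3)
  for (i in seq_len(nrow(f$foci)))
    expect_equal(f$mask[round(f$foci$y[i]) + 1, round(f$foci$x[i]) + 1],
                 f$foci$cell_id[i])
})

test_that("sample_focus_position honours the zone mixture", {
  nd <- gauss_raster(31, 61, 30, 15, 12, 5)
  cm <- nd > 0.02
  nd[!cm] <- NA
  # degenerate weight: always the dense zone
  for (i in 1:20) {
    dr <- sample_focus_position(cm, nd, c(1, 0, 0))
    expect_identical(dr$zone, "DENSE")
    expect_gte(nd[dr$position["y"] + 1, dr$position["x"] + 1], 0.5)
  }
  # uniform mixture: empirical fractions within the 99% binomial CI of 1/3
  set.seed(99)
  n <- 3000
  zones <- character(n)
  for (i in seq_len(n)) zones[i] <- sample_focus_position(cm, nd, rep(1/3, 3))$zone
  ci <- stats::qbinom(c(0.005, 0.995), n, 1/3) / n
  for (z in c("DENSE", "PERIPHERAL", "FREE")) {
    frac <- mean(zones == z)
    expect_gte(frac, ci[1])
    expect_lte(frac, ci[2])
  }
})

test_that("requesting an empty zone falls back with a warning", {
  nd <- gauss_raster(21, 21, 10, 10, 30) # nearly flat high density: no FREE
  nd <- nd / max(nd)
  cm <- matrix(TRUE, 21, 21)
  expect_warning(dr <- sample_focus_position(cm, nd, c(0, 0, 1)),
                 "empty")
  expect_true(dr$zone %in% c("DENSE", "PERIPHERAL"))
})

test_that("render_spot adds the closed-form Gaussian mass at the right place", {
  r <- matrix(0, 41, 41)
  out <- render_spot(r, c(20.4, 17.8), 100, 1.5)
  added <- sum(out) # 100 * 2 pi * 1.5^2 = 1413.717
  expect_lt(abs(added - 100 * 2 * pi * 1.5^2) / (100 * 2 * pi * 1.5^2), 0.01)
  gx <- outer(rep(1, 41), 0:40); gy <- outer(0:40, rep(1, 41))
  cx <- sum(out * gx) / sum(out); cy <- sum(out * gy) / sum(out)
  expect_lt(abs(cx - 20.4), 0.05)
  expect_lt(abs(cy - 17.8), 0.05)
  expect_identical(render_spot(r, c(20, 20), 0, 1.5), r)
})

test_that("render_dispersed fills uniformly at zero heterogeneity and conserves intensity", {
  r <- matrix(0, 30, 30)
  cm <- matrix(FALSE, 30, 30); cm[8:22, 10:20] <- TRUE
  out0 <- render_dispersed(r, cm, 5000, heterogeneity = 0)
  expect_equal(length(unique(out0[cm])), 1)
  expect_equal(sum(out0[cm]), 5000, tolerance = 1e-9)
  expect_true(all(out0[!cm] == 0))
  set.seed(4)
  out5 <- render_dispersed(r, cm, 5000, heterogeneity = 0.5)
  expect_equal(sum(out5[cm]), 5000, tolerance = 1e-9)
  expect_gt(stats::sd(out5[cm]), 0)
})

test_that("apply_noise is unbiased, clipped, and vanishes in the noiseless limit", {
  r <- matrix(50, 20, 20)
  st <- image_stack(list(red = r), depth = 65535)
  noiseless <- apply_noise(st, photon_scale = 1e7, read_sigma = 0)
  expect_equal(noiseless$channels$red, r, tolerance = 1e-2)
  set.seed(8)
  acc <- 0
  for (i in 1:500) acc <- acc + mean(noisy_mat <- apply_noise(r, 0.2, 10))
  expect_equal(acc / 500, 50, tolerance = 0.01 * 50)
  big <- apply_noise(image_stack(list(red = matrix(65500, 10, 10))), 0.2, 500)
  expect_true(all(big$channels$red >= 0 & big$channels$red <= 65535))
})

test_that("impossible cell placement fails naming the retry budget", {
  p <- sim_params(field_size = c(80L, 80L), n_cells = 60L,
                  max_place_retries = 20L)
  expect_error(generate_field(p, tol_condition("WT_pWW0", "NONE"), 1),
               "max_place_retries|retries")
})

test_that("plasmid focus counts stay in the observed one-to-two range", {
  for (preset in c("wt_mxylene", "t7_iptg")) {
    pp <- preset_params(preset)
    p <- small_params()
    means <- vapply(1:3, function(s) {
      f <- generate_field(p, pp$cond, s)
      g <- f$foci[f$foci$channel == "green", ]
      nrow(g) / nrow(f$cells)
    }, numeric(1))
    expect_true(all(means >= 1 & means <= 2), label = preset)
  }
})

test_that("generated zone truth matches contour classification on the noiseless channel", {
  pp <- preset_params("wt_mxylene")
  f <- generate_field(small_params(), pp$cond, 21)
  cells <- segment_cells(NULL, mask = f$mask)
  want <- c(DENSE = "NUCLEOID_OVERLAP", PERIPHERAL = "PERIPHERAL",
            FREE = "NUCLEOID_FREE")
  for (cell in cells) {
    nd <- normalize_channel(f$noiseless_dapi, cell)
    z <- nucleoid_zones(nd, cell, 0.5, 0.2)
    fo <- f$foci[f$foci$cell_id == cell$id, ]
    for (i in seq_len(nrow(fo)))
      expect_identical(classify_focus_zone(list(x = fo$x[i], y = fo$y[i]), z),
                       unname(want[fo$zone[i]]))
  }
})
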