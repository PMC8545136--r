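make_zones <- function() {
  nd <- gauss_raster(41, 61, 30, 20, 10, 6)
  nucleoid_zones(nd, full_cell(41, 61))
}

test_that("zone classification follows the dense/diffuse/free partition", {
  z <- make_zones()
  expect_identical(classify_focus_zone(list(x = 30, y = 20), z),
                   "NUCLEOID_OVERLAP")
  expect_identical(classify_focus_zone(list(x = 2, y = 2), z),
                   "NUCLEOID_FREE")
  # a point between the two levels
  expect_identical(classify_focus_zone(list(x = 30 + 10 * 1.4, y = 20), z),
                   "PERIPHERAL")
  # no contours at all: free, with a warning
  empty <- structure(list(cell_id = 9, dense = list(), diffuse = list()),
                     class = "nucleoid_zones")
  expect_warning(out <- classify_focus_zone(list(x = 1, y = 1), empty),
                 "no nucleoid")
  expect_identical(out, "NUCLEOID_FREE")
})

test_that("classification agrees with a ray-casting oracle on random points", {
  z <- make_zones()
  set.seed(5)
  for (i in 1:1000) {
    x <- runif(1, 0, 60); y <- runif(1, 0, 40)
    got <- classify_focus_zone(list(x = x, y = y), z)
    want <- if (in_any_polygon(x, y, z$dense)) "NUCLEOID_OVERLAP"
            else if (in_any_polygon(x, y, z$diffuse)) "PERIPHERAL"
            else "NUCLEOID_FREE"
    expect_identical(got, want)
  }
})

test_that("band-mode peripheral classification uses distance to the dense contour", {
  z <- make_zones()
  # just outside the dense contour (semi-axis ~ 10*sqrt(2 ln 2) = 11.8 px)
  expect_identical(classify_focus_zone(list(x = 30 + 13.5, y = 20), z,
                                       mode = "band", band_width = 3),
                   "PERIPHERAL")
  expect_identical(classify_focus_zone(list(x = 58, y = 2), z,
                                       mode = "band", band_width = 3),
                   "NUCLEOID_FREE")
})

test_that("region overlap handles identity, disjoint and half-overlap exactly", {
  sq <- rect_contour(0, 0, 1, 1)
  expect_equal(region_overlap(list(sq), list(sq)), 1.0)
  far <- rect_contour(5, 5, 6, 6)
  expect_equal(region_overlap(list(sq), list(far)), 0.0)
  half <- rect_contour(0.5, 0, 1.5, 1)
  expect_equal(region_overlap(list(sq), list(half)), 0.5, tolerance = 1e-6)
  # degenerate: zero-area A
  degen <- rect_contour(0, 0, 0, 1)
  expect_true(is.na(region_overlap(list(degen), list(sq))))
  # jaccard option
  expect_equal(region_overlap(list(sq), list(half), denom = "jaccard"),
               0.5 / 1.5, tolerance = 1e-6)
})

test_that("region overlap matches supersampled rasterization on random polygons", {
  set.seed(12)
  for (i in 1:20) {
    A <- list(random_star_polygon(sample(6:12, 1), 10, 10, 3, 8))
    B <- list(random_star_polygon(sample(6:12, 1), runif(1, 8, 14),
                                  runif(1, 8, 14), 3, 8))
    got <- region_overlap(A, B)
    oracle <- supersample_overlap(A, B, factor = 10)
    expect_lt(abs(got - oracle), 0.02)
  }
})

test_that("region overlap is invariant under joint rigid motion", {
  set.seed(23)
  rot <- function(ct, th, dx, dy) {
    v <- ct$vertices
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    w <- t(R %*% t(v)) + matrix(c(dx, dy), nrow(v), 2, byrow = TRUE)
    structure(list(vertices = w, level = ct$level, area = ct$area),
              class = "tol_contour")
  }
  for (i in 1:5) {
    A <- list(random_star_polygon(8, 10, 10, 3, 7))
    B <- list(random_star_polygon(8, 13, 11, 3, 7))
    base <- region_overlap(A, B)
    th <- runif(1, 0, 2 * pi); dx <- runif(1, -5, 5); dy <- runif(1, -5, 5)
    moved <- region_overlap(lapply(A, rot, th, dx, dy),
                            lapply(B, rot, th, dx, dy))
    expect_equal(moved, base, tolerance = 1e-6)
  }
})

test_that("pairing labels follow the distance bands", {
  red <- data.frame(x = 10, y = 10)
  expect_identical(
    pair_mrna_plasmid(red, data.frame(x = 10.5, y = 10), 2, 8)$pair_label,
    "COLOCALIZED")
  pr <- pair_mrna_plasmid(red, data.frame(x = 14, y = 10), 2, 8)
  expect_identical(pr$pair_label, "ADJACENT")
  expect_equal(pr$distance, 4.0)
  expect_identical(
    pair_mrna_plasmid(red, data.frame(x = 30, y = 10), 2, 8)$pair_label,
    "SEPARATE")
  # greedy: the closer red focus takes the single plasmid
  red2 <- data.frame(x = c(10, 13), y = c(10, 10))
  pr2 <- pair_mrna_plasmid(red2, data.frame(x = 12.5, y = 10), 2, 8)
  expect_identical(pr2$pair_label, c("SEPARATE", "COLOCALIZED"))
})

test_that("pairing recovers the generator's realized pairing mix", {
  pp <- preset_params("wt_mxylene")
  conf <- matrix(0, 3, 3,
                 dimnames = list(c("COLOCALIZED", "ADJACENT", "INDEPENDENT"),
                                 c("COLOCALIZED", "ADJACENT", "SEPARATE")))
  for (s in 1:10) {
    f <- generate_field(pp$params, pp$cond, s)
    for (cid in unique(f$foci$cell_id)) {
      r <- f$foci[f$foci$cell_id == cid & f$foci$channel == "red", ]
      g <- f$foci[f$foci$cell_id == cid & f$foci$channel == "green", ]
      if (!nrow(r)) next
      pr <- pair_mrna_plasmid(r, g)
      for (i in seq_len(nrow(r)))
        conf[r$pair_label[i], pr$pair_label[i]] <-
          conf[r$pair_label[i], pr$pair_label[i]] + 1
    }
  }
  n <- sum(conf)
  expect_gte(n, 300)
  truth_frac <- rowSums(conf) / n
  est_frac <- colSums(conf) / n
  for (i in 1:3) {
    ci <- stats::qbinom(c(0.025, 0.975), n, truth_frac[i]) / n
    expect_gte(est_frac[i], ci[1])
    expect_lte(est_frac[i], ci[2])
  }
  expect_gte(sum(diag(conf)) / n, 0.85) # per-focus label agreement
})

test_that("line profiles normalize per channel and track geometry", {
  # constant channel: relative intensity 1 everywhere
  st <- list(red = matrix(3, 21, 21))
  pr <- line_profile(st, c(2, 10), c(18, 10))
  expect_true(all(pr$red == 1))
  expect_true(all(diff(pr$distance) > 0))
  # linear ramp along x sampled by a horizontal arrow stays linear
  ramp <- outer(rep(1, 21), 0:20) + 0
  pr2 <- line_profile(list(g = ramp), c(2, 5), c(12, 5), width = 1)
  want <- (2 + pr2$distance) / 12
  expect_lt(max(abs(pr2$g - want)), 1e-6)
  # peak of a profile through a rendered spot projects to the spot centroid
  r <- matrix(0, 31, 31)
  r <- render_spot(r, c(15.3, 10.2), 100, 1.5)
  pr3 <- line_profile(list(red = r), c(5, 10.2), c(25, 10.2),
                      samples_per_px = 8)
  peak_d <- pr3$distance[which.max(pr3$red)]
  expect_lt(abs(peak_d - 10.3), 0.5)
  expect_error(line_profile(st, c(3, 3), c(3, 3)), "zero-length")
})

test_that("zone categories partition the red foci of a cell", {
  pp <- preset_params("wt_mxylene", field_size = c(160L, 160L), n_cells = 6L)
  f <- generate_field(pp$params, pp$cond, 2)
  res <- analyze_stack(f$stack, analysis_params(), mask = f$mask)
  red <- res$records[res$records$channel == "red", ]
  expect_true(all(red$zone %in% c("NUCLEOID_OVERLAP", "PERIPHERAL",
                                  "NUCLEOID_FREE")))
  for (cid in unique(red$cell_id)) {
    sub <- red[red$cell_id == cid, ]
    expect_equal(sum(table(sub$zone)), nrow(sub))
  }
})
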