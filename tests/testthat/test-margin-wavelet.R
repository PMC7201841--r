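# Wavelet gradient, orientation entropy, valley segmentation and the
# area / erosion-thickness features.

make_map <- function(z, spacing = 2.5e-5) height_map(z, spacing)

test_that("derivative wavelets annihilate constant surfaces", {
  hm <- make_map(matrix(3.7, 32, 32))
  g <- cwt_gradient(hm, 5e-5)
  expect_equal(g$wx, matrix(0, 32, 32), tolerance = 1e-15)
  expect_equal(g$wy, matrix(0, 32, 32), tolerance = 1e-15)
})

test_that("wavelet gradient of a ramp matches direct quadrature", {
  sp <- 2.5e-5
  hm <- make_map(matrix(rep(seq_len(32), each = 32) * sp, 32, 32), sp)  # f = x
  g <- cwt_gradient(hm, 5e-5)
  for (pt in list(c(14, 14), c(16, 20), c(20, 16), c(15, 18), c(18, 15))) {
    o <- quadrature_cwt(hm, 5e-5, pt[1L], pt[2L])
    expect_lt(abs(g$wx[pt[1L], pt[2L]] - o["wx"]), 1e-6 * max(abs(o["wx"]), 1e-12))
    expect_lt(abs(g$wy[pt[1L], pt[2L]] - o["wy"]), 1e-12)
  }
  # interior response is one constant (~ -2*pi*a^2 under the 1/a form)
  interior <- g$wx[10:23, 10:23]
  expect_lt(diff(range(interior)), 1e-6 * abs(mean(interior)))
})

test_that("the wavelet transform is linear in the surface", {
  set.seed(31)
  f <- matrix(rnorm(1024), 32, 32)
  g <- matrix(rnorm(1024), 32, 32)
  a <- cwt_gradient(make_map(f), 5e-5)
  b <- cwt_gradient(make_map(g), 5e-5)
  ab <- cwt_gradient(make_map(f + g), 5e-5)
  expect_equal(ab$wx, a$wx + b$wx, tolerance = 1e-10)
  expect_equal(ab$wy, a$wy + b$wy, tolerance = 1e-10)
})

test_that("scales whose kernel exceeds the grid are rejected", {
  hm <- make_map(matrix(0, 16, 16))
  expect_error(cwt_gradient(hm, 1e-3), "support")
  expect_error(cwt_gradient(hm, -1), "positive")
})

test_that("orientation entropy hits its limit cases", {
  # identical directions -> single occupied bin -> entropy 0
  fld <- structure(list(wx = matrix(1, 16, 16), wy = matrix(0.5, 16, 16),
                        scale = 1), class = "gradient_field")
  em <- orientation_entropy(fld, window = 5, bins = 36, mag_floor = 0)
  expect_equal(em$E, matrix(0, 16, 16))
  # every clipped window of a 2x2 field holds the 4 cardinal directions
  # exactly once: equal counts over B = 4 bins -> ln 4 everywhere
  ang <- matrix(c(0, pi / 2, pi, 3 * pi / 2), 2, 2)
  fld4 <- structure(list(wx = cos(ang), wy = sin(ang), scale = 1),
                    class = "gradient_field")
  em4 <- orientation_entropy(fld4, window = 3, bins = 4, mag_floor = 0)
  expect_equal(em4$E, matrix(log(4), 2, 2), tolerance = 1e-12)
  # zero-magnitude windows get entropy 0
  fld0 <- structure(list(wx = matrix(0, 16, 16), wy = matrix(0, 16, 16),
                         scale = 1), class = "gradient_field")
  expect_equal(orientation_entropy(fld0, 5, 36, mag_floor = 1)$E,
               matrix(0, 16, 16))
})

test_that("entropy of uniform random angles approaches ln(bins)", {
  set.seed(77)
  n <- 100L                                  # 100x100 grid, window 101 illegal;
  ang <- matrix(stats::runif(n * n, -pi, pi), n, n)
  fld <- structure(list(wx = cos(ang), wy = sin(ang), scale = 1),
                   class = "gradient_field")
  # one pixel's window of 99x99 = 9801 ~ 10^4 i.i.d. angles
  em <- orientation_entropy(fld, window = 99, bins = 36, mag_floor = 0)
  expect_lt(abs(em$E[50, 50] - log(36)), 0.02)
})

test_that("entropy is bounded by [0, ln(bins)] on arbitrary fields", {
  set.seed(5)
  for (rep in 1:5) {
    fld <- structure(list(wx = matrix(rnorm(400), 20, 20),
                          wy = matrix(rnorm(400), 20, 20), scale = 1),
                     class = "gradient_field")
    em <- orientation_entropy(fld, window = 5, bins = 12)
    expect_true(all(em$E >= 0))
    expect_true(all(em$E <= log(12) + 1e-12))
  }
})

test_that("valley segmentation obeys its threshold limit cases", {
  p <- default_dimorphism_params("male", noise_sd = 0)
  hm <- generate_margin_surface(p, 1)
  em <- orientation_entropy(cwt_gradient(hm, 5e-5))
  expect_false(any(segment_valley(hm, em, th = 2, te = log(36) + 1)$mask))
  expect_true(all(segment_valley(hm, em, th = Inf, te = 0)$mask))
})

test_that("valley mask equals the per-pixel predicate", {
  p <- default_dimorphism_params("female", noise_sd = 0)
  hm <- generate_margin_surface(p, 1)
  em <- orientation_entropy(cwt_gradient(hm, 5e-5))
  vf <- segment_valley(hm, em, th = 2, te = 0.8)
  rel <- hm$heights - craniosex:::.reference_plane(hm$heights)
  for (i in seq(1, 64, by = 7)) for (j in seq(1, 64, by = 7))
    expect_identical(vf$mask[i, j], rel[i, j] <= 2 && em$E[i, j] >= 0.8)
})

test_that("valley area is an exact pixel count", {
  expect_identical(valley_area(matrix(FALSE, 5, 5)), 0L)
  expect_identical(valley_area(matrix(TRUE, 7, 7)), 49L)
  set.seed(3)
  m <- matrix(runif(100) > 0.5, 10, 10)
  count <- 0L
  for (i in 1:10) for (j in 1:10) if (m[i, j]) count <- count + 1L
  expect_identical(valley_area(m), count)
})

test_that("erosion thickness matches step-by-step erosion", {
  expect_identical(valley_thickness(matrix(FALSE, 5, 5)), 0L)
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_identical(valley_thickness(single), 1L)
  solid <- matrix(FALSE, 11, 11); solid[3:9, 3:9] <- TRUE   # 7x7 square
  expect_identical(valley_thickness(solid), 4L)             # 7->5->3->1->0
  # independent oracle: erode manually with the same 3x3 square element
  manual <- function(mask) {
    n <- 0L
    while (any(mask)) {
      nxt <- matrix(FALSE, nrow(mask), ncol(mask))
      for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
        nb <- TRUE
        for (di in -1:1) for (dj in -1:1) {
          ii <- i + di; jj <- j + dj
          inside <- ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask)
          if (!inside || !mask[ii, jj]) nb <- FALSE
        }
        nxt[i, j] <- nb
      }
      mask <- nxt; n <- n + 1L
    }
    n
  }
  set.seed(21)
  blob <- matrix(runif(144) > 0.35, 12, 12)
  expect_identical(valley_thickness(blob), manual(blob))
})

test_that("margin features echo their configuration and vanish on flat input", {
  cfg <- margin_config()
  expect_equal(cfg$th, 2)
  expect_equal(cfg$te, 0.8)
  expect_equal(cfg$scale, 5e-5)
  flat <- make_map(matrix(1, 32, 32))
  f <- extract_margin_features(flat)
  expect_identical(f$area, 0L)
  expect_identical(f$thickness, 0L)
  expect_equal(f$config$th, 2)
})

test_that("sharp female-template margins are thinner than blunt male ones", {
  fm <- extract_margin_features(
    generate_margin_surface(default_dimorphism_params("male", 0), 1))
  ff <- extract_margin_features(
    generate_margin_surface(default_dimorphism_params("female", 0), 1))
  expect_lt(ff$thickness, fm$thickness)
  expect_lt(ff$area, fm$area)
})

test_that("whole-pixel translation shifts the entropy map identically", {
  p <- default_dimorphism_params("male", noise_sd = 0)
  z <- margin_template(p)
  k <- 3L
  z_shift <- rbind(z[(k + 1):64, ], z[1:k, ])       # shift up by k rows
  E1 <- orientation_entropy(cwt_gradient(make_map(z), 5e-5))$E
  E2 <- orientation_entropy(cwt_gradient(make_map(z_shift), 5e-5))$E
  guard <- 14L                                      # kernel + window support
  rows <- (guard + 1L):(64L - guard - k)
  expect_equal(E2[rows, (guard + 1L):(64L - guard)],
               E1[rows + k, (guard + 1L):(64L - guard)], tolerance = 1e-12)
})

test_that("area and thickness are invariant to 90-degree rotation", {
  p <- default_dimorphism_params("female", noise_sd = 0)
  z <- margin_template(p)
  rot90 <- t(z)[, rev(seq_len(nrow(z)))]            # counter-clockwise
  f1 <- extract_margin_features(make_map(z))
  f2 <- extract_margin_features(make_map(rot90))
  expect_identical(f1$area, f2$area)
  expect_identical(f1$thickness, f2$thickness)
})

test_that("valley area is monotone in the segmentation thresholds", {
  p <- default_dimorphism_params("male")
  hm <- generate_margin_surface(p, 6)
  em <- orientation_entropy(cwt_gradient(hm, 5e-5))
  areas_th <- vapply(1:4, function(th)
    valley_area(segment_valley(hm, em, th, 0.8)), integer(1L))
  expect_true(all(diff(areas_th) >= 0))
  areas_te <- vapply(c(0.5, 0.6, 0.7, 0.8), function(te)
    valley_area(segment_valley(hm, em, 2, te)), integer(1L))
  expect_true(all(diff(areas_te) <= 0))
})
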