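PSZ600 <- 25.4 / 600

test_that("measure_particle: calibrated square and single pixel", {
  m <- matrix(0L, 14, 14); m[3:12, 3:12] <- 1L
  rec <- measure_single(m)
  expect_equal(rec$Area, 100 * PSZ600^2)
  expect_equal(rec$Width, 10 * PSZ600)
  expect_equal(rec$Height, 10 * PSZ600)
  expect_equal(rec$Perim, 40 * PSZ600)
  expect_equal(rec$Feret, sqrt(200) * PSZ600)
  expect_equal(rec$MinFeret, 10 * PSZ600)
  expect_identical(rec$Solidity, 1)
  expect_equal(rec$Circ, pi / 4)
  expect_equal(rec$X, rec$Y)
  expect_true(rec$Width * rec$Height >= rec$Area)
  expect_true(is.na(rec$Skew) && is.na(rec$Kurt))  # binary scan

  single <- matrix(0L, 3, 3); single[2, 2] <- 1L
  rs <- measure_single(single)
  expect_equal(rs$Area, PSZ600^2)
  expect_equal(rs$Perim, 4 * PSZ600)
  expect_identical(rs$Solidity, 1)
  expect_equal(rs$Feret, sqrt(2) * PSZ600)
  expect_equal(rs$MinFeret, PSZ600)
})

test_that("digital disk: area within 1.5% of pi r^2, crack perimeter ~ 8r", {
  r <- 20
  rec <- measure_single(disk_mask(r))
  # rasterization oracle: area = count of pixel centers inside the circle
  expect_identical(as.integer(round(rec$Area / PSZ600^2)), sum(disk_mask(r)))
  expect_lt(abs(rec$Area / (pi * r^2 * PSZ600^2) - 1), 0.015)
  # the crack boundary of a disk has L1 length ~ 8r, hence Circ ~ pi^2/16,
  # a documented divergence from smooth-perimeter estimators
  expect_lt(abs(rec$Perim / (8 * r * PSZ600) - 1), 0.03)
  expect_lt(abs(rec$Circ - pi^2 / 16), 0.05)
  expect_true(rec$Circ > 0 && rec$Circ <= 1)
  expect_identical(rec$Angle, 0)          # isotropic degeneracy rule
  expect_lt(abs(rec$AR - 1), 0.01)
})

test_that("fit_ellipse: moment oracle on rectangles, angle convention", {
  # axis-aligned 40x10 rectangle: exact unit-square moments give AR = 4
  m <- matrix(0L, 20, 50); m[6:15, 6:45] <- 1L
  rec <- measure_single(m)
  expect_identical(rec$Angle, 0)
  expect_lt(abs(rec$AR - 4), 4 * 0.02)
  # moment oracle by direct summation over pixel centers + 1/12
  xs <- rep(1:40, each = 10); ys <- rep(1:10, 40)
  oracle_ar <- sqrt((mean((xs - mean(xs))^2) + 1 / 12) /
                    (mean((ys - mean(ys))^2) + 1 / 12))
  expect_equal(rec$AR, oracle_ar)
  rec90 <- measure_single(t(m))
  expect_identical(rec90$Angle, 90)
  expect_equal(rec90$Major, rec$Major)

  # ellipse area matches particle area => Round * AR = 1
  expect_equal(rec$Major * rec$Minor * pi / 4, rec$Area)
  expect_equal(rec$Round * rec$AR, 1, tolerance = 1e-15)
})

test_that("feret_diameters equals brute-force oracles on 100 random polygons", {
  set.seed(61)
  for (i in 1:100) {
    b <- random_boundary(sample(6:12, 1))
    fer <- feret_diameters(b)
    expect_equal(fer$feret, feret_oracle(b), tolerance = 1e-9)
    expect_equal(fer$min_feret, min_feret_oracle(b), tolerance = 1e-9)
    expect_true(fer$min_feret <= fer$feret + 1e-12)
    expect_true(fer$feret_angle >= 0 && fer$feret_angle < 180)
  }
})

test_that("feret chord bookkeeping is deterministic on ties", {
  m <- matrix(0L, 14, 14); m[3:12, 3:12] <- 1L   # both diagonals tie
  p <- label_particles(m, 0, 1)[[1]]
  fer <- feret_diameters(p$boundary)
  expect_identical(as.numeric(c(fer$feret_x, fer$feret_y)), c(2, 2))
  expect_equal(fer$feret_angle, 135)
})

test_that("shape_ratios formulas and clamp", {
  r <- 3
  sr <- shape_ratios(pi * r^2, 2 * pi * r, 2 * r, 2 * r, pi * r^2)
  expect_equal(sr$circ, 1, tolerance = 1e-15)         # analytic circle
  expect_equal(shape_ratios(4, 8, 2, 2, 4)$circ, pi / 4)  # square s=2
  sr2 <- shape_ratios(2 * pi, 10, 4, 2, 2 * pi)
  expect_equal(sr2$ar, 2)
  expect_equal(sr2$round, 0.5)
  expect_equal(sr2$round * sr2$ar, 1, tolerance = 1e-15)
  expect_identical(shape_ratios(100, 10, 2, 1, 100)$circ, 1)  # clamped
  expect_error(shape_ratios(0, 1, 1, 1, 1), "positive")
})

test_that("intensity statistics: sums, median, zero-variance rule", {
  g <- matrix(255L, 8, 8)
  g[4, 3:5] <- c(10L, 20L, 40L)
  img <- scan_image(g, 600)
  p <- label_particles(matrix(as.integer(g < 255), 8, 8), 0, 1)[[1]]
  st <- intensity_stats(p, img)
  expect_identical(st$raw_int_den, 70)
  expect_equal(st$median, 20)
  expect_equal(st$int_den, (70 / 3) * 3 * PSZ600^2)

  # constant intensity: weighted centroid equals geometric centroid
  flat <- scan_image(matrix(255L, 8, 8), 600)
  stf <- intensity_stats(p, flat)
  expect_true(is.na(stf$skew) && is.na(stf$kurt))
  rec <- measure_particle(p, flat)
  expect_equal(rec$XM, rec$X)
  expect_equal(rec$YM, rec$Y)
  expect_identical(rec$RawIntDen, 255 * 3)
})

test_that("scale equivariance: doubling dpi halves lengths, quarters areas", {
  # same physical 2 mm radius disk rasterized at 300 and 600 dpi
  mk <- function(dpi) {
    r_px <- 2 / (25.4 / dpi)
    side <- ceiling(2 * r_px + 6)
    col <- matrix(rep(seq_len(side), each = side), side)
    row <- matrix(rep(seq_len(side), side), side)
    c0 <- side / 2
    m <- matrix(as.integer((col - c0)^2 + (row - c0)^2 <= r_px^2), side, side)
    measure_single(m, dpi = dpi)
  }
  lo <- mk(300); hi <- mk(600)
  expect_equal(hi$Area, lo$Area, tolerance = 0.02)
  expect_equal(hi$Feret, lo$Feret, tolerance = 0.02)
  expect_equal(hi$MinFeret, lo$MinFeret, tolerance = 0.02)
  for (col in c("Circ", "AR", "Round", "Solidity"))
    expect_equal(hi[[col]], lo[[col]], tolerance = 0.02)
})

test_that("rotation robustness: Area, Feret, AR stable across 0/37/90 deg", {
  id <- list(species = "x", body_length = 4, aspect = 2, wing_fraction = 1,
             wing_width = 1, wing_asymmetry = 0.2, damaged = FALSE,
             bite_angle = 0, bite_radius = 0)
  ras <- seedmorph:::rasterize_silhouette
  recs <- lapply(c(0, 37, 90) * pi / 180, function(th)
    measure_single(ras(id, th, FALSE, 600)))
  for (col in c("Area", "Feret", "AR")) {
    v <- vapply(recs, `[[`, 0, col)
    expect_lt(diff(range(v)) / mean(v), 0.03)
  }
})

test_that("axis-aligned rectangles have Solidity exactly 1", {
  for (dims in list(c(3, 7), c(10, 10), c(1, 12))) {
    m <- matrix(0L, dims[1] + 4, dims[2] + 4)
    m[3:(2 + dims[1]), 3:(2 + dims[2])] <- 1L
    expect_identical(measure_single(m)$Solidity, 1)
  }
})
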