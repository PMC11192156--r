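test_that("binarize handles binary, bimodal, and degenerate images", {
  mask <- matrix(0L, 6, 6); mask[2:4, 2:4] <- 1L
  img <- bilevel_scan(mask)
  expect_identical(binarize(img, "none"), mask)

  # perfectly bimodal 8-bit histogram: otsu keeps exactly the dark level
  g <- matrix(220L, 30, 30); g[10:20, 10:20] <- 40L
  got <- binarize(scan_image(g, 600), "otsu")
  expect_identical(got, matrix(as.integer(g == 40L), 30, 30))

  # constant image -> all background (degenerate histogram rule)
  expect_true(all(binarize(scan_image(matrix(77L, 9, 9), 600), "otsu") == 0L))
  expect_true(all(binarize(scan_image(matrix(0L, 4, 4), 600), "none") == 0L))

  # fixed threshold, polarity-adjusted
  expect_identical(binarize(scan_image(g, 600), 40), got)
  inv <- scan_image(255L - g, 600, polarity = "light_on_dark")
  expect_identical(binarize(inv, "otsu"), got)

  expect_error(binarize(scan_image(matrix(0:24, 5, 5), 600), "none"), "binary")
  expect_error(binarize(img, "mystery"), "unknown")
})

test_that("otsu threshold maximizes between-class variance (exhaustive oracle)", {
  set.seed(21)
  for (i in 1:20) {
    counts <- rpois(16, lambda = sample(1:30, 1))
    if (sum(counts > 0) < 2) next
    bcv <- sapply(0:14, function(t) {
      n0 <- sum(counts[1:(t + 1)]); n1 <- sum(counts) - n0
      if (n0 == 0 || n1 == 0) return(-Inf)
      mu0 <- sum((0:t) * counts[1:(t + 1)]) / n0
      mu1 <- sum((15:(t + 1)) * counts[16:(t + 2)]) / n1
      n0 * n1 * (mu0 - mu1)^2
    })
    expect_identical(otsu_threshold(counts), as.integer(which.max(bcv) - 1L))
  }
})

test_that("label_particles filters debris, fills holes, orders canonically", {
  mask <- matrix(0L, 12, 12)
  mask[2:6, 2:6] <- 1L; mask[4, 4] <- 0L      # 24 px + 1 px hole -> 25
  mask[9:11, 8:10] <- 1L                       # 9 px
  mask[1, 12] <- 1L                            # 1 px speck
  parts <- label_particles(mask, min_area_mm2 = 5, pixel_mm = 1)
  expect_length(parts, 2L)
  expect_identical(vapply(parts, function(p) p$n_px, 0L), c(25L, 9L))
  expect_identical(vapply(parts, function(p) p$label_id, 0L), 1:2)
  # top-to-bottom then left-to-right by bbox origin
  expect_true(parts[[1]]$bbox[["y0"]] < parts[[2]]$bbox[["y0"]])
  expect_length(label_particles(matrix(0L, 5, 5), 0, 1), 0L)
})

test_that("labeling matches a brute-force flood-fill oracle (incl. 20/9/4 toy)", {
  toy <- matrix(0L, 12, 12)
  toy[2:6, 2:5] <- 1L                          # 20 px
  toy[8:10, 2:4] <- 1L                         # 9 px
  toy[9:10, 9:10] <- 1L                        # 4 px
  parts <- label_particles(toy, min_area_mm2 = 5, pixel_mm = 1)
  expect_identical(sort(vapply(parts, function(p) p$n_px, 0L)), c(9L, 20L))
  oracle <- flood_components_oracle(toy)
  expect_identical(sort(tabulate(oracle[oracle > 0])), c(4L, 9L, 20L))

  set.seed(31)
  for (i in 1:15) {
    m <- matrix(rbinom(100, 1L, 0.45), 10, 10)
    parts <- label_particles(m, min_area_mm2 = 0, pixel_mm = 1)
    lab <- flood_components_oracle(seedmorph:::.fill_holes(m))
    expect_identical(sort(vapply(parts, function(p) p$n_px, 0L)),
                     sort(tabulate(lab[lab > 0])))
  }
})

test_that("crack boundaries are exact: shoelace area equals pixel count", {
  # unit square
  p1 <- label_particles(diag(1L), 0, 1)[[1]]
  expect_identical(dim(p1$boundary), c(4L, 2L))
  expect_equal(seedmorph:::shoelace_area(p1$boundary), 1)
  expect_equal(seedmorph:::polygon_perimeter(p1$boundary), 4)

  # 2x3 rectangle, perimeter 10
  m <- matrix(0L, 5, 6); m[2:3, 2:4] <- 1L
  p <- label_particles(m, 0, 1)[[1]]
  expect_equal(seedmorph:::polygon_perimeter(p$boundary), 10)
  expect_equal(seedmorph:::shoelace_area(p$boundary), 6)

  # L-pentomino: 5 px, 12-edge rectilinear outline
  L <- matrix(0L, 6, 6); L[2:5, 2] <- 1L; L[5, 3] <- 1L
  pL <- label_particles(L, 0, 1)[[1]]
  expect_equal(seedmorph:::shoelace_area(pL$boundary), 5)
  expect_equal(seedmorph:::polygon_perimeter(pL$boundary), 12)

  # edge-walk oracle: perimeter equals the count of fg/bg pixel-edge pairs
  set.seed(41)
  for (i in 1:20) {
    m <- matrix(rbinom(81, 1L, 0.5), 9, 9)
    parts <- label_particles(m, 0, 1)
    total <- sum(vapply(parts, function(p)
      seedmorph:::polygon_perimeter(p$boundary), 0))
    filled <- seedmorph:::.fill_holes(m)
    expect_equal(total, crack_edge_count_oracle(filled))
    for (p in parts)
      expect_equal(seedmorph:::shoelace_area(p$boundary), p$n_px)
  }
})

test_that("mask pixel accounting: components partition the filled mask", {
  set.seed(51)
  m <- matrix(rbinom(400, 1L, 0.35), 20, 20)
  filled <- seedmorph:::.fill_holes(m)
  parts <- label_particles(m, min_area_mm2 = 0, pixel_mm = 1)
  expect_identical(sum(vapply(parts, function(p) p$n_px, 0L)), sum(filled))
  # with a size filter, kept + removed = total
  parts3 <- label_particles(m, min_area_mm2 = 3, pixel_mm = 1)
  removed <- sum(vapply(parts, function(p) p$n_px, 0L)[
    vapply(parts, function(p) p$n_px, 0L) < 3])
  expect_identical(sum(vapply(parts3, function(p) p$n_px, 0L)) + removed,
                   sum(filled))
})

test_that("labeling order is canonical regardless of construction order", {
  a <- matrix(0L, 10, 10); a[7:9, 2:4] <- 1L; a[2:3, 6:9] <- 1L
  b <- matrix(0L, 10, 10); b[2:3, 6:9] <- 1L; b[7:9, 2:4] <- 1L
  pa <- label_particles(a, 0, 1); pb <- label_particles(b, 0, 1)
  expect_identical(lapply(pa, function(p) p$pixels),
                   lapply(pb, function(p) p$pixels))
})
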