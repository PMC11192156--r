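# Morphometry: the full per-particle descriptor vector, in calibrated units.
# Lengths and areas are reported in mm / mm^2 via the scan dpi; the Feret
# start coordinates stay in pixel-corner units (positional bookkeeping).

# angle of direction (dx, dy-image-down), mathematical y-up, in [0, 180)
axis_angle_deg <- function(dx, dy_down) {
  a <- atan2(-dy_down, dx) * 180 / pi
  a <- a %% 180
  if (a >= 180) a <- a - 180
  a
}

#' Fit an ellipse to a particle by second moments
#'
#' Axes come from the eigen-decomposition of the second central moments of
#' the pixel set (each pixel treated as a unit square, adding 1/12 per axis),
#' then both axes are rescaled by a common factor so the ellipse area
#' `pi * Major/2 * Minor/2` equals the particle's pixel area. This makes
#' `Round = Minor/Major` the exact inverse of the aspect ratio.
#'
#' @param particle A `particle`.
#' @param pixel_mm Pixel size in mm (default 1 = report in pixel units).
#' @return List with `major`, `minor` (full axis lengths, calibrated) and
#'   `angle` (degrees in `[0, 180)`, counter-clockwise from the image x-axis
#'   with y flipped to mathematical orientation; 0 for an isotropic particle).
#' @export
fit_ellipse <- function(particle, pixel_mm = 1) {
  px <- particle$pixels
  n <- nrow(px)
  xc <- px[, 2] + 0.5
  yc <- px[, 1] + 0.5
  mx <- mean(xc); my <- mean(yc)
  # population central moments of a union of unit squares
  cxx <- sum((xc - mx)^2) / n + 1 / 12
  cyy <- sum((yc - my)^2) / n + 1 / 12
  cxy <- sum((xc - mx) * (yc - my)) / n
  tr <- cxx + cyy
  disc <- sqrt(max(0, (cxx - cyy)^2 + 4 * cxy^2))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  semi1 <- 2 * sqrt(l1)
  semi2 <- 2 * sqrt(max(l2, 0))
  scale <- sqrt(n / (pi * semi1 * semi2))
  angle <- if (disc < 1e-12 * tr) 0 else {
    # eigenvector of the largest eigenvalue
    if (abs(cxy) > 1e-300) axis_angle_deg(l1 - cyy, cxy)
    else if (cxx >= cyy) 0 else 90
  }
  list(major = 2 * semi1 * scale * pixel_mm,
       minor = 2 * semi2 * scale * pixel_mm,
       angle = angle)
}

#' Feret (caliper) diameters of a boundary polygon
#'
#' Maximum Feret diameter is the largest pairwise distance between convex
#' hull vertices; the minimum Feret diameter is the smallest width over hull
#' edges, found by rotating calipers.
#'
#' @param boundary m x 2 matrix of `(x, y)` boundary vertices (pixel-corner
#'   coordinates).
#' @param pixel_mm Pixel size in mm (default 1 = pixel units) applied to the
#'   `feret` and `min_feret` lengths; `feret_x`/`feret_y` stay in pixels.
#' @return List with `feret`, `feret_angle` (degrees in `[0, 180)`, y-up),
#'   `feret_x`, `feret_y` (starting corner of the maximal chord: of its two
#'   endpoints, the one with the smaller y, ties broken by smaller x), and
#'   `min_feret`.
#' @export
feret_diameters <- function(boundary, pixel_mm = 1) {
  hull <- boundary[chull(boundary[, 1], boundary[, 2]), , drop = FALSE]
  h <- nrow(hull)
  if (h == 1L) stop("degenerate boundary: a crack polygon has >= 4 vertices")
  x <- hull[, 1]; y <- hull[, 2]
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  dmax <- max(d2)
  cand <- which(d2 >= dmax * (1 - 1e-12), arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  # deterministic chord among ties: order each pair's endpoints by (y, x),
  # then pick the pair with the lexicographically smallest (start, end) key
  best <- NULL
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (y[j] < y[i] || (y[j] == y[i] && x[j] < x[i])) { tmp <- i; i <- j; j <- tmp }
    k <- c(y[i], x[i], y[j], x[j])
    if (is.null(best) || .lex_less(k, best$k)) best <- list(i = i, j = j, k = k)
  }
  i <- best$i; j <- best$j
  feret <- sqrt(dmax)
  # min width by rotating calipers: for each hull edge, the max distance of
  # any vertex from the edge's supporting line
  if (h == 2L) {
    min_feret <- 0
  } else {
    widths <- vapply(seq_len(h), function(e) {
      e2 <- if (e == h) 1L else e + 1L
      ex <- x[e2] - x[e]; ey <- y[e2] - y[e]
      len <- sqrt(ex^2 + ey^2)
      if (len == 0) return(Inf)
      max(abs((x - x[e]) * ey - (y - y[e]) * ex)) / len
    }, 0)
    min_feret <- min(widths)
  }
  list(feret = feret * pixel_mm,
       feret_angle = axis_angle_deg(x[j] - x[i], y[j] - y[i]),
       feret_x = x[i], feret_y = y[i],
       min_feret = min_feret * pixel_mm)
}

.lex_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' Dimensionless shape ratios
#'
#' Circularity `4*pi*Area/Perim^2` (clamped at 1: the crack-boundary
#' perimeter overestimates smooth outlines, so rasterized disks can exceed 1
#' slightly), aspect ratio `Major/Minor`, roundness (the inverse aspect
#' ratio, equivalently `4*Area/(pi*Major^2)` for the area-matched ellipse
#' fit), and solidity `Area/ConvexArea`.
#'
#' @param area,perim,major,minor,hull_area Positive scalars in consistent
#'   units.
#' @return List with `circ`, `ar`, `round`, `solidity`.
#' @examples
#' r <- 3
#' shape_ratios(pi * r^2, 2 * pi * r, 2 * r, 2 * r, pi * r^2)$circ  # exactly 1
#' @export
shape_ratios <- function(area, perim, major, minor, hull_area) {
  vals <- c(area, perim, major, minor, hull_area)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all shape-ratio inputs must be positive and finite")
  list(circ = min(1, 4 * pi * area / perim^2),
       ar = major / minor,
       round = minor / major,
       solidity = area / hull_area)
}

#' Intensity statistics of a particle
#'
#' @param particle A `particle`.
#' @param image The [scan_image()] the particle came from.
#' @return List with `raw_int_den` (sum of intensities), `int_den` (mean
#'   intensity times calibrated area), `median`, `skew` and `kurt` (third and
#'   fourth standardized central moments, excess kurtosis; `NA` when the
#'   intensity variance is zero, as on binary scans), and the
#'   intensity-weighted centroid `xm`, `ym` in mm (equal to the geometric
#'   centroid when all intensities are zero).
#' @export
intensity_stats <- function(particle, image) {
  px <- particle$pixels
  vals <- image$pixels[px + 1L]  # (row, col) 0-based -> R matrix indexing
  n <- length(vals)
  pmm <- pixel_size_mm(image$dpi)
  s <- sum(as.numeric(vals))
  m <- s / n
  v <- sum((vals - m)^2) / n
  if (v > 0) {
    skew <- sum((vals - m)^3) / n / v^1.5
    kurt <- sum((vals - m)^4) / n / v^2 - 3
  } else skew <- kurt <- NA_real_
  w <- if (s > 0) vals / s else rep(1 / n, n)
  list(raw_int_den = s,
       int_den = m * n * pmm^2,
       median = median(vals),
       skew = skew, kurt = kurt,
       xm = sum(w * (px[, 2] + 0.5)) * pmm,
       ym = sum(w * (px[, 1] + 0.5)) * pmm)
}

#' Measure one particle
#'
#' Computes the full descriptor vector for a segmented particle: calibrated
#' area and perimeter, centroids, bounding box, fitted-ellipse axes and
#' angle, circularity, Feret diameters, integrated densities, median
#' intensity, skewness/kurtosis (missing on binary scans), aspect ratio,
#' roundness and solidity.
#'
#' @param particle A `particle` from [label_particles()].
#' @param image The [scan_image()] it was segmented from.
#' @return One-row `data.frame` with the columns listed in
#'   `MEASUREMENT_COLUMNS` plus `tag`.
#' @export
measure_particle <- function(particle, image) {
  stopifnot(inherits(particle, "particle"), inherits(image, "scan_image"))
  pmm <- pixel_size_mm(image$dpi)
  px <- particle$pixels
  n <- particle$n_px
  area <- n * pmm^2
  bnd <- particle$boundary
  perim <- polygon_perimeter(bnd) * pmm
  hull <- bnd[chull(bnd[, 1], bnd[, 2]), , drop = FALSE]
  hull_area <- abs(shoelace_area(hull)) * pmm^2
  ell <- fit_ellipse(particle, pixel_mm = pmm)
  fer <- feret_diameters(bnd, pixel_mm = pmm)
  ints <- intensity_stats(particle, image)
  sr <- shape_ratios(area, perim, ell$major, ell$minor, hull_area)
  data.frame(
    Area = area,
    X = (mean(px[, 2]) + 0.5) * pmm,
    Y = (mean(px[, 1]) + 0.5) * pmm,
    XM = ints$xm, YM = ints$ym,
    Perim = perim,
    BX = particle$bbox[["x0"]] * pmm, BY = particle$bbox[["y0"]] * pmm,
    Width = particle$bbox[["w"]] * pmm, Height = particle$bbox[["h"]] * pmm,
    Major = ell$major, Minor = ell$minor, Angle = ell$angle,
    Circ = sr$circ,
    Feret = fer$feret, IntDen = ints$int_den, Median = ints$median,
    Skew = ints$skew, Kurt = ints$kurt, RawIntDen = ints$raw_int_den,
    FeretX = fer$feret_x, FeretY = fer$feret_y,
    FeretAngle = fer$feret_angle, MinFeret = fer$min_feret,
    AR = sr$ar, Round = sr$round, Solidity = sr$solidity,
    tag = particle$source_tag,
    stringsAsFactors = FALSE)
}

#' Segment and measure a whole scan
#'
#' @inheritParams segment_scan
#' @return `data.frame` of one [measure_particle()] row per particle (zero
#'   rows for a blank scan), in particle label order.
#' @export
measure_scan <- function(image, method = "otsu", min_area_mm2 = 0.2) {
  parts <- segment_scan(image, method = method, min_area_mm2 = min_area_mm2)
  if (length(parts) == 0L) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(MEASUREMENT_COLUMNS)),
                                  MEASUREMENT_COLUMNS))
    out$tag <- character(0)
    return(out)
  }
  do.call(rbind, lapply(parts, measure_particle, image = image))
}
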